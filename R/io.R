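#' Read genomic intervals in the BED dialects the pipeline uses
#'
#' Parses plain-text interval files into tibbles with 0-based half-open
#' coordinates. Supported dialects:
#' \describe{
#'   \item{`bed3`}{`chrom start end`}
#'   \item{`bed6`}{`chrom start end name score strand`}
#'   \item{`state_bed`}{`chrom start end state` -- chromatin-state label in
#'     the fourth column}
#'   \item{`motif_bed`}{BED6 with the motif/TF name in `name` and an
#'     informative strand}
#'   \item{`bedpe`}{paired intervals, 6 or 10 columns
#'     (`chromA startA endA chromB startB endB [name score strandA strandB]`)}
#' }
#'
#' @param path File path.
#' @param dialect One of `"bed3"`, `"bed6"`, `"state_bed"`, `"motif_bed"`,
#'   `"bedpe"`.
#' @return A tibble; for `bedpe`, one row per pair with `_a`/`_b` suffixed
#'   coordinate columns.
#' @export
read_intervals <- function(path, dialect = c("bed3", "bed6", "state_bed",
                                             "motif_bed", "bedpe")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n_fields <- switch(dialect, bed3 = 3L, bed6 = 6L, state_bed = 4L,
                     motif_bed = 6L, bedpe = c(6L, 10L))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_intervals(dialect))
  }
  fields <- stringr::str_split(lines, "\t")
  len <- lengths(fields)
  bad <- which(!len %in% n_fields)
  if (length(bad) > 0) {
    stop("parse error at line ", bad[1], " of ", path, ": expected ",
         paste(n_fields, collapse = " or "), " tab-separated fields, found ",
         len[bad[1]], call. = FALSE)
  }
  if (dialect == "bedpe") {
    wide <- len[1] == 10L
    if (!all(len == len[1])) {
      stop("parse error in ", path, ": mixed 6- and 10-column BEDPE records",
           call. = FALSE)
    }
    m <- do.call(rbind, fields)
    out <- tibble::tibble(
      chrom_a = m[, 1], start_a = parse_coord(m[, 2], path, "startA"),
      end_a = parse_coord(m[, 3], path, "endA"),
      chrom_b = m[, 4], start_b = parse_coord(m[, 5], path, "startB"),
      end_b = parse_coord(m[, 6], path, "endB")
    )
    if (wide) {
      out$name <- m[, 7]
      out$score <- as.numeric(m[, 8])
      out$strand_a <- m[, 9]
      out$strand_b <- m[, 10]
    }
    check_pair_intervals(out, path)
    return(out)
  }
  m <- do.call(rbind, fields)
  out <- tibble::tibble(
    chrom = m[, 1],
    start = parse_coord(m[, 2], path, "start"),
    end = parse_coord(m[, 3], path, "end")
  )
  if (dialect == "state_bed") out$state <- m[, 4]
  if (dialect %in% c("bed6", "motif_bed")) {
    out$name <- m[, 4]
    out$score <- as.numeric(m[, 5])
    out$strand <- m[, 6]
  }
  bad <- which(out$start < 0 | out$end <= out$start)
  if (length(bad) > 0) {
    stop("parse error at line ", bad[1], " of ", path, ": invalid interval [",
         out$start[bad[1]], ",", out$end[bad[1]], ")", call. = FALSE)
  }
  if ("strand" %in% names(out)) {
    bad <- which(!out$strand %in% c("+", "-", "."))
    if (length(bad) > 0) {
      stop("parse error at line ", bad[1], " of ", path, ": bad strand '",
           out$strand[bad[1]], "'", call. = FALSE)
    }
  }
  out
}

parse_coord <- function(x, path, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    stop("parse error at line ", bad[1], " of ", path, ": non-integer ",
         what, " '", x[bad[1]], "'", call. = FALSE)
  }
  v
}

check_pair_intervals <- function(x, path) {
  bad <- which(x$start_a < 0 | x$end_a <= x$start_a |
                 x$start_b < 0 | x$end_b <= x$start_b)
  if (length(bad) > 0) {
    stop("parse error at line ", bad[1], " of ", path,
         ": invalid interval in BEDPE record", call. = FALSE)
  }
  invisible(x)
}

empty_intervals <- function(dialect) {
  if (dialect == "bedpe") {
    return(tibble::tibble(chrom_a = character(), start_a = integer(),
                          end_a = integer(), chrom_b = character(),
                          start_b = integer(), end_b = integer()))
  }
  out <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  if (dialect == "state_bed") out$state <- character()
  if (dialect %in% c("bed6", "motif_bed")) {
    out$name <- character(); out$score <- numeric(); out$strand <- character()
  }
  out
}

#' Write interval or matrix tables back to their plain-text formats
#'
#' The writers are exact inverses of [read_intervals()] and
#' [read_matrix_tsv()]: a written file read back yields the same records
#' field-for-field.
#'
#' @param x Tibble of records consistent with `dialect`.
#' @param path Output path.
#' @param dialect As in [read_intervals()].
#' @export
write_intervals <- function(x, path, dialect = c("bed3", "bed6", "state_bed",
                                                 "motif_bed", "bedpe")) {
  dialect <- match.arg(dialect)
  cols <- switch(dialect,
    bed3 = c("chrom", "start", "end"),
    state_bed = c("chrom", "start", "end", "state"),
    bed6 = c("chrom", "start", "end", "name", "score", "strand"),
    motif_bed = c("chrom", "start", "end", "name", "score", "strand"),
    bedpe = {
      base <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b")
      if (all(c("name", "score", "strand_a", "strand_b") %in% names(x))) {
        c(base, "name", "score", "strand_a", "strand_b")
      } else base
    }
  )
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop("write_intervals: records lack column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @param id_col Name of the identifier column written first.
#' @export
write_matrix_tsv <- function(x, path, id_col = names(x)[1]) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_matrix_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a sample sheet
#'
#' The sample sheet maps each sequencing library to its cell type,
#' replicate index, biological group (`blood`, `embryonic` or `solid`),
#' processing batch and unique-PET depth.
#'
#' @param path TSV with named columns `sample_id`, `cell_type`, `replicate`,
#'   `group`, `batch`, `depth`.
#' @return Validated tibble.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(x)
}

validate_sample_sheet <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("sample_id", "cell_type", "replicate", "group", "batch", "depth")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("sample sheet: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x[, c("cell_type", "replicate")])) {
    stop("sample sheet: (cell_type, replicate) pairs must be unique",
         call. = FALSE)
  }
  g <- dplyr::distinct(x, .data$cell_type, .data$group)
  if (anyDuplicated(g$cell_type)) {
    stop("sample sheet: a cell type maps to more than one group", call. = FALSE)
  }
  x
}
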