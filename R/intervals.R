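#' Genomic interval tables
#'
#' `loopvar` represents genomic features as plain tibbles in BED convention:
#' 0-based, half-open `[start, end)` coordinates with columns `chrom`,
#' `start`, `end` and optionally `name`, `score` and `strand`. All interval
#' arithmetic is delegated to \pkg{GenomicRanges}/\pkg{IRanges}; these
#' helpers convert between the two representations and enforce the
#' invariants (`start >= 0`, `end > start`, strand in `+`/`-`/`.`).
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @param context A string used in error messages.
#' @return `as_track()` returns the input as a validated tibble sorted by
#'   `(chrom, start, end)`.
#' @export
as_track <- function(x, context = "track") {
  x <- tibble::as_tibble(x)
  required <- c("chrom", "start", "end")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(context, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_intervals(x, context = context)
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

validate_intervals <- function(x, context = "track") {
  bad <- which(x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    stop(context, ": invalid interval at row ", bad[1],
         " (start=", x$start[bad[1]], ", end=", x$end[bad[1]],
         "); need start >= 0 and end > start", call. = FALSE)
  }
  if ("strand" %in% names(x)) {
    ok <- x$strand %in% c("+", "-", ".")
    if (!all(ok)) {
      stop(context, ": invalid strand '", x$strand[which(!ok)[1]],
           "' at row ", which(!ok)[1], call. = FALSE)
    }
  }
  invisible(x)
}

#' @rdname as_track
#' @export
track_to_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand == ".", "*", x$strand)
  } else {
    "*"
  }
  # BED half-open -> GRanges 1-based closed
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

granges_to_track <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Merge overlapping intervals
#'
#' Collapses overlapping (or near-adjacent, within `gap` bp) intervals into
#' disjoint intervals spanning their union, the standard peak-merging step
#' used when pooling per-sample peak calls into one anchor set.
#'
#' @param track Interval tibble (see [as_track()]).
#' @param gap Maximum gap (bp) between intervals that are still merged.
#'   `gap = 0` merges touching-or-overlapping intervals only.
#' @return A tibble of disjoint intervals covering the same bases.
#' @export
merge_intervals <- function(track, gap = 0) {
  track <- as_track(track, "merge_intervals")
  if (nrow(track) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::reduce(track_to_granges(track), min.gapwidth = gap + 1L,
                              ignore.strand = TRUE)
  dplyr::arrange(granges_to_track(gr), .data$chrom, .data$start, .data$end)
}

#' Overlap join between two interval tables
#'
#' Reports every pair of intervals (one from `query`, one from `subject`)
#' on the same chromosome that share at least `min_overlap` bases under
#' half-open coordinates. Row indices refer to the inputs *after* sorting
#' by `(chrom, start, end)` is NOT applied -- indices are positions in the
#' tables as given.
#'
#' @param query,subject Interval tibbles.
#' @param min_overlap Minimum shared bases (default 1).
#' @return Tibble with columns `query_idx`, `subject_idx`.
#' @export
overlap_join <- function(query, subject, min_overlap = 1) {
  validate_intervals(tibble::as_tibble(query), "overlap_join query")
  validate_intervals(tibble::as_tibble(subject), "overlap_join subject")
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble::tibble(query_idx = integer(), subject_idx = integer()))
  }
  # disjoint seqlevel sets are a legitimate no-overlap case, not a problem
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    track_to_granges(query), track_to_granges(subject),
    minoverlap = min_overlap, ignore.strand = TRUE
  ))
  out <- tibble::tibble(
    query_idx = S4Vectors::queryHits(hits),
    subject_idx = S4Vectors::subjectHits(hits)
  )
  dplyr::arrange(out, .data$query_idx, .data$subject_idx)
}

#' Which intervals overlap any interval of another track?
#'
#' @inheritParams overlap_join
#' @return Logical vector along `query` rows.
#' @export
overlaps_any <- function(query, subject, min_overlap = 1) {
  query <- tibble::as_tibble(query)
  out <- rep(FALSE, nrow(query))
  if (nrow(query) == 0 || nrow(subject) == 0) return(out)
  hits <- overlap_join(query, subject, min_overlap = min_overlap)
  out[unique(hits$query_idx)] <- TRUE
  out
}
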