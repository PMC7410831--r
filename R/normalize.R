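# Accepts a tibble whose first column is an id (or a column named
# loop_id/gene_id/...) with numeric sample columns, or a plain matrix.
as_id_matrix <- function(x, context = "matrix") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
    return(x)
  }
  x <- tibble::as_tibble(x)
  id_col <- names(x)[1]
  num <- vapply(x, is.numeric, logical(1))
  num[1] <- FALSE
  m <- as.matrix(x[, num])
  rownames(m) <- as.character(x[[id_col]])
  m
}

matrix_to_tibble <- function(m, id_name = "loop_id") {
  dplyr::bind_cols(
    tibble::tibble(!!id_name := rownames(m)),
    tibble::as_tibble(m)
  )
}

#' Keep loops testable for cross-cell-type variability
#'
#' Retains rows whose maximum count over samples is at least `min_pets`
#' (by default 4 PETs in at least one sample).
#'
#' @param M Interaction matrix: tibble with an id column first, or matrix.
#' @param min_pets Threshold (default 4).
#' @return Same representation as the input, filtered.
#' @export
filter_testable <- function(M, min_pets = 4) {
  m <- as_id_matrix(M)
  keep <- apply(m, 1, max) >= min_pets
  if (is.matrix(M)) M[keep, , drop = FALSE] else M[keep, ]
}

#' Drop rows that cannot be z-scored
#'
#' Rows with zero variance across samples cannot be row-standardized and
#' must be removed before [normalize_matrix()]. The number removed is
#' reported via a message.
#'
#' @inheritParams filter_testable
#' @return Filtered input.
#' @export
drop_invariant_rows <- function(M) {
  m <- as_id_matrix(M)
  sds <- apply(m, 1, stats::sd)
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    message("drop_invariant_rows: removed ", sum(drop),
            " zero-variance row(s)")
  }
  if (is.matrix(M)) M[!drop, , drop = FALSE] else M[!drop, ]
}

#' Normalize the interaction matrix
#'
#' Three steps, in order: (1) each row is standardized to mean 0, sd 1;
#' (2) columns are quantile-normalized so that every column shares one
#' multiset of values (ties receive the mean of the reference values at
#' their tied ranks); (3) each column is affinely rescaled to the range
#' 0 to 1000.
#'
#' @param M Interaction matrix (tibble with id column, or matrix) with at
#'   least 2 columns and no zero-variance rows (see
#'   [drop_invariant_rows()]).
#' @return Normalized matrix in the input's representation.
#' @export
normalize_matrix <- function(M) {
  m <- as_id_matrix(M)
  if (ncol(m) < 2) stop("normalize_matrix: need >= 2 samples", call. = FALSE)
  sds <- apply(m, 1, stats::sd)
  if (any(is.na(sds) | sds == 0)) {
    stop("normalize_matrix: ", sum(is.na(sds) | sds == 0),
         " zero-variance row(s); filter with drop_invariant_rows() first",
         call. = FALSE)
  }
  z <- t(scale(t(m)))
  qn <- limma::normalizeQuantiles(z, ties = TRUE)
  rng <- apply(qn, 2, range)
  scaled <- sweep(sweep(qn, 2, rng[1, ], "-"), 2,
                  rng[2, ] - rng[1, ], "/") * 1000
  scaled <- matrix(scaled, nrow = nrow(m), ncol = ncol(m),
                   dimnames = dimnames(m))
  if (is.matrix(M)) scaled else matrix_to_tibble(scaled, names(M)[1])
}

#' Mean-variance precision weights
#'
#' Estimates the mean-variance trend of the log-counts with the voom
#' method (a lowess fit of sqrt residual standard deviation against mean
#' log2 count, with cell type as the design) and returns the inverse
#' variance weights, one per observation. With fewer than `min_rows` rows
#' the trend cannot be estimated reliably and unit weights are returned
#' with a warning.
#'
#' @param M_raw Filtered raw count matrix (tibble with id column, or
#'   matrix).
#' @param samples Sample sheet aligned to the matrix columns.
#' @param min_rows Minimum rows required to fit the trend.
#' @return Numeric weight matrix (all entries > 0) aligned to the input.
#' @export
voom_weights <- function(M_raw, samples, min_rows = 50) {
  m <- as_id_matrix(M_raw)
  samples <- samples[match(colnames(m), samples$sample_id), ]
  if (nrow(m) < min_rows) {
    warning("voom_weights: fewer than ", min_rows,
            " rows; returning unit weights")
    w <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
    return(w)
  }
  design <- stats::model.matrix(~ 0 + factor(samples$cell_type))
  v <- limma::voom(m, design = design)
  w <- v$weights
  dimnames(w) <- dimnames(m)
  w
}
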