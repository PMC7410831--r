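#' Relative entropy of a non-negative profile
#'
#' \eqn{RE = \sum_j f_j \log_2(f_j / q_j)} in bits, where `f` is the
#' vector rescaled to sum to 1 and `q` the reference distribution (uniform
#' by default, the null of equal counts in every sample);
#' \eqn{0 \log 0 := 0}. Bounded by \eqn{[0, \log_2 J]} for `J` entries
#' under the uniform reference and invariant to rescaling of the input.
#'
#' @param values Non-negative numeric vector with positive sum.
#' @param reference Optional reference probabilities (defaults uniform).
#' @return Relative entropy in bits.
#' @export
relative_entropy <- function(values, reference = NULL) {
  if (any(is.na(values)) || any(values < 0)) {
    stop("relative_entropy: values must be non-negative", call. = FALSE)
  }
  tot <- sum(values)
  if (tot <= 0) stop("relative_entropy: all-zero input", call. = FALSE)
  f <- values / tot
  q <- if (is.null(reference)) rep(1 / length(f), length(f))
       else reference / sum(reference)
  nz <- f > 0
  sum(f[nz] * log2(f[nz] / q[nz]))
}

row_relative_entropy <- function(m) {
  apply(m, 1, function(x) {
    if (all(x == 0)) NA_real_ else relative_entropy(x)
  })
}

#' Select non-variable ("static") control loops
#'
#' Two modes:
#' \describe{
#'   \item{`score_ranked`}{each loop gets a static score, mean PET
#'     frequency divided by its relative entropy across samples (a high
#'     score means strong, uniform interaction). Loops with zero relative
#'     entropy rank above all others, ordered by mean frequency; remaining
#'     ties break by loop id. The top `|variable set|` loops are
#'     returned.}
#'   \item{`matched`}{samples, deterministically under `seed`, a set the
#'     same size as the variable set from candidates with variability
#'     q > 0.5, matching the variable set's joint distribution over span
#'     deciles and loop-score p-value deciles.}
#' }
#'
#' @param M Raw count matrix of the tested loops (tibble or matrix).
#' @param variability A [test_variability()] result (used for the variable
#'   set and, in matched mode, the q > 0.5 candidate pool).
#' @param loop_scores Loop-score tibble with `p` per loop (matched mode).
#' @param spans Named numeric vector of loop spans (matched mode); names
#'   are loop ids.
#' @param mode `"score_ranked"` or `"matched"`.
#' @param seed Seed for matched sampling.
#' @return Character vector of selected loop ids (attributes carry the
#'   per-loop static scores in `score_ranked` mode).
#' @export
static_sets <- function(M, variability, loop_scores = NULL, spans = NULL,
                        mode = c("score_ranked", "matched"), seed = 1L) {
  mode <- match.arg(mode)
  m <- as_id_matrix(M)
  var_ids <- variability$loop_id[variability$variable]
  n_take <- length(var_ids)
  if (n_take == 0) return(character())

  if (mode == "score_ranked") {
    re <- row_relative_entropy(m)
    mean_freq <- rowMeans(m)
    score <- ifelse(is.na(re), 0, ifelse(re == 0, Inf, mean_freq / re))
    ord <- order(-is.infinite(score), -ifelse(is.infinite(score),
                                              mean_freq, score),
                 rownames(m))
    out <- rownames(m)[ord][seq_len(min(n_take, nrow(m)))]
    attr(out, "static_score") <- stats::setNames(score, rownames(m))
    return(out)
  }

  if (is.null(loop_scores) || is.null(spans)) {
    stop("static_sets: matched mode needs loop_scores and spans",
         call. = FALSE)
  }
  ids <- rownames(m)
  qv <- variability$q[match(ids, variability$loop_id)]
  p_loop <- loop_scores$p[match(ids, as.character(loop_scores$loop_id))]
  span <- spans[ids]
  span_dec <- cut_decile(span)
  p_dec <- cut_decile(p_loop)
  stratum <- paste(span_dec, p_dec, sep = ":")
  is_var <- ids %in% var_ids
  cand <- !is_var & !is.na(qv) & qv > 0.5
  need <- table(stratum[is_var])
  set.seed(as.integer(seed))
  picked <- character()
  deficits <- character()
  for (s in names(need)) {
    pool <- ids[cand & stratum == s]
    k <- need[[s]]
    if (length(pool) < k) {
      deficits <- c(deficits, paste0(s, " (need ", k, ", have ",
                                     length(pool), ")"))
    } else {
      picked <- c(picked, sample(pool, k))
    }
  }
  if (length(deficits) > 0) {
    stop("static_sets: matched sampling infeasible in strata: ",
         paste(deficits, collapse = "; "), call. = FALSE)
  }
  picked
}

cut_decile <- function(x) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, 0.1), na.rm = TRUE))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Classify genes as housekeeping or cell-type-specific by expression
#' entropy
#'
#' Ranks genes by the relative entropy of their expression profile across
#' cell types. The top `tail` fraction is called cell-type-specific; the
#' bottom of the ranking, restricted to genes whose minimum expression
#' exceeds `min_expr_tpm` in every cell type, is called housekeeping. Both
#' sets have size `floor(tail * n_ranked)` and are disjoint.
#'
#' @param expression Tibble `gene_id` + one column per cell type (TPM), or
#'   matrix. Average replicates first (see [average_by_cell_type()]).
#' @param min_expr_tpm Housekeeping minimum-expression filter.
#' @param tail Fraction for each tail.
#' @return List with `cell_type_specific`, `housekeeping` (character id
#'   vectors) and `entropy` (tibble `gene_id`, `relative_entropy`,
#'   `mean_expr`).
#' @export
classify_genes_entropy <- function(expression, min_expr_tpm = 1,
                                   tail = 0.10) {
  m <- as_id_matrix(expression)
  expressed <- rowSums(m) > 0
  m <- m[expressed, , drop = FALSE]
  if (nrow(m) < 10) {
    stop("classify_genes_entropy: fewer than 10 usable genes", call. = FALSE)
  }
  re <- row_relative_entropy(m)
  n_take <- floor(tail * nrow(m))
  ord <- order(-re, rownames(m))
  cts <- rownames(m)[ord][seq_len(n_take)]
  passes_min <- apply(m, 1, min) > min_expr_tpm
  hk_pool <- rownames(m)[order(re, rownames(m))]
  hk_pool <- hk_pool[passes_min[hk_pool] & !hk_pool %in% cts]
  hk <- hk_pool[seq_len(min(n_take, length(hk_pool)))]
  list(
    cell_type_specific = cts,
    housekeeping = hk,
    entropy = tibble::tibble(gene_id = rownames(m), relative_entropy = re,
                             mean_expr = rowMeans(m))
  )
}

#' Average matrix columns by cell type
#'
#' @param M Tibble with id column + sample columns, or matrix.
#' @param samples Sample sheet mapping `sample_id` to `cell_type`.
#' @return Matrix with one column per cell type.
#' @export
average_by_cell_type <- function(M, samples) {
  m <- as_id_matrix(M)
  ct <- samples$cell_type[match(colnames(m), samples$sample_id)]
  out <- sapply(unique(ct), function(c) {
    rowMeans(m[, ct == c, drop = FALSE])
  })
  rownames(out) <- rownames(m)
  out
}
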