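# Vectorised Welch t-statistic per row: group 1 columns vs group 2 columns.
row_welch_t <- function(m, idx1, idx2, pooled = FALSE) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(m[, idx1, drop = FALSE])
  m2 <- rowMeans(m[, idx2, drop = FALSE])
  v1 <- rowSums((m[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((m[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se <- if (pooled) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    sqrt(sp * (1 / n1 + 1 / n2))
  } else {
    sqrt(v1 / n1 + v2 / n2)
  }
  d <- m1 - m2
  ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
}

new_specific_set <- function(kind, target, members, stats, top_frac) {
  structure(
    list(kind = kind, target = target, members = members,
         statistics = stats, top_frac = top_frac),
    class = "specific_set"
  )
}

#' @export
print.specific_set <- function(x, ...) {
  cat("<specific_set> ", x$kind, " specific to ", x$target, ": ",
      length(x$members), " members (top ", 100 * x$top_frac, "%)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.specific_set <- function(x, ...) {
  dplyr::mutate(x$statistics,
                member = .data$id %in% x$members,
                kind = x$kind, target = x$target)
}

# Rank ids by statistic descending, ties broken by id ascending, and take
# the top floor(top_frac * N).
top_ranked <- function(ids, t_stat, top_frac) {
  ord <- order(-t_stat, ids)
  ids[ord][seq_len(floor(top_frac * length(ids)))]
}

#' Call cell-type-specific entities by t-statistic ranking
#'
#' Computes, for every entity (loop, enhancer or gene), a Welch
#' t-statistic comparing the query cell type's samples against all other
#' samples pooled, ranks the statistics in descending order (ties broken
#' by entity id) and returns the top `floor(top_frac * N)` entities.
#'
#' @param M Entity-by-sample matrix (tibble with id column, or matrix) of
#'   normalized values (interaction frequency, enhancer signal or
#'   expression).
#' @param samples Sample sheet aligned to columns.
#' @param query_cell Cell type of interest.
#' @param top_frac Fraction of entities returned (default 0.10).
#' @param kind Entity kind label (`"loop"`, `"enhancer"`, `"gene"`).
#' @param pooled Use the pooled-variance t instead of Welch.
#' @return A `specific_set` object.
#' @export
celltype_specific <- function(M, samples, query_cell, top_frac = 0.10,
                              kind = "loop", pooled = FALSE) {
  m <- as_id_matrix(M)
  samples <- samples[match(colnames(m), samples$sample_id), ]
  idx1 <- which(samples$cell_type == query_cell)
  if (length(idx1) == 0) {
    stop("celltype_specific: cell type '", query_cell,
         "' absent from sample sheet", call. = FALSE)
  }
  idx2 <- which(samples$cell_type != query_cell)
  if (length(idx1) < 2 || length(idx2) < 2) {
    stop("celltype_specific: need >= 2 samples on each side", call. = FALSE)
  }
  t_stat <- row_welch_t(m, idx1, idx2, pooled = pooled)
  members <- top_ranked(rownames(m), t_stat, top_frac)
  new_specific_set(kind, query_cell, members,
                   tibble::tibble(id = rownames(m), t = t_stat), top_frac)
}

#' Call group-specific entities by three-way t-statistic set algebra
#'
#' For a query group g against the two other groups o1 and o2 (ordered
#' alphabetically), three Welch t-statistics are computed per entity:
#' t1 (g vs o1), t2 (g vs o2) and t3 (o1 vs o2). With T_k the top
#' `floor(top_frac * N)` entities by each statistic (descending), the
#' group-specific set is \eqn{(T_1 \cap T_2) \setminus T_3}: high in the
#' query group relative to both others, with no difference between the
#' others.
#'
#' @inheritParams celltype_specific
#' @param group_labels Groups to call (default: all groups in the sheet).
#' @return Named list of `specific_set` objects, one per group.
#' @export
group_specific <- function(M, samples, group_labels = NULL, top_frac = 0.10,
                           kind = "loop", pooled = FALSE) {
  m <- as_id_matrix(M)
  samples <- samples[match(colnames(m), samples$sample_id), ]
  groups <- sort(unique(samples$group))
  if (length(groups) < 3) {
    stop("group_specific: need 3 groups", call. = FALSE)
  }
  if (is.null(group_labels)) group_labels <- groups
  ids <- rownames(m)
  out <- lapply(group_labels, function(g) {
    others <- sort(setdiff(groups, g))
    iq <- which(samples$group == g)
    i1 <- which(samples$group == others[1])
    i2 <- which(samples$group == others[2])
    t1 <- row_welch_t(m, iq, i1, pooled = pooled)
    t2 <- row_welch_t(m, iq, i2, pooled = pooled)
    t3 <- row_welch_t(m, i1, i2, pooled = pooled)
    T1 <- top_ranked(ids, t1, top_frac)
    T2 <- top_ranked(ids, t2, top_frac)
    T3 <- top_ranked(ids, t3, top_frac)
    members <- setdiff(intersect(T1, T2), T3)
    new_specific_set(kind, g, members,
                     tibble::tibble(id = ids, t1 = t1, t2 = t2, t3 = t3),
                     top_frac)
  })
  names(out) <- group_labels
  out
}

#' Cell-type-specific enhancers or genes
#'
#' The same ranking machinery as [celltype_specific()], applied to a
#' normalized enhancer (H3K27ac) signal matrix or a gene expression
#' matrix. The study uses top 10% for enhancers and genes, widened to 20%
#' for the enhancer/promoter pair-type analysis.
#'
#' @inheritParams celltype_specific
#' @param kind `"enhancer"` or `"gene"`.
#' @return A `specific_set` object.
#' @export
specific_features_for <- function(M, samples, query_cell, top_frac = 0.10,
                                  kind = c("enhancer", "gene"),
                                  pooled = FALSE) {
  kind <- match.arg(kind)
  celltype_specific(M, samples, query_cell, top_frac = top_frac,
                    kind = kind, pooled = pooled)
}
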