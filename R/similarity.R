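#' Pairwise sample similarity of interaction profiles
#'
#' Spearman rank correlation between raw PET counts for every pair of
#' samples, plus rank-sum comparisons of the correlation distributions
#' between sample groupings. Default groupings: `all` (pairs of samples
#' from different cell types), `same_group` (different cell types within
#' one biological group), and `replicates` (same cell type). Each
#' grouping other than `all` is compared against `all` with a two-sided
#' Wilcoxon rank-sum test, Bonferroni-adjusted.
#'
#' @param M Raw filtered count matrix (tibble or matrix).
#' @param samples Sample sheet.
#' @param pair_groups Optional named list of predicate functions
#'   `f(info_i, info_j)` over two sample-sheet rows, defining extra
#'   groupings.
#' @return A `sample_similarity` object: list with `pairs` (tibble
#'   `sample_1`, `sample_2`, `rho`, plus one logical column per grouping)
#'   and `tests` (tibble `grouping`, `n_pairs`, `median_rho`, `p`,
#'   `p_bonf`).
#' @export
sample_similarity <- function(M, samples, pair_groups = NULL) {
  m <- as_id_matrix(M)
  if (ncol(m) < 2) stop("sample_similarity: need >= 2 samples", call. = FALSE)
  samples <- samples[match(colnames(m), samples$sample_id), ]
  rho <- stats::cor(m, method = "spearman")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  info <- function(i) samples[i, ]
  groups <- list(
    all = function(a, b) a$cell_type != b$cell_type,
    same_group = function(a, b) a$group == b$group &&
      a$cell_type != b$cell_type,
    replicates = function(a, b) a$cell_type == b$cell_type
  )
  if (!is.null(pair_groups)) groups <- c(groups, pair_groups)
  pairs <- tibble::tibble(
    sample_1 = colnames(m)[idx[, 1]],
    sample_2 = colnames(m)[idx[, 2]],
    rho = rho[idx]
  )
  for (g in names(groups)) {
    pairs[[g]] <- purrr::map2_lgl(idx[, 1], idx[, 2], function(i, j) {
      isTRUE(groups[[g]](info(i), info(j)))
    })
  }
  tests <- purrr::map_dfr(setdiff(names(groups), "all"), function(g) {
    x <- pairs$rho[pairs[[g]]]
    y <- pairs$rho[pairs$all]
    if (length(x) < 2 || length(y) < 2) {
      warning("sample_similarity: grouping '", g, "' has < 2 pairs; skipped")
      return(NULL)
    }
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    tibble::tibble(grouping = g, n_pairs = length(x),
                   median_rho = stats::median(x), p = wt$p.value)
  })
  if (nrow(tests) > 0) tests$p_bonf <- stats::p.adjust(tests$p, "bonferroni")
  out <- list(pairs = pairs, tests = tests)
  class(out) <- "sample_similarity"
  out
}

#' @export
tidy.sample_similarity <- function(x, ...) x$pairs

#' @export
glance.sample_similarity <- function(x, ...) x$tests

#' PCA of the normalized interaction matrix and covariate associations
#'
#' Principal components of the samples (loops as features, `prcomp` with
#' default options), per-PC variance fractions, and a one-way linear-model
#' F-test of each PC against each covariate, BH-adjusted across all
#' (PC, covariate) pairs. Constant covariates are skipped with a warning.
#'
#' @param normM Normalized matrix (tibble or matrix).
#' @param samples Sample sheet.
#' @param covariates Character vector of sample-sheet columns to test.
#' @param n_pcs Number of leading PCs to test (capped by the data).
#' @return A `loop_pca` object: list with `scores` (tibble: `sample_id`,
#'   covariates, `PC1..`), `var_explained` (numeric), `assoc` (tibble
#'   `pc`, `covariate`, `p`, `q`).
#' @export
pca_and_confounders <- function(normM, samples,
                                covariates = c("group", "batch", "depth"),
                                n_pcs = 10) {
  m <- as_id_matrix(normM)
  if (anyNA(m)) stop("pca_and_confounders: matrix has missing entries",
                     call. = FALSE)
  samples <- samples[match(colnames(m), samples$sample_id), ]
  pc <- stats::prcomp(t(m))
  n_pcs <- min(n_pcs, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(
    samples[, c("sample_id", intersect(covariates, names(samples)))],
    tibble::as_tibble(pc$x[, seq_len(n_pcs), drop = FALSE])
  )
  assoc <- purrr::map_dfr(covariates, function(cv) {
    v <- samples[[cv]]
    if (is.null(v)) return(NULL)
    if (length(unique(v)) < 2) {
      warning("pca_and_confounders: covariate '", cv, "' is constant; skipped")
      return(NULL)
    }
    purrr::map_dfr(seq_len(n_pcs), function(k) {
      fit <- stats::lm(pc$x[, k] ~ v)
      a <- stats::anova(fit)
      tibble::tibble(pc = paste0("PC", k), covariate = cv,
                     p = a[["Pr(>F)"]][1])
    })
  })
  if (nrow(assoc) > 0) assoc$q <- stats::p.adjust(assoc$p, "BH")
  out <- list(scores = scores, var_explained = ve[seq_len(n_pcs)],
              assoc = assoc)
  class(out) <- "loop_pca"
  out
}

#' @export
tidy.loop_pca <- function(x, ...) x$assoc

#' @export
glance.loop_pca <- function(x, ...) {
  tibble::tibble(n_pcs = length(x$var_explained),
                 var_pc1 = x$var_explained[1],
                 var_pc2 = x$var_explained[2])
}

#' @export
#' @method autoplot loop_pca
#' @importFrom ggplot2 autoplot
autoplot.loop_pca <- function(object, colour = "group", ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
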