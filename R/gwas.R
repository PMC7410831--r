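#' LD-prune GWAS SNPs and attach proxy positions
#'
#' Keeps one SNP per LD cluster (the minimum p-value, ties broken by SNP
#' id), drops studies with fewer than `min_snps` pruned SNPs (reported in
#' the `dropped_studies` attribute), and attaches to each retained SNP
#' the positions of its cluster partners with r-squared at least
#' `r2_min`.
#'
#' @param snps SNP tibble: `study_id`, `snp_id`, `chrom`, `pos`,
#'   `p_value`, `ld_cluster`, `r2` (r-squared to the cluster lead).
#' @param r2_min Proxy attachment threshold (default 0.8).
#' @param min_snps Minimum pruned SNPs for a study to be kept
#'   (default 1000).
#' @return Pruned tibble with a `proxies` list-column of tibbles
#'   (`snp_id`, `chrom`, `pos`, `r2`).
#' @export
prune_and_expand <- function(snps, r2_min = 0.8, min_snps = 1000) {
  pruned <- snps |>
    dplyr::group_by(.data$study_id, .data$ld_cluster) |>
    dplyr::arrange(.data$p_value, .data$snp_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  sizes <- table(pruned$study_id)
  drop <- names(sizes)[sizes < min_snps]
  if (length(drop) > 0) {
    message("prune_and_expand: dropping study(ies) with < ", min_snps,
            " pruned SNPs: ", paste(drop, collapse = ", "))
    pruned <- pruned[!pruned$study_id %in% drop, ]
  }
  prox <- snps[snps$r2 >= r2_min & !snps$snp_id %in% pruned$snp_id, ]
  prox_by <- split(prox[, c("snp_id", "chrom", "pos", "r2")],
                   paste(prox$study_id, prox$ld_cluster))
  key <- paste(pruned$study_id, pruned$ld_cluster)
  empty <- tibble::tibble(snp_id = character(), chrom = character(),
                          pos = integer(), r2 = numeric())
  pruned$proxies <- lapply(key, function(k) {
    x <- prox_by[[k]]
    if (is.null(x)) empty else tibble::as_tibble(x)
  })
  attr(pruned, "dropped_studies") <- drop
  pruned
}

# TRUE when the SNP itself or any attached proxy lies inside a region.
snp_overlaps <- function(pruned, regions) {
  pts <- dplyr::bind_rows(
    tibble::tibble(idx = seq_len(nrow(pruned)), chrom = pruned$chrom,
                   pos = pruned$pos),
    purrr::map_dfr(seq_len(nrow(pruned)), function(i) {
      px <- pruned$proxies[[i]]
      if (is.null(px) || nrow(px) == 0) return(NULL)
      tibble::tibble(idx = i, chrom = px$chrom, pos = px$pos)
    })
  )
  trk <- tibble::tibble(chrom = pts$chrom, start = as.integer(pts$pos),
                        end = as.integer(pts$pos) + 1L)
  hit <- overlaps_any(trk, regions)
  out <- rep(FALSE, nrow(pruned))
  out[unique(pts$idx[hit])] <- TRUE
  out
}

#' Binned rank fold-change enrichment of GWAS SNPs in regions
#'
#' Pruned SNPs are ranked by p-value; cumulative significance bins are
#' set at ranks 50, 150, 350 and 750 (minimum bin 50, then 2x, 4x and 8x
#' 50) and then at the four quartiles of the remaining p-value
#' distribution. The fold change of a bin is the fraction of SNPs at or
#' below its p threshold overlapping the regions (a SNP overlaps if it or
#' any proxy does), divided by the overlap fraction of all the study's
#' SNPs. Significance of the top bin comes from `n_perm` permutations of
#' the p-values among SNPs (positions fixed), with add-one smoothing:
#' \eqn{p = (1 + \#\{fold_{perm} \ge fold_{obs}\}) / (n_{perm} + 1)}.
#'
#' @param pruned One study's rows from [prune_and_expand()].
#' @param regions Interval tibble (e.g. group-specific loop anchors).
#' @param n_perm Number of p-value permutations (default 200).
#' @param seed Permutation seed.
#' @return List with `bins` (tibble `bin`, `rank_threshold`,
#'   `p_threshold`, `n_snps`, `fold`), `top_bin_fold`, `empirical_p`, and
#'   `feasible` (FALSE when the study has < 750 pruned SNPs so only the
#'   feasible bins are reported).
#' @export
binned_rank_enrichment <- function(pruned, regions, n_perm = 200,
                                   seed = 1L) {
  stopifnot(length(unique(pruned$study_id)) == 1)
  n <- nrow(pruned)
  ov <- snp_overlaps(pruned, regions)
  base_frac <- mean(ov)
  if (base_frac == 0) {
    stop("binned_rank_enrichment: no SNP overlaps any region", call. = FALSE)
  }
  fixed_ranks <- c(50, 150, 350, 750)
  feasible <- n >= 750
  ranks <- fixed_ranks[fixed_ranks <= n]
  if (n > 750) {
    rest <- n - 750
    ranks <- c(ranks, 750 + round(rest * c(0.25, 0.5, 0.75, 1)))
  }
  ranks <- unique(pmin(ranks, n))
  fold_at <- function(p_sorted_ov, r) mean(p_sorted_ov[seq_len(r)]) / base_frac
  obs_ord <- order(pruned$p_value, pruned$snp_id)
  obs_ov <- ov[obs_ord]
  folds <- vapply(ranks, function(r) fold_at(obs_ov, r), numeric(1))
  p_sorted <- pruned$p_value[obs_ord]
  bins <- tibble::tibble(
    bin = seq_along(ranks), rank_threshold = ranks,
    p_threshold = p_sorted[ranks], n_snps = ranks, fold = folds
  )
  set.seed(as.integer(seed))
  top <- folds[1]
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    perm_ord <- order(sample(pruned$p_value))
    if (fold_at(ov[perm_ord], ranks[1]) >= top) exceed <- exceed + 1L
  }
  list(bins = bins, top_bin_fold = top,
       empirical_p = (1 + exceed) / (n_perm + 1), feasible = feasible,
       baseline_overlap = base_frac)
}

#' Relative GWAS enrichment between two region sets
#'
#' Counts the genome-wide-significant pruned SNPs (p below
#' `gw_threshold`; the study's literal threshold 1e-7 by default, with
#' 5e-8 available) overlapping each region set (proxies count) and
#' compares the overlap rates with a two-sided Fisher exact test.
#'
#' @param regions_a,regions_b Interval tibbles.
#' @param pruned Pruned SNP tibble (one study).
#' @param gw_threshold Genome-wide significance threshold.
#' @return Enrichment row (see [fisher_2x2()]) with counts for set A vs
#'   set B.
#' @export
relative_enrichment <- function(regions_a, regions_b, pruned,
                                gw_threshold = 1e-7) {
  if (nrow(regions_a) == 0 || nrow(regions_b) == 0) {
    stop("relative_enrichment: empty region set", call. = FALSE)
  }
  gw <- pruned[pruned$p_value < gw_threshold, ]
  if (nrow(gw) == 0) {
    stop("relative_enrichment: no genome-wide-significant pruned SNPs",
         call. = FALSE)
  }
  ov_a <- snp_overlaps(gw, regions_a)
  ov_b <- snp_overlaps(gw, regions_b)
  fisher_2x2(sum(ov_a), sum(!ov_a), sum(ov_b), sum(!ov_b),
             label = "regions_a_vs_b")
}
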