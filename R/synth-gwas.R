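#' Simulate GWAS SNP panels with planted anchor enrichment
#'
#' Emits two studies of LD-clustered SNPs. In the planted study
#' (`study_planted`), a fraction `gwas_planted_frac` of the 50
#' most-significant pruned SNPs is relocated inside blood-group-specific
#' loop anchors (falling back to variable-loop anchors when no
#' group-specific loops are planted); in `study_null`, placement is
#' uniform. Each LD cluster's lead SNP (minimum p) carries proxies with
#' simulated r-squared values.
#'
#' @param config A [synth_config()].
#' @param anchors,loops,truth Upstream generator outputs.
#' @param n_clusters LD clusters per study.
#' @return Tibble with columns `study_id`, `snp_id`, `chrom`, `pos`,
#'   `p_value`, `ld_cluster`, `r2` (r-squared to the cluster's lead SNP;
#'   the lead has `r2 = 1`).
#' @export
generate_gwas_panel <- function(config, anchors, loops, truth,
                                n_clusters = 1200L) {
  set.seed(substream_seed(config$seed, 20L))
  blood <- unique(c(
    loops$anchor_a[!is.na(truth$group_specific) & truth$group_specific == "blood"],
    loops$anchor_b[!is.na(truth$group_specific) & truth$group_specific == "blood"]
  ))
  if (length(blood) == 0) {
    blood <- unique(c(loops$anchor_a[truth$variable],
                      loops$anchor_b[truth$variable]))
  }
  if (length(blood) == 0) blood <- anchors$anchor_id
  target <- anchors[match(blood, anchors$anchor_id), ]

  one_study <- function(study_id, planted) {
    sizes <- sample(1:10, n_clusters, replace = TRUE,
                    prob = c(0.35, 0.2, 0.13, 0.09, 0.07, 0.05, 0.04, 0.03,
                             0.02, 0.02))
    cl <- rep(seq_len(n_clusters), sizes)
    n <- length(cl)
    chrom <- paste0("chr", sample.int(config$n_chroms, n_clusters,
                                      replace = TRUE))[cl]
    lead_pos <- round(stats::runif(n_clusters, 1e4,
                                   config$chrom_length - 1e4))
    pos <- lead_pos[cl] +
      round(stats::runif(n, -50000, 50000)) * (stats::runif(n) < 0.9)
    pos <- pmin(pmax(pos, 0), config$chrom_length - 1)
    # the cluster lead's p is drawn once per cluster (independent of
    # cluster size, so pruned-SNP significance is not confounded with the
    # number of proxies); members get uniformly larger p
    lead_p <- 10^(-stats::runif(n_clusters, 0, 10))
    p <- stats::runif(n, lead_p[cl], 1)
    first_of <- match(seq_len(n_clusters), cl)
    p[first_of] <- lead_p
    snp <- tibble::tibble(
      study_id = study_id,
      snp_id = paste0(study_id, "_snp", seq_len(n)),
      chrom = chrom, pos = as.integer(pos), p_value = p,
      ld_cluster = paste0(study_id, "_cl", cl)
    )
    # lead = first index of min p per cluster; r2 is relative to the lead
    snp$lead <- FALSE
    lead_idx <- tapply(seq_len(nrow(snp)), snp$ld_cluster,
                       function(ii) ii[which.min(snp$p_value[ii])])
    snp$lead[unlist(lead_idx)] <- TRUE
    snp$r2 <- ifelse(snp$lead, 1,
                     ifelse(stats::runif(nrow(snp)) < 0.7,
                            stats::runif(nrow(snp), 0.8, 1),
                            stats::runif(nrow(snp), 0.3, 0.8)))
    if (planted && config$gwas_planted_frac > 0) {
      leads <- which(snp$lead)
      top <- leads[order(snp$p_value[leads])][1:min(50, length(leads))]
      move <- top[stats::runif(length(top)) < config$gwas_planted_frac]
      if (length(move) > 0) {
        ai <- sample.int(nrow(target), length(move), replace = TRUE)
        snp$chrom[move] <- target$chrom[ai]
        snp$pos[move] <- as.integer(round(
          stats::runif(length(move), target$start[ai], target$end[ai] - 1)
        ))
      }
    }
    dplyr::select(snp, -"lead")
  }
  dplyr::bind_rows(
    one_study("study_planted", planted = TRUE),
    one_study("study_null", planted = FALSE)
  )
}
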