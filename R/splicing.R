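#' Find intragenic promoter-to-gene-body loops
#'
#' Keeps protein-coding genes with at least one middle exon (an exon that
#' is neither first nor last in genomic order), removes exons overlapping
#' CAGE peaks from the middle-exon pool, and returns loops for which one
#' anchor overlaps the gene's promoter window (TSS +/- 1 kb) and the
#' other anchor overlaps the 5-kb upstream window of a middle exon of the
#' same gene (strand-aware: upstream means toward the promoter).
#'
#' @param genes Gene tibble.
#' @param exons Exon tibble (`gene_id`, `exon_id`, `chrom`, `start`,
#'   `end`).
#' @param loops Loop tibble.
#' @param cage Optional CAGE peak interval tibble.
#' @param strand_aware Orient the upstream window by gene strand
#'   (default); otherwise always to the left of the exon start.
#' @return Tibble (`loop_id`, `gene_id`, `exon_id`, `anchor_prom`,
#'   `anchor_up`) where `anchor_up` identifies the anchor side (`"a"` or
#'   `"b"`) falling in the exon's upstream window.
#' @export
find_intragenic_loops <- function(genes, exons, loops, cage = NULL,
                                  strand_aware = TRUE) {
  genes <- genes[genes$biotype == "protein_coding", ]
  exons <- exons[exons$gene_id %in% genes$gene_id, ]
  # middle exons in genomic order, per gene
  exons <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(.ord = rank(.data$start, ties.method = "first"),
                  .n = dplyr::n()) |>
    dplyr::ungroup()
  middle <- exons[exons$.ord > 1 & exons$.ord < exons$.n, ]
  if (!is.null(cage) && nrow(cage) > 0 && nrow(middle) > 0) {
    middle <- middle[!overlaps_any(middle, cage), ]
  }
  if (nrow(middle) == 0) {
    return(tibble::tibble(loop_id = integer(), gene_id = character(),
                          exon_id = character(), anchor_prom = character(),
                          anchor_up = character()))
  }
  gstr <- genes$strand[match(middle$gene_id, genes$gene_id)]
  e5 <- ifelse(!strand_aware | gstr == "+", middle$start, middle$end)
  upwin <- tibble::tibble(
    chrom = middle$chrom,
    start = pmax(0, ifelse(!strand_aware | gstr == "+", e5 - 5000, e5)),
    end = ifelse(!strand_aware | gstr == "+", e5, e5 + 5000)
  )
  promwin <- tibble::tibble(chrom = genes$chrom,
                            start = pmax(0, genes$tss - 1000),
                            end = genes$tss + 1000)
  side <- function(s) {
    tibble::tibble(chrom = loops$chrom,
                   start = loops[[paste0("start_", s)]],
                   end = loops[[paste0("end_", s)]])
  }
  out <- purrr::map_dfr(c("a", "b"), function(prom_side) {
    up_side <- setdiff(c("a", "b"), prom_side)
    ph <- overlap_join(side(prom_side), promwin)
    uh <- overlap_join(side(up_side), upwin)
    ph <- dplyr::rename(ph, loop_idx = "query_idx", gene_idx = "subject_idx")
    uh <- dplyr::rename(uh, loop_idx = "query_idx", exon_idx = "subject_idx")
    j <- dplyr::inner_join(ph, uh, by = "loop_idx",
                           relationship = "many-to-many")
    j <- j[genes$gene_id[j$gene_idx] == middle$gene_id[j$exon_idx], ]
    if (nrow(j) == 0) return(NULL)
    tibble::tibble(
      loop_id = loops$loop_id[j$loop_idx],
      gene_id = genes$gene_id[j$gene_idx],
      exon_id = middle$exon_id[j$exon_idx],
      anchor_prom = prom_side, anchor_up = up_side
    )
  })
  dplyr::distinct(out)
}

#' Correlate exon counts with intragenic-loop anchor strength
#'
#' Builds real exon-anchor pairs by associating each intragenic loop's
#' upstream anchor with exons of the same gene whose 5' boundary lies
#' within `pair_window` bp of the anchor's 5' (left) boundary; same-gene
#' controls are the looping gene's other exons farther than
#' `exclusion_bp` from the anchor centre. Counts are log-transformed,
#' averaged per cell type, and Pearson-correlated per pair; the null
#' replaces the exons of the real pairs with randomly drawn exons
#' `n_perm` times.
#'
#' @param exon_counts Tibble `exon_id`, `gene_id`, `due_flag` + sample
#'   columns.
#' @param anchor_counts Anchor-by-sample count matrix (rownames anchor
#'   ids), e.g. summed loop counts per anchor.
#' @param intragenic Output of [find_intragenic_loops()].
#' @param loops Loop tibble.
#' @param exons Exon tibble.
#' @param genes Gene tibble.
#' @param samples Sample sheet.
#' @param due_only Restrict real pairs to DUE-flagged exons.
#' @param n_perm Number of exon permutations (default 100).
#' @param exclusion_bp Control exons must lie farther than this from the
#'   anchor centre (default 20 kb).
#' @param pair_window Real-pair boundary distance (default 5 kb).
#' @param seed Seed for the permutations.
#' @param min_obs Minimum complete observations per pair.
#' @return List with `real` and `controls` (tibbles with `r` per pair),
#'   `perm_means` (numeric of length `n_perm`) and `summary`.
#' @export
exon_loop_correlation <- function(exon_counts, anchor_counts, intragenic,
                                  loops, exons, genes, samples,
                                  due_only = FALSE, n_perm = 100,
                                  exclusion_bp = 20000, pair_window = 5000,
                                  seed = 1L, min_obs = 5) {
  ec <- as_id_matrix(exon_counts[, !names(exon_counts) %in%
                                   c("gene_id", "due_flag")])
  ec_ct <- average_by_cell_type(log1p(ec), samples)
  an_ct <- average_by_cell_type(log1p(anchor_counts), samples)
  due <- exon_counts$due_flag[match(rownames(ec), exon_counts$exon_id)]
  names(due) <- rownames(ec)
  gstr <- genes$strand[match(exons$gene_id, genes$gene_id)]
  e5 <- ifelse(gstr == "+", exons$start, exons$end)
  names(e5) <- exons$exon_id

  li <- match(intragenic$loop_id, loops$loop_id)
  up_start <- ifelse(intragenic$anchor_up == "a", loops$start_a[li],
                     loops$start_b[li])
  up_end <- ifelse(intragenic$anchor_up == "a", loops$end_a[li],
                   loops$end_b[li])
  up_anchor <- ifelse(intragenic$anchor_up == "a", loops$anchor_a[li],
                      loops$anchor_b[li])

  real <- purrr::map_dfr(seq_len(nrow(intragenic)), function(k) {
    gx <- exons[exons$gene_id == intragenic$gene_id[k], ]
    d <- abs(e5[gx$exon_id] - up_start[k])
    hit <- gx$exon_id[d <= pair_window]
    if (length(hit) == 0) return(NULL)
    tibble::tibble(loop_id = intragenic$loop_id[k],
                   gene_id = intragenic$gene_id[k],
                   exon_id = hit, anchor_id = up_anchor[k])
  })
  real <- dplyr::distinct(real)
  if (due_only && nrow(real) > 0) real <- real[due[real$exon_id], ]
  if (nrow(real) == 0) {
    stop("exon_loop_correlation: no real exon-anchor pairs", call. = FALSE)
  }
  pair_cor <- function(exon_ids, anchor_ids) {
    keep <- exon_ids %in% rownames(ec_ct) &
      as.character(anchor_ids) %in% rownames(an_ct)
    r <- rep(NA_real_, length(exon_ids))
    if (any(keep)) {
      A <- ec_ct[exon_ids[keep], , drop = FALSE]
      B <- an_ct[as.character(anchor_ids[keep]), , drop = FALSE]
      za <- t(scale(t(A))); zb <- t(scale(t(B)))
      rr <- rowSums(za * zb) / (ncol(A) - 1)
      rr[!is.finite(rr)] <- NA_real_
      r[keep] <- rr
    }
    r
  }
  if (ncol(ec_ct) < min_obs) {
    stop("exon_loop_correlation: fewer than ", min_obs,
         " complete cell types", call. = FALSE)
  }
  real$r <- pair_cor(real$exon_id, real$anchor_id)

  centre <- (up_start + up_end) / 2
  controls <- purrr::map_dfr(seq_len(nrow(intragenic)), function(k) {
    gx <- exons[exons$gene_id == intragenic$gene_id[k], ]
    d <- abs(e5[gx$exon_id] - centre[k])
    far <- gx$exon_id[d > exclusion_bp]
    if (length(far) == 0) return(NULL)
    tibble::tibble(loop_id = intragenic$loop_id[k],
                   gene_id = intragenic$gene_id[k],
                   exon_id = far, anchor_id = up_anchor[k])
  })
  controls <- dplyr::distinct(controls)
  if (nrow(controls) > 0) {
    controls$r <- pair_cor(controls$exon_id, controls$anchor_id)
  }

  set.seed(as.integer(seed))
  all_exons <- rownames(ec_ct)
  perm_means <- vapply(seq_len(n_perm), function(k) {
    ex <- sample(all_exons, nrow(real), replace = length(all_exons) <
                   nrow(real))
    mean(pair_cor(ex, real$anchor_id), na.rm = TRUE)
  }, numeric(1))

  list(
    real = real, controls = controls, perm_means = perm_means,
    summary = tibble::tibble(
      n_real = sum(!is.na(real$r)),
      mean_r_real = mean(real$r, na.rm = TRUE),
      mean_r_controls = if (nrow(controls) > 0)
        mean(controls$r, na.rm = TRUE) else NA_real_,
      perm_mean = mean(perm_means),
      perm_q95 = stats::quantile(perm_means, 0.95, names = FALSE)
    )
  )
}
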