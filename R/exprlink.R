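#' Map loops to genes under the four assignment schemes
#'
#' The loop interval runs from the outer edge of the left anchor to the
#' outer edge of the right anchor. Schemes:
#' \describe{
#'   \item{`all`}{the loop lies within 1 kb of the gene's start or end
#'     coordinate, or the gene body overlaps the loop partially;}
#'   \item{`promoter`}{the gene's TSS lies within 1 kb of either anchor
#'     region;}
#'   \item{`contained`}{the gene is entirely contained in the loop and its
#'     TSS is more than 1 kb from both anchors;}
#'   \item{`promoter_enhancer`}{the TSS is within 1 kb of one anchor and
#'     the other anchor overlaps an H3K27ac (enhancer) peak.}
#' }
#'
#' @param loops Loop tibble (`loop_id`, `chrom`, `start_a`, `end_a`,
#'   `start_b`, `end_b`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`).
#' @param enhancers Enhancer interval tibble (needed for
#'   `promoter_enhancer`).
#' @param scheme Assignment scheme.
#' @return Tibble (`loop_id`, `gene_id`, `scheme`), unique pairs.
#' @export
map_loops_to_genes <- function(loops, genes, enhancers = NULL,
                               scheme = c("all", "promoter", "contained",
                                          "promoter_enhancer")) {
  scheme <- match.arg(scheme)
  loop_iv <- tibble::tibble(chrom = loops$chrom, start = loops$start_a,
                            end = loops$end_b)
  tss_pt <- tibble::tibble(chrom = genes$chrom, start = genes$tss,
                           end = genes$tss + 1L)
  anchor_a <- tibble::tibble(chrom = loops$chrom, start = loops$start_a,
                             end = loops$end_a)
  anchor_b <- tibble::tibble(chrom = loops$chrom, start = loops$start_b,
                             end = loops$end_b)
  expand <- function(x, by) {
    dplyr::mutate(x, start = pmax(0, .data$start - by), end = .data$end + by)
  }
  tss_near <- function(anc) {
    overlap_join(tss_pt, expand(anc, 1000))
  }

  pairs <- switch(scheme,
    all = {
      body <- tibble::tibble(chrom = genes$chrom, start = genes$start,
                             end = genes$end)
      ov <- overlap_join(body, loop_iv)
      pts <- dplyr::bind_rows(
        tibble::tibble(chrom = genes$chrom, start = genes$start,
                       end = genes$start + 1L),
        tibble::tibble(chrom = genes$chrom, start = genes$end,
                       end = genes$end + 1L)
      )
      near <- overlap_join(pts, expand(loop_iv, 1000))
      near$query_idx <- ((near$query_idx - 1L) %% nrow(genes)) + 1L
      dplyr::distinct(dplyr::bind_rows(ov, near))
    },
    promoter = {
      dplyr::distinct(dplyr::bind_rows(tss_near(anchor_a), tss_near(anchor_b)))
    },
    contained = {
      body <- tibble::tibble(chrom = genes$chrom, start = genes$start,
                             end = genes$end)
      ov <- overlap_join(body, loop_iv)
      contained <- ov[genes$start[ov$query_idx] >=
                        loops$start_a[ov$subject_idx] &
                      genes$end[ov$query_idx] <= loops$end_b[ov$subject_idx], ]
      near <- dplyr::distinct(dplyr::bind_rows(tss_near(anchor_a),
                                               tss_near(anchor_b)))
      dplyr::anti_join(contained, near, by = c("query_idx", "subject_idx"))
    },
    promoter_enhancer = {
      if (is.null(enhancers)) {
        stop("map_loops_to_genes: promoter_enhancer needs an enhancer track",
             call. = FALSE)
      }
      enh_a <- overlaps_any(anchor_a, enhancers)
      enh_b <- overlaps_any(anchor_b, enhancers)
      pa <- tss_near(anchor_a)
      pb <- tss_near(anchor_b)
      dplyr::distinct(dplyr::bind_rows(
        pa[enh_b[pa$subject_idx], ],
        pb[enh_a[pb$subject_idx], ]
      ))
    }
  )
  tibble::tibble(
    loop_id = loops$loop_id[pairs$subject_idx],
    gene_id = genes$gene_id[pairs$query_idx],
    scheme = scheme
  ) |> dplyr::distinct() |> dplyr::arrange(.data$loop_id, .data$gene_id)
}

# Row-wise Spearman correlation between matched rows of two matrices with
# identical column sets.
rowwise_spearman <- function(A, B) {
  ra <- t(apply(A, 1, rank))
  rb <- t(apply(B, 1, rank))
  za <- t(scale(t(ra)))
  zb <- t(scale(t(rb)))
  rho <- rowSums(za * zb) / (ncol(A) - 1)
  rho[!is.finite(rho)] <- NA_real_
  rho
}

#' Correlate loop interaction frequency with gene expression
#'
#' For each mapped loop-gene pair, the Spearman correlation across cell
#' types between normalized interaction frequency and normalized
#' expression (replicates averaged per cell type first). The null is
#' obtained by shuffling the gene side of the mapping (preserving the
#' number of genes per loop) `n_shuffles` times; the enrichment of
#' positive over negative coefficients in the real vs shuffled pairs is
#' Fisher-tested.
#'
#' @param normM Normalized loop matrix (tibble or matrix).
#' @param expression Expression matrix (tibble `gene_id` + samples, or
#'   matrix).
#' @param map Loop-gene map from [map_loops_to_genes()].
#' @param samples Sample sheet covering both matrices' columns.
#' @param n_shuffles Number of mapping shuffles (default 100).
#' @param seed Seed for the shuffles.
#' @param min_cell_types Minimum shared cell types (default 5).
#' @return A `loop_expr_correlation` object: list with `pairs` (tibble
#'   `loop_id`, `gene_id`, `rho`), `null` (tibble `shuffle`, `mean_rho`,
#'   `mean_abs_rho`), `sign_test` (Fisher row) and `summary`.
#' @export
loop_expression_correlation <- function(normM, expression, map, samples,
                                        n_shuffles = 100, seed = 1L,
                                        min_cell_types = 5) {
  lm_ct <- average_by_cell_type(normM, samples)
  ex_ct <- average_by_cell_type(expression, samples)
  if (ncol(lm_ct) < min_cell_types) {
    stop("loop_expression_correlation: fewer than ", min_cell_types,
         " shared cell types", call. = FALSE)
  }
  map <- map[as.character(map$loop_id) %in% rownames(lm_ct) &
               map$gene_id %in% rownames(ex_ct), ]
  if (nrow(map) == 0) {
    stop("loop_expression_correlation: no mapped pairs in the matrices",
         call. = FALSE)
  }
  A <- lm_ct[as.character(map$loop_id), , drop = FALSE]
  B <- ex_ct[map$gene_id, , drop = FALSE]
  rho <- rowwise_spearman(A, B)
  pairs <- tibble::tibble(loop_id = map$loop_id, gene_id = map$gene_id,
                          rho = rho)
  set.seed(as.integer(seed))
  null_pos <- 0; null_neg <- 0
  null <- purrr::map_dfr(seq_len(n_shuffles), function(k) {
    g <- sample(map$gene_id)
    r <- rowwise_spearman(A, ex_ct[g, , drop = FALSE])
    null_pos <<- null_pos + sum(r > 0, na.rm = TRUE)
    null_neg <<- null_neg + sum(r < 0, na.rm = TRUE)
    tibble::tibble(shuffle = k, mean_rho = mean(r, na.rm = TRUE),
                   mean_abs_rho = mean(abs(r), na.rm = TRUE))
  })
  sign_test <- fisher_2x2(sum(rho > 0, na.rm = TRUE),
                          sum(rho < 0, na.rm = TRUE),
                          null_pos, null_neg, label = "positive_vs_null")
  out <- list(
    pairs = pairs, null = null, sign_test = sign_test,
    summary = tibble::tibble(
      n_pairs = sum(!is.na(rho)),
      mean_abs_rho = mean(abs(rho), na.rm = TRUE),
      null_mean_abs_rho = mean(null$mean_abs_rho),
      positive_or = sign_test$odds_ratio
    )
  )
  class(out) <- "loop_expr_correlation"
  out
}

#' @export
tidy.loop_expr_correlation <- function(x, ...) x$pairs

#' @export
glance.loop_expr_correlation <- function(x, ...) x$summary

#' Co-expression of gene pairs sharing a loop
#'
#' Same-chromosome gene pairs with TSS-to-TSS distance inside the loop
#' span window are split into `same_loop` (both TSS inside one loop's
#' interval), `same_variable_loop` (that loop is in the variable set) and
#' distance-matched `not_same_loop` controls within log-spaced distance
#' bins; expression Spearman correlations (cell-type averages) are
#' summarised by the median per bin and category. Self-pairs are
#' excluded.
#'
#' @param genes Gene tibble.
#' @param loops Loop tibble.
#' @param variable_loops Character/integer vector of variable loop ids.
#' @param expression Expression matrix.
#' @param samples Sample sheet.
#' @param n_bins Number of log-spaced distance bins over (10 kb, 5 Mb).
#' @return List with `pairs` (tibble) and `medians` (tibble per bin and
#'   category).
#' @export
coexpression_in_loops <- function(genes, loops, variable_loops, expression,
                                  samples, n_bins = 10) {
  ex_ct <- average_by_cell_type(expression, samples)
  genes <- genes[genes$gene_id %in% rownames(ex_ct), ]
  tss_pt <- tibble::tibble(chrom = genes$chrom, start = genes$tss,
                           end = genes$tss + 1L)
  loop_iv <- tibble::tibble(chrom = loops$chrom, start = loops$start_a,
                            end = loops$end_b)
  inloop <- overlap_join(tss_pt, loop_iv)
  loops_of_gene <- split(inloop$subject_idx, inloop$query_idx)

  pairs <- purrr::map_dfr(split(seq_len(nrow(genes)), genes$chrom),
                          function(idx) {
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    d <- abs(genes$tss[cmb[1, ]] - genes$tss[cmb[2, ]])
    keep <- d > 10000 & d < 5000000
    tibble::tibble(g1 = cmb[1, keep], g2 = cmb[2, keep], dist = d[keep])
  })
  if (nrow(pairs) == 0) {
    stop("coexpression_in_loops: no eligible gene pairs", call. = FALSE)
  }
  shared <- purrr::map2(pairs$g1, pairs$g2, function(i, j) {
    intersect(loops_of_gene[[as.character(i)]],
              loops_of_gene[[as.character(j)]])
  })
  pairs$same_loop <- lengths(shared) > 0
  var_idx <- which(as.character(loops$loop_id) %in%
                     as.character(variable_loops))
  pairs$same_variable_loop <- purrr::map_lgl(shared, function(s) {
    any(s %in% var_idx)
  })
  rho <- rowwise_spearman(ex_ct[genes$gene_id[pairs$g1], , drop = FALSE],
                          ex_ct[genes$gene_id[pairs$g2], , drop = FALSE])
  pairs$rho <- rho
  brk <- exp(seq(log(10000), log(5000000), length.out = n_bins + 1))
  pairs$bin <- cut(pairs$dist, breaks = brk, include.lowest = TRUE)
  medians <- purrr::map_dfr(levels(pairs$bin), function(b) {
    pb <- pairs[!is.na(pairs$bin) & pairs$bin == b, ]
    ctrl <- pb$rho[!pb$same_loop]
    sl <- pb$rho[pb$same_loop]
    svl <- pb$rho[pb$same_variable_loop]
    if (length(ctrl) == 0 && length(sl) == 0) return(NULL)
    if (length(ctrl) == 0) {
      message("coexpression_in_loops: bin ", b, " has no control pairs")
      return(NULL)
    }
    tibble::tibble(
      bin = b,
      n_same_loop = length(sl), n_control = length(ctrl),
      median_same_loop = stats::median(sl, na.rm = TRUE),
      median_same_variable_loop = stats::median(svl, na.rm = TRUE),
      median_control = stats::median(ctrl, na.rm = TRUE)
    )
  })
  pairs$gene_1 <- genes$gene_id[pairs$g1]
  pairs$gene_2 <- genes$gene_id[pairs$g2]
  list(pairs = dplyr::select(pairs, -"g1", -"g2"), medians = medians)
}

#' Expression dose response to linked cell-type-specific enhancers
#'
#' For every cell type, counts per specifically expressed gene the number
#' of distinct cell-type-specific enhancers linked to its promoter
#' through a cell-type-specific loop (promoter within 1 kb of one anchor,
#' enhancer overlapping the other). Genes are binned by linked-enhancer
#' count (1, 2, 3+, aggregated across cell types) and expression levels
#' are compared pairwise between bins with two-sided Wilcoxon rank-sum
#' tests.
#'
#' @param cell_sets Named list (cell type -> list with `loops` (ids),
#'   `enhancer_track` (interval tibble), `genes` (gene ids)).
#' @param loops Loop tibble.
#' @param genes Gene tibble.
#' @param expression Expression matrix (for the per-gene level in its
#'   target cell type).
#' @param samples Sample sheet.
#' @return List with `genes` (tibble `cell_type`, `gene_id`,
#'   `n_enhancers`, `bin`, `expr`) and `tests` (pairwise rank-sum rows).
#' @export
enhancer_dose_response <- function(cell_sets, loops, genes, expression,
                                   samples) {
  ex_ct <- average_by_cell_type(expression, samples)
  rows <- purrr::map_dfr(names(cell_sets), function(ct) {
    cs <- cell_sets[[ct]]
    lp <- loops[as.character(loops$loop_id) %in% as.character(cs$loops), ]
    if (nrow(lp) == 0) return(NULL)
    gset <- genes[genes$gene_id %in% cs$genes, ]
    if (nrow(gset) == 0) return(NULL)
    promwin <- tibble::tibble(chrom = gset$chrom,
                              start = pmax(0, gset$tss - 1000),
                              end = gset$tss + 1000)
    anchor_a <- tibble::tibble(chrom = lp$chrom, start = lp$start_a,
                               end = lp$end_a)
    anchor_b <- tibble::tibble(chrom = lp$chrom, start = lp$start_b,
                               end = lp$end_b)
    enh <- cs$enhancer_track
    ea <- overlap_join(anchor_a, enh)
    eb <- overlap_join(anchor_b, enh)
    pa <- overlap_join(promwin, anchor_a)
    pb <- overlap_join(promwin, anchor_b)
    # gene-enhancer links: promoter at one anchor, enhancer at the other
    link_via <- function(prom_hits, enh_hits) {
      ph <- dplyr::rename(prom_hits, gene_idx = "query_idx",
                          loop_idx = "subject_idx")
      eh <- dplyr::rename(enh_hits, loop_idx = "query_idx",
                          enh_idx = "subject_idx")
      dplyr::inner_join(ph, eh, by = "loop_idx",
                        relationship = "many-to-many")
    }
    links <- dplyr::distinct(
      dplyr::bind_rows(link_via(pa, eb), link_via(pb, ea))[,
        c("gene_idx", "enh_idx")]
    )
    if (nrow(links) == 0) return(NULL)
    cnt <- table(links$gene_idx)
    tibble::tibble(
      cell_type = ct,
      gene_id = gset$gene_id[as.integer(names(cnt))],
      n_enhancers = as.integer(cnt),
      expr = ex_ct[gset$gene_id[as.integer(names(cnt))], ct]
    )
  })
  if (nrow(rows) == 0) {
    return(list(genes = rows, tests = tibble::tibble()))
  }
  rows$bin <- cut(rows$n_enhancers, breaks = c(0.5, 1.5, 2.5, Inf),
                  labels = c("1", "2", "3+"))
  combos <- utils::combn(levels(rows$bin), 2)
  tests <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    x <- rows$expr[rows$bin == combos[1, k]]
    y <- rows$expr[rows$bin == combos[2, k]]
    if (length(x) < 2 || length(y) < 2) {
      message("enhancer_dose_response: bin comparison ", combos[1, k],
              " vs ", combos[2, k], " skipped (too few genes)")
      return(NULL)
    }
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    tibble::tibble(bin_1 = combos[1, k], bin_2 = combos[2, k],
                   n_1 = length(x), n_2 = length(y),
                   median_1 = stats::median(x), median_2 = stats::median(y),
                   p = wt$p.value)
  })
  list(genes = rows, tests = tests)
}
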