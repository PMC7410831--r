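test_that("fisher_2x2 reports the cross-product odds ratio", {
  r <- fisher_2x2(10, 90, 5, 195)
  expect_equal(r$odds_ratio, 10 * 195 / (90 * 5))
  sym <- fisher_2x2(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)
  degen <- fisher_2x2(5, 0, 3, 4)
  expect_true(degen$degenerate)
  expect_equal(degen$odds_ratio, Inf)
  expect_error(fisher_2x2(0, 0, 3, 4), "margin")
  expect_error(fisher_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("fisher_2x2 matches exhaustive hypergeometric enumeration", {
  # spot-check against enumeration for a grid of small tables (the full
  # total <= 30 sweep runs in the acceptance suite)
  enum_p <- function(a, b, c, d) {
    rs <- a + b; cs <- a + c; n <- a + b + c + d
    as <- max(0, cs - (n - rs)):min(rs, cs)
    pr <- dhyper(as, rs, n - rs, cs)
    sum(pr[pr <= dhyper(a, rs, n - rs, cs) * (1 + 1e-7)])
  }
  set.seed(6)
  for (k in 1:40) {
    cells <- as.integer(rmultinom(1, sample(8:25, 1), rep(1, 4)))
    if ((cells[1] + cells[2]) == 0 || (cells[3] + cells[4]) == 0 ||
        (cells[1] + cells[3]) == 0 || (cells[2] + cells[4]) == 0) next
    r <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$p, enum_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("anchor degree and connectivity enrichment behave as planted", {
  # explicit geometry: 12 anchors, enhancers only at degree >= 3 anchors
  anchors <- tibble::tibble(chrom = "chr1",
                            start = as.integer((0:11) * 50000),
                            end = as.integer((0:11) * 50000 + 1000),
                            anchor_id = 1:12)
  pairs <- rbind(
    c(1, 2), c(3, 4), c(5, 6), c(7, 8),           # degree-1 anchors
    c(9, 10), c(9, 11), c(9, 12),
    c(10, 11), c(10, 12), c(11, 12)               # degree >= 3 anchors
  )
  loops <- tibble::tibble(
    loop_id = seq_len(nrow(pairs)), chrom = "chr1",
    anchor_a = pairs[, 1], anchor_b = pairs[, 2],
    start_a = anchors$start[pairs[, 1]], end_a = anchors$end[pairs[, 1]],
    start_b = anchors$start[pairs[, 2]], end_b = anchors$end[pairs[, 2]]
  )
  deg <- tabulate(c(loops$anchor_a, loops$anchor_b), 12)
  expect_equal(deg, c(rep(1, 8), rep(3, 4)))
  enh <- anchors[9:12, c("chrom", "start", "end")]
  cp <- suppressMessages(connectivity_profile(loops, anchors,
                                              list(enhancer = enh),
                                              degree_breaks = c(1, 2, 3)))
  or1 <- cp$odds_ratio[cp$bin == "1"]
  or3 <- cp$odds_ratio[cp$bin == "3+"]
  expect_lt(or1, 1)
  expect_gt(or3, 1)
})

test_that("chromatin-state enrichment validates labels and finds ENH", {
  sim <- cached("state_sim", suppressMessages(
    simulate_loop_study(synth_config(seed = 63, n_loops = 5000),
                        gwas = FALSE)))
  m <- sim$counts; rownames(m) <- sim$loops$loop_id
  m <- suppressMessages(drop_invariant_rows(filter_testable(m)))
  nm <- normalize_matrix(m)
  tl <- sim$loops[as.character(sim$loops$loop_id) %in% rownames(nm), ]
  ct <- names(sort(table(sim$truth$target_cell), decreasing = TRUE))[1]
  cs <- celltype_specific(nm, sim$samples, ct, top_frac = 0.05)
  se <- state_enrichment(stats::setNames(list(cs), ct), tl, sim$states)
  enh <- se$enrichment[se$enrichment$state == "ENH", ]
  expect_gt(enh$odds_ratio, 1)
  expect_lt(enh$q, 0.05)
  comp <- se$composition
  expect_equal(sum(comp$proportion), 1, tolerance = 1e-9)
  bad <- sim$states[[ct]]
  bad$state[1] <- "MYSTERY"
  expect_error(state_enrichment(stats::setNames(list(cs), ct), tl,
                                stats::setNames(list(bad), ct)),
               "unknown state")
})

test_that("pair-type enrichment finds planted enhancer-promoter wiring", {
  sim <- cached("state_sim", suppressMessages(
    simulate_loop_study(synth_config(seed = 63, n_loops = 5000),
                        gwas = FALSE)))
  m <- sim$counts; rownames(m) <- sim$loops$loop_id
  m <- suppressMessages(drop_invariant_rows(filter_testable(m)))
  nm <- normalize_matrix(m)
  tl <- sim$loops[as.character(sim$loops$loop_id) %in% rownames(nm), ]
  ct <- names(sort(table(sim$truth$target_cell), decreasing = TRUE))[1]
  cs <- celltype_specific(nm, sim$samples, ct)
  enh_set <- specific_features_for(sim$enhancer_signal, sim$samples, ct,
                                   kind = "enhancer")
  gene_set <- specific_features_for(sim$expression, sim$samples, ct,
                                    top_frac = 0.20, kind = "gene")
  pe <- pairtype_enrichment(
    cs,
    sim$enhancers[sim$enhancers$enh_id %in% enh_set$members, ],
    sim$genes[sim$genes$gene_id %in% gene_set$members, ],
    tl
  )
  expect_gt(pe$odds_ratio[pe$pair_type == "ENH-TSS"], 1)
  expect_lt(pe$p[pe$pair_type == "ENH-TSS"], 0.05)
  expect_error(pairtype_enrichment(character(), sim$enhancers, sim$genes,
                                   tl), "empty")
})

test_that("motif enrichment excludes sparse TFs and finds the planted one", {
  sim <- default_sim()
  m <- sim$counts; rownames(m) <- sim$loops$loop_id
  m <- suppressMessages(drop_invariant_rows(filter_testable(m)))
  nm <- normalize_matrix(m)
  tl <- sim$loops[as.character(sim$loops$loop_id) %in% rownames(nm), ]
  gs <- group_specific(nm, sim$samples)
  me <- motif_enrichment(gs$blood, sim$tf_motifs, tl)
  expect_true("TF_BLOOD" %in% me$tf)
  top <- me[which.max(me$odds_ratio), ]
  expect_equal(top$tf, "TF_BLOOD")
  expect_lt(top$q, 0.05)
  # a TF overlapping almost nothing is excluded by the min-cell rule
  rare <- tibble::tibble(chrom = "chr1", start = 1L, end = 12L,
                         name = "TF_RARE", score = 0, strand = "+")
  me2 <- motif_enrichment(gs$blood, rare, tl, min_cell = 5)
  expect_false("TF_RARE" %in% me2$tf)
})

test_that("gene-list connectivity enrichment is degenerate-safe and
           monotone thresholds nest", {
  sim <- default_sim()
  pm <- map_loops_to_genes(sim$loops, sim$genes, scheme = "promoter")
  universe <- sim$genes$gene_id
  # degenerate list covering every gene: OR 1 at every feasible X
  deg <- table(pm$gene_id)
  xs <- unique(quantile(as.integer(deg), c(0.25, 0.5, 0.75), type = 1))
  res_all <- suppressMessages(
    gene_connectivity_enrichment(universe, pm, universe, x_range = xs)
  )
  expect_true(all(res_all$odds_ratio == 1 | is.nan(res_all$odds_ratio) |
                    res_all$degenerate))
  # planted: driver genes have elevated promoter connectivity
  gl <- sim$gene_truth$gene_id[!is.na(sim$gene_truth$driver_anchor)]
  res <- suppressMessages(
    gene_connectivity_enrichment(gl, pm, universe, x_range = xs)
  )
  expect_true(all(res$log2_or > 0))
  expect_error(gene_connectivity_enrichment("NOPE", pm, universe),
               "disjoint")
})

test_that("signal aggregation averages, reverses minus strands, subsets", {
  sig <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                        end = c(100L, 200L), value = c(1, 3))
  # asymmetric ramp across a plus- and a minus-strand motif
  mot_plus <- tibble::tibble(chrom = "chr1", start = 95L, end = 105L,
                             strand = "+")
  mot_minus <- dplyr::mutate(mot_plus, strand = "-")
  p_plus <- aggregate_signal_at_motifs(sig, mot_plus, flank_bp = 5)
  p_minus <- aggregate_signal_at_motifs(sig, mot_minus, flank_bp = 5)
  expect_equal(p_minus$profile, rev(p_plus$profile))
  # constant signal gives a flat profile; single motif returns its window
  flat <- tibble::tibble(chrom = "chr1", start = 0L, end = 400L, value = 2)
  pf <- aggregate_signal_at_motifs(flat, mot_plus, flank_bp = 10)
  expect_true(all(pf$profile == 2))
  expect_equal(length(pf$profile), 21L)
  # windows hanging over the chromosome start are skipped and counted
  edge <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L, strand = "+")
  pe <- aggregate_signal_at_motifs(flat, edge, flank_bp = 50)
  expect_equal(pe$n_skipped, 1L)
})
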