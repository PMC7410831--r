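test_that("generator is deterministic under one seed", {
  cfg <- synth_config(seed = 33, n_anchors = 100, n_loops = 400,
                      library_depth = 30000, n_genes = 60)
  s1 <- suppressMessages(simulate_loop_study(cfg))
  s2 <- suppressMessages(simulate_loop_study(cfg))
  expect_identical(s1$anchors, s2$anchors)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$gwas_snps, s2$gwas_snps)
  expect_identical(s1$ctcf_motifs, s2$ctcf_motifs)
})

test_that("anchors are disjoint and candidate spans respect the window", {
  sim <- tiny_sim()
  a <- sim$anchors
  by_chrom <- split(a, a$chrom)
  for (ch in by_chrom) {
    expect_true(all(ch$start[-1] >= ch$end[-nrow(ch)]))
  }
  expect_true(all(sim$loops$span > 10000 & sim$loops$span < 5000000))
  expect_true(all(diff(a$anchor_id) > 0))
})

test_that("candidate pairs equal the brute-force in-window enumeration", {
  cfg <- synth_config(seed = 5, n_anchors = 40, chrom_length = 6e6,
                      n_chroms = 1L)
  al <- generate_anchors_and_loops(cfg)
  mids <- (al$anchors$start + al$anchors$end) / 2
  n_bf <- 0
  for (i in seq_len(39)) {
    for (j in (i + 1):40) {
      d <- mids[j] - mids[i]
      if (d > 10000 && d < 5000000) n_bf <- n_bf + 1
    }
  }
  expect_equal(nrow(al$loops), n_bf)
})

test_that("truth tables are consistent with the config fractions", {
  sim <- default_sim()
  n <- nrow(sim$loops)
  expect_equal(sum(sim$truth$variable), round(0.10 * n))
  for (g in c("blood", "embryonic", "solid")) {
    expect_equal(sum(sim$truth$group_specific == g, na.rm = TRUE),
                 round(0.02 * n))
  }
  # flags are disjoint and every flagged loop id exists
  expect_false(any(sim$truth$variable & !is.na(sim$truth$group_specific)))
  expect_true(all(sim$truth$loop_id %in% sim$loops$loop_id))
  # every variable loop has a target cell and a driver anchor
  v <- sim$truth[sim$truth$variable, ]
  expect_false(anyNA(v$target_cell))
  expect_true(all(v$driver_anchor == sim$loops$anchor_a[v$loop_id] |
                    v$driver_anchor == sim$loops$anchor_b[v$loop_id]))
})

test_that("simulated counts match their negative-binomial model", {
  cfg <- synth_config(seed = 11, n_anchors = 60, n_loops = 150,
                      chrom_length = 6e6, library_depth = 3e4,
                      frac_variable = 0, frac_group_specific = 0)
  al <- generate_anchors_and_loops(cfg)
  smp <- generate_samples(cfg)
  tr <- generate_loop_truth(cfg, al$loops, smp)
  pc <- generate_pet_counts(cfg, al$anchors, al$loops, tr, smp)
  # law of large numbers: observed mean within 3 SE of mu, per loop over
  # all 12 samples treated as draws around the same mu (null data)
  mu <- pc$mu[, 1]
  se <- sqrt((mu + cfg$nb_dispersion * mu^2) / ncol(pc$counts))
  z <- (rowMeans(pc$counts) - mu) / pmax(se, 1e-9)
  expect_lt(mean(abs(z) > 3), 0.02)

  # chi-square goodness of fit against the NB marginal on 10,000 draws
  phi <- 0.1; m0 <- 8
  set.seed(2)
  draws <- rnbinom(10000, size = 1 / phi, mu = m0)
  br <- c(-0.5, seq(0.5, 20.5, 1), Inf)
  obs <- table(cut(draws, br))
  pr <- diff(pnbinom(c(-1, 0:20, Inf), size = 1 / phi, mu = m0))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = pr,
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted effects vanish when effect_size is 1", {
  cfg <- synth_config(seed = 13, n_anchors = 80, n_loops = 300,
                      chrom_length = 8e6, effect_size = 1,
                      library_depth = 5e4)
  al <- generate_anchors_and_loops(cfg)
  smp <- generate_samples(cfg)
  tr <- generate_loop_truth(cfg, al$loops, smp)
  pc <- generate_pet_counts(cfg, al$anchors, al$loops, tr, smp)
  expect_true(any(tr$variable))
  # means are identical across samples for every loop
  expect_true(all(abs(pc$mu - pc$mu[, 1]) < 1e-9))
})

test_that("written dataset round-trips through the readers", {
  td <- withr::local_tempdir()
  sim <- tiny_sim()
  write_synth_dataset(sim, td)
  expect_true(file.exists(file.path(td, "manifest.txt")))
  anchors <- read_intervals(file.path(td, "anchors.bed"), "bed6")
  expect_equal(nrow(anchors), nrow(sim$anchors))
  expect_equal(anchors$start, sim$anchors$start)
  loops <- read_intervals(file.path(td, "loops.bedpe"), "bedpe")
  expect_equal(nrow(loops), nrow(sim$loops))
  counts <- read_matrix_tsv(file.path(td, "counts.tsv"))
  expect_equal(as.matrix(counts[, -1]), unname(sim$counts),
               ignore_attr = TRUE)
  sheet <- read_sample_sheet(file.path(td, "samples.tsv"))
  expect_equal(sheet$sample_id, sim$samples$sample_id)
})

test_that("GWAS panel plants overlap only in the planted study", {
  sim <- tiny_sim()
  snp <- sim$gwas_snps
  expect_true(all(c("study_planted", "study_null") %in% snp$study_id))
  # every cluster's lead (r2 == 1) has the cluster's minimum p
  key <- paste(snp$study_id, snp$ld_cluster)
  ok <- tapply(seq_len(nrow(snp)), key, function(ii) {
    min(snp$p_value[ii]) == snp$p_value[ii][snp$r2[ii] == 1][1]
  })
  expect_true(all(ok))
  expect_true(all(snp$r2 >= 0 & snp$r2 <= 1))
})
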