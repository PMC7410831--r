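toy_group_samples <- function() {
  tibble::tibble(
    sample_id = paste0(rep(c("B1", "B2", "E1", "E2", "S1", "S2"), each = 2),
                       "_r", rep(1:2, 6)),
    cell_type = rep(c("B1", "B2", "E1", "E2", "S1", "S2"), each = 2),
    replicate = rep(1:2, 6),
    group = rep(c("blood", "embryonic", "solid"), each = 4),
    batch = "b1", depth = 1
  )
}

test_that("group-specific set algebra matches hand-worked toy cases", {
  samples <- toy_group_samples()
  set.seed(3)
  m <- matrix(rnorm(10 * 12, 100, 0.5), 10, 12,
              dimnames = list(paste0("L", sprintf("%02d", 1:10)),
                              samples$sample_id))
  # L01 strongly elevated only in blood -> blood-specific
  m["L01", samples$group == "blood"] <- 400 + rnorm(4, 0, 0.5)
  # L02 elevated in blood AND embryonic -> differs between the others,
  # so the t3 ranking and the t1 comparison both exclude it
  m["L02", samples$group != "solid"] <- 200 + rnorm(8, 0, 0.5)
  # L03 elevated in embryonic only: tops t3 (embryonic vs solid)
  m["L03", samples$group == "embryonic"] <- 200 + rnorm(4, 0, 0.5)
  gs <- group_specific(m, samples, top_frac = 0.10)
  expect_true("L01" %in% gs$blood$members)
  expect_false("L02" %in% gs$blood$members)
  # uniform loops excluded everywhere
  expect_false("L05" %in% unlist(lapply(gs, `[[`, "members")))
  expect_error(group_specific(m, samples[samples$group != "solid", ]),
               "3 groups")
})

test_that("group_specific equals brute-force set algebra on random data", {
  samples <- toy_group_samples()
  welch <- function(x, i1, i2) {
    m1 <- mean(x[i1]); m2 <- mean(x[i2])
    se <- sqrt(var(x[i1]) / length(i1) + var(x[i2]) / length(i2))
    if (se > 0) (m1 - m2) / se else if (m1 == m2) 0 else sign(m1 - m2) * Inf
  }
  for (seed in 1:50) {
    set.seed(seed)
    m <- matrix(rnorm(100 * 12, 50, 10), 100, 12,
                dimnames = list(sprintf("L%03d", 1:100),
                                samples$sample_id))
    gs <- group_specific(m, samples, top_frac = 0.10)
    ids <- rownames(m)
    groups <- sort(unique(samples$group))
    for (g in groups) {
      others <- sort(setdiff(groups, g))
      iq <- which(samples$group == g)
      i1 <- which(samples$group == others[1])
      i2 <- which(samples$group == others[2])
      t1 <- apply(m, 1, welch, iq, i1)
      t2 <- apply(m, 1, welch, iq, i2)
      t3 <- apply(m, 1, welch, i1, i2)
      top <- function(t) ids[order(-t, ids)][1:10]
      expected <- setdiff(intersect(top(t1), top(t2)), top(t3))
      expect_setequal(gs[[g]]$members, expected)
    }
  }
})

test_that("ranked prefixes nest and sets ignore column order", {
  nd <- default_norm()
  s05 <- celltype_specific(nd$norm, nd$sim$samples, "BLD1", top_frac = 0.05)
  s10 <- celltype_specific(nd$norm, nd$sim$samples, "BLD1", top_frac = 0.10)
  expect_true(all(s05$members %in% s10$members))
  expect_length(s10$members, floor(0.10 * nrow(nd$norm)))
  shuffled <- nd$norm[, sample(ncol(nd$norm))]
  s10b <- celltype_specific(shuffled, nd$sim$samples, "BLD1",
                            top_frac = 0.10)
  expect_setequal(s10$members, s10b$members)
  expect_error(celltype_specific(nd$norm, nd$sim$samples, "NOPE"),
               "absent")
})

test_that("planted cell-type effects are recovered by the ranking", {
  nd <- default_norm()
  truth <- nd$sim$truth
  ct <- names(sort(table(truth$target_cell), decreasing = TRUE))[1]
  cs <- celltype_specific(nd$norm, nd$sim$samples, ct)
  planted <- truth$loop_id[truth$variable & !is.na(truth$target_cell) &
                             truth$target_cell == ct]
  planted <- intersect(as.character(planted), rownames(nd$norm))
  expect_gt(mean(planted %in% cs$members), 0.8)
})

test_that("enhancer and gene specificity use the same machinery", {
  sim <- default_sim()
  ct <- names(sort(table(sim$truth$target_cell), decreasing = TRUE))[1]
  es <- specific_features_for(sim$enhancer_signal, sim$samples, ct,
                              top_frac = 0.20, kind = "enhancer")
  expect_equal(length(es$members),
               floor(0.20 * nrow(sim$enhancer_signal)))
  gs20 <- specific_features_for(sim$expression, sim$samples, ct,
                                top_frac = 0.20, kind = "gene")
  expect_equal(length(gs20$members), floor(0.20 * nrow(sim$expression)))
  # planted specific enhancers (opposite the drivers of ct) are recovered
  tr <- sim$truth
  opp <- ifelse(sim$loops$anchor_a == tr$driver_anchor,
                sim$loops$anchor_b, sim$loops$anchor_a)
  planted_anchors <- unique(opp[tr$variable & tr$target_cell == ct])
  planted_enh <- sim$enhancers$enh_id[sim$enhancers$at_anchor %in%
                                        planted_anchors]
  expect_gt(mean(planted_enh %in% es$members), 0.5)
  # determinism
  es2 <- specific_features_for(sim$enhancer_signal, sim$samples, ct,
                               top_frac = 0.20, kind = "enhancer")
  expect_identical(es$members, es2$members)
})
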