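test_that("build_anchor_set extends, merges, clips and filters", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(1000L, 1500L),
                          end = c(1200L, 1700L))
  a <- build_anchor_set(peaks, extension_bp = 500)
  expect_equal(nrow(a), 1L)
  expect_equal(c(a$start, a$end), c(500L, 2200L))

  clip <- build_anchor_set(tibble::tibble(chrom = "chr1", start = 200L,
                                          end = 400L), 500)
  expect_equal(c(clip$start, clip$end), c(0L, 900L))

  bl <- tibble::tibble(chrom = "chr1", start = 600L, end = 700L)
  filtered <- build_anchor_set(peaks, 500, blacklist = bl)
  expect_equal(nrow(filtered), 0L)

  expect_error(build_anchor_set(peaks[0, ]), "empty")
})

test_that("tabulate_pets applies the strict span window and midpoints", {
  anchors <- tibble::tibble(
    chrom = "chr1",
    start = c(9500L, 17500L, 59500L),
    end = c(10500L, 18500L, 60500L),
    anchor_id = 1:3
  )
  # midpoints at 10,000 / 18,000 / 60,000
  pet <- function(p1, p2) {
    tibble::tibble(chrom_a = "chr1", start_a = p1 - 50L, end_a = p1 + 50L,
                   chrom_b = "chr1", start_b = p2 - 50L, end_b = p2 + 50L)
  }
  # span 50 kb -> counted
  t1 <- tabulate_pets(pet(10000L, 60000L), anchors)
  expect_equal(t1$count, 1L)
  expect_equal(c(t1$anchor_a, t1$anchor_b), c(1L, 3L))
  # span 8 kb -> excluded (window is strict)
  expect_equal(nrow(tabulate_pets(pet(10000L, 18000L), anchors)), 0L)
  # endpoint in no anchor -> excluded
  expect_equal(nrow(tabulate_pets(pet(30000L, 60000L), anchors)), 0L)
  # order independence and column-sum bound
  pets <- dplyr::bind_rows(pet(10000L, 60000L), pet(60000L, 10000L),
                           pet(18000L, 60000L))
  tab <- tabulate_pets(pets, anchors)
  expect_lte(sum(tab$count), nrow(pets))
  tab_rev <- tabulate_pets(pets[nrow(pets):1, ], anchors)
  expect_equal(tab, tab_rev)
})

test_that("tabulation recovers the simulated counts from PET records", {
  cfg <- synth_config(seed = 71, n_anchors = 100, n_loops = 500,
                      library_depth = 20000, frac_background_pets = 0.2)
  sim <- suppressMessages(simulate_loop_study(cfg, annotations = FALSE,
                                              gwas = FALSE))
  pets <- sim_pet_records(cfg, sim$anchors, sim$loops, sim$counts,
                          "BLD1_rep1")
  tab <- tabulate_pets(pets, sim$anchors)
  key <- paste(sim$loops$anchor_a, sim$loops$anchor_b)
  truth <- stats::setNames(sim$counts[, "BLD1_rep1"], key)
  got <- stats::setNames(tab$count, paste(tab$anchor_a, tab$anchor_b))
  expect_setequal(names(got), names(truth)[truth > 0])
  expect_equal(unname(got[names(truth)[truth > 0]]),
               unname(truth[truth > 0]))
})

test_that("downsampling caps, passes small sets and is deterministic", {
  pets <- tibble::tibble(chrom_a = "chr1", start_a = 1:5000,
                         end_a = 101:5100, chrom_b = "chr1",
                         start_b = 20001:25000, end_b = 20101:25100)
  d1 <- downsample_pets(pets, cap = 1000, seed = 4)
  expect_equal(nrow(d1), 1000L)
  expect_identical(d1, downsample_pets(pets, cap = 1000, seed = 4))
  expect_identical(downsample_pets(pets, cap = 10000, seed = 4), pets)
  # downsampling is uniform: per-pair expected retention proportional
  keep <- replicate(50, {
    d <- downsample_pets(pets, cap = 1000, seed = sample.int(1e6, 1))
    mean(d$start_a <= 2500)
  })
  expect_lt(abs(mean(keep) - 0.5), 3 * sd(keep) / sqrt(50))
})

test_that("score_loops reproduces the exact Poisson tail", {
  # k = 0 gives p = 1 by definition of the upper tail
  anchors <- tibble::tibble(chrom = "chr1",
                            start = seq(0L, 39L * 50000L, 50000L),
                            end = seq(1000L, 39L * 50000L + 1000L, 50000L),
                            anchor_id = 1:40, efficiency = 1)
  pairs <- tibble::tibble(anchor_a = 1:20, anchor_b = 21:40,
                          count = c(0L, rep(2L, 19)))
  sc <- score_loops(pairs, anchors, n_distance_bins = 1)
  expect_equal(sc$p[sc$count == 0], 1)
  # brute-force tail summation oracle for P(X >= k)
  tail_sum <- function(k, lam) {
    1 - sum(exp(-lam) * lam^(0:(k - 1)) / factorial(0:(k - 1)))
  }
  expect_equal(ppois(7 - 1, 2, lower.tail = FALSE), tail_sum(7, 2),
               tolerance = 1e-12)
  lam <- sc$lambda[5]
  expect_equal(sc$p[5], tail_sum(sc$count[5], lam), tolerance = 1e-10)
})

test_that("score_loops is calibrated on a uniform-efficiency null bin", {
  set.seed(42)
  n <- 2000
  anchors <- tibble::tibble(chrom = "chr1",
                            start = as.integer(seq(0, (2 * n - 1) * 20000,
                                                   20000)),
                            end = as.integer(seq(0, (2 * n - 1) * 20000,
                                                 20000) + 1000),
                            anchor_id = seq_len(2 * n), efficiency = 1)
  # all pairs share one bin; counts multinomially uniform (the expected
  # count is large enough that the discrete p-values resolve the KS grid)
  counts <- as.integer(rmultinom(1, size = 500 * n, prob = rep(1, n)))
  pairs <- tibble::tibble(anchor_a = seq_len(n), anchor_b = n + seq_len(n),
                          span = 50000, count = counts)
  sc <- score_loops(pairs, anchors, n_distance_bins = 1)
  ks <- suppressWarnings(stats::ks.test(sc$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("score_loops warns on and skips zero-efficiency anchors", {
  anchors <- tibble::tibble(chrom = "chr1", start = c(0L, 50000L, 100000L),
                            end = c(1000L, 51000L, 101000L),
                            anchor_id = 1:3, efficiency = c(0, 1, 1))
  pairs <- tibble::tibble(anchor_a = c(1L, 2L), anchor_b = c(2L, 3L),
                          count = c(5L, 5L))
  expect_warning(sc <- score_loops(pairs, anchors, n_distance_bins = 1),
                 "zero-efficiency")
  expect_equal(nrow(sc), 1L)
})

test_that("CTCF orientation classifies strand pairs and excludes
           multi-motif anchors", {
  loops <- tibble::tibble(
    loop_id = 1:3, chrom = "chr1",
    start_a = c(0L, 10000L, 20000L), end_a = c(1000L, 11000L, 21000L),
    start_b = c(50000L, 60000L, 70000L), end_b = c(51000L, 61000L, 71000L)
  )
  motifs <- tibble::tibble(
    chrom = "chr1",
    start = c(500L, 50500L, 10500L, 60500L, 20500L, 20600L, 70500L),
    end = c(519L, 50519L, 10519L, 60519L, 20519L, 20619L, 70519L),
    name = "CTCF", score = 0,
    strand = c("+", "-", "-", "+", "+", "+", "-")
  )
  o <- ctcf_orientation_summary(loops, motifs)
  # loop 3 has two motifs in its left anchor -> excluded
  expect_equal(attr(o, "n_loops_included"), 2L)
  expect_equal(o$n[o$orientation == "convergent"], 1L)
  expect_equal(o$n[o$orientation == "divergent"], 1L)
  expect_equal(sum(o$percent), 100)
  bad <- motifs; bad$strand[1] <- "."
  expect_error(ctcf_orientation_summary(loops, bad), "strand")
})
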