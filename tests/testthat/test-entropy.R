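test_that("relative entropy matches direct formula evaluation", {
  expect_equal(relative_entropy(c(5, 5, 5, 5)), 0)
  expect_equal(relative_entropy(c(1, 0, 0, 0)), 2)
  expect_equal(relative_entropy(c(0.5, 0.5, 0, 0)), 1)
  # bounds and scale invariance
  set.seed(1)
  for (j in c(3, 6, 12)) {
    x <- runif(j)
    re <- relative_entropy(x)
    expect_gte(re, 0)
    expect_lte(re, log2(j))
    expect_equal(relative_entropy(17 * x), re)
  }
  expect_error(relative_entropy(c(0, 0, 0)), "all-zero")
  expect_error(relative_entropy(c(-1, 1)), "non-negative")
})

test_that("static score ranks uniform strong loops above specific ones", {
  samples_cols <- paste0("s", 1:4)
  m <- matrix(c(8, 8, 8, 8,
                8, 0, 0, 0,
                2, 2, 2, 2), 3, 4, byrow = TRUE,
              dimnames = list(c("uniform8", "onehot8", "uniform2"),
                              samples_cols))
  # a pretend variability result flagging one loop as variable
  v <- tibble::tibble(loop_id = rownames(m), statistic = 1,
                      p = c(0.9, 0.9, 0.9), q = c(0.9, 0.9, 0.9),
                      variable = c(FALSE, TRUE, FALSE),
                      method = "lm_anova")
  class(v) <- c("loop_variability", class(v))
  out <- static_sets(m, v, mode = "score_ranked")
  expect_length(out, 1L)
  # RE = 0 rows rank first, ordered by mean frequency
  expect_equal(out[1], "uniform8")
  sc <- attr(out, "static_score")
  expect_true(is.infinite(sc["uniform8"]))
  expect_lt(sc[["onehot8"]], Inf)
})

test_that("matched static sampling respects strata and reports deficits", {
  set.seed(2)
  n <- 2000
  m <- matrix(rpois(n * 4, 20), n, 4, dimnames = list(1:n, paste0("s", 1:4)))
  v <- tibble::tibble(loop_id = as.character(1:n), statistic = 1,
                      p = runif(n), q = c(rep(0.01, 40), runif(n - 40, 0.51, 1)),
                      variable = c(rep(TRUE, 40), rep(FALSE, n - 40)),
                      method = "lm_anova")
  class(v) <- c("loop_variability", class(v))
  scores <- tibble::tibble(loop_id = 1:n, p = runif(n))
  spans <- stats::setNames(runif(n, 1e4, 5e6), 1:n)
  out <- static_sets(m, v, loop_scores = scores, spans = spans,
                     mode = "matched", seed = 3)
  expect_length(out, 40L)
  expect_true(all(v$q[match(out, v$loop_id)] > 0.5))
  # matched strata have identical per-stratum counts
  dec <- function(x) as.integer(cut(x, unique(quantile(x, 0:10 / 10)),
                                    include.lowest = TRUE))
  strat <- paste(dec(spans), dec(scores$p))
  expect_equal(sort(table(strat[match(out, as.character(1:n))])),
               sort(table(strat[v$variable])))
  # determinism
  expect_identical(out, static_sets(m, v, loop_scores = scores,
                                    spans = spans, mode = "matched",
                                    seed = 3))
  # infeasible when candidates are exhausted
  v2 <- v; v2$q[41:n] <- 0.1
  expect_error(static_sets(m, v2, loop_scores = scores, spans = spans,
                           mode = "matched"), "infeasible")
})

test_that("entropy gene classification finds planted tails", {
  expr <- tibble::tibble(
    gene_id = sprintf("G%02d", 1:30),
    A = c(rep(50, 10), rep(0.01, 10), runif(10, 1, 80)),
    B = c(rep(50, 10), rep(0.01, 10), runif(10, 1, 80)),
    C = c(rep(50, 10), c(64, rep(0.01, 9)), runif(10, 1, 80)),
    D = c(rep(50, 10), rep(c(64, 0.01), c(9, 1)), runif(10, 1, 80))
  )
  gc <- classify_genes_entropy(expr, tail = 0.10)
  expect_length(gc$cell_type_specific, 3L)  # floor(0.1 * 30)
  expect_length(gc$housekeeping, 3L)
  # uniform >1 TPM genes are housekeeping; one-hot genes are specific
  expect_true(all(gc$housekeeping %in% sprintf("G%02d", 1:10)))
  expect_true(all(gc$cell_type_specific %in% sprintf("G%02d", 11:20)))
  expect_length(intersect(gc$housekeeping, gc$cell_type_specific), 0L)
  expect_error(classify_genes_entropy(expr[1:5, ]), "fewer than 10")
})

test_that("planted housekeeping and specific genes are recovered", {
  sim <- default_sim()
  ex_ct <- average_by_cell_type(sim$expression, sim$samples)
  gc <- classify_genes_entropy(ex_ct)
  gt <- sim$gene_truth
  hk_truth <- gt$gene_id[gt$housekeeping]
  cts_truth <- gt$gene_id[!is.na(gt$target_cell) & !gt$housekeeping]
  expect_gt(mean(hk_truth %in% gc$housekeeping), 0.8)
  expect_gt(mean(cts_truth %in% gc$cell_type_specific), 0.8)
})
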