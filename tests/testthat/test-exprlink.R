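toy_geometry <- function() {
  loops <- tibble::tibble(
    loop_id = 1L, chrom = "chr1",
    anchor_a = 1L, anchor_b = 2L,
    start_a = 10000L, end_a = 11000L,
    start_b = 60000L, end_b = 61000L
  )
  genes <- tibble::tibble(
    gene_id = c("near_prom", "contained", "far"),
    chrom = "chr1", strand = "+",
    start = c(11500L, 30000L, 200000L),
    end = c(20000L, 40000L, 250000L),
    tss = c(11500L, 30000L, 200000L),
    biotype = "protein_coding"
  )
  list(loops = loops, genes = genes)
}

test_that("loop-gene maps follow their geometric rules", {
  g <- toy_geometry()
  # TSS 500 bp from the anchor edge -> promoter map
  pm <- map_loops_to_genes(g$loops, g$genes, scheme = "promoter")
  expect_equal(pm$gene_id, "near_prom")
  # gene strictly inside the span, TSS far from both anchors -> contained
  cm <- map_loops_to_genes(g$loops, g$genes, scheme = "contained")
  expect_equal(cm$gene_id, "contained")
  # "all" covers both; the distant gene is in no map
  am <- map_loops_to_genes(g$loops, g$genes, scheme = "all")
  expect_setequal(am$gene_id, c("near_prom", "contained"))
  # promoter_enhancer needs an enhancer at the far anchor
  enh_far <- tibble::tibble(chrom = "chr1", start = 60200L, end = 60400L)
  pe <- map_loops_to_genes(g$loops, g$genes, enhancers = enh_far,
                           scheme = "promoter_enhancer")
  expect_equal(pe$gene_id, "near_prom")
  enh_elsewhere <- tibble::tibble(chrom = "chr1", start = 150000L,
                                  end = 150200L)
  pe2 <- map_loops_to_genes(g$loops, g$genes, enhancers = enh_elsewhere,
                            scheme = "promoter_enhancer")
  expect_equal(nrow(pe2), 0L)
})

test_that("map pairs re-verify their geometric predicate", {
  sim <- tiny_sim()
  pm <- map_loops_to_genes(sim$loops, sim$genes, scheme = "promoter")
  li <- match(pm$loop_id, sim$loops$loop_id)
  gi <- match(pm$gene_id, sim$genes$gene_id)
  tss <- sim$genes$tss[gi]
  near_a <- tss >= sim$loops$start_a[li] - 1000 &
    tss < sim$loops$end_a[li] + 1000
  near_b <- tss >= sim$loops$start_b[li] - 1000 &
    tss < sim$loops$end_b[li] + 1000
  expect_true(all(near_a | near_b))
  cm <- map_loops_to_genes(sim$loops, sim$genes, scheme = "contained")
  if (nrow(cm) > 0) {
    li <- match(cm$loop_id, sim$loops$loop_id)
    gi <- match(cm$gene_id, sim$genes$gene_id)
    expect_true(all(sim$genes$start[gi] >= sim$loops$start_a[li] &
                      sim$genes$end[gi] <= sim$loops$end_b[li]))
  }
})

test_that("loop-expression correlation is exact for monotone coupling and
           its shuffle preserves per-loop multiplicity", {
  sheet <- tibble::tibble(
    sample_id = paste0("c", 1:6), cell_type = paste0("c", 1:6),
    replicate = 1L, group = rep(c("blood", "embryonic", "solid"), 2),
    batch = "b", depth = 1
  )
  set.seed(10)
  lm_mat <- matrix(runif(30, 0, 1000), 5, 6,
                   dimnames = list(paste0("L", 1:5), sheet$sample_id))
  expr <- 2^(lm_mat / 200)  # strictly monotone transform
  rownames(expr) <- paste0("G", 1:5)
  map <- tibble::tibble(loop_id = paste0("L", c(1, 1, 2, 3, 4, 5)),
                        gene_id = paste0("G", c(1, 2, 2, 3, 4, 5)),
                        scheme = "promoter")
  # gene Gk equals a monotone transform of loop Lk -> rho exactly 1
  lec <- loop_expression_correlation(lm_mat, expr, map, sheet,
                                     n_shuffles = 20, seed = 1)
  exact <- lec$pairs$rho[lec$pairs$loop_id == "L3"]
  expect_equal(unname(exact), 1)
  # the shuffled mapping preserves the per-loop gene count histogram
  set.seed(1)
  shuffled <- sample(map$gene_id)
  expect_equal(table(table(map$loop_id)), table(table(map$loop_id)))
  expect_equal(sort(as.vector(table(map$loop_id))),
               sort(as.vector(table(map$loop_id[order(shuffled)]))))
  expect_error(loop_expression_correlation(lm_mat[, 1:4], expr[, 1:4],
                                           map, sheet[1:4, ]),
               "cell types")
})

test_that("gene pairs sharing a variable loop co-express above controls", {
  sim <- default_sim()
  m <- sim$counts; rownames(m) <- sim$loops$loop_id
  m <- suppressMessages(drop_invariant_rows(filter_testable(m)))
  var_ids <- sim$truth$loop_id[sim$truth$variable]
  cx <- suppressMessages(coexpression_in_loops(
    sim$genes, sim$loops, var_ids, sim$expression, sim$samples
  ))
  # self-pairs are excluded by construction
  expect_false(any(cx$pairs$gene_1 == cx$pairs$gene_2))
  ok <- !is.na(cx$medians$median_same_loop)
  expect_gt(
    mean(cx$medians$median_same_loop[ok] > cx$medians$median_control[ok]),
    0.5
  )
})

test_that("enhancer dose-response bins genes and ranks expression", {
  # constructed data: expression increases with linked-enhancer count
  genes <- tibble::tibble(
    gene_id = paste0("G", 1:9), chrom = "chr1", strand = "+",
    start = seq(10000L, 90000L, 10000L),
    end = seq(10000L, 90000L, 10000L) + 5000L,
    tss = seq(10000L, 90000L, 10000L), biotype = "protein_coding"
  )
  # per gene: k loops from its promoter to k distinct enhancer anchors
  k_of <- rep(1:3, each = 3)
  loops <- purrr::map_dfr(1:9, function(i) {
    k <- k_of[i]
    tibble::tibble(
      loop_id = i * 10L + seq_len(k), chrom = "chr1",
      anchor_a = i * 100L, anchor_b = i * 100L + seq_len(k),
      start_a = genes$tss[i] - 500L, end_a = genes$tss[i] + 500L,
      start_b = 500000L + i * 10000L + seq_len(k) * 2000L,
      end_b = 500000L + i * 10000L + seq_len(k) * 2000L + 1000L
    )
  })
  enh <- tibble::tibble(chrom = "chr1", start = loops$start_b + 100L,
                        end = loops$start_b + 300L,
                        enh_id = paste0("E", seq_len(nrow(loops))))
  sheet <- tibble::tibble(sample_id = c("X_r1", "X_r2"), cell_type = "X",
                          replicate = 1:2, group = "blood", batch = "b",
                          depth = 1)
  expr <- matrix(rep(2^k_of, 2), 9, 2,
                 dimnames = list(genes$gene_id, sheet$sample_id))
  cell_sets <- list(X = list(loops = loops$loop_id, enhancer_track = enh,
                             genes = genes$gene_id))
  dr <- enhancer_dose_response(cell_sets, loops, genes, expr, sheet)
  expect_equal(as.vector(table(dr$genes$bin)), c(3, 3, 3))
  med <- tapply(dr$genes$expr, dr$genes$bin, median)
  expect_true(all(diff(med) > 0))
  expect_equal(nrow(dr$tests), 3L)
})
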