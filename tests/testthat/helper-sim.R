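# Shared simulations, built once per test run and memoised, so several
# test files can reuse the same desk-scale study.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# Default-condition study: 5,000 loops, 6 cell types x 2 replicates.
default_sim <- function() {
  cached("default_sim", {
    suppressMessages(
      simulate_loop_study(synth_config(seed = 61, n_loops = 5000))
    )
  })
}

# The default study taken through filtering and normalization.
default_norm <- function() {
  cached("default_norm", {
    sim <- default_sim()
    m <- sim$counts
    rownames(m) <- sim$loops$loop_id
    m <- suppressMessages(drop_invariant_rows(filter_testable(m)))
    list(sim = sim, counts = m, norm = normalize_matrix(m),
         weights = suppressWarnings(voom_weights(m, sim$samples)))
  })
}

# A tiny study for fast structural tests.
tiny_sim <- function() {
  cached("tiny_sim", {
    suppressMessages(simulate_loop_study(
      synth_config(seed = 7, n_anchors = 100, n_loops = 600,
                   library_depth = 50000, n_genes = 80)
    ))
  })
}

brute_force_overlaps <- function(query, subject, min_overlap = 1) {
  out <- NULL
  for (i in seq_len(nrow(query))) {
    shared <- pmin(query$end[i], subject$end) -
      pmax(query$start[i], subject$start)
    j <- which(subject$chrom == query$chrom[i] & shared >= min_overlap)
    if (length(j) > 0) out <- rbind(out, cbind(i, j))
  }
  if (is.null(out)) {
    return(tibble::tibble(query_idx = integer(), subject_idx = integer()))
  }
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  tibble::tibble(query_idx = as.integer(out[, 1]),
                 subject_idx = as.integer(out[, 2]))
}

random_track <- function(n, seed, chroms = c("chr1", "chr2"), span = 5000) {
  set.seed(seed)
  start <- sample.int(span, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(300, n, replace = TRUE)
  )
}
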