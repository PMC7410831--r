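#' Simulate anchors and candidate loops
#'
#' Places disjoint cohesin anchors along each chromosome (one anchor per
#' equal-width slot, with jittered position and width) and enumerates every
#' intra-chromosomal anchor pair whose midpoint distance lies strictly
#' inside the candidate span window (10 kb to 5 Mb by default). Each anchor
#' receives a log-normal ChIP-efficiency factor.
#'
#' @param config A [synth_config()].
#' @return List with `anchors` (tibble: `chrom`, `start`, `end`,
#'   `anchor_id`, `efficiency`) and `loops` (tibble: `loop_id`, `chrom`,
#'   `anchor_a`, `anchor_b`, coordinates and `span`).
#' @export
generate_anchors_and_loops <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(substream_seed(config$seed, 1L))
  n_per <- ceiling(config$n_anchors / config$n_chroms)
  slot <- config$chrom_length / n_per
  if (slot < 4000) {
    stop("generate_anchors_and_loops: chromosomes too short for n_anchors ",
         "(slot width ", round(slot), " bp < 4000 bp)", call. = FALSE)
  }
  # uniform-random disjoint placement (min gap 3 kb) gives a continuous
  # span distribution, matching the smooth power-law decay model
  gap <- 3000
  anchors <- purrr::map_dfr(seq_len(config$n_chroms), function(ci) {
    width <- round(stats::runif(n_per, 800, 2500))
    slack <- config$chrom_length - sum(width) - n_per * gap
    if (slack <= 0) {
      stop("generate_anchors_and_loops: chromosome too short for n_anchors",
           call. = FALSE)
    }
    u <- sort(stats::runif(n_per, 0, slack))
    start <- as.integer(round(u + c(0, cumsum(width + gap))[seq_len(n_per)]))
    tibble::tibble(
      chrom = paste0("chr", ci),
      start = start,
      end = start + as.integer(width)
    )
  })
  anchors <- dplyr::arrange(anchors, .data$chrom, .data$start)
  anchors$anchor_id <- seq_len(nrow(anchors))
  anchors$efficiency <- stats::rlnorm(nrow(anchors), meanlog = 0, sdlog = 0.5)

  loops <- candidate_pairs(anchors, config$min_span, config$max_span)
  if (!is.null(config$n_loops) && config$n_loops < nrow(loops)) {
    keep <- sort(sample.int(nrow(loops), config$n_loops))
    loops <- loops[keep, ]
  }
  loops$loop_id <- seq_len(nrow(loops))
  list(anchors = anchors, loops = dplyr::relocate(loops, "loop_id"))
}

# All intra-chromosomal anchor pairs with midpoint span strictly inside
# (min_span, max_span), in genome order.
candidate_pairs <- function(anchors, min_span, max_span) {
  mids <- (anchors$start + anchors$end) / 2
  purrr::map_dfr(split(seq_len(nrow(anchors)), anchors$chrom), function(idx) {
    m <- mids[idx]
    n <- length(m)
    if (n < 2) return(NULL)
    pairs <- purrr::map_dfr(seq_len(n - 1), function(i) {
      d <- m[(i + 1):n] - m[i]
      j <- which(d > min_span & d < max_span) + i
      if (length(j) == 0) return(NULL)
      tibble::tibble(ai = idx[i], bj = idx[j])
    })
    pairs
  }) -> p
  if (nrow(p) == 0) {
    stop("candidate_pairs: no anchor pairs inside the span window",
         call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = anchors$chrom[p$ai],
    anchor_a = anchors$anchor_id[p$ai],
    anchor_b = anchors$anchor_id[p$bj],
    start_a = anchors$start[p$ai], end_a = anchors$end[p$ai],
    start_b = anchors$start[p$bj], end_b = anchors$end[p$bj],
    span = (anchors$start[p$bj] + anchors$end[p$bj]) / 2 -
      (anchors$start[p$ai] + anchors$end[p$ai]) / 2
  )
  dplyr::arrange(out, .data$chrom, .data$start_a, .data$start_b)
}

#' Simulated sample sheet
#'
#' Three biological groups (blood, embryonic, solid) with
#' `n_cell_types_per_group` cell types each and `n_replicates` replicates
#' per cell type; batches are assigned at random (two batches) so that any
#' batch-PC association is null by construction.
#'
#' @param config A [synth_config()].
#' @return Sample sheet tibble.
#' @export
generate_samples <- function(config) {
  set.seed(substream_seed(config$seed, 2L))
  groups <- c("blood", "embryonic", "solid")
  prefix <- c(blood = "BLD", embryonic = "EMB", solid = "SOL")
  sheet <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(seq_len(config$n_cell_types_per_group), function(k) {
      ct <- paste0(prefix[[g]], k)
      tibble::tibble(
        sample_id = paste0(ct, "_rep", seq_len(config$n_replicates)),
        cell_type = ct,
        replicate = seq_len(config$n_replicates),
        group = g
      )
    })
  })
  sheet$batch <- paste0("batch", sample(1:2, nrow(sheet), replace = TRUE))
  sheet$depth <- config$library_depth
  validate_sample_sheet(sheet)
}

#' Planted per-loop truth
#'
#' Flags `frac_variable` of loops as variable (each with a single target
#' cell type), `frac_group_specific` per group as group-specific (elevated
#' in every cell type of the target group; disjoint from the variable set),
#' and `score_planted_frac` as carrying a pooled rate excess.
#'
#' @param config A [synth_config()].
#' @param loops Candidate loop tibble.
#' @param samples Sample sheet.
#' @return Tibble `loop_id`, `variable`, `target_cell`, `group_specific`,
#'   `score_planted`.
#' @export
generate_loop_truth <- function(config, loops, samples) {
  set.seed(substream_seed(config$seed, 3L))
  n <- nrow(loops)
  cells <- unique(samples$cell_type)
  truth <- tibble::tibble(
    loop_id = loops$loop_id,
    variable = FALSE,
    target_cell = NA_character_,
    driver_anchor = NA_integer_,
    group_specific = NA_character_,
    score_planted = FALSE
  )
  n_var <- round(config$frac_variable * n)
  pool <- seq_len(n)
  if (n_var > 0) {
    # variable loops are organised around "driver" anchors, each tied to
    # one target cell type: every loop incident to a driver varies
    # coherently in that cell, as loops emanating from a cell-type-
    # specific regulatory element do
    anchor_ids <- sample(unique(c(loops$anchor_a, loops$anchor_b)))
    idx <- integer(0)
    tcell <- character(0)
    driver <- integer(0)
    drivers <- character(0)
    for (a in anchor_ids) {
      if (length(idx) >= n_var) break
      inc <- setdiff(which(loops$anchor_a == a | loops$anchor_b == a), idx)
      if (length(inc) == 0) next
      ct <- sample(cells, 1)
      idx <- c(idx, inc)
      tcell <- c(tcell, rep(ct, length(inc)))
      driver <- c(driver, rep(a, length(inc)))
      drivers[as.character(a)] <- ct
    }
    keep <- seq_len(min(n_var, length(idx)))
    idx <- idx[keep]; tcell <- tcell[keep]; driver <- driver[keep]
    truth$variable[idx] <- TRUE
    truth$target_cell[idx] <- tcell
    truth$driver_anchor[idx] <- driver
    attr(truth, "anchor_targets") <- drivers[as.character(unique(driver))]
    pool <- setdiff(pool, idx)
  }
  n_gs <- round(config$frac_group_specific * n)
  for (g in unique(samples$group)) {
    if (n_gs > 0 && length(pool) >= n_gs) {
      idx <- sample(pool, n_gs)
      truth$group_specific[idx] <- g
      pool <- setdiff(pool, idx)
    }
  }
  n_sp <- round(config$score_planted_frac * n)
  if (n_sp > 0 && length(pool) >= n_sp) {
    idx <- sample(pool, n_sp)
    truth$score_planted[idx] <- TRUE
  }
  truth
}

#' Simulate the loop-by-sample PET count matrix
#'
#' Counts are negative-binomially dispersed around
#' \eqn{\mu_{ls} = D \cdot p_l \cdot s_{l,c(s)}} where \eqn{D} is the
#' library depth, \eqn{p_l \propto d_l^{-\alpha} e_i e_j} combines the
#' distance-decay and anchor-efficiency factors, and \eqn{s} is the planted
#' effect fold (variable loops in their target cell type, group-specific
#' loops in their target group, pooled-excess loops everywhere). Replicates
#' of a cell type share \eqn{\mu}.
#'
#' @param config A [synth_config()].
#' @param anchors,loops Output of [generate_anchors_and_loops()].
#' @param truth Output of [generate_loop_truth()].
#' @param samples Sample sheet.
#' @return List with `counts` (integer matrix, rows = loops in `loops`
#'   order, columns = `samples$sample_id`) and `mu` (matrix of means).
#' @export
generate_pet_counts <- function(config, anchors, loops, truth, samples) {
  set.seed(substream_seed(config$seed, 4L))
  e <- anchors$efficiency[match(loops$anchor_a, anchors$anchor_id)] *
    anchors$efficiency[match(loops$anchor_b, anchors$anchor_id)]
  w <- loops$span^(-config$decay_exponent) * e
  p <- w / sum(w)
  n <- nrow(loops)
  mu <- matrix(0, nrow = n, ncol = nrow(samples),
               dimnames = list(loops$loop_id, samples$sample_id))
  # each driver anchor carries a graded activity profile across cell
  # types, shared by all its loops, on top of the discrete target-cell
  # fold; loops from one regulatory locus therefore co-vary across all
  # cell types, not only in the target
  cells <- unique(samples$cell_type)
  driver_ids <- unique(truth$driver_anchor[!is.na(truth$driver_anchor)])
  gmod <- matrix(1, nrow = max(1, length(driver_ids)), ncol = length(cells),
                 dimnames = list(driver_ids, cells))
  if (length(driver_ids) > 0 && config$effect_size != 1) {
    gmod[] <- config$effect_size ^
      stats::runif(length(driver_ids) * length(cells), -0.5, 0.5)
  }
  for (s in seq_len(nrow(samples))) {
    fold <- rep(1, n)
    ct <- samples$cell_type[s]
    g <- samples$group[s]
    isv <- truth$variable & !is.na(truth$target_cell)
    fold[isv & truth$target_cell == ct] <- config$effect_size
    if (length(driver_ids) > 0) {
      fold[isv] <- fold[isv] * gmod[as.character(truth$driver_anchor[isv]), ct]
    }
    fold[!is.na(truth$group_specific) & truth$group_specific == g] <-
      config$effect_size
    fold[truth$score_planted] <- fold[truth$score_planted] *
      config$score_planted_fold
    mu[, s] <- config$library_depth * p * fold
  }
  counts <- mu
  for (s in seq_len(ncol(mu))) {
    counts[, s] <- if (config$nb_dispersion > 0) {
      stats::rnbinom(n, size = 1 / config$nb_dispersion, mu = mu[, s])
    } else {
      stats::rpois(n, mu[, s])
    }
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, mu = mu)
}

#' Materialise one sample's PETs as BEDPE records
#'
#' Each loop contributes its simulated count of PETs with 100-bp endpoint
#' intervals placed uniformly inside the two anchors; a configurable
#' fraction of background PETs is added at random genomic positions.
#'
#' @param config A [synth_config()].
#' @param anchors,loops As from [generate_anchors_and_loops()].
#' @param counts Count matrix from [generate_pet_counts()].
#' @param sample_id Column of `counts` to materialise.
#' @return BEDPE tibble (`chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`).
#' @export
sim_pet_records <- function(config, anchors, loops, counts, sample_id) {
  set.seed(substream_seed(config$seed, 100L + match(sample_id, colnames(counts))))
  k <- counts[, sample_id]
  idx <- rep(seq_len(nrow(loops)), k)
  draw_in <- function(start, end) {
    lo <- start
    hi <- pmax(lo + 1, end - 100)
    as.integer(floor(stats::runif(length(lo), lo, hi)))
  }
  a <- draw_in(loops$start_a[idx], loops$end_a[idx])
  b <- draw_in(loops$start_b[idx], loops$end_b[idx])
  out <- tibble::tibble(
    chrom_a = loops$chrom[idx], start_a = a, end_a = a + 100L,
    chrom_b = loops$chrom[idx], start_b = b, end_b = b + 100L
  )
  n_bg <- round(config$frac_background_pets * nrow(out))
  if (n_bg > 0) {
    chr <- paste0("chr", sample.int(config$n_chroms, n_bg, replace = TRUE))
    p1 <- as.integer(floor(stats::runif(n_bg, 0, config$chrom_length - 200)))
    gap <- as.integer(round(stats::runif(n_bg, 1000, 2e6)))
    p2 <- pmin(p1 + gap, as.integer(config$chrom_length - 200))
    bg <- tibble::tibble(
      chrom_a = chr, start_a = p1, end_a = p1 + 100L,
      chrom_b = chr, start_b = p2, end_b = p2 + 100L
    )
    out <- dplyr::bind_rows(out, bg)
  }
  out
}

#' Per-sample peak calls consistent with the simulated anchors
#'
#' Emits, for each sample, the anchor intervals jittered by up to 200 bp
#' and randomly thinned to 90%, emulating per-sample peak calling so that
#' [build_anchor_set()] approximately recovers the anchor set.
#'
#' @param config A [synth_config()].
#' @param anchors Anchor tibble.
#' @param samples Sample sheet.
#' @return Named list of per-sample peak tibbles.
#' @export
generate_peaks <- function(config, anchors, samples) {
  set.seed(substream_seed(config$seed, 5L))
  out <- lapply(samples$sample_id, function(s) {
    keep <- stats::runif(nrow(anchors)) < 0.9
    jit <- as.integer(round(stats::runif(sum(keep), -200, 200)))
    tibble::tibble(
      chrom = anchors$chrom[keep],
      start = pmax(0L, anchors$start[keep] + jit),
      end = anchors$end[keep] + jit
    )
  })
  names(out) <- samples$sample_id
  out
}
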