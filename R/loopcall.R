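#' Build the unified anchor set from per-sample peak calls
#'
#' Pools peak calls across samples, extends each peak by `extension_bp` on
#' both sides (clipped at position 0), merges overlapping intervals into
#' disjoint anchors, removes anchors overlapping the blacklist, and assigns
#' integer ids in genome order.
#'
#' @param peak_tracks A single peak tibble or a (per-sample) list of them.
#' @param extension_bp Extension in bp applied to each side of each peak.
#' @param blacklist Optional interval tibble of regions to exclude.
#' @return Anchor tibble (`chrom`, `start`, `end`, `anchor_id`).
#' @export
build_anchor_set <- function(peak_tracks, extension_bp = 500,
                             blacklist = NULL) {
  if (is.data.frame(peak_tracks)) peak_tracks <- list(peak_tracks)
  stopifnot(extension_bp >= 0)
  pooled <- dplyr::bind_rows(lapply(peak_tracks, function(x) {
    tibble::as_tibble(x)[, c("chrom", "start", "end")]
  }))
  if (nrow(pooled) == 0) {
    stop("build_anchor_set: pooled peak set is empty", call. = FALSE)
  }
  pooled$start <- pmax(0L, pooled$start - as.integer(extension_bp))
  pooled$end <- pooled$end + as.integer(extension_bp)
  anchors <- merge_intervals(pooled)
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    anchors <- anchors[!overlaps_any(anchors, blacklist), ]
  }
  anchors <- dplyr::arrange(anchors, .data$chrom, .data$start)
  anchors$anchor_id <- seq_len(nrow(anchors))
  anchors
}

# Assign each position (endpoint midpoint) to the anchor containing it;
# NA when no anchor contains the position.
assign_to_anchor <- function(chrom, pos, anchors) {
  pts <- tibble::tibble(chrom = chrom, start = as.integer(floor(pos)),
                        end = as.integer(floor(pos)) + 1L)
  hits <- overlap_join(pts, anchors[, c("chrom", "start", "end")])
  out <- rep(NA_integer_, length(pos))
  out[hits$query_idx] <- anchors$anchor_id[hits$subject_idx]
  out
}

#' Tabulate PETs into anchor-pair counts
#'
#' A PET increments the count of anchor pair (i, j) iff the midpoints of
#' both endpoint intervals fall inside two distinct anchors on the same
#' chromosome and the distance between the two anchor midpoints is strictly
#' inside `(min_span, max_span)`. Pairs are canonicalised to `i < j`.
#'
#' @param pets BEDPE tibble of PET endpoint pairs.
#' @param anchors Anchor tibble from [build_anchor_set()].
#' @param min_span,max_span Span window in bp (exclusive bounds).
#' @return Tibble (`anchor_a`, `anchor_b`, `span`, `count`), one row per
#'   observed pair.
#' @export
tabulate_pets <- function(pets, anchors, min_span = 10000,
                          max_span = 5000000) {
  if (nrow(pets) == 0) {
    return(tibble::tibble(anchor_a = integer(), anchor_b = integer(),
                          span = numeric(), count = integer()))
  }
  intra <- pets$chrom_a == pets$chrom_b
  a <- assign_to_anchor(pets$chrom_a, (pets$start_a + pets$end_a) / 2, anchors)
  b <- assign_to_anchor(pets$chrom_b, (pets$start_b + pets$end_b) / 2, anchors)
  keep <- intra & !is.na(a) & !is.na(b) & a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  mids <- (anchors$start + anchors$end)[match(seq_len(max(anchors$anchor_id)),
                                              anchors$anchor_id)] / 2
  span <- mids[hi] - mids[lo]
  ok <- span > min_span & span < max_span
  if (!any(ok)) {
    return(tibble::tibble(anchor_a = integer(), anchor_b = integer(),
                          span = numeric(), count = integer()))
  }
  tibble::tibble(anchor_a = lo[ok], anchor_b = hi[ok], span = span[ok]) |>
    dplyr::count(.data$anchor_a, .data$anchor_b, .data$span,
                 name = "count") |>
    dplyr::arrange(.data$anchor_a, .data$anchor_b)
}

#' Count pooled PET endpoints per anchor (ChIP efficiency)
#'
#' @param pets BEDPE tibble.
#' @param anchors Anchor tibble.
#' @return Integer vector of endpoint counts along `anchors` rows.
#' @export
count_anchor_endpoints <- function(pets, anchors) {
  a <- assign_to_anchor(pets$chrom_a, (pets$start_a + pets$end_a) / 2, anchors)
  b <- assign_to_anchor(pets$chrom_b, (pets$start_b + pets$end_b) / 2, anchors)
  tab <- table(factor(c(a, b), levels = anchors$anchor_id))
  as.integer(tab)
}

#' Down-sample a PET set to a fixed cap
#'
#' Libraries above `cap` unique PETs are reduced to a uniform
#' without-replacement subset of exactly `cap` records; smaller libraries
#' pass through unchanged. Deterministic under `seed`.
#'
#' @param pets BEDPE tibble.
#' @param cap Maximum PETs retained (default 2,250,000).
#' @param seed Integer seed.
#' @return BEDPE tibble.
#' @export
downsample_pets <- function(pets, cap = 2250000, seed = 1L) {
  stopifnot(cap > 0)
  if (nrow(pets) <= cap) return(pets)
  set.seed(as.integer(seed))
  pets[sort(sample.int(nrow(pets), cap)), ]
}

#' Score candidate loops against a distance- and efficiency-aware
#' Poisson background
#'
#' Candidate anchor pairs are assigned to equal-occupancy span bins; within
#' a bin the expected PET count of pair (i, j) is
#' \eqn{\lambda_{ij} = T_b \, e_i e_j / \sum_b e_a e_b}, the bin's total
#' PET count shared out proportionally to the product of the two anchors'
#' ChIP efficiencies. The p-value is the upper-tail Poisson probability
#' \eqn{P(X \ge k; \lambda_{ij})}; Benjamini-Hochberg and Bonferroni
#' adjusted values are reported. Bins with fewer than `min_bin_pairs`
#' candidates are widened (the bin count is reduced).
#'
#' @param pairs Tibble (`anchor_a`, `anchor_b`, `count`) of pooled counts,
#'   as from [tabulate_pets()] run on pooled PETs (or a summed matrix).
#' @param anchors Anchor tibble with an `efficiency` column (pooled PET
#'   endpoint counts, see [count_anchor_endpoints()]).
#' @param n_distance_bins Target number of equal-occupancy span bins.
#' @param min_bin_pairs Minimum candidate pairs per bin.
#' @param p_threshold Optional raw p-value call threshold (the full-scale
#'   study value is 2.3e-9); when `NULL`, calls use `fdr` on BH q-values.
#' @param fdr BH q-value threshold used when `p_threshold` is `NULL`.
#' @return Tibble with class `loop_scores`: `anchor_a`, `anchor_b`, `span`,
#'   `count`, `lambda`, `p`, `q_bh`, `q_bonf`, `called`.
#' @export
score_loops <- function(pairs, anchors, n_distance_bins = 50,
                        min_bin_pairs = 20, p_threshold = NULL, fdr = 0.01) {
  eff <- anchors$efficiency[match(pairs$anchor_a, anchors$anchor_id)] *
    anchors$efficiency[match(pairs$anchor_b, anchors$anchor_id)]
  zero <- is.na(eff) | eff <= 0
  if (any(zero)) {
    warning("score_loops: skipping ", sum(zero),
            " pair(s) with zero-efficiency anchors")
    pairs <- pairs[!zero, ]
    eff <- eff[!zero]
  }
  if (!"span" %in% names(pairs)) {
    mids <- (anchors$start + anchors$end) / 2
    pairs$span <- mids[match(pairs$anchor_b, anchors$anchor_id)] -
      mids[match(pairs$anchor_a, anchors$anchor_id)]
  }
  n <- nrow(pairs)
  n_bins <- max(1, min(n_distance_bins, floor(n / min_bin_pairs)))
  bin <- ceiling(rank(pairs$span, ties.method = "first") * n_bins / n)
  lambda <- numeric(n)
  for (b in unique(bin)) {
    ii <- which(bin == b)
    tot <- sum(pairs$count[ii])
    lambda[ii] <- tot * eff[ii] / sum(eff[ii])
  }
  p <- stats::ppois(pairs$count - 1, lambda, lower.tail = FALSE)
  out <- tibble::tibble(
    anchor_a = pairs$anchor_a, anchor_b = pairs$anchor_b,
    span = pairs$span, count = pairs$count, lambda = lambda, p = p,
    q_bh = stats::p.adjust(p, "BH"), q_bonf = stats::p.adjust(p, "bonferroni")
  )
  out$called <- if (!is.null(p_threshold)) out$p < p_threshold
                else out$q_bh < fdr
  class(out) <- c("loop_scores", class(out))
  out
}

#' Summarise CTCF motif orientation at loop anchors
#'
#' Restricts to loops whose two anchors each contain exactly one CTCF
#' motif, then classifies the pair of motif strands: `convergent`
#' (lower-coordinate anchor `+`, higher `-`), `divergent` (the reverse),
#' `tandem_plus` (`+/+`) or `tandem_minus` (`-/-`). Percentages are over
#' the included loops and sum to 100.
#'
#' @param loops Loop tibble with `chrom`, `start_a`, `end_a`, `start_b`,
#'   `end_b` (and optionally `loop_id`).
#' @param motifs Motif tibble (`chrom`, `start`, `end`, `strand`); strands
#'   must be `+` or `-`.
#' @return Tibble with class `ctcf_orientation`: `orientation`, `n`,
#'   `percent`; attribute `n_loops_included`.
#' @export
ctcf_orientation_summary <- function(loops, motifs) {
  if (any(!motifs$strand %in% c("+", "-"))) {
    stop("ctcf_orientation_summary: motif strands must be '+' or '-'",
         call. = FALSE)
  }
  side <- function(start, end) {
    trk <- tibble::tibble(chrom = loops$chrom, start = start, end = end)
    hits <- overlap_join(trk, motifs[, c("chrom", "start", "end")])
    n_m <- tabulate(hits$query_idx, nbins = nrow(loops))
    strand <- rep(NA_character_, nrow(loops))
    one <- hits$query_idx %in% which(n_m == 1)
    strand[hits$query_idx[one]] <- motifs$strand[hits$subject_idx[one]]
    list(n = n_m, strand = strand)
  }
  left <- side(loops$start_a, loops$end_a)
  right <- side(loops$start_b, loops$end_b)
  keep <- left$n == 1 & right$n == 1
  ori <- dplyr::case_when(
    left$strand == "+" & right$strand == "-" ~ "convergent",
    left$strand == "-" & right$strand == "+" ~ "divergent",
    left$strand == "+" & right$strand == "+" ~ "tandem_plus",
    left$strand == "-" & right$strand == "-" ~ "tandem_minus"
  )[keep]
  lev <- c("convergent", "divergent", "tandem_plus", "tandem_minus")
  n <- as.integer(table(factor(ori, levels = lev)))
  out <- tibble::tibble(
    orientation = lev, n = n,
    percent = if (sum(n) > 0) 100 * n / sum(n) else rep(NA_real_, 4)
  )
  attr(out, "n_loops_included") <- sum(keep)
  class(out) <- c("ctcf_orientation", class(out))
  out
}
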