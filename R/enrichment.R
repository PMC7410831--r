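#' Two-by-two Fisher enrichment
#'
#' Builds the contingency table `rbind(c(a, b), c(c, d))`, reports the
#' cross-product odds ratio `(a*d)/(b*c)` (with `Inf`/`0` and a
#' `degenerate` flag when a zero cell makes it so) and the two-sided
#' Fisher exact p-value (the sum of hypergeometric probabilities no
#' larger than the observed table's).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param label Optional label carried through.
#' @return One-row tibble: `label`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `degenerate`, `p`.
#' @export
fisher_2x2 <- function(a, b, c, d, label = NA_character_) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_2x2: cells must be non-negative integers", call. = FALSE)
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("fisher_2x2: a margin of the table is zero", call. = FALSE)
  }
  or <- if (b * c > 0) (a * d) / (b * c) else if (a * d > 0) Inf else 0
  p <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
  tibble::tibble(label = label, a = a, b = b, c = c, d = d,
                 odds_ratio = or, degenerate = (b * c == 0) || (a * d == 0),
                 p = p)
}

# Loop ends (= anchor intervals) of a loop table, two rows per loop.
loop_ends <- function(loops) {
  dplyr::bind_rows(
    tibble::tibble(loop_id = loops$loop_id, chrom = loops$chrom,
                   start = loops$start_a, end = loops$end_a, side = "a",
                   anchor_id = loops$anchor_a),
    tibble::tibble(loop_id = loops$loop_id, chrom = loops$chrom,
                   start = loops$start_b, end = loops$end_b, side = "b",
                   anchor_id = loops$anchor_b)
  )
}

#' Anchor-connectivity ("hub") enrichment profile
#'
#' Bins anchors by their degree (number of loops touching them) and, for
#' each bin and feature track, tests whether in-bin anchors are enriched
#' for overlapping the feature relative to anchors in all other bins
#' (Fisher 2x2; BH across bins within a feature).
#'
#' @param loops Loop tibble (`anchor_a`, `anchor_b`, coordinates).
#' @param anchors Anchor tibble.
#' @param feature_tracks Named list of interval tibbles (e.g. enhancer,
#'   promoter, domain boundary).
#' @param degree_breaks Lower edges of the degree bins; the last bin is
#'   open-ended (default bins 1, 2, 3, 4, 5+). Anchors with degree 0 are
#'   excluded.
#' @return Tibble of enrichment rows (`feature`, `bin`, counts, odds
#'   ratio, `p`, `q`).
#' @export
connectivity_profile <- function(loops, anchors, feature_tracks,
                                 degree_breaks = c(1, 2, 3, 4, 5)) {
  deg <- tabulate(match(c(loops$anchor_a, loops$anchor_b),
                        anchors$anchor_id), nbins = nrow(anchors))
  keep <- deg > 0
  anc <- anchors[keep, ]
  deg <- deg[keep]
  labs <- c(utils::head(degree_breaks, -1),
            paste0(utils::tail(degree_breaks, 1), "+"))
  bin <- cut(deg, breaks = c(degree_breaks - 0.5, Inf), labels = labs)
  purrr::map_dfr(names(feature_tracks), function(f) {
    ov <- overlaps_any(anc, feature_tracks[[f]])
    rows <- purrr::map_dfr(levels(bin), function(bl) {
      inb <- bin == bl
      if (!any(inb) || all(inb)) {
        message("connectivity_profile: degree bin ", bl,
                if (!any(inb)) " is empty" else " holds every anchor",
                "; skipped")
        return(NULL)
      }
      res <- fisher_2x2(sum(inb & ov), sum(inb & !ov),
                        sum(!inb & ov), sum(!inb & !ov), label = bl)
      dplyr::mutate(res, feature = f, bin = bl, .before = 1)
    })
    if (nrow(rows) == 0) return(NULL)
    rows$q <- stats::p.adjust(rows$p, "BH")
    rows
  })
}

#' Chromatin-state enrichment at cell-type-specific loop ends
#'
#' For each cell type's specific loop set and each of the eight merged
#' chromatin states, tests whether loop ends participating in a specific
#' interaction overlap the state more often than non-specific loop ends
#' (Fisher 2x2, BH across all cell-state combinations). Also reports the
#' state composition of specific loop ends per cell type.
#'
#' @param specific_sets Named list (cell type -> loop id vector or
#'   `specific_set`).
#' @param loops Loop tibble covering all tested loops.
#' @param states State tibble (`chrom`, `start`, `end`, `state`) with
#'   labels among TSS, BIV, TX, REPRESS, REPEAT, ENH, HET, QUIES, or a
#'   named list of such tibbles, one per cell type (state maps are
#'   cell-type-resolved in practice).
#' @return List with `enrichment` (tibble per cell-state) and
#'   `composition` (tibble of per-cell state proportions, summing to 1).
#' @export
state_enrichment <- function(specific_sets, loops, states) {
  states8 <- c("TSS", "BIV", "TX", "REPRESS", "REPEAT", "ENH", "HET", "QUIES")
  state_of <- function(ct) {
    trk <- if (is.data.frame(states)) states else states[[ct]]
    if (is.null(trk)) {
      stop("state_enrichment: no state track for cell type '", ct, "'",
           call. = FALSE)
    }
    bad <- setdiff(unique(trk$state), states8)
    if (length(bad) > 0) {
      stop("state_enrichment: unknown state label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    trk
  }
  ends <- loop_ends(loops)
  rows <- list(); comps <- list()
  for (ct in names(specific_sets)) {
    trk <- state_of(ct)
    ov <- sapply(states8, function(s) {
      overlaps_any(ends, trk[trk$state == s, ])
    })
    ids <- specific_sets[[ct]]
    if (inherits(ids, "specific_set")) ids <- ids$members
    spec <- ends$loop_id %in% ids
    rows[[ct]] <- purrr::map_dfr(states8, function(s) {
      cells <- c(sum(spec & ov[, s]), sum(spec & !ov[, s]),
                 sum(!spec & ov[, s]), sum(!spec & !ov[, s]))
      if ((cells[1] + cells[2]) == 0 || (cells[3] + cells[4]) == 0 ||
            (cells[1] + cells[3]) == 0 || (cells[2] + cells[4]) == 0) {
        message("state_enrichment: degenerate table for (", ct, ", ", s,
                "); skipped")
        return(NULL)
      }
      r <- fisher_2x2(cells[1], cells[2], cells[3], cells[4], label = s)
      dplyr::mutate(r, cell_type = ct, state = s, .before = 1)
    })
    cnt <- colSums(ov[spec, , drop = FALSE])
    comps[[ct]] <- tibble::tibble(
      cell_type = ct, state = states8,
      proportion = if (sum(cnt) > 0) cnt / sum(cnt)
                   else rep(NA_real_, length(cnt))
    )
  }
  res <- dplyr::bind_rows(rows)
  res$q <- stats::p.adjust(res$p, "BH")
  list(enrichment = res, composition = dplyr::bind_rows(comps))
}

#' Enhancer/promoter pair-type enrichment of cell-type-specific loops
#'
#' Labels each loop end as ENH if it overlaps a cell-type-specific
#' enhancer and TSS if it overlaps a specific gene's promoter (the 500-bp
#' strand-aware window immediately upstream of the gene start). For each
#' end combination (ENH-ENH, ENH-TSS, TSS-TSS), tests specific vs
#' non-specific loops for carrying the combination (Fisher 2x2). A loop
#' whose ends carry several labels contributes to every matching
#' combination.
#'
#' @param specific_loops Loop ids (or `specific_set`) of the cell type.
#' @param specific_enhancers Interval tibble of the cell type's specific
#'   enhancers.
#' @param specific_genes Gene tibble (with `tss`, `strand`) of the cell
#'   type's specific genes.
#' @param loops All tested loops.
#' @return Enrichment tibble, one row per pair type.
#' @export
pairtype_enrichment <- function(specific_loops, specific_enhancers,
                                specific_genes, loops) {
  if (inherits(specific_loops, "specific_set")) {
    specific_loops <- specific_loops$members
  }
  if (length(specific_loops) == 0 || nrow(specific_enhancers) == 0 ||
      nrow(specific_genes) == 0) {
    stop("pairtype_enrichment: empty specific set", call. = FALSE)
  }
  prom <- promoter_windows(specific_genes, width = 500)
  is_enh_a <- overlaps_any(
    tibble::tibble(chrom = loops$chrom, start = loops$start_a,
                   end = loops$end_a), specific_enhancers)
  is_enh_b <- overlaps_any(
    tibble::tibble(chrom = loops$chrom, start = loops$start_b,
                   end = loops$end_b), specific_enhancers)
  is_tss_a <- overlaps_any(
    tibble::tibble(chrom = loops$chrom, start = loops$start_a,
                   end = loops$end_a), prom)
  is_tss_b <- overlaps_any(
    tibble::tibble(chrom = loops$chrom, start = loops$start_b,
                   end = loops$end_b), prom)
  combos <- list(
    "ENH-ENH" = is_enh_a & is_enh_b,
    "ENH-TSS" = (is_enh_a & is_tss_b) | (is_tss_a & is_enh_b),
    "TSS-TSS" = is_tss_a & is_tss_b
  )
  spec <- loops$loop_id %in% specific_loops
  purrr::map_dfr(names(combos), function(cb) {
    has <- combos[[cb]]
    r <- fisher_2x2(sum(spec & has), sum(spec & !has),
                    sum(!spec & has), sum(!spec & !has), label = cb)
    dplyr::mutate(r, pair_type = cb, .before = 1)
  })
}

#' Strand-aware promoter windows
#'
#' @param genes Gene tibble with `chrom`, `strand` and either `tss` or
#'   `start`/`end`.
#' @param width Window width in bp immediately upstream of the gene start.
#' @return Interval tibble.
#' @export
promoter_windows <- function(genes, width = 500) {
  tss <- if ("tss" %in% names(genes)) genes$tss
         else ifelse(genes$strand == "+", genes$start, genes$end)
  start <- ifelse(genes$strand == "+", tss - width, tss)
  tibble::tibble(chrom = genes$chrom, start = pmax(0, start),
                 end = start + width, gene_id = genes$gene_id)
}

#' TF-motif enrichment at group-specific loop ends
#'
#' Per transcription factor: a 2x2 table over loop ends (group-specific
#' vs not, motif-overlapping vs not), Fisher-tested. TFs whose table has
#' any cell below `min_cell` are excluded; BH across tested TFs.
#'
#' @param group_loops Loop ids (or `specific_set`) of the group.
#' @param motifs Motif tibble with a `name` column identifying the TF.
#' @param loops All tested loops.
#' @param min_cell Minimum count allowed in any table cell.
#' @return Tibble with one row per tested TF (`tf`, counts, odds ratio,
#'   `p`, `q`); excluded TFs are absent.
#' @export
motif_enrichment <- function(group_loops, motifs, loops, min_cell = 5) {
  if (inherits(group_loops, "specific_set")) group_loops <- group_loops$members
  ends <- loop_ends(loops)
  spec <- ends$loop_id %in% group_loops
  res <- purrr::map_dfr(unique(motifs$name), function(tf) {
    ov <- overlaps_any(ends, motifs[motifs$name == tf, ])
    cells <- c(sum(spec & ov), sum(spec & !ov), sum(!spec & ov),
               sum(!spec & !ov))
    if (any(cells < min_cell)) return(NULL)
    r <- fisher_2x2(cells[1], cells[2], cells[3], cells[4], label = tf)
    dplyr::mutate(r, tf = tf, .before = 1)
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(tf = character(), label = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), odds_ratio = numeric(),
                          degenerate = logical(), p = numeric(),
                          q = numeric()))
  }
  res$q <- stats::p.adjust(res$p, "BH")
  res
}

#' Gene-connectivity enrichment for a gene list
#'
#' For each threshold X in `x_range`, tests list membership against
#' having at least X loops connected to the gene's promoter (Fisher 2x2,
#' BH across X, reported as log2 odds ratio).
#'
#' @param gene_list Character vector of gene ids (e.g. disease genes).
#' @param promoter_map Loop-gene map tibble (`loop_id`, `gene_id`) from
#'   [map_loops_to_genes()] under the promoter scheme, optionally
#'   pre-filtered to enhancer loops.
#' @param all_genes Character vector of the gene universe.
#' @param x_range Integer thresholds (default 1:10).
#' @return Tibble (`x`, counts, `log2_or`, `p`, `q`).
#' @export
gene_connectivity_enrichment <- function(gene_list, promoter_map, all_genes,
                                         x_range = 1:10) {
  gene_list <- intersect(gene_list, all_genes)
  if (length(gene_list) == 0) {
    stop("gene_connectivity_enrichment: gene list disjoint from universe",
         call. = FALSE)
  }
  degree <- table(promoter_map$gene_id)
  deg <- stats::setNames(rep(0, length(all_genes)), all_genes)
  deg[names(degree)] <- as.integer(degree)
  in_list <- all_genes %in% gene_list
  res <- purrr::map_dfr(x_range, function(x) {
    hi <- deg >= x
    if (all(hi) || !any(hi)) {
      message("gene_connectivity_enrichment: threshold X=", x,
              " is degenerate (all or no genes pass); skipped")
      return(NULL)
    }
    if (all(in_list) || !any(in_list)) {
      # the list covers the whole universe (or none of it): membership is
      # uninformative, odds ratio 1 by convention
      r <- tibble::tibble(label = as.character(x), a = sum(in_list & hi),
                          b = sum(in_list & !hi), c = sum(!in_list & hi),
                          d = sum(!in_list & !hi), odds_ratio = 1,
                          degenerate = TRUE, p = 1)
    } else {
      r <- fisher_2x2(sum(in_list & hi), sum(in_list & !hi),
                      sum(!in_list & hi), sum(!in_list & !hi),
                      label = as.character(x))
    }
    dplyr::mutate(r, x = x, log2_or = log2(.data$odds_ratio), .before = 1)
  })
  if (nrow(res) == 0) {
    stop("gene_connectivity_enrichment: every threshold degenerate",
         call. = FALSE)
  }
  res$q <- stats::p.adjust(res$p, "BH")
  res
}

#' Average a per-bp signal across motif instances
#'
#' Extracts a window of `2 * flank_bp + 1` positions centred on each
#' motif midpoint from a bedGraph-style signal table, reverses windows on
#' `-`-strand motifs, and averages elementwise. When `anchor_subset` is
#' given, profiles are computed separately for motifs overlapping that
#' subset and for all motifs, together with their ratio.
#'
#' @param signal Tibble (`chrom`, `start`, `end`, `value`), bedGraph
#'   semantics (value constant over the half-open interval; positions not
#'   covered are 0).
#' @param motifs Motif tibble with `strand`.
#' @param flank_bp Flank on each side of the motif midpoint.
#' @param anchor_subset Optional interval tibble restricting a second
#'   profile.
#' @return List with `profile` (numeric, length `2*flank_bp+1`),
#'   `n_motifs`, `n_skipped` and, when subsetting, `subset_profile` and
#'   `ratio`.
#' @export
aggregate_signal_at_motifs <- function(signal, motifs, flank_bp = 100,
                                       anchor_subset = NULL) {
  width <- 2L * as.integer(flank_bp) + 1L
  one_profile <- function(mot) {
    acc <- numeric(width)
    used <- 0L
    skipped <- 0L
    for (i in seq_len(nrow(mot))) {
      centre <- floor((mot$start[i] + mot$end[i]) / 2)
      w0 <- centre - flank_bp
      w1 <- centre + flank_bp
      if (w0 < 0) { skipped <- skipped + 1L; next }
      seg <- signal[signal$chrom == mot$chrom[i] & signal$end > w0 &
                      signal$start <= w1, ]
      vec <- numeric(width)
      for (r in seq_len(nrow(seg))) {
        lo <- max(seg$start[r], w0) - w0 + 1
        hi <- min(seg$end[r] - 1, w1) - w0 + 1
        if (hi >= lo) vec[lo:hi] <- seg$value[r]
      }
      if (!is.null(mot$strand) && mot$strand[i] == "-") vec <- rev(vec)
      acc <- acc + vec
      used <- used + 1L
    }
    list(profile = if (used > 0) acc / used else rep(NA_real_, width),
         n = used, skipped = skipped)
  }
  all_p <- one_profile(motifs)
  out <- list(profile = all_p$profile, n_motifs = all_p$n,
              n_skipped = all_p$skipped)
  if (!is.null(anchor_subset)) {
    sub <- motifs[overlaps_any(motifs, anchor_subset), ]
    sub_p <- one_profile(sub)
    out$subset_profile <- sub_p$profile
    out$ratio <- sub_p$profile / all_p$profile
  }
  out
}
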