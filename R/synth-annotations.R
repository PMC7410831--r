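#' Simulate regulatory annotations coupled to the loop structure
#'
#' Generates every annotation layer the downstream analyses consume, with
#' planted structure tied to the loop truth:
#' \itemize{
#'   \item gene models (a subset built around planted intragenic
#'     promoter-to-gene-body loops; anchor-proximal genes preferentially
#'     at driver anchors) with exons;
#'   \item a gene-by-sample expression matrix in which expression tracks the
#'     normalized promoter loop frequency with coupling `expr_coupling`,
#'     plus planted housekeeping (uniform, >1 TPM) and single-cell-type
#'     genes;
#'   \item an exon-by-sample count matrix in which exons paired to
#'     intragenic-loop anchors track the anchor PET count with coupling
#'     `exon_coupling`, plus differential-usage (DUE) flags;
#'   \item H3K27ac enhancer peaks placed preferentially at high-degree
#'     anchors with cell-type-coupled signal;
#'   \item per-cell-type 8-category chromatin-state tilings with ENH
#'     enriched at that cell's driver anchors and TSS at promoters;
#'   \item CTCF motifs giving a controlled fraction of convergent
#'     two-motif loops, plus one planted and one null TF motif track;
#'   \item CAGE peaks, and a blacklist track.
#' }
#'
#' @param config A [synth_config()].
#' @param anchors,loops,truth,samples,counts Outputs of the upstream
#'   generator stages.
#' @return A list of annotation tibbles and ground-truth tables.
#' @export
generate_regulatory_annotations <- function(config, anchors, loops, truth,
                                            samples, counts) {
  set.seed(substream_seed(config$seed, 6L))
  genes <- sim_gene_models(config, anchors, loops, truth)
  set.seed(substream_seed(config$seed, 7L))
  expr <- sim_expression(config, genes, anchors, loops, counts, samples,
                         truth = truth)
  genes$gene_truth <- expr$gene_truth
  expr$gene_truth <- NULL
  set.seed(substream_seed(config$seed, 8L))
  exon_counts <- sim_exon_counts(config, genes, anchors, loops, counts, samples)
  set.seed(substream_seed(config$seed, 9L))
  enh <- sim_enhancers(config, anchors, loops, truth, samples)
  set.seed(substream_seed(config$seed, 10L))
  states <- sim_states(config, anchors, loops, truth, genes$genes, samples)
  set.seed(substream_seed(config$seed, 11L))
  motifs <- sim_motifs(config, anchors, loops, truth)
  set.seed(substream_seed(config$seed, 12L))
  cage <- sim_cage(config, genes)
  set.seed(substream_seed(config$seed, 13L))
  blacklist <- sim_blacklist(config)
  c(genes, expr, exon_counts, enh,
    list(states = states, cage = cage, blacklist = blacklist), motifs)
}

anchor_mid <- function(anchors) (anchors$start + anchors$end) / 2

# Gene models: intragenic genes are built around loops (promoter window at
# one anchor, a middle exon's upstream window at the other), a subset of
# variable loops is wired to a cell-type-specific gene at its far anchor,
# and the remainder are random.
sim_gene_models <- function(config, anchors, loops, truth) {
  mid_a <- (loops$start_a + loops$end_a) / 2
  mid_b <- (loops$start_b + loops$end_b) / 2
  genes <- list(); exons <- list(); gtruth <- list()
  gid <- 0
  next_id <- function() { gid <<- gid + 1; sprintf("G%04d", gid) }

  # intragenic genes around medium-span loops
  cand <- which(loops$span >= 20000 & loops$span <= 150000)
  n_intra <- min(40L, length(cand))
  intra_loops <- sort(sample(cand, n_intra))
  for (k in seq_along(intra_loops)) {
    l <- intra_loops[k]
    id <- next_id()
    strand <- if (k %% 2 == 0) "-" else "+"
    if (strand == "+") {
      tss <- round(mid_a[l]); gend <- round(mid_b[l]) + 10000
      e5p <- round(mid_b[l]) + 2000
      ex <- tibble::tibble(
        start = c(tss, round(tss + (e5p - tss) / 2), e5p, gend - 300),
        end = c(tss + 200, round(tss + (e5p - tss) / 2) + 200, e5p + 200,
                gend - 100)
      )
      gstart <- tss
    } else {
      tss <- round(mid_b[l]); gstart <- round(mid_a[l]) - 10000
      e5p <- round(mid_a[l]) - 2000
      ex <- tibble::tibble(
        start = c(gstart + 100, e5p - 200, round(e5p + (tss - e5p) / 2) - 200,
                  tss - 200),
        end = c(gstart + 300, e5p, round(e5p + (tss - e5p) / 2), tss)
      )
      gend <- tss
    }
    ex <- dplyr::arrange(ex, .data$start)
    genes[[id]] <- tibble::tibble(
      gene_id = id, chrom = loops$chrom[l], strand = strand,
      start = gstart, end = gend, tss = tss, biotype = "protein_coding"
    )
    exons[[id]] <- tibble::tibble(
      gene_id = id, exon_id = paste0(id, ":E", seq_len(nrow(ex))),
      chrom = loops$chrom[l], start = as.integer(ex$start),
      end = as.integer(ex$end), exon_rank = seq_len(nrow(ex))
    )
    coupled_rank <- if (strand == "+") 3L else 2L
    coupled_anchor <- if (strand == "+") loops$anchor_b[l] else loops$anchor_a[l]
    gtruth[[id]] <- tibble::tibble(
      gene_id = id, housekeeping = FALSE, target_cell = NA_character_,
      intragenic_loop = loops$loop_id[l],
      coupled_exon = paste0(id, ":E", coupled_rank),
      coupled_anchor = coupled_anchor
    )
  }

  # random genes; anchor-proximal genes preferentially sit at driver
  # anchors (cell-type-specific regulatory hubs are gene-rich), so the
  # promoter maps are dominated by loci where loops actually vary
  n_rand <- max(0L, config$n_genes - length(genes))
  amid <- anchor_mid(anchors)
  drivers <- attr(truth, "anchor_targets")
  driver_rows <- match(as.integer(names(drivers)), anchors$anchor_id)
  driver_rows <- driver_rows[!is.na(driver_rows)]
  for (k in seq_len(n_rand)) {
    id <- next_id()
    strand <- sample(c("+", "-"), 1)
    len <- round(stats::runif(1, 5000, 100000))
    ai <- NA_integer_
    if (stats::runif(1) < 0.5) {
      ai <- if (length(driver_rows) > 0 && stats::runif(1) < 0.6) {
        driver_rows[sample.int(length(driver_rows), 1)]
      } else {
        sample.int(nrow(anchors), 1)
      }
      chrom <- anchors$chrom[ai]
      tss <- round(amid[ai] + stats::runif(1, -400, 400))
    } else {
      chrom <- paste0("chr", sample.int(config$n_chroms, 1))
      tss <- round(stats::runif(1, 1e5, config$chrom_length - 1e5))
    }
    if (strand == "+") { gstart <- tss; gend <- tss + len }
    else { gend <- tss; gstart <- tss - len }
    genes[[id]] <- tibble::tibble(
      gene_id = id, chrom = chrom, strand = strand, start = gstart,
      end = gend, tss = tss, biotype = "protein_coding"
    )
    st <- round(seq(gstart + 50, gend - 300, length.out = 5))
    exons[[id]] <- tibble::tibble(
      gene_id = id, exon_id = paste0(id, ":E", 1:5), chrom = chrom,
      start = as.integer(st), end = as.integer(st + 200), exon_rank = 1:5
    )
    gtruth[[id]] <- tibble::tibble(
      gene_id = id, housekeeping = FALSE, target_cell = NA_character_,
      intragenic_loop = NA_integer_, coupled_exon = NA_character_,
      coupled_anchor = NA_integer_,
      driver_anchor = if (!is.na(ai) && ai %in% driver_rows)
        anchors$anchor_id[ai] else NA_integer_
    )
  }
  genes <- dplyr::bind_rows(genes)
  exons <- dplyr::bind_rows(exons)
  gtruth <- dplyr::bind_rows(gtruth)
  if (!"driver_anchor" %in% names(gtruth)) {
    gtruth$driver_anchor <- NA_integer_
  }

  # housekeeping among genes away from drivers; cell-type-specific genes
  # preferentially at driver anchors (targets assigned in sim_expression)
  free <- which(is.na(gtruth$intragenic_loop) & is.na(gtruth$driver_anchor))
  n_hk <- round(0.1 * length(free))
  hk <- sample(free, n_hk)
  gtruth$housekeeping[hk] <- TRUE
  free <- setdiff(free, hk)
  at_driver <- which(!is.na(gtruth$driver_anchor))
  n_cts <- round(0.1 * (length(free) + length(at_driver)))
  cts <- at_driver[seq_len(min(n_cts, length(at_driver)))]
  if (length(cts) < n_cts) cts <- c(cts, sample(free, n_cts - length(cts)))
  attr(gtruth, "cts_rows") <- cts
  attr(gtruth, "anchor_targets") <- drivers
  list(genes = genes, exons = exons, gene_truth = gtruth)
}

# Per-cell-type promoter loop signal, standardized across cell types.
promoter_loop_signal <- function(genes, anchors, loops, counts, samples,
                                 window = 1000) {
  promwin <- tibble::tibble(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - window),
    end = genes$tss + window
  )
  atrack <- anchors[, c("chrom", "start", "end")]
  hits <- overlap_join(promwin, atrack)
  cells <- unique(samples$cell_type)
  sig <- matrix(0, nrow = nrow(genes), ncol = length(cells),
                dimnames = list(genes$gene_id, cells))
  if (nrow(hits) > 0) {
    cell_means <- sapply(cells, function(ct) {
      cols <- samples$sample_id[samples$cell_type == ct]
      rowMeans(counts[, cols, drop = FALSE])
    })
    for (r in seq_len(nrow(hits))) {
      g <- hits$query_idx[r]
      aid <- anchors$anchor_id[hits$subject_idx[r]]
      li <- which(loops$anchor_a == aid | loops$anchor_b == aid)
      if (length(li) > 0) {
        sig[g, ] <- sig[g, ] + colSums(cell_means[li, , drop = FALSE])
      }
    }
  }
  lg <- log1p(sig)
  z <- t(apply(lg, 1, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  dimnames(z) <- dimnames(sig)
  z
}

sim_expression <- function(config, gm, anchors, loops, counts, samples,
                           truth = NULL) {
  genes <- gm$genes; gtruth <- gm$gene_truth
  cells <- unique(samples$cell_type)
  z <- promoter_loop_signal(genes, anchors, loops, counts, samples)
  n <- nrow(genes)
  base <- stats::rnorm(n, mean = 4, sd = 1.5)
  lexpr <- base + 2.5 * config$expr_coupling * z +
    matrix(stats::rnorm(n * length(cells), 0, 0.35), n)
  # genes lying inside a variable loop are co-driven by that loop's
  # driver-anchor activity, so genes sharing a loop co-express
  if (!is.null(truth) && any(truth$variable)) {
    astr <- anchor_strength(anchors, loops, counts)
    a_ct <- sapply(cells, function(ct) {
      cols <- samples$sample_id[samples$cell_type == ct]
      rowMeans(log1p(astr[, cols, drop = FALSE]))
    })
    za <- t(apply(a_ct, 1, function(x) {
      s <- stats::sd(x)
      if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }))
    rownames(za) <- rownames(astr)
    vl <- loops[truth$variable & !is.na(truth$driver_anchor), ]
    vdrv <- truth$driver_anchor[truth$variable & !is.na(truth$driver_anchor)]
    tss_pt <- tibble::tibble(chrom = genes$chrom, start = genes$tss,
                             end = genes$tss + 1L)
    inloop <- overlap_join(tss_pt, tibble::tibble(
      chrom = vl$chrom, start = vl$start_a, end = vl$end_b))
    if (nrow(inloop) > 0) {
      for (gi in unique(inloop$query_idx)) {
        drv <- unique(vdrv[inloop$subject_idx[inloop$query_idx == gi]])
        zd <- colMeans(za[as.character(drv), , drop = FALSE])
        lexpr[gi, ] <- lexpr[gi, ] + 1.5 * config$expr_coupling * zd
      }
    }
  }
  # planted housekeeping: uniform and comfortably above 1 TPM
  hk <- which(gtruth$housekeeping)
  lexpr[hk, ] <- stats::rnorm(length(hk), 5, 0.5) +
    matrix(stats::rnorm(length(hk) * length(cells), 0, 0.03), length(hk))
  # planted single-cell-type genes; genes at a driver anchor are specific
  # to that driver's cell type (when loop-expression coupling is on), so
  # specific enhancers, loops and genes co-locate as they do in tissue
  cts <- attr(gtruth, "cts_rows")
  targets <- attr(gtruth, "anchor_targets")
  if (length(cts) > 0) {
    tc <- vapply(cts, function(i) {
      da <- gtruth$driver_anchor[i]
      if (config$expr_coupling > 0 && !is.na(da) &&
            as.character(da) %in% names(targets)) {
        targets[[as.character(da)]]
      } else {
        sample(cells, 1)
      }
    }, character(1))
    gtruth$target_cell[cts] <- tc
    lexpr[cts, ] <- -4
    for (i in seq_along(cts)) lexpr[cts[i], tc[i]] <- 6
  }
  # replicate-level matrix with small replicate noise
  expr <- sapply(seq_len(nrow(samples)), function(s) {
    2^(lexpr[, samples$cell_type[s]] + stats::rnorm(n, 0, 0.1))
  })
  colnames(expr) <- samples$sample_id
  rownames(expr) <- genes$gene_id
  attr(gtruth, "cts_rows") <- NULL
  list(expression = tibble::as_tibble(cbind(
    tibble::tibble(gene_id = genes$gene_id), tibble::as_tibble(expr)
  )), gene_truth = gtruth)
}

# Anchor strength per sample: total PETs in loops touching the anchor.
anchor_strength <- function(anchors, loops, counts) {
  out <- matrix(0, nrow = nrow(anchors), ncol = ncol(counts),
                dimnames = list(anchors$anchor_id, colnames(counts)))
  ia <- match(loops$anchor_a, anchors$anchor_id)
  ib <- match(loops$anchor_b, anchors$anchor_id)
  for (s in seq_len(ncol(counts))) {
    ta <- tapply(counts[, s], ia, sum)
    tb <- tapply(counts[, s], ib, sum)
    out[as.integer(names(ta)), s] <- out[as.integer(names(ta)), s] + ta
    out[as.integer(names(tb)), s] <- out[as.integer(names(tb)), s] + tb
  }
  out
}

sim_exon_counts <- function(config, gm, anchors, loops, counts, samples) {
  exons <- gm$exons; gtruth <- gm$gene_truth
  astr <- anchor_strength(anchors, loops, counts)
  lg <- log1p(astr)
  za <- t(apply(lg, 1, function(x) {
    s <- stats::sd(x); if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  colnames(za) <- colnames(astr)
  n_s <- nrow(samples)
  base <- stats::rnorm(nrow(exons), 5, 1)
  lc <- matrix(base, nrow(exons), n_s) +
    matrix(stats::rnorm(nrow(exons) * n_s, 0, 0.5), nrow(exons))
  coupled <- gtruth[!is.na(gtruth$coupled_exon), ]
  for (r in seq_len(nrow(coupled))) {
    ei <- match(coupled$coupled_exon[r], exons$exon_id)
    ai <- match(coupled$coupled_anchor[r], anchors$anchor_id)
    lc[ei, ] <- base[ei] + 1.5 * config$exon_coupling * za[ai, ] +
      stats::rnorm(n_s, 0, 0.45)
  }
  cnt <- round(2^lc)
  colnames(cnt) <- samples$sample_id
  due <- exons$exon_id %in% coupled$coupled_exon |
    stats::runif(nrow(exons)) < 0.1
  list(exon_counts = tibble::as_tibble(cbind(
    tibble::tibble(exon_id = exons$exon_id, gene_id = exons$gene_id,
                   due_flag = due),
    tibble::as_tibble(cnt)
  )))
}

sim_enhancers <- function(config, anchors, loops, truth, samples) {
  deg <- tabulate(match(c(loops$anchor_a, loops$anchor_b), anchors$anchor_id),
                  nbins = nrow(anchors))
  p_in <- 0.1 + 0.6 * deg / max(deg, 1)
  take <- stats::runif(nrow(anchors)) < p_in
  # the anchor opposite a variable loop's driver always carries an
  # enhancer (the distal regulatory element contacting the driver locus)
  opp <- ifelse(loops$anchor_a == truth$driver_anchor,
                loops$anchor_b, loops$anchor_a)[truth$variable]
  take[match(unique(opp[!is.na(opp)]), anchors$anchor_id)] <- TRUE
  enh_anchor <- tibble::tibble(
    chrom = anchors$chrom[take], start = anchors$start[take],
    end = anchors$end[take], at_anchor = anchors$anchor_id[take]
  )
  n_bg <- 100L
  chr <- paste0("chr", sample.int(config$n_chroms, n_bg, replace = TRUE))
  st <- round(stats::runif(n_bg, 0, config$chrom_length - 2000))
  enh_bg <- tibble::tibble(chrom = chr, start = as.integer(st),
                           end = as.integer(st + 1500),
                           at_anchor = NA_integer_)
  enh <- dplyr::arrange(dplyr::bind_rows(enh_anchor, enh_bg),
                        .data$chrom, .data$start)
  enh$enh_id <- sprintf("ENH%04d", seq_len(nrow(enh)))
  base <- stats::rlnorm(nrow(enh), meanlog = 2, sdlog = 0.5)
  sig <- sapply(seq_len(nrow(samples)), function(s) {
    base * exp(stats::rnorm(nrow(enh), 0, 0.2))
  })
  colnames(sig) <- samples$sample_id
  # couple enhancer activity at the non-driver anchors of variable loops
  # to their target cell
  vl <- which(truth$variable & !is.na(truth$target_cell))
  for (l in vl) {
    a_opp <- if (!is.na(truth$driver_anchor[l]) &&
                   loops$anchor_a[l] == truth$driver_anchor[l]) {
      loops$anchor_b[l]
    } else {
      loops$anchor_a[l]
    }
    ei <- which(enh$at_anchor == a_opp)
    if (length(ei) > 0) {
      cols <- samples$sample_id[samples$cell_type == truth$target_cell[l]]
      sig[ei, cols] <- sig[ei, cols] * config$effect_size
    }
  }
  list(enhancers = enh, enhancer_signal = tibble::as_tibble(cbind(
    tibble::tibble(enh_id = enh$enh_id), tibble::as_tibble(sig)
  )))
}

# Chromatin states are per cell type, as chromatin-state maps are in
# practice: each cell type gets its own background tiling with ENH planted
# at that cell's driver anchors and TSS at promoters.
sim_states <- function(config, anchors, loops, truth, genes, samples) {
  tile <- 2000
  states8 <- c("TSS", "BIV", "TX", "REPRESS", "REPEAT", "ENH", "HET", "QUIES")
  probs <- c(0.05, 0.02, 0.15, 0.08, 0.03, 0.07, 0.10, 0.50)
  targets <- attr(truth, "anchor_targets")
  cells <- unique(samples$cell_type)
  prom <- tibble::tibble(chrom = genes$chrom,
                         start = pmax(0, genes$tss - 500),
                         end = genes$tss + 500)
  out <- lapply(cells, function(ct) {
    trk <- purrr::map_dfr(seq_len(config$n_chroms), function(ci) {
      n_t <- floor(config$chrom_length / tile)
      tibble::tibble(
        chrom = paste0("chr", ci),
        start = as.integer((seq_len(n_t) - 1) * tile),
        end = as.integer(seq_len(n_t) * tile),
        state = sample(states8, n_t, replace = TRUE, prob = probs)
      )
    })
    drv <- as.integer(names(targets)[targets == ct])
    if (length(drv) > 0) {
      va <- anchors[match(drv, anchors$anchor_id), ]
      hit <- overlap_join(trk[, c("chrom", "start", "end")],
                          va[, c("chrom", "start", "end")])
      flip <- unique(hit$query_idx)
      flip <- flip[stats::runif(length(flip)) < 0.9]
      trk$state[flip] <- "ENH"
    }
    hit <- overlap_join(trk[, c("chrom", "start", "end")], prom)
    flip <- unique(hit$query_idx)
    flip <- flip[stats::runif(length(flip)) < 0.7]
    trk$state[flip] <- "TSS"
    trk
  })
  names(out) <- cells
  out
}

# CTCF motifs: a greedy anchor-disjoint matching over candidate loops
# defines the two-motif loops; each gets an orientation (convergent with
# probability motif_convergent_frac, the rest split evenly). Unmatched
# anchors carry zero or two motifs so that only matched loops enter the
# exactly-one-motif-per-anchor denominator.
sim_motifs <- function(config, anchors, loops, truth) {
  ord <- sample.int(nrow(loops))
  used <- logical(max(anchors$anchor_id))
  matched <- integer(0)
  for (l in ord) {
    a <- loops$anchor_a[l]; b <- loops$anchor_b[l]
    if (!used[a] && !used[b]) {
      used[a] <- TRUE; used[b] <- TRUE
      matched <- c(matched, l)
    }
  }
  ori_levels <- c("convergent", "divergent", "tandem_plus", "tandem_minus")
  rest <- (1 - config$motif_convergent_frac) / 3
  ori <- sample(ori_levels, length(matched), replace = TRUE,
                prob = c(config$motif_convergent_frac, rest, rest, rest))
  strands <- list(
    convergent = c("+", "-"), divergent = c("-", "+"),
    tandem_plus = c("+", "+"), tandem_minus = c("-", "-")
  )
  place <- function(anchor_ids, strand) {
    a <- anchors[match(anchor_ids, anchors$anchor_id), ]
    pos <- round((a$start + a$end) / 2 +
                   stats::runif(nrow(a), -200, 200)) - 9
    tibble::tibble(chrom = a$chrom, start = as.integer(pos),
                   end = as.integer(pos + 19), name = "CTCF", score = 0,
                   strand = strand)
  }
  left <- place(loops$anchor_a[matched],
                purrr::map_chr(ori, ~ strands[[.x]][1]))
  right <- place(loops$anchor_b[matched],
                 purrr::map_chr(ori, ~ strands[[.x]][2]))
  un <- anchors$anchor_id[!anchors$anchor_id %in%
                            c(loops$anchor_a[matched], loops$anchor_b[matched])]
  dbl <- un[stats::runif(length(un)) < 0.4]
  two <- dplyr::bind_rows(
    place(dbl, sample(c("+", "-"), length(dbl), replace = TRUE)),
    {
      x <- place(dbl, sample(c("+", "-"), length(dbl), replace = TRUE))
      x$start <- x$start + 60L; x$end <- x$end + 60L; x
    }
  )
  ctcf <- dplyr::arrange(dplyr::bind_rows(left, right, two),
                         .data$chrom, .data$start)

  # planted TF at blood-group-specific loop anchors, plus a null TF
  blood_anchors <- unique(c(
    loops$anchor_a[!is.na(truth$group_specific) & truth$group_specific == "blood"],
    loops$anchor_b[!is.na(truth$group_specific) & truth$group_specific == "blood"]
  ))
  p_tf <- ifelse(anchors$anchor_id %in% blood_anchors, 0.6, 0.1)
  tfb_at <- anchors$anchor_id[stats::runif(nrow(anchors)) < p_tf]
  tfb <- place(tfb_at, sample(c("+", "-"), length(tfb_at), replace = TRUE))
  tfb$name <- "TF_BLOOD"
  tfn_at <- anchors$anchor_id[stats::runif(nrow(anchors)) < 0.2]
  tfn <- place(tfn_at, sample(c("+", "-"), length(tfn_at), replace = TRUE))
  tfn$name <- "TF_NULL"
  motif_truth <- tibble::tibble(loop_id = loops$loop_id[matched],
                                orientation = ori)
  list(ctcf_motifs = ctcf,
       tf_motifs = dplyr::arrange(dplyr::bind_rows(tfb, tfn),
                                  .data$chrom, .data$start),
       motif_truth = motif_truth)
}

sim_cage <- function(config, gm) {
  exons <- gm$exons
  gtruth <- gm$gene_truth
  # CAGE peaks over a few exons that are not coupled, plus random peaks
  pool <- exons[!exons$exon_id %in% gtruth$coupled_exon & exons$exon_rank > 1, ]
  take <- pool[sample.int(nrow(pool), min(10L, nrow(pool))), ]
  n_bg <- 30L
  chr <- paste0("chr", sample.int(config$n_chroms, n_bg, replace = TRUE))
  st <- round(stats::runif(n_bg, 0, config$chrom_length - 500))
  dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(chrom = take$chrom, start = take$start, end = take$end),
    tibble::tibble(chrom = chr, start = as.integer(st),
                   end = as.integer(st + 300))
  ), .data$chrom, .data$start)
}

sim_blacklist <- function(config) {
  n <- 5L
  chr <- paste0("chr", sample.int(config$n_chroms, n, replace = TRUE))
  st <- round(stats::runif(n, 0, config$chrom_length - 20000))
  dplyr::arrange(
    tibble::tibble(chrom = chr, start = as.integer(st),
                   end = as.integer(st + 10000)),
    .data$chrom, .data$start
  )
}

#' Generate the CTCF motif layer alone
#'
#' Runs the CTCF motif placement (anchor-disjoint matching, planted
#' orientation, double-motif decoys) on its own substream, without the
#' other annotation layers. Useful when only motif orientation is being
#' studied.
#'
#' @param config A [synth_config()].
#' @param anchors,loops,truth Upstream generator outputs.
#' @return List with `ctcf_motifs`, `tf_motifs` and `motif_truth`.
#' @export
generate_ctcf_motifs <- function(config, anchors, loops, truth) {
  set.seed(substream_seed(config$seed, 11L))
  sim_motifs(config, anchors, loops, truth)
}
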