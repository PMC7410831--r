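#' Run the full synthetic-study pipeline
#'
#' Executes every stage in dependency order on a simulated study:
#' simulation, pooled loop scoring and CTCF orientation, filtering and
#' normalization, precision weights and variability testing, static and
#' entropy-based sets, cell-type/group specificity, chromatin-state and
#' TF enrichments, loop-expression coupling, intragenic-loop/exon
#' coupling, and GWAS enrichment. All stage seeds derive from the config
#' seed, so two runs with one config are identical.
#'
#' @param config A [synth_config()].
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as TSV plus a summary table.
#' @param variability_method Method for [test_variability()].
#' @param stages Character vector of stages to run (dependency order is
#'   enforced; later stages require earlier ones).
#' @return A list of stage results plus a `summary` tibble of headline
#'   counts.
#' @export
run_loop_pipeline <- function(config = synth_config(), out_dir = NULL,
                              variability_method = "lm_anova",
                              stages = c("simulate", "score", "normalize",
                                         "variability", "specificity",
                                         "enrichment", "exprlink",
                                         "splicing", "gwas")) {
  state <- list(config = config)
  for (s in stages) state <- run_stage(s, state,
                                       variability_method = variability_method)
  state$summary <- pipeline_summary(state)
  if (!is.null(out_dir)) write_pipeline_outputs(state, out_dir)
  state
}

#' @rdname run_loop_pipeline
#' @param stage_name One stage name.
#' @param state Accumulated pipeline state (a list; must contain the
#'   outputs of the stage's upstream stages).
#' @param ... Stage options (currently `variability_method`).
#' @export
run_stage <- function(stage_name, state, ...) {
  opts <- list(...)
  need <- function(what) {
    if (is.null(state[[what]])) {
      stop("run_stage('", stage_name, "'): missing upstream result '", what,
           "'", call. = FALSE)
    }
  }
  cfg <- state$config
  switch(stage_name,
    simulate = {
      state$sim <- simulate_loop_study(cfg)
    },
    score = {
      need("sim")
      sim <- state$sim
      pooled <- tibble::tibble(
        anchor_a = sim$loops$anchor_a, anchor_b = sim$loops$anchor_b,
        span = sim$loops$span, count = as.integer(rowSums(sim$counts))
      )
      eff <- anchor_strength(sim$anchors, sim$loops, sim$counts)
      anchors_eff <- dplyr::mutate(sim$anchors,
                                   efficiency = rowSums(eff))
      state$loop_scores <- score_loops(pooled, anchors_eff)
      called_rows <- match(
        paste(state$loop_scores$anchor_a[state$loop_scores$called],
              state$loop_scores$anchor_b[state$loop_scores$called]),
        paste(sim$loops$anchor_a, sim$loops$anchor_b)
      )
      state$called_loops <- sim$loops[sort(called_rows), ]
      # orientation is summarised over the CTCF-anchored loop list (the
      # analogue of called loops); unlooped anchor combinations carry no
      # planted orientation
      ctcf_loops <- sim$loops[sim$loops$loop_id %in%
                                sim$motif_truth$loop_id, ]
      state$orientation <- ctcf_orientation_summary(ctcf_loops,
                                                    sim$ctcf_motifs)
    },
    normalize = {
      need("sim")
      sim <- state$sim
      m <- sim$counts
      rownames(m) <- as.character(sim$loops$loop_id)
      m <- filter_testable(m)
      m <- drop_invariant_rows(m)
      state$testable <- m
      state$normM <- normalize_matrix(m)
      state$weights <- voom_weights(m, sim$samples)
      state$pca <- pca_and_confounders(state$normM, sim$samples)
      state$similarity <- sample_similarity(m, sim$samples)
    },
    variability = {
      need("normM")
      sim <- state$sim
      method <- if (is.null(opts$variability_method)) "lm_anova"
                else opts$variability_method
      state$variability <- test_variability(state$normM, sim$samples,
                                            weights = state$weights,
                                            method = method)
      state$static_loops <- static_sets(state$testable, state$variability,
                                        mode = "score_ranked")
      ex_ct <- average_by_cell_type(state$sim$expression, sim$samples)
      state$gene_classes <- classify_genes_entropy(ex_ct)
    },
    specificity = {
      need("normM")
      sim <- state$sim
      cells <- unique(sim$samples$cell_type)
      state$celltype_loops <- lapply(stats::setNames(cells, cells),
        function(ct) celltype_specific(state$normM, sim$samples, ct))
      state$group_loops <- group_specific(state$normM, sim$samples)
    },
    enrichment = {
      need("celltype_loops")
      sim <- state$sim
      testable_ids <- rownames(state$testable)
      tloops <- sim$loops[as.character(sim$loops$loop_id) %in% testable_ids, ]
      state$state_enrichment <- state_enrichment(state$celltype_loops,
                                                 tloops, sim$states)
      blood <- state$group_loops[["blood"]]
      state$tf_enrichment <- motif_enrichment(blood, sim$tf_motifs, tloops)
      state$connectivity <- connectivity_profile(
        tloops, sim$anchors,
        list(enhancer = sim$enhancers[, c("chrom", "start", "end")])
      )
    },
    exprlink = {
      need("normM")
      sim <- state$sim
      testable_ids <- rownames(state$testable)
      tloops <- sim$loops[as.character(sim$loops$loop_id) %in% testable_ids, ]
      state$promoter_map <- map_loops_to_genes(tloops, sim$genes,
                                               scheme = "promoter")
      state$expr_correlation <- loop_expression_correlation(
        state$normM, sim$expression, state$promoter_map, sim$samples,
        seed = substream_seed(cfg$seed, 30L)
      )
    },
    splicing = {
      need("sim")
      sim <- state$sim
      state$intragenic <- find_intragenic_loops(sim$genes, sim$exons,
                                                sim$loops, sim$cage)
      ac <- anchor_strength(sim$anchors, sim$loops, sim$counts)
      state$exon_correlation <- exon_loop_correlation(
        sim$exon_counts, ac, state$intragenic, sim$loops, sim$exons,
        sim$genes, sim$samples, seed = substream_seed(cfg$seed, 31L)
      )
    },
    gwas = {
      need("sim")
      sim <- state$sim
      pruned <- prune_and_expand(sim$gwas_snps)
      blood_ids <- state$group_loops[["blood"]]$members
      gs <- sim$truth$loop_id[!is.na(sim$truth$group_specific) &
                                sim$truth$group_specific == "blood"]
      use_ids <- if (length(blood_ids) > 0) blood_ids else gs
      bl <- sim$loops[as.character(sim$loops$loop_id) %in%
                        as.character(use_ids), ]
      regions <- dplyr::bind_rows(
        tibble::tibble(chrom = bl$chrom, start = bl$start_a, end = bl$end_a),
        tibble::tibble(chrom = bl$chrom, start = bl$start_b, end = bl$end_b)
      )
      regions <- merge_intervals(regions)
      state$gwas <- lapply(split(pruned, pruned$study_id), function(st) {
        binned_rank_enrichment(st, regions,
                               seed = substream_seed(cfg$seed, 32L))
      })
      all_anchor_regions <- state$sim$anchors[, c("chrom", "start", "end")]
      state$gwas_relative <- tryCatch(
        relative_enrichment(regions, all_anchor_regions,
                            pruned[pruned$study_id == "study_planted", ]),
        error = function(e) NULL
      )
    },
    stop("run_stage: unknown stage '", stage_name, "'", call. = FALSE)
  )
  state
}

pipeline_summary <- function(state) {
  add <- function(stage, quantity, value) {
    tibble::tibble(stage = stage, quantity = quantity, value = value)
  }
  out <- list()
  if (!is.null(state$sim)) {
    out <- c(out, list(
      add("simulate", "n_anchors", nrow(state$sim$anchors)),
      add("simulate", "n_candidate_loops", nrow(state$sim$loops))
    ))
  }
  if (!is.null(state$loop_scores)) {
    out <- c(out, list(
      add("score", "n_called_loops", sum(state$loop_scores$called)),
      add("score", "pct_convergent",
          state$orientation$percent[state$orientation$orientation ==
                                      "convergent"])
    ))
  }
  if (!is.null(state$testable)) {
    out <- c(out, list(add("normalize", "n_testable", nrow(state$testable))))
  }
  if (!is.null(state$variability)) {
    out <- c(out, list(
      add("variability", "n_variable", sum(state$variability$variable)),
      add("variability", "n_static", length(state$static_loops))
    ))
  }
  if (!is.null(state$group_loops)) {
    for (g in names(state$group_loops)) {
      out <- c(out, list(add("specificity", paste0("n_", g, "_specific"),
                             length(state$group_loops[[g]]$members))))
    }
  }
  if (!is.null(state$gwas)) {
    for (s in names(state$gwas)) {
      out <- c(out, list(
        add("gwas", paste0(s, "_top_fold"), state$gwas[[s]]$top_bin_fold),
        add("gwas", paste0(s, "_empirical_p"), state$gwas[[s]]$empirical_p)
      ))
    }
  }
  dplyr::bind_rows(out)
}

write_pipeline_outputs <- function(state, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f),
                                       progress = FALSE)
  if (!is.null(state$loop_scores)) {
    w(tibble::as_tibble(unclass(state$loop_scores)), "loop_scores.tsv")
  }
  if (!is.null(state$orientation)) {
    w(tibble::as_tibble(unclass(state$orientation)), "ctcf_orientation.tsv")
  }
  if (!is.null(state$normM)) {
    w(matrix_to_tibble(state$normM), "normalized_matrix.tsv")
  }
  if (!is.null(state$variability)) {
    w(tidy(state$variability), "variability.tsv")
    w(tibble::tibble(loop_id = state$static_loops), "static_loops.tsv")
  }
  if (!is.null(state$group_loops)) {
    w(purrr::map_dfr(state$group_loops, function(s) {
      tibble::tibble(group = s$target, loop_id = s$members)
    }), "group_specific_loops.tsv")
  }
  if (!is.null(state$state_enrichment)) {
    w(state$state_enrichment$enrichment, "state_enrichment.tsv")
  }
  if (!is.null(state$tf_enrichment)) w(state$tf_enrichment,
                                       "tf_enrichment.tsv")
  if (!is.null(state$expr_correlation)) {
    w(state$expr_correlation$pairs, "loop_expression_correlation.tsv")
  }
  if (!is.null(state$gwas)) {
    w(purrr::map_dfr(names(state$gwas), function(s) {
      dplyr::mutate(state$gwas[[s]]$bins, study_id = s,
                    empirical_p = state$gwas[[s]]$empirical_p, .before = 1)
    }), "gwas_enrichment.tsv")
  }
  w(state$summary, "summary.tsv")
  invisible(out_dir)
}
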