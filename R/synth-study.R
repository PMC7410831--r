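#' Simulate a complete synthetic loop study
#'
#' Runs every generator stage under one master seed and returns all layers
#' plus the planted ground truth. With the same config (including seed) the
#' result is identical across runs.
#'
#' @param config A [synth_config()].
#' @param annotations Generate the regulatory annotation layers (gene
#'   models, expression, exon counts, enhancers, states, motifs, CAGE,
#'   blacklist)? Skipping them speeds up count-only simulations.
#' @param gwas Generate the GWAS SNP panels?
#' @return A list with components `config`, `samples`, `anchors`, `loops`,
#'   `truth`, `counts`, `mu` and, when requested, the annotation and GWAS
#'   layers.
#' @export
simulate_loop_study <- function(config = synth_config(), annotations = TRUE,
                                gwas = TRUE) {
  al <- generate_anchors_and_loops(config)
  samples <- generate_samples(config)
  truth <- generate_loop_truth(config, al$loops, samples)
  pc <- generate_pet_counts(config, al$anchors, al$loops, truth, samples)
  sim <- list(config = config, samples = samples, anchors = al$anchors,
              loops = al$loops, truth = truth, counts = pc$counts,
              mu = pc$mu)
  if (annotations) {
    ann <- generate_regulatory_annotations(config, al$anchors, al$loops,
                                           truth, samples, pc$counts)
    sim <- c(sim, ann)
  }
  if (gwas) {
    sim$gwas_snps <- generate_gwas_panel(config, al$anchors, al$loops, truth)
  }
  sim
}

#' Write a simulated study to disk in the pipeline's exchange formats
#'
#' Emits BED/BEDPE/TSV files for every simulated layer plus a key-value
#' `manifest.txt` listing each path and echoing the generator config.
#' Truth tables are written as TSV alongside.
#'
#' @param sim Output of [simulate_loop_study()].
#' @param dir Output directory (created if needed).
#' @param pets Also materialise per-sample PET BEDPE files (large).
#' @return The manifest path, invisibly.
#' @export
write_synth_dataset <- function(sim, dir, pets = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(key, file) { paths[[key]] <<- file; file.path(dir, file) }

  anchors_bed <- tibble::tibble(
    chrom = sim$anchors$chrom, start = sim$anchors$start,
    end = sim$anchors$end, name = as.character(sim$anchors$anchor_id),
    score = sim$anchors$efficiency, strand = "."
  )
  write_intervals(anchors_bed, put("anchors", "anchors.bed"), "bed6")
  loops_bedpe <- tibble::tibble(
    chrom_a = sim$loops$chrom, start_a = sim$loops$start_a,
    end_a = sim$loops$end_a, chrom_b = sim$loops$chrom,
    start_b = sim$loops$start_b, end_b = sim$loops$end_b,
    name = as.character(sim$loops$loop_id), score = 0,
    strand_a = ".", strand_b = "."
  )
  write_intervals(loops_bedpe, put("loops", "loops.bedpe"), "bedpe")
  write_matrix_tsv(
    dplyr::bind_cols(tibble::tibble(loop_id = sim$loops$loop_id),
                     tibble::as_tibble(sim$counts)),
    put("counts", "counts.tsv")
  )
  readr::write_tsv(sim$samples, put("samples", "samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth, put("truth_loops", "truth_loops.tsv"),
                   progress = FALSE)

  if (!is.null(sim$genes)) {
    readr::write_tsv(sim$genes, put("genes", "genes.tsv"), progress = FALSE)
    readr::write_tsv(sim$exons, put("exons", "exons.tsv"), progress = FALSE)
    readr::write_tsv(sim$gene_truth, put("truth_genes", "truth_genes.tsv"),
                     progress = FALSE)
    write_matrix_tsv(sim$expression, put("expression", "expression.tsv"))
    write_matrix_tsv(sim$exon_counts, put("exon_counts", "exon_counts.tsv"))
    write_intervals(sim$enhancers[, c("chrom", "start", "end")],
                    put("enhancers", "enhancers.bed"), "bed3")
    write_matrix_tsv(sim$enhancer_signal,
                     put("enhancer_signal", "enhancer_signal.tsv"))
    for (ct in names(sim$states)) {
      write_intervals(sim$states[[ct]],
                      put(paste0("states_", ct),
                          paste0("states_", ct, ".bed")), "state_bed")
    }
    write_intervals(sim$ctcf_motifs, put("ctcf_motifs", "ctcf_motifs.bed"),
                    "motif_bed")
    write_intervals(sim$tf_motifs, put("tf_motifs", "tf_motifs.bed"),
                    "motif_bed")
    write_intervals(sim$cage, put("cage", "cage.bed"), "bed3")
    write_intervals(sim$blacklist, put("blacklist", "blacklist.bed"), "bed3")
    readr::write_tsv(sim$motif_truth, put("motif_truth", "motif_truth.tsv"),
                     progress = FALSE)
  }
  if (!is.null(sim$gwas_snps)) {
    readr::write_tsv(sim$gwas_snps, put("gwas_snps", "gwas_snps.tsv"),
                     progress = FALSE)
  }
  if (pets) {
    for (s in sim$samples$sample_id) {
      rec <- sim_pet_records(sim$config, sim$anchors, sim$loops, sim$counts, s)
      write_intervals(rec, put(paste0("pets_", s),
                               paste0("pets_", s, ".bedpe")), "bedpe")
    }
  }

  cfg <- sim$config
  cfg_lines <- purrr::map_chr(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0("config.", k, "\t", if (is.null(v)) "NULL" else as.character(v))
  })
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c(paste0("file.", names(paths), "\t", unlist(paths)), cfg_lines),
             manifest)
  invisible(manifest)
}
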