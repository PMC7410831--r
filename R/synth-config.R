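#' Configuration for the synthetic loop-study generator
#'
#' Returns a validated list of generator parameters. The defaults define a
#' desk-scale study: 2 chromosomes of 20 Mb, 400 disjoint anchors
#' (~10,000 candidate loops in the 10 kb--5 Mb span window), three
#' biological groups (blood, embryonic, solid) with 2 cell types each and
#' 2 replicates per cell type, and 2,250,000 PETs per library (the deep-library downsampling cap).
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_anchors Total anchors, split evenly across chromosomes.
#' @param n_cell_types_per_group Cell types per biological group (3 groups).
#' @param n_replicates Replicates per cell type.
#' @param library_depth Expected PETs per sample landing in candidate loops.
#' @param decay_exponent Power-law exponent \eqn{\alpha} of contact decay
#'   \eqn{d^{-\alpha}} with anchor-midpoint distance \eqn{d}.
#' @param nb_dispersion Negative-binomial dispersion \eqn{\phi}
#'   (variance \eqn{\mu + \phi\mu^2}); 0 gives Poisson counts.
#' @param frac_variable Fraction of loops with a planted cell-type effect.
#' @param frac_group_specific Fraction of loops planted as specific to each
#'   group (per group, disjoint from the variable set).
#' @param effect_size Multiplicative fold applied to a planted loop's mean
#'   in its target cell type(s).
#' @param score_planted_frac,score_planted_fold Fraction of loops with a
#'   pooled (all-sample) rate excess and its fold, used to exercise loop
#'   significance scoring.
#' @param motif_convergent_frac Probability that a two-motif loop carries
#'   convergently oriented CTCF motifs.
#' @param expr_coupling Coupling \eqn{\beta \in [0,1]} between promoter
#'   loop frequency and gene expression.
#' @param exon_coupling Coupling \eqn{\gamma \in [0,1]} between anchor PET
#'   counts and exon counts for planted intragenic loops.
#' @param gwas_planted_frac Fraction of a planted study's top-50 SNPs
#'   placed inside blood-specific loop anchors.
#' @param n_genes Number of gene models.
#' @param n_loops Optionally subsample the candidate loop set to exactly
#'   this many loops (genome order preserved); `NULL` keeps all.
#' @param frac_background_pets Fraction of extra PETs emitted outside
#'   anchors when materialising BEDPE files.
#' @return A list with class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_chroms = 2L,
                         chrom_length = 2e7,
                         n_anchors = 400L,
                         n_cell_types_per_group = 2L,
                         n_replicates = 2L,
                         library_depth = 2250000,
                         decay_exponent = 1.0,
                         nb_dispersion = 0.02,
                         frac_variable = 0.10,
                         frac_group_specific = 0.02,
                         effect_size = 3,
                         score_planted_frac = 0,
                         score_planted_fold = 10,
                         motif_convergent_frac = 0.72,
                         expr_coupling = 0.8,
                         exon_coupling = 0.8,
                         gwas_planted_frac = 0.5,
                         n_genes = 300L,
                         n_loops = NULL,
                         frac_background_pets = 0.05) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = chrom_length, n_anchors = as.integer(n_anchors),
    n_cell_types_per_group = as.integer(n_cell_types_per_group),
    n_replicates = as.integer(n_replicates), library_depth = library_depth,
    decay_exponent = decay_exponent, nb_dispersion = nb_dispersion,
    frac_variable = frac_variable, frac_group_specific = frac_group_specific,
    effect_size = effect_size, score_planted_frac = score_planted_frac,
    score_planted_fold = score_planted_fold,
    motif_convergent_frac = motif_convergent_frac,
    expr_coupling = expr_coupling, exon_coupling = exon_coupling,
    gwas_planted_frac = gwas_planted_frac, n_genes = as.integer(n_genes),
    n_loops = if (is.null(n_loops)) NULL else as.integer(n_loops),
    frac_background_pets = frac_background_pets,
    min_span = 10000, max_span = 5000000
  )
  fracs <- c("frac_variable", "frac_group_specific", "motif_convergent_frac",
             "expr_coupling", "exon_coupling", "gwas_planted_frac",
             "score_planted_frac", "frac_background_pets")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("synth_config: ", f, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$library_depth <= 0) stop("synth_config: library_depth must be > 0",
                                   call. = FALSE)
  if (cfg$decay_exponent <= 0) stop("synth_config: decay_exponent must be > 0",
                                    call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("synth_config: nb_dispersion must be >= 0",
                                  call. = FALSE)
  if (cfg$effect_size <= 0) stop("synth_config: effect_size must be > 0",
                                 call. = FALSE)
  structure(cfg, class = "synth_config")
}

# Deterministic per-stage substream seed below 2^31.
substream_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 16807) %% 2147483629
}
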