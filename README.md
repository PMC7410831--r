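# loopvar

Cross-cell-type analysis of cohesin-mediated chromatin loops from
ChIA-PET data.

Cohesin (RAD21) ChIA-PET measures which pairs of genomic loci are held in
physical contact. Given per-sample PET (paired-end tag) endpoint tables
and peak calls across a panel of cell types, `loopvar` builds a unified
anchor set, tabulates the loop-by-sample interaction matrix, scores
pooled loops against a distance- and ChIP-efficiency-aware Poisson
background, and asks the downstream questions that make such a panel
interesting:

- **Which loops vary between cell types?** Normalized interaction
  frequencies (row z-score, quantile normalization, 0–1000 rescale) are
  tested per loop with a weighted random-intercept model (cell type as a
  random effect) against the intercept-only model by likelihood ratio,
  with voom-style precision weights; fixed-effect ANOVA and
  Kruskal–Wallis alternatives share the interface. BH control at FDR 10%
  defines the variable set.
- **Which loops are stable?** The static score, mean PET frequency over
  the relative entropy of the sample profile
  (RE = Σ f_j log2 f_j/q_j), ranks strong uniform loops; a matched
  sampler draws non-variable controls matching the variable set's span
  and loop-score-p strata.
- **Which loops, enhancers and genes are cell-type- or group-specific?**
  Welch-t ranking (top 10% by default) per cell type; for groups, the set
  algebra (T1 ∩ T2) − T3 over the three pairwise comparisons.
- **What do specific loops touch?** Fisher 2×2 enrichment of chromatin
  states, enhancer/promoter pair types, TF motifs at loop ends, anchor
  connectivity ("hub") profiles, and gene-list connectivity.
- **Do loops couple to expression and splicing?** Spearman correlation of
  loop frequency with expression across cell types under four loop-gene
  maps with a multiplicity-preserving shuffle null; intragenic
  promoter-to-gene-body loops and exon–anchor Pearson coupling with a
  permutation null.
- **Do GWAS hits land in specific anchors?** LD-aware pruning and proxy
  expansion, binned rank fold-change enrichment with a 200-permutation
  null, and Fisher comparisons between region sets.

A seeded synthetic-data generator (`synth_config()`,
`simulate_loop_study()`) emits every input layer with planted ground
truth — anchors, PET counts with distance decay and negative-binomial
noise, CTCF motifs with a controlled convergent fraction, per-cell-type
chromatin states, expression and exon counts with tunable coupling, and
GWAS SNP panels — so the full pipeline is testable at desk scale.

## Worked example

```r
library(loopvar)

cfg <- synth_config(seed = 5, n_loops = 8000)
st  <- run_loop_pipeline(cfg, variability_method = "lm_anova")
st$summary
#> # A tibble: 14 x 3
#>    stage       quantity                       value
#>    <chr>       <chr>                          <dbl>
#>  1 simulate    n_anchors                  400
#>  2 simulate    n_candidate_loops         8000
#>  3 score       n_called_loops            4828
#>  4 score       pct_convergent              72.6
#>  5 normalize   n_testable                8000
#>  6 variability n_variable                1264
#>  7 variability n_static                  1264
#>  8 specificity n_blood_specific           355
#>  9 specificity n_embryonic_specific       339
#> 10 specificity n_solid_specific           387
#> 11 gwas        study_null_top_fold          0.8
#> 12 gwas        study_null_empirical_p       0.692
#> 13 gwas        study_planted_top_fold      11.6
#> 14 gwas        study_planted_empirical_p    0.00498
```

Reading the numbers: of 8,000 candidate anchor pairs, 4,828 pass the
pooled significance call; all 8,000 clear the ≥4-PET testable filter at
this depth; 1,264 loops vary across the six cell types at FDR 10% (the
generator planted 10% variable plus 2% group-specific per group), matched
by 1,264 static controls. Among two-motif loops, 72.6% carry convergent
CTCF motifs (72% planted). The planted GWAS study is ~10-fold enriched in
blood-specific loop anchors (permutation p ≈ 0.005); the null study is
not (fold 0.8, p ≈ 0.69).

Per-stage functions (`build_anchor_set()`, `tabulate_pets()`,
`score_loops()`, `normalize_matrix()`, `test_variability()`,
`group_specific()`, `state_enrichment()`, `map_loops_to_genes()`,
`binned_rank_enrichment()`, ...) take tibbles and return tibbles, so the
pipeline composes with dplyr; fitted results carry `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` helpers.

See `vignettes/loopvar-methods.Rmd` for the models, parameter defaults
and the design of the synthetic generator.

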