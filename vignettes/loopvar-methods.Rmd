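---
title: "Methods: cross-cell-type chromatin-loop variability and its regulatory couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cell-type chromatin-loop variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`loopvar` analyses cohesin-mediated chromatin loops measured by ChIA-PET
across a panel of cell types: which loops exist, which vary between cell
types, which are specific to a cell type or biological group, and how loop
activity couples to chromatin state, transcription-factor occupancy, gene
expression, splicing and GWAS signal. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic data
generator does and does not emulate.

## The data model

A *PET* (paired-end tag) is one sequenced ligation product whose two ends
mark genomic loci in physical contact. Pooled peak calls, extended by
500 bp and merged, define disjoint *anchors*; a candidate *loop* is an
intra-chromosomal anchor pair whose midpoint distance lies strictly
between 10 kb and 5 Mb. Tabulating PETs whose endpoint midpoints land in
two distinct anchors yields the loop-by-sample count matrix `M[l, s]`.
Libraries above 2,250,000 unique PETs are down-sampled to that cap before
tabulation.

## Loop significance scoring

Candidate pairs are assigned to equal-occupancy span bins (at least 20
pairs per bin; by default as many bins as that floor allows). Within a
bin with total PET count $T_b$, the expected count of pair $(i, j)$ is

$$\lambda_{ij} = T_b \, \frac{e_i e_j}{\sum_{(a,b) \in b} e_a e_b},$$

where $e_i$ is anchor $i$'s ChIP efficiency; the p-value is the exact
upper Poisson tail $P(X \ge k_{ij};\, \lambda_{ij})$, with
Benjamini-Hochberg and Bonferroni control reported. This follows the
published description of distance- and efficiency-aware scoring; the
binned Poisson background is this package's concrete likelihood choice,
since only the model's inputs (distance, local ChIP efficiency) are fixed
by that description. The full-scale study threshold ($p < 2.3 \times
10^{-9}$) is appropriate at billions of reads; at desk scale the default
call is BH $q < 0.01$.

Two numerical notes. First, exact tail p-values of counts are discrete:
a Kolmogorov-Smirnov check against the continuous uniform is only
meaningful when $1/\sqrt{2\pi\lambda}$ is small relative to the KS
resolution, so calibration checks run at pooled depths giving
$\lambda \sim$ hundreds and evaluate a 3,000-p subsample. Second, the
within-bin efficiency-share model absorbs distance decay only between
bins; the finest binning compatible with the 20-pair floor is therefore
the default.

## Normalization, weights and variability

Rows of the testable matrix (loops with at least 4 PETs in some sample)
are z-scored, columns are quantile-normalized (ties receive the mean of
the reference values at their tied ranks), and each column is affinely
rescaled to [0, 1000]. Zero-variance rows cannot be z-scored; they are
removed explicitly (`drop_invariant_rows()`), never silently.

Mean-variance precision weights come from the voom method (log-counts,
lowess trend of $\sqrt{\mathrm{sd}}$ versus mean, weights
$1/\mathrm{sd}^4$); with fewer than 50 rows the trend is not estimable
and unit weights are substituted with a warning.

Variability across cell types is tested per loop on
$\log(\text{normalized frequency} + 1)$ — the offset is needed because
the normalized range includes 0. The flagship test is the weighted
random-intercept model (cell type as a random effect) against the
intercept-only model by likelihood ratio; the reference distribution is
$\chi^2_1$, conservative for a variance component on the boundary (the
50:50 $\chi^2_0/\chi^2_1$ mixture is available via
`boundary_mixture = TRUE`). Fixed-effect ANOVA and Kruskal-Wallis
alternatives use the same interface. BH control at FDR 10% defines the
variable set.

## Static loops, entropy scores and gene classes

The *relative entropy* of a loop's fractional PET profile over samples,
$\sum_j f_j \log_2 (f_j / q_j)$ against the uniform null, is 0 for a flat
profile and $\log_2 J$ for a one-hot profile. The *static score* is mean
PET frequency divided by relative entropy: strong, uniform loops rank
highest. Loops with zero entropy would divide by zero; they rank above
all others, ordered by mean frequency, which honours the score's intent.
The matched alternative samples non-variable candidates (variability
q > 0.5) matching the variable set's joint span-decile and
loop-score-p-decile distribution, deterministically under a seed; an
under-populated stratum is an error naming the deficient cells.

Gene expression profiles are classified with the same entropy: the top
decile of the entropy ranking is cell-type-specific, the bottom decile —
restricted to genes above 1 TPM in every cell type — is housekeeping.

## Specificity by t-statistic ranking

Cell-type-specific loops (and, identically, enhancers and genes) are the
top `floor(top_frac * N)` entities by a Welch t-statistic of the query
cell's samples against all others; Welch is the default because nothing
justifies pooling variances at two replicates per condition (a pooled
option exists). Ties break by entity id so results are deterministic.
Group-specific loops use three pairwise statistics — query versus each
other group ($t_1$, $t_2$) and the two other groups against each other
($t_3$) — and return $(T_1 \cap T_2) \setminus T_3$.

## Enrichment machinery

Every enrichment is a two-by-two Fisher exact test (two-sided, exact
hypergeometric tail). "Loop end" means the anchor interval itself and
overlap means at least one shared base. Families for BH correction follow
the analysis: cell types x states for chromatin states, TFs within a
group for motif enrichment, thresholds X for gene connectivity. TF tables
with any cell below 5 are excluded. The promoter is the 500-bp window
immediately upstream of the gene start (strand-aware) for end labelling;
the gene-to-loop maps use their own 1-kb rules. Degenerate tables (an
empty degree bin, a bin holding every anchor, a gene list covering the
whole universe) are skipped or reported with odds ratio 1 rather than
crashing a batch run.

## Gene maps, expression coupling and splicing

Four loop-to-gene maps are supported: *all* (loop within 1 kb of the gene
start or end, or gene body overlapping the loop), *promoter* (TSS within
1 kb of either anchor), *contained* (gene inside the loop interval with
its TSS more than 1 kb from both anchors) and *promoter-enhancer*
(promoter rule at one anchor, H3K27ac overlap at the other). Replicates
are averaged per cell type before cross-cell-type correlations
(configurable). The mapping-shuffle null permutes the gene side of the
map, which preserves each loop's gene multiplicity exactly.

Intragenic promoter-to-gene-body loops require protein-coding genes with
a middle exon; exons overlapping CAGE peaks are removed from the
middle-exon pool; the promoter window is TSS +/- 1 kb and the upstream
window extends 5 kb from the exon's 5' boundary toward the promoter
(strand-aware, with a flag to disable). Exon-anchor pairs match 5'
boundaries within 5 kb; same-gene control exons must lie more than 20 kb
from the anchor centre; the permutation null redraws exons 100 times.

## GWAS enrichment

Pruning keeps each LD cluster's minimum-p SNP (ties by id); studies with
fewer than 1,000 pruned SNPs are dropped; proxies with $r^2 \ge 0.8$
travel with their lead. Rank bins are cumulative at pruned ranks 50, 150,
350 and 750, then the four quartiles of the remaining p distribution; a
bin's fold change is its overlap fraction (a SNP overlaps if it or any
proxy does) divided by the study-wide fraction. The permutation null
shuffles p-values among pruned SNPs with positions fixed, 200 times, with
add-one smoothing. The genome-wide threshold for between-set comparisons
defaults to the literal $10^{-7}$, with $5 \times 10^{-8}$ selectable.

## The synthetic generator

The generator emulates the study's structure at desk scale: by default 2
chromosomes of 20 Mb, 400 anchors placed uniformly at random with a 3-kb
minimum gap (a continuous span distribution, matching the smooth
power-law decay $d^{-\alpha}$, $\alpha = 1$), three groups (blood,
embryonic, solid) of 2 cell types with 2 replicates each, and 2,250,000
PETs per library — the study's own down-sampling cap. Counts are negative
binomial around $\mu_{ls} = D\,p_l\,s_{l,c(s)}$ with dispersion
$\phi = 0.02$, chosen to reproduce the replicate concordance regime of
deep, down-sampled libraries (raw-count replicate Spearman ~0.95); at
$\phi$ several-fold larger, replicate scatter would exceed anything the
assay shows and a 3-fold effect would be undetectable at 2 replicates
regardless of depth.

Planted truth is organised around ~20 *driver anchors*, each tied to one
target cell type: all loops incident to a driver are "variable" with an
`effect_size`-fold mean in the target cell, plus a graded activity
profile over all cell types shared within the driver
($\mathrm{effect}^{U(-0.5, 0.5)}$ per cell). The graded component
matters: with a purely one-hot profile the expected Spearman correlation
between two coupled 6-cell profiles is bounded near 0.43, so no generator
without multi-cell covariation can exhibit a strong loop-expression
correlation signal. Group-specific loops (disjoint from the variable set)
are elevated in every cell type of one group. Anchor-proximal genes sit
preferentially at driver anchors; gene expression couples to the
standardized promoter contact profile with coefficient `expr_coupling`
and, for genes inside a variable loop, to the driver's activity profile —
so genes sharing a loop co-express. Planted cell-type-specific genes take
their driver's target cell (only while `expr_coupling > 0`, so the zero
coupling setting is a true null); enhancers sit at the anchor opposite
each driver with activity elevated in the target cell; per-cell-type
chromatin-state tracks plant ENH at that cell's drivers. Intragenic genes
are constructed around medium-span loops so that the planted loop
satisfies the promoter/upstream windows by construction, and the paired
exon's counts track the anchor with coefficient `exon_coupling`. GWAS
panels comprise a null study (uniform placement, cluster-lead p drawn
independently of cluster size — otherwise larger clusters would pair
smaller minimum p with more proxies and bias the null fold upward) and a
planted study whose top-50 pruned SNPs fall inside blood-specific anchors
with probability `gwas_planted_frac`.

CTCF motifs deserve a note. A greedy anchor-disjoint matching over
candidate pairs defines the *CTCF-anchored loop list*; each matched loop
draws an orientation (convergent with probability
`motif_convergent_frac` = 0.72, the remainder split evenly) and places
one motif per anchor accordingly, while unmatched anchors carry zero or
two motifs. Orientation summaries are evaluated on that loop list — the
synthetic analogue of a called loop set. Evaluating on *all* candidate
pairs would mix anchors matched in different loops (pairs that are not
loops) and dilute any planted convergence toward 25%; this is a property
of dense candidate enumeration, not of the estimator.

## What passing tests do and do not show

The generator produces smooth power-law decay, independent
negative-binomial noise, and clean planted effects. Real ChIA-PET adds
self-ligation artefacts, mappability and GC structure, anchor-width
variation correlated with occupancy, and efficiency estimates
contaminated by short-range reads — none of which are modelled. In
particular, per-anchor endpoint counts estimated from the synthetic
long-range PETs alone absorb each anchor's neighbourhood decay sum and
are a poor stand-in for ChIP efficiency, so synthetic scoring runs use
the generator's true efficiency factors; with real libraries, endpoint
counts are dominated by short-range reads and are the standard proxy.
Passing the suite therefore demonstrates correctness of the machinery
and calibration under the stated model, not robustness to every
real-data artefact.

## Problem sizes

Default analyses run at 5,000-8,000 candidate loops, 12 samples, 300
genes, ~1,400 exons, two GWAS studies of ~1,200 pruned SNPs with 200
permutations, and a 60,000-pair study for motif orientation; the full
pipeline completes in about a minute and the statistical checks in a few
minutes on one CPU.
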