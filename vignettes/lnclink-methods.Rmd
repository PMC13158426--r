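---
title: "Methods: multi-tissue lncRNA training-response analysis with chromatin integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue lncRNA training-response analysis with chromatin integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnclink)
```

## The analysis in one paragraph

`lnclink` analyzes how long non-coding RNAs (lncRNAs) respond to endurance
exercise training in a multi-tissue, two-sex design with a sedentary
control (week 0) and training timepoints at 1, 2, 4 and 8 weeks. It filters
RNA-seq counts to reliably expressed genes, calls timewise sex-stratified
differential lncRNAs (DELncs), summarizes their trajectories and sex
specificity, clusters temporal profiles, characterizes the sequences of
differential transcripts, and — the core integrative step — links each
DELnc to nearby training-responsive ATAC-seq peaks and ranks
lncRNA–peak–gene triads by an activity score that combines trajectory
correlation with promoter proximity. A synthetic-data generator reproduces
the entire study design at desk scale so that every stage can be validated
against planted ground truth.

## Expression filtering and differential calling

Counts are analyzed per tissue. Detection requires CPM strictly above 0.5
in at least two samples of the tissue; lncRNAs additionally require a mean
FPKM of at least 1 ("adequately expressed"). The differential engine
normalizes by median-of-ratios size factors (the median, over genes with
nonzero counts in every sample, of the ratio of a sample's count to the
gene's geometric mean), transforms to `log2(normalized + 1)`, and
contrasts each training timepoint against the sex-matched sedentary
controls with a two-sided Welch test; the effect size is the difference of
group means on the log2 scale. DELncs are called at `p <= 0.01` and
`|log2FC| >= 1` (both inclusive), a deliberately sensitive rule for
low-abundance, variable lncRNAs; a stringent alternative (within-tissue BH
at 10% FDR with `|log2FC| >= 0.5`) is provided. TMM factors (trim 30% of
M-values and 5% of A-values per side, precision-weighted) are available
for exploratory log-CPM work.

The Welch engine is a transparent stand-in for a negative-binomial GLM
with study covariates (RNA integrity, mapping bias, and similar), which
the synthetic data does not model; externally computed tables can be
injected through `import_de_table()`, and every downstream stage consumes
only (`log2fc`, `p`). The pseudocount (default 1) and all thresholds are
configurable.

## Peak processing and the sex meta-analysis

ATAC peaks are trimmed to 200 bp around their summit (so the trimmed
midpoint *is* the summit), and kept when they show at least 10 reads in at
least 4 samples on an allowed chromosome. Within each tissue and sex, a
one-way F-test across the five timepoint groups screens for any training
response; the male and female p-values are combined with Fisher's
sum-of-logs (`-2 * sum(log p)` against a chi-squared with 2k df, p-floor
1e-300 to avoid `log(0)`). Adjustment uses weighted BH with tissue as the
covariate: per-tissue signal fractions `1 - pi0` are estimated by Storey's
method at `lambda = 0.5`, normalized to mean weight 1, floored at 0.05,
with groups under 20 hypotheses forced to weight 1. This is a
deterministic approximation of covariate-weighted FDR procedures whose
cross-validated binning is out of scope; with a single group it reduces
exactly to BH. Peaks at adjusted `p <= 0.05` are training-differential.

## lncRNA–peak pairing, correlation and triads

Each DELnc is paired with every training-differential peak on the same
chromosome whose summit lies within 500 kb (inclusive) of the midpoint of
the lncRNA gene span. The span midpoint (not the spliced transcript) is
used because the pairing is about the genomic locus. For each pair, the
Pearson correlation `r` is computed over the timewise log2FC values; the
default stacks both sexes (up to 8 points: 2 sexes x 4 weeks), since the
effects are estimated per sex but the association of interest is the
overall training response; a per-sex mode is provided. Pairs with fewer
than 3 finite shared points, or zero variance on either side, are dropped
with a logged count. The pair landscape is summarized as a Gaussian-kernel
density over (signed TSS distance, r) with Scott's-rule bandwidths on a
fixed grid renormalized to integrate to 1.

Triads attach each peak's nearest protein-coding TSS (strand-aware TSS
position, unstranded distance, ties to the lexicographically smaller gene
id) and keep pairs with `r >= 0.5`, scored as

```
activity_score = r / (distance_to_TSS + 1)
```

When several triads map to one gene, only the maximum-score triad
survives (ties: smaller distance, then smaller lncRNA id). No distance
cap is applied to the TSS search: the score's built-in `1/(d+1)` penalty
already demotes remote genes. The gene's direction (`up`/`down`/`ns`) is
the sign of its log2FC at its most significant differential timepoint.
Negative-`r` pairs are retained in the pair table (they are informative
for the density summary) but never become triads.

## Trajectories, sex specificity, clustering

Z-score trajectories standardize each gene's timewise log2FC within
tissue x sex (flat trajectories map to all-zero profiles); tissue-level
summaries report the mean Z over the DELnc set per timepoint plus the
week-8 minus week-1 change. The Z-score basis is a documented
interpretation: the upstream study does not pin down whether such
summaries are computed on expression or effect sizes, and per-sex
log2FC profiles are the choice here.

Sex specificity partitions DELncs into `male_only`, `female_only`,
`shared_concordant`, `shared_opposing` (some common differential timepoint
with opposite signs), and `shared_disjoint_timepoints` — mutually
exclusive and exhaustive, and symmetric under swapping the sex labels.

Temporal clustering uses fuzzy c-means on standardized 4-point profiles.
Genes observed at fewer than 3 of the 4 training timepoints are excluded;
single missing values are filled by linear interpolation *on the week
axis* (1, 2, 4, 8 — not equally spaced ranks), with flat extrapolation at
the boundaries. Defaults are 6 clusters and fuzzifier `m = 1.25`
(configurable); the data-driven fuzzifier estimate used by Mfuzz is
deliberately not reproduced, as cluster-number and fuzzifier selection are
out of scope. Memberships are normalized per gene (a profile coinciding
with a center receives membership 1 there), the objective
`sum(u^m d^2)` is non-increasing by construction, and core members require
membership >= 0.5.

## Sequence features

Transcript features are computed on the spliced (exon-concatenated)
sequence: length, GC content (`N` excluded from the denominator), ORFs,
and a folding score. The ORF scanner reports, per frame and strand, the
outermost ATG-to-stop span of each stop-bounded segment, with a 30-nt
minimum; ORFs that reach the sequence end without a stop carry an
`open_ended` flag (included by default, configurable) since reference
ORF finders leave this unspecified. The folding score is a Nussinov-style
dynamic program maximizing nested Watson–Crick + GU pairs (minimum loop
3), either unweighted or with toy stacking weights GC = 3 / AU = 2 /
GU = 1; it is explicitly a base-pairing proxy, not a thermodynamic
nearest-neighbor minimum free energy, and is used only for group-level
distribution comparisons (Mann–Whitney or Kolmogorov–Smirnov, two-sided).
In the pipeline, folding uses a fixed-length 5' window (default 300 nt),
which keeps the O(n^3) DP fast and removes the length confound from the
folding comparison.

## The synthetic experiment

The generator emulates the study design: negative-binomial counts
(variance `mu + alpha mu^2`, global `alpha = 0.1` by default) for each
tissue x sex x timepoint cell with 5 replicates, four chromosomes of
25 Mb holding 1000 genes (~10 genes/Mb, matching mammalian gene density),
base means log-uniform over 2^6..2^12 — the "adequately expressed" regime
that survives the detection filters — with lncRNAs shifted −2 log2 and
GC-poorer (44% vs 50%). Planted differential genes get a ±2 log2FC mean
shift in their flagged cells. Planted triads share a latent 8-point
timewise signal between the lncRNA and a peak placed within 5 kb of a
coding TSS (and within 500 kb of the lncRNA midpoint); the peak trajectory
is `r * z + sqrt(1 - r^2) * noise`, scaled to a 2-log2FC amplitude, which
realizes the target correlation up to 8-point sampling noise. Decoy peaks
are placed uniformly; 80% respond to training with their own independent
trajectories (so pairing alone cannot separate them) and 20% are flat.
Distinct animals are profiled at each timepoint in the emulated design, so
timepoints are drawn independently — no within-gene autocorrelation is
simulated. Batch covariates, fragment-level effects and read-level
simulation are out of scope.

All randomness flows from one root seed through named substreams (one per
artifact), so adding an artifact never perturbs the others and the same
seed reproduces every output bit-identically.

What passing the planted-recovery tests shows — and what it does not: the
pipeline recovers strong, clean signals injected under its own noise
model. Real data add dispersion heterogeneity, covariate structure,
spatially clustered peaks and correlated genes, none of which the
generator emulates; recovery rates here are upper bounds, not estimates of
field performance.

## Numerical choices and edge cases

* Coordinates are 0-based half-open everywhere internally (BED-native);
  GTF converts at the boundary. The TSS of a minus-strand gene is its last
  base (`end - 1`).
* Inclusive comparisons exactly as stated: `p <= 0.01`, `|log2FC| >= 1`,
  `mean FPKM >= 1`, `>= 10 reads in >= 4` samples, `r >= 0.5`, 500,000 bp
  pairs, 500,001 does not.
* Degenerate guards: equal-mean zero-variance contrasts report `p = 1`;
  zero-variance trajectories give zero z-profiles and are excluded from
  correlations; p-values are floored at 1e-300; a profile exactly on a
  cluster center takes membership 1.
* Validation problem sizes (chosen to exercise every code path while the
  whole suite stays desk-scale): 2000 genes x 100 samples for recovery and
  calibration, 20 planted triads against ~650 decoys, 200 short sequences
  for the folding oracle, two-tissue default runs for end-to-end
  determinism.

## Known limitations

The Welch stand-in does not shrink dispersions and will be conservative at
very low counts; the weighted-FDR approximation ignores covariate binning
uncertainty; the folding proxy has no thermodynamic meaning beyond
ordering; the ceRNA stage consumes externally predicted interaction
tables and performs no seed matching of its own; and none of the planted
recovery rates should be read as field performance on real tissue panels.
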