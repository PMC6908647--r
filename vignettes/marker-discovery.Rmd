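---
title: "Methods: cancer-specific methylation marker discovery with methpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cancer-specific methylation marker discovery with methpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpanel)
```

`methpanel` implements an integrative methylation + expression workflow
whose end product is a small CpG panel with a fitted logistic classifier
that separates tumors of one target cancer from normal tissue while
staying unmethylated in other cancers. This vignette documents the
statistical model behind each stage, the tunable parameters and their
defaults, the design choices that were genuinely open, and what the
synthetic cohort does and does not demonstrate.

## Data model

A cohort consists of four tables: a beta matrix (CpG probes × samples,
β ∈ [0, 1], missing cells allowed), a manifest-style probe annotation
(per probe: chromosome, 1-based position, semicolon-joined gene links with
a region class from TSS1500/TSS200/5UTR/1stExon/Body/3UTR, a CGI relation
from Island/N_Shore/S_Shore/N_Shelf/S_Shelf/OpenSea, and a SNP flag), a
raw count matrix (genes × samples, non-negative integers) and a sample
sheet (condition tumor/normal, cancer type, optional clinical columns).
"Promoter" throughout means a gene link with region class TSS1500 or
TSS200; the `promoter_regions` argument of the mapping functions accepts
a wider class set (e.g. adding 5UTR/1stExon) where a broader definition
is preferred.

## Quality control and imputation

Probes are dropped if SNP-flagged, on chromosome X, or more than 10 %
missing (`max_missing = 0.10`, strict inequality, so exactly 10 % is
kept). Each removed probe is accounted to the *first* matching reason in
the order SNP → chrX → missingness, making the QC report a partition of
the input. Remaining gaps are filled with per-probe means computed within
condition when every condition has at least three samples, else globally.
Methylation arrays are not ordered series, so no interpolation-style
method applies; within-condition means were chosen because they preserve
the tumor–normal group difference that every downstream stage consumes.
A probe with no observed value at all is an error (impossible after the
filter at the default threshold).

## Differential methylation

Each probe is tested with a two-sided Wilcoxon rank-sum test. When both
groups have ≤ 8 samples the p-value is exact: all C(N, n₁) assignments of
the observed (midrank-tied) ranks are enumerated and the two-sided mass
is the fraction of assignments whose rank sum deviates from the
exchangeable-null expectation at least as much as the observed one. This
definition handles ties exactly, at the price of enumeration — hence the
switch to a tie-corrected normal approximation (no continuity correction)
above 8 per group, where enumeration is both infeasible and unnecessary.
P-values get Benjamini–Hochberg adjustment over all tested probes, and a
DMC requires |Δβ̄| > 0.2 *and* FDR < 0.05 (both strict). The FDR is
computed before either filter is applied; applying the effect-size filter
first would change the multiplicity universe and is not done.
Both directions are reported (hyper: Δ > 0; hypo: Δ < 0); a gene is a
differentially methylated gene (DMG) of a direction if at least one of
its promoter probes is a DMC of that direction, so a gene can be both
hyper- and hypomethylated via different probes.

## Differential expression

Counts are normalized with trimmed-mean-of-M-values (TMM) factors
(`trim_m = 0.30` on log-ratios, `trim_a = 0.05` on abundances) and fitted
with a negative-binomial log-linear model — offset log(library size ×
factor), a single dispersion common to all genes, and a likelihood-ratio
χ² test (1 df) of the group coefficient. Both steps are delegated to
edgeR, the standard implementation of exactly this estimator; the package
keeps its own module surface (`tmm_factors()`, `nb_test()`) and verifies
the factors in its tests against an independent re-implementation of the
doubly trimmed, precision-weighted mean. Common dispersion (rather than
tagwise or trended) is the smallest model consistent with "NB log-linear
with one dispersion" and keeps the type-I-error and fold-change-recovery
simulations interpretable; the threshold semantics are |log₂FC| > 1.5
with FDR < 0.05, reading the fold-change cutoff on the log₂ scale.
All-zero genes never enter the fit and are reported with log₂FC 0,
p = 1 and a flag.

## CIMP consensus clustering

The most variable probes are CpG-island promoter probes with tumor SD
strictly above 0.2 and normal mean strictly below 0.05. Clustering runs
`n_reps = 1000` subsampled repetitions (80 % of samples drawn without
replacement); each repetition runs K-means with Euclidean distance,
k-means++ seeding and 10 restarts, with its own seed derived from the
master seed. The consensus entry for a sample pair is the co-clustering
count divided by the co-sampling count; final labels cut an
average-linkage dendrogram of 1 − consensus at k. k = 3 is the default
(CIMP-high / intermediate / low); the repetition count and subsample
fraction follow common consensus-clustering practice since only the
algorithm and distance were fixed a priori. A pair never co-sampled is an
error advising more repetitions. Cluster–clinical association uses
Fisher's exact test — exact for tables within 2 × 3 margins or total
≤ 30, Monte-Carlo with 100 000 tables (fixed seed, standard error
reported) beyond that, because exact r × c enumeration grows
exponentially. Methylation differences between clusters use classical
one-way ANOVA; a perfect fit (zero within-cluster variance) is reported
as F = ∞, p = 0 rather than a numerically meaningless finite value.

## Integration

DMGs (promoter-defined) are intersected with DEG directions into four
quadrants; hyper–down genes — promoter-hypermethylated and
downregulated, the tumor-suppressor-silencing pattern — feed the marker
funnel. Correlation analyses use Pearson r between promoter β and
log₂(CPM + 1) on TMM-effective library sizes ("normalized expression"
is not otherwise pinned down; the transform is a config point).
Significance needs |r| > 0.3 and BH-FDR < 0.05, with BH applied within
each call's pair universe — local (CpG × own gene) and distant
(CpG × other DEGs) runs are never pooled, since they ask different
questions over different universes. Distant analysis excludes self-pairs
by definition of "distant". A gene whose significant local pairs mix
signs is classed "both". Pairs with fewer than 3 shared samples or a
constant vector are skipped and reported, not silently dropped. The
hypergeometric gene-set enrichment (`geneset_enrichment()`) is a
deliberately generic over-representation test over GMT collections — a
self-contained stand-in for web-service annotation tools, not a
re-implementation of any of them.

## Marker discovery

Candidates are hyper DMCs lying in promoter links of hyper–down genes.
The specificity screen removes any candidate whose probe is a DMC — in
either direction, under the same thresholds — in at least one other
cancer's tumor-vs-normal comparison; the screen is monotone (more
reference cancers can only shrink the set). Survivors are ranked by
information gain in bits, IG = H(X) − H(X|Y), after discretizing β into
10 equal-width bins on [0, 1]; CpGs with IG > 0.3 (strict) continue.
Equal-width binning on the natural [0, 1] support is the least arbitrary
discretization for beta values, and the bin count is a parameter. The
gain is mutual information, so it is non-negative and bounded by
min(H(X), H(Y)) — a formulation sometimes mistyped with a plus sign,
which would make the quantity negative and the cutoff meaningless.

SBFS then starts from the full filtered set and repeatedly removes the
single CpG whose removal maximizes the stratified 5-fold CV accuracy of
a ridge-logistic classifier. Ties are resolved by removing the CpG with
the lowest information gain, then lexicographically by probe id; the
procedure records every visited subset and returns the subset with the
*global* accuracy maximum (ties: smallest subset, then lexicographic) —
it does not stop at the first accuracy drop, because the target is the
best-scoring subset, not a local stopping point. Fold assignment is
derived once from the seed and reused for every subset, so subsets are
compared on identical resampling and the whole trajectory is
deterministic.

## Classifier and evaluation

The logistic classifier is fit by Newton–Raphson with step halving on
the penalized log-likelihood, ridge penalty `l2 = 1e-4` on the slopes
(intercept unpenalized), convergence when the largest coefficient update
drops below 1e-8, at most 100 iterations, error on non-convergence. The
small ridge term exists because perfect markers make the training data
separable, where the unpenalized MLE diverges; 1e-4 is small enough to
leave non-separable fits essentially unchanged. Confusion counts use
probability cutoff 0.5; AUC is the rank-based (Mann–Whitney) form with
ties counted ½, so it is invariant under monotone score transforms and
needs no cutoff. Cross-validation is stratified (10 folds by default,
reduced with a warning when the rarer class is smaller); held-out scores
are pooled before computing the confusion table and AUC. Reports carry
per-class rows (tumor TP rate = sensitivity, normal TP rate =
specificity) plus a class-size-weighted average row. External evaluation
applies the frozen coefficients unchanged.

## The synthetic cohort

`generate_cohort()` draws each β from Beta(μκ, (1 − μ)κ) with
κ = `beta_precision` (default 50), giving the bounded, heteroskedastic
noise of array betas; background probes are bimodal (half low ~0.03–0.15,
half high ~0.70–0.92). The default cohort has three cancer types — the
target with 100 tumors / 100 normals, two others with 50/50 — 2000
probes and 500 genes: large enough for every stage to behave
asymptotically, small enough that the whole pipeline runs in seconds.
Planted structure, all recorded as ground truth:

* 4 target-specific markers (island/TSS200, normal μ 0.08, shifted by
  `hyper_delta = 0.4` in target tumors only);
* 6 shared markers shifted in tumors of *all* types;
* 8 hypomethylated gene-body probes (μ 0.75 → 0.35 in target tumors), so
  DMC calls exercise both directions;
* a 60-probe CIMP block (island promoter, normal μ 0.03) whose target
  tumors split into 3 clusters with means 0.15/0.45/0.75 — offsets several
  times the Beta noise SD, so the planted partition is recoverable;
* expression: NB counts (dispersion 0.1) with log-mean coupled to the
  realized marker β via `coupling_strength = -5` per unit β (marker genes
  thus become hyper–down DEGs with log₂FC well past the 1.5 cutoff), plus
  30 methylation-independent DE genes per direction at |log₂FC| = 3;
* 5 % missing cells completely at random; ~3 % of background probes
  SNP-flagged and ~3 % on chrX so the QC filter has work to do.

`hyper_delta = 0.4` places the planted effect comfortably past the 0.2
calling threshold — the regime the pipeline is designed for — and the
default coupling makes methylation–expression correlations clearly
negative. A run with `hyper_delta` near 0.2 or weaker coupling would
probe the threshold boundary instead; that behaviour is exercised by the
strict-inequality unit tests, not by the reference simulation.

What the generator does **not** emulate: realistic genomic coordinates or
probe spacing, cross-reactive probes, batch and cell-composition effects,
copy-number interference with β, correlated probe blocks beyond the CIMP
block, or any virus-integration biology. Passing the recovery tests
therefore shows the algorithms are correct under their stated model, not
that the thresholds are optimal for any particular real cohort.

## Determinism and numerical conventions

Every stochastic stage takes a seed and derives child seeds
deterministically (consensus repetition i uses a child of the master
seed; the pipeline derives its CV seed from the run seed), so identical
configuration + seed gives bit-identical outputs, including the written
summary JSON. All threshold comparisons at stage boundaries are strict
inequalities. Degenerate inputs have defined behaviour rather than NaNs:
all-tied Wilcoxon gives p = 1, all-zero genes give (0, 1, flagged),
precision with an empty positive call set is 0, F-measure with both terms
0 is 0, one-class validation sets produce a well-defined report with NA
AUC.

## Problem sizes used in the checks

The packaged checks run the reference cohort above plus a lighter variant
(50/50 target samples, 600 probes) for stage-level recovery, 600–2000
simulated NB genes at n = 20/20 for the expression calibration, 200
consensus repetitions for cluster recovery, and exhaustive subset search
up to 6 candidates as the SBFS oracle. These sizes were chosen so the
full suite completes in well under a minute of compute per module while
keeping every comparison statistically meaningful.

## Known limitations

* The NB dispersion is common across genes; tagwise shrinkage would be
  more powerful on real RNA-seq.
* The specificity screen is binary (DMC anywhere else ⇒ out); a
  magnitude-aware screen could rank borderline probes instead.
* SBFS is greedy; it matches exhaustive search on the tested problem
  sizes but carries no global guarantee for large candidate sets.
* Information gain ignores inter-CpG redundancy; two perfectly
  correlated markers both pass the filter and must be disentangled by
  the wrapper stage.
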