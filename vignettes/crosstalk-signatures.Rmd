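---
title: "Deriving and validating tumor-stroma crosstalk signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating tumor-stroma crosstalk signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocusig)
```

# The problem

When carcinoma cells and cancer-associated fibroblasts (CAFs) are grown in
direct co-culture, both populations shift their transcriptomes relative to
mono-culture. Genes consistently up-regulated by this crosstalk across
multiple independent cancer-cell/CAF pairs form candidate signatures of
tumor–stroma interaction, which can then be scored in bulk tumor cohorts and
related to outcome. `cocusig` implements that full chain: differential
ranking, gene set enrichment, two alternative signature-derivation rules,
purity correction of sorted samples, per-sample scoring, survival analysis
and a multi-region concordance test, together with synthetic generators that
emulate the statistical structure each stage assumes.

# Ranking and enrichment

For each experiment the co-vs-mono contrast is summarized per gene by a
pooled-variance two-sample Student *t* statistic on the log2(x+1) scale. The
pooled variance is floored at $10^{-8}$ so that noise-free fixtures (zero
within-group variance) stay finite: genes with equal means then get a metric
of exactly 0 rather than 0/0. Ties in the ranking are broken by gene id so
the ranked list is deterministic. Log2(x+1) is used as the variance-damping
transform throughout; the procedures downstream only require a monotone
transform of abundance, so any variance-stabilizing alternative would give
the same ranks where it preserves order.

The enrichment score of a gene set $S$ over a ranked list of $N$ genes is the
classic weighted Kolmogorov–Smirnov running sum: positions in $S$ add
$|r_i|^p / \sum_{j \in S} |r_j|^p$, positions outside $S$ subtract
$1/(N - N_S)$, and ES is the signed maximum deviation from zero. We use
$p = 1$ (the standard weighted form); at $p = 0$ the statistic reduces to the
unweighted KS statistic and is invariant under monotone transforms of the
metric. If every in-set weight is zero (an all-null fixture) the hit
increments fall back to $1/N_S$, which keeps the statistic defined. The
leading edge is the in-set genes at or before the extremum (at or after it
for negative ES). One consequence worth noting: a single-gene set whose gene
sits at the very bottom of the list drives the running sum to exactly $-1$
immediately before the final hit, so ES $= -1$ in that limit.

Significance uses *gene-set permutation*: the null for a set of size $k$ is
the ES of `n_perm` random $k$-subsets of the ranked genes. The permutation p
is one-sided toward the observed sign with +1 smoothing, so it is never 0.
NES divides ES by the mean |null ES| of matching sign, and the FDR q follows
the sign-stratified convention — the fraction of pooled null NES at least as
extreme, divided by the fraction of observed NES at least as extreme, clipped
to [0, 1] and made monotone in |NES| within each sign class. Because the null
depends only on the ranked list and the set size, null streams are keyed by
(seed, size): duplicate sets, or distinct sets of equal size, are calibrated
against an identical null, which makes results reproducible set-by-set and
means duplicated sets get bitwise-identical statistics.

Sets with fewer than 5 or more than 500 genes after intersection with the
ranked universe are skipped with a warning — conventional GSEA bounds, since
the statistic is unstable below and undiscriminating above them.

# Two derivation rules

Both rules operate per dataset and per cell type, require presence in *all*
datasets of a cell type, and union the cancer-cell and CAF lists at the end
(so the signature size is $|A| + |B| - |A \cap B|$).

**Pathway-frequency rule.** Per dataset: the enriched pathways are the sets
with FDR q < 0.05 and ES > 0; the up-regulated pool is the union of their
leading edges; a pool gene is kept if it belongs to at least 20% of the
enriched sets, counted against full set membership, with an inclusive
boundary (`ceiling(0.20 × n_enriched)` sets). Pooling leading edges is a
design choice: the leading edge is GSEA's own definition of the genes that
drive an enrichment, which makes it the natural reading of "the up-regulated
genes of the enriched pathways"; membership frequency is counted against full
sets because pathway membership, not position relative to one dataset's
extremum, is the reproducible property across datasets.

**Fold-change rule.** Per dataset: keep genes whose linear co/mono mean ratio
is ≥ 1.5, inclusive. Genes with a mono-culture mean of zero and positive
co-culture signal count as up-regulated (ratio +∞); 0/0 genes are undefined
and excluded.

# Purity correction of sorted samples

Sorted co-culture samples can carry a fraction of the other lineage. We model
the observed linear-scale profile as a convex mixture
$\mathrm{obs} = (1-\alpha)\,\mathrm{own} + \alpha\,\mathrm{other}$ and
estimate $\alpha$ by one-parameter least squares restricted to lineage
markers — carcinoma: CDH1, EPCAM, CD24 and the KRT family; fibroblast:
COL1A1, COL1A2, DCN, CD248 and the PDGFR genes (prefix families are expanded
against the data's gene universe). The closed form is the projection of
$\mathrm{obs}-\mathrm{own}$ onto $\mathrm{other}-\mathrm{own}$, clipped to
[0, 1]; collinear mono-culture profiles on the markers are rejected as
unidentifiable. Correction then inverts the mixture per gene,
$(\mathrm{obs} - \alpha\,\mathrm{other})/(1-\alpha)$, clipping negatives to
zero with a logged count. Correction is refused at $\alpha \ge 0.9$, where
the $1/(1-\alpha)$ inflation makes it numerically unstable. Everything
happens on the linear scale, because mixing of transcript abundance is linear
there; per-gene inversion (rather than a global scaling) is the only
correction consistent with the mixture model.

# Scoring, stratification and survival

The per-sample signature score is the mean of per-gene z-scores of log2(x+1)
expression over the signature genes present in the matrix. z-scoring makes
the score invariant under gene-wise affine transforms of the log expression
and makes quartile boundaries scale-free; all-constant genes contribute 0.

Quartile stratification uses type-7 quantile boundaries with ties assigned to
the lower group — a deterministic rule, so repeated runs on tied scores agree.
Kaplan–Meier estimation, the two-group log-rank test and Cox regression are
delegated to the `survival` package; Cox fits use Efron tie handling (the
modern default), report HR with a 95% Wald interval, drop constant covariates
with a warning, and flag monotone-likelihood separation as an error rather
than returning a divergent estimate. Covariate-adjusted fits take age, sex
and stage (stage as a continuous 1–4 level). Spearman correlations use
average ranks with the *t* approximation for p; two-group comparisons use the
equal-variance Student *t*, independent or paired.

# Multi-region concordance

Regions are labeled high when their score strictly exceeds the cohort-wide
median of region scores (ties to low). A patient with ≥ 2 regions is
concordant when all regions share one label; single-region patients are
excluded from the concordance denominator but keep their risk label. Under
the null that labels vary randomly between regions — i.i.d. Bernoulli($q$),
with $q = 0.5$ matching the median split — a patient with $n_i$ regions is
concordant with probability $q^{n_i} + (1-q)^{n_i}$, and the expected
concordant count is the sum over multi-region patients. The observed and
expected (rounded) counts form a 2×2 table tested by a two-sided Fisher exact
test; rounding the expectation is required because Fisher's test needs
integer cells, and the rounded discordant cell is defined as the multi-region
total minus the rounded concordant cell so margins always match. The median
split and $q$ are exposed as parameters: median is the simplest two-level
stratification consistent with an "always high or always low" definition of
concordance, but nothing in the machinery depends on that choice.

# What the synthetic generators emulate — and what they do not

All generators are pure functions of (config, seed); a single seed fans out
to per-component child seeds by fixed offsets, so components are independent
and individually reproducible.

- `simulate_coculture_experiments`: per dataset pair and cell type, per-gene
  baselines uniform on log2 [2, 8], a planted co-up-regulated program shared
  across datasets (default 20 genes at log2 FC +1.5 in a 200-gene universe),
  and Gaussian log2-scale noise (sd 0.2, i.e. log-normal multiplicative on
  the linear scale). Defaults of 3 dataset pairs and 4 replicates per
  condition mirror a realistic meta-analysis of three cancer-cell/CAF pairs.
- `simulate_gene_set_collection`: 6 "signal" sets each carrying ~70% of the
  planted program plus random background genes, and 9 pure background sets of
  30 genes — a hallmark-collection-scale fixture for the frequency rule.
- `simulate_contaminated_sort`: exact convex mixtures of two mono-culture
  profiles with optional log-normal noise; the true α is recorded.
- `simulate_survival_cohort`: exponential event times with hazard
  $h_0 \exp(\beta\,\mathrm{score} + \text{covariates})$ and independent
  Uniform(0, b) censoring, with b solved numerically so the average censoring
  probability matches the target rate. Exponential baseline + uniform
  censoring is the simplest model satisfying proportional hazards, which is
  all the parameter-recovery tests require.
- `simulate_multiregion_cohort`: per patient a latent high/low state
  (P(high) = q), a region count from a configurable distribution, per-region
  label flips with probability ε, and label-conditional Gaussian scores
  (means ±2, sd 0.5).

These fixtures deliberately omit count-model (negative-binomial) noise, batch
effects, library-size variation and correlated gene modules. Passing tests
therefore demonstrate that the *procedures* are implemented correctly and
recover planted truth under clean assumptions — not that the signatures
derived from any particular real dataset are biologically right. Two
generator-level caveats worth knowing: at ε = 0 every patient is concordant
in the generator's own labels, but re-deriving labels via the median split
can disagree for a handful of regions when the realized high fraction is not
exactly one half; and record-duplication invariance of the Cox fit holds only
approximately under Efron tie handling, since duplication creates ties.

# Problem sizes and numerical choices

The test suite and the acceptance script run the planted-recovery study at 50
and 25 seeds respectively, with a 200-gene universe and 200 permutations per
GSEA call — sizes chosen so a full run takes seconds per seed while keeping
Monte-Carlo error well below the decision margins (recovery ≥ 80%, ≤ 2 false
positives). Impurity recovery uses 100 mixtures spanning α ∈ [0.1, 0.8] at
noise sd 0.2; Cox recovery uses cohorts of 500 at a true HR of 2 with ~30%
censoring. Numerical guards: the t-statistic variance floor ($10^{-8}$), the
+1-smoothed permutation p, clipping of α to [0, 1] and of corrected
expression to ≥ 0, the α < 0.9 correction bound, and the error (not silent
output) on degenerate stratifications, constant correlation inputs and
all-equal region scores.

# Known limitations

- Phenotype (sample-label) permutation GSEA is not implemented; the gene-set
  permutation null is blind to inter-gene correlation and is anti-conservative
  on correlated sets.
- The frequency rule depends on which collection is supplied; with few
  enriched sets the 20% threshold (`ceiling` of a small number) can be
  toothless.
- The concordance null treats regions as independent given the cohort split;
  spatially correlated sampling within a tumor would make it conservative in
  the direction of calling concordance significant.
- Competing risks, time-varying covariates and multi-component (> 2 lineage)
  deconvolution are out of scope.
```{r session}
sessionInfo()
```
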