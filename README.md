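# cocusig

Cancer cells and cancer-associated fibroblasts (CAFs) reprogram each other's
transcriptomes when grown in direct contact. `cocusig` turns that observation
into a reusable analysis pipeline for deriving **tumor–stroma crosstalk gene
signatures** from paired mono-culture / co-culture expression profiles, and
for testing their clinical relevance in bulk cohorts. It is aimed at
computational biologists who have (or simulate) paired culture transcriptomes
and want to go from raw expression tables to prognostic signature calls.

The pipeline covers:

- **Signature derivation**, two strategies applied per cancer-cell/CAF dataset
  pair and per cell type, then intersected across datasets and unioned across
  cell types:
  - *pathway-frequency rule*: run gene set enrichment analysis (GSEA) on the
    co-vs-mono contrast, pool the leading-edge genes of significantly enriched
    sets (FDR < 0.05, ES > 0), and keep genes present in ≥ 20% of the enriched
    pathways;
  - *fold-change rule*: keep genes with a co/mono fold change ≥ 1.5 in every
    dataset of a cell type.
- **GSEA**: the weighted Kolmogorov–Smirnov running-sum statistic
  ES = max deviation of (P_hit − P_miss), with P_hit weighted by
  |t|^p (p = 1) and gene-set permutation nulls for p, NES and a
  sign-stratified FDR q. Genes are ranked by a pooled-variance two-sample
  Student t statistic on log2(x+1) expression.
- **Purity correction** for sorted co-culture samples: the contaminating
  fraction α is estimated by one-parameter least squares on lineage markers
  (CDH1/EPCAM/CD24/KRT… vs COL1A1/COL1A2/DCN/CD248/PDGFR…) under the
  two-component mixture model `obs = (1−α)·own + α·other`, then inverted per
  gene: `corrected = (obs − α·other) / (1−α)`.
- **Signature scoring and survival**: per-sample score = mean of per-gene
  z-scores of log2(x+1) expression; quartile stratification (Q4 vs Q1),
  Kaplan–Meier curves, log-rank tests, and Cox proportional-hazards fits
  (Efron ties; HR = exp(β̂), 95% CI = exp(β̂ ± 1.96·se)), plus Spearman
  correlation and two-group t comparisons against cell-abundance scores.
- **Multi-region concordance**: regions are labeled high/low by the cohort
  median score; a multi-region patient is *concordant* when all regions share
  one label. The observed concordant count is compared with the analytic
  chance expectation `E[concordant] = Σ_i (q^{n_i} + (1−q)^{n_i})` by a
  two-sided Fisher exact test.
- **Synthetic data generators** for every stage — planted co-upregulation
  programs, contaminated sorted mixtures, proportional-hazards cohorts,
  multi-region cohorts with controllable concordance — so the whole pipeline
  is testable without any external download.

## Worked example

Simulate three cancer/CAF dataset pairs with a 20-gene program planted at
log2 fold change +1.5, derive a signature by each rule, and test the score's
effect on survival in a simulated cohort:

```r
library(cocusig)

cfg  <- coculture_sim_config(seed = 1)
exps <- simulate_coculture_experiments(cfg)
sets <- simulate_gene_set_collection(cfg$genes, names(cfg$planted_program),
                                     seed = 1)

enr <- lapply(exps, function(e)
  list(dataset_id = e$dataset_id, cell_type = e$cell_type,
       result = gsea(rank_by_tstat(e), sets, n_perm = 200, seed = 1)))

sig_freq <- derive_frequency_signature(enr, sets)
sig_fc   <- derive_foldchange_signature(exps)
sig_freq
#> signature 'frequency_signature': 20 genes (20 cancer, 20 CAF, 20 shared)
length(intersect(sig_fc$genes, names(cfg$planted_program)))
#> [1] 20

coh <- simulate_survival_cohort(
  survival_sim_config(seed = 1, n_patients = 400, log_hr = log(2)))
grp <- quartile_stratify(coh$score)
sub <- coh[grp %in% c("Q1", "Q4"), ]
sub$q4 <- as.integer(grp[grp %in% c("Q1", "Q4")] == "Q4")
fit <- cox_fit(sub, "q4")
round(c(hr = fit$hr, lo = fit$ci95_low, hi = fit$ci95_high), 2)
#>   hr   lo   hi
#> 6.68 4.43 10.06
logrank_test(sub$time, sub$event, sub$q4)$p
#> [1] 5.768313e-24
```

Both rules recover the full planted program (20/20 genes, no false
positives), and the highest-scoring quartile has a markedly worse outcome
than the lowest — the hazard ratio of 6.7 for Q4 vs Q1 is what a per-unit
log-hazard of log(2) implies once scores are split at their outer quartiles.

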