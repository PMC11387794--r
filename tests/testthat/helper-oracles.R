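# Independent oracles used across test files. Each re-derives the expected
# quantity by the most literal route available (explicit loops, enumeration,
# closed forms) and never calls the implementation it checks.

# Strip an expr_matrix down to a plain named matrix for comparisons.
unclass_mat <- function(x) {
  matrix(as.numeric(x), nrow = nrow(x), dimnames = dimnames(x))
}

# Weighted KS running sum by explicit position-by-position loop.
oracle_enrichment_score <- function(genes, metric, gene_set, weight_p = 1) {
  n <- length(genes)
  hit <- genes %in% gene_set
  n_hit <- sum(hit)
  total <- sum(abs(metric[hit])^weight_p)
  run <- 0
  runs <- numeric(n)
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + if (total > 0) abs(metric[i])^weight_p / total else 1 / n_hit
    } else {
      run <- run - 1 / (n - n_hit)
    }
    runs[i] <- run
  }
  runs[which.max(abs(runs))]
}

# Two-group log-rank by looping over distinct event times and accumulating
# hypergeometric expectations and variances.
oracle_logrank_chi2 <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L)
  g1 <- levels(group)[1L]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Two-sided Fisher exact p by exhaustive enumeration of tables with the
# observed margins, summing probabilities <= the observed table's.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L])
  total <- r1 + r2
  prob <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(total, c1)
  }
  ks <- max(0L, c1 - r2):min(r1, c1)
  probs <- vapply(ks, prob, numeric(1L))
  p_obs <- prob(tab[1L, 1L])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo concordant-patient count under i.i.d. Bernoulli(q) region labels.
oracle_mc_concordant <- function(region_counts, q, n_draws, seed) {
  set.seed(seed)
  conc <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    conc[i] <- sum(vapply(region_counts, function(n) {
      h <- sum(stats::runif(n) < q)
      h == 0L || h == n
    }, logical(1L)))
  }
  conc
}

# Small random culture experiment on linear scale.
random_experiment <- function(seed, n_genes = 50L, n_rep = 3L,
                              cell_type = "cancer") {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  vals <- matrix(rexp(n_genes * 2L * n_rep, rate = 0.1), nrow = n_genes,
                 dimnames = list(genes, sprintf("s%d", seq_len(2L * n_rep))))
  culture_experiment("ds1", cell_type, expression_matrix(vals, "linear"),
                     rep(c("mono", "co"), each = n_rep))
}
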