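#' A paired mono-/co-culture experiment
#'
#' @param dataset_id dataset label (e.g. the cancer-cell/CAF pair).
#' @param cell_type `"cancer"` or `"caf"` — which sorted population the
#'   expression profiles belong to.
#' @param expression an [expression_matrix()] over the experiment's samples.
#' @param condition per-sample condition labels, `"mono"` or `"co"`, in column
#'   order; at least two samples per condition.
#' @return a `culture_experiment` object.
#' @export
culture_experiment <- function(dataset_id, cell_type = c("cancer", "caf"),
                               expression, condition) {
  cell_type <- match.arg(cell_type)
  stopifnot(inherits(expression, "expr_matrix"))
  condition <- as.character(condition)
  if (length(condition) != ncol(expression)) {
    stop("condition labels must cover all samples")
  }
  if (!all(condition %in% c("mono", "co"))) stop("conditions must be 'mono' or 'co'")
  if (sum(condition == "mono") < 2L || sum(condition == "co") < 2L) {
    stop("need >= 2 samples per condition")
  }
  structure(list(dataset_id = dataset_id, cell_type = cell_type,
                 expression = expression, condition = condition),
            class = "culture_experiment")
}

#' Per-gene co-culture vs mono-culture fold changes
#'
#' Ratio of mean linear expression across co-culture samples over mean across
#' mono-culture samples. Genes with mono mean 0 and co mean > 0 give `Inf`;
#' 0/0 gives `NaN` (excluded by downstream selection).
#'
#' @param exp a [culture_experiment()].
#' @return named numeric vector of fold changes.
#' @export
fold_changes <- function(exp) {
  stopifnot(inherits(exp, "culture_experiment"))
  vals <- unclass_expr(as_linear(exp$expression))
  co <- vals[, exp$condition == "co", drop = FALSE]
  mono <- vals[, exp$condition == "mono", drop = FALSE]
  if (all(co == 0) || all(mono == 0)) stop("a condition has an all-zero library")
  rowMeans(co) / rowMeans(mono)
}

#' Rank genes by the co-vs-mono Student t statistic
#'
#' Pooled-variance two-sample t statistic (co minus mono) computed on the
#' log2(x+1) scale, with the pooled variance floored at 1e-8 so that
#' noise-free fixtures with zero within-group variance yield finite metrics
#' (equal means then give a metric of exactly 0). The list is sorted by metric
#' descending, ties broken by gene id (lexicographic) for determinism.
#'
#' @param exp a [culture_experiment()].
#' @param var_floor lower bound on the pooled variance.
#' @return a data.frame with columns `gene` and `metric`, sorted descending;
#'   class `ranked_list`.
#' @export
rank_by_tstat <- function(exp, var_floor = 1e-8) {
  stopifnot(inherits(exp, "culture_experiment"))
  vals <- unclass_expr(as_log2p1(exp$expression))
  co <- vals[, exp$condition == "co", drop = FALSE]
  mono <- vals[, exp$condition == "mono", drop = FALSE]
  n1 <- ncol(co); n2 <- ncol(mono)
  m1 <- rowMeans(co); m2 <- rowMeans(mono)
  v1 <- apply(co, 1L, stats::var); v2 <- apply(mono, 1L, stats::var)
  sp2 <- pmax(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2), var_floor)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  ranked_list(rownames(vals), tstat, metric_name = "tstat")
}

#' Construct a ranked gene list
#'
#' @param genes gene ids.
#' @param metric ranking metric values (one per gene).
#' @param metric_name metric label.
#' @return data.frame (`gene`, `metric`) sorted by metric descending, ties
#'   broken by gene id; class `ranked_list`.
#' @export
ranked_list <- function(genes, metric, metric_name = "metric") {
  stopifnot(length(genes) == length(metric), !anyDuplicated(genes))
  ord <- order(-metric, genes, method = "radix")
  structure(data.frame(gene = genes[ord], metric = metric[ord],
                       stringsAsFactors = FALSE),
            metric_name = metric_name,
            class = c("ranked_list", "data.frame"))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running sum: walking down the ranked list, in-set genes
#' increment the running sum by `|metric|^weight_p` normalized by the in-set
#' total, genes outside the set decrement it by `1 / (N - N_hit)`. The
#' enrichment score is the signed maximum deviation from zero; the leading
#' edge is the in-set genes at or before the extremum (for ES > 0; at or
#' after, for ES < 0). If all in-set metric weights are zero the hit
#' increments fall back to equal weights `1 / N_hit`.
#'
#' @param ranked a [ranked_list()].
#' @param gene_set character vector of gene ids.
#' @param weight_p metric weighting exponent (1 = GSEA "weighted" default;
#'   0 = unweighted KS).
#' @return list with `es`, `running_sum` (numeric, one value per ranked
#'   position), and `leading_edge` (character).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- ranked$gene %in% gene_set
  n <- length(hit)
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("no overlap between gene set and ranked list")
  if (n_hit == n) stop("gene set covers the entire ranked list")
  w <- abs(ranked$metric)^weight_p
  w[!hit] <- 0
  total <- sum(w)
  inc <- if (total > 0) w / total else ifelse(hit, 1 / n_hit, 0)
  dec <- ifelse(hit, 0, 1 / (n - n_hit))
  running <- cumsum(inc - dec)
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading <- if (es >= 0) {
    ranked$gene[seq_len(i_ext)][hit[seq_len(i_ext)]]
  } else {
    ranked$gene[i_ext:n][hit[i_ext:n]]
  }
  list(es = es, running_sum = running, leading_edge = leading)
}

# Null ES distribution for a given set size: random same-size gene sets drawn
# without replacement from the ranked genes. Depends on the ranked list and
# the size only, so it is shared across (and identical for) same-size sets.
null_es_for_size <- function(ranked, size, n_perm, seed, weight_p) {
  n <- nrow(ranked)
  with_seed(child_seed(seed, 7000L + size), {
    vapply(seq_len(n_perm), function(i) {
      rand <- ranked$gene[sample.int(n, size)]
      enrichment_score(ranked, rand, weight_p)$es
    }, numeric(1L))
  })
}

#' Gene set enrichment analysis with gene-set permutation
#'
#' Computes per-set enrichment scores over a ranked list and calibrates them
#' against a null of random same-size gene sets ("gene set" permutation type).
#' The permutation p value is one-sided toward the observed ES sign with +1
#' smoothing (never exactly 0); NES divides ES by the mean absolute null ES of
#' matching sign; the FDR q follows the sign-stratified GSEA convention,
#' pooling null NES across sets within a sign class, with monotonicity
#' enforced. The null for each set size is generated from a child seed derived
#' from (`seed`, size), so identical or same-sized sets share an identical
#' null stream and results are deterministic given `seed`.
#'
#' @param ranked a [ranked_list()].
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param min_size,max_size set-size filter after intersection with the ranked
#'   genes; out-of-range sets are skipped with a warning.
#' @param weight_p metric weighting exponent.
#' @return data.frame with one row per retained set: `set`, `size`, `es`,
#'   `nes`, `p_perm`, `fdr_q`, `n_perm`, and list-column `leading_edge`.
#' @export
gsea <- function(ranked, sets, n_perm = 1000L, seed = 1L, min_size = 5L,
                 max_size = 500L, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  genes <- ranked$gene
  eff <- lapply(sets, function(s) intersect(s, genes))
  sizes <- lengths(eff)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep)) {
    warning(sum(!keep), " set(s) outside size range [", min_size, ", ",
            max_size, "] skipped: ", paste(names(sets)[!keep], collapse = ", "))
  }
  eff <- eff[keep]
  sizes <- sizes[keep]
  if (!length(eff)) stop("no gene sets within the size filter")

  nulls <- lapply(stats::setNames(nm = unique(sizes)), function(s) {
    null_es_for_size(ranked, as.integer(s), n_perm, seed, weight_p)
  })

  obs <- lapply(eff, function(s) enrichment_score(ranked, s, weight_p))
  es <- vapply(obs, `[[`, numeric(1L), "es")

  p_perm <- numeric(length(es))
  nes <- numeric(length(es))
  null_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    null_i <- nulls[[as.character(sizes[i])]]
    pos <- null_i[null_i >= 0]
    neg <- null_i[null_i < 0]
    if (es[i] >= 0) {
      p_perm[i] <- (1 + sum(null_i >= es[i])) / (1 + n_perm)
      denom <- if (length(pos)) mean(pos) else NA_real_
    } else {
      p_perm[i] <- (1 + sum(null_i <= es[i])) / (1 + n_perm)
      denom <- if (length(neg)) mean(abs(neg)) else NA_real_
    }
    nes[i] <- es[i] / denom
    # null NES: each null ES normalized by its own sign-class mean
    pn <- if (length(pos)) pos / mean(pos) else numeric()
    nn <- if (length(neg)) neg / mean(abs(neg)) else numeric()
    null_nes[[i]] <- c(pn, nn)
  }

  fdr_q <- gsea_fdr(nes, null_nes)

  out <- data.frame(set = names(eff), size = as.integer(sizes), es = es,
                    nes = nes, p_perm = p_perm, fdr_q = fdr_q,
                    n_perm = as.integer(n_perm), stringsAsFactors = FALSE,
                    row.names = NULL)
  out$leading_edge <- lapply(obs, `[[`, "leading_edge")
  out
}

# Sign-stratified GSEA FDR: for each set, q = (fraction of pooled null NES of
# the same sign at least as extreme) / (fraction of observed NES of the same
# sign at least as extreme), clipped to [0, 1], then made monotone in |NES|
# within each sign class.
gsea_fdr <- function(nes, null_nes) {
  all_null <- unlist(null_nes)
  q <- numeric(length(nes))
  for (i in seq_along(nes)) {
    if (is.na(nes[i])) { q[i] <- NA_real_; next }
    if (nes[i] >= 0) {
      null_pool <- all_null[all_null >= 0]
      num <- if (length(null_pool)) mean(null_pool >= nes[i]) else 0
      den <- mean(nes[nes >= 0 & !is.na(nes)] >= nes[i])
    } else {
      null_pool <- all_null[all_null < 0]
      num <- if (length(null_pool)) mean(null_pool <= nes[i]) else 0
      den <- mean(nes[nes < 0 & !is.na(nes)] <= nes[i])
    }
    q[i] <- min(1, num / max(den, .Machine$double.eps))
  }
  # monotone: a more extreme NES never gets a larger q within its sign class
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes) & (if (sgn > 0) nes >= 0 else nes < 0))
    if (length(idx) > 1L) {
      ord <- idx[order(abs(nes[idx]), decreasing = TRUE)]
      q[ord] <- rev(cummin(rev(q[ord])))
    }
  }
  q
}
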