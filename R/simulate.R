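# Run code under a local RNG state so generators are pure in (config, seed).
with_seed <- function(seed, code) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# A single global seed fans out to per-component child seeds by fixed offsets,
# so changing e.g. the survival simulation never perturbs the co-culture draws.
child_seed <- function(seed, offset) (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max

#' Configuration for the paired mono-/co-culture simulator
#'
#' Defaults emulate the study design behind crosstalk-signature derivation:
#' three cancer-cell/CAF dataset pairs, four replicates per condition, a
#' co-upregulated program of 20 genes planted at log2 fold change +1.5 shared
#' across datasets and cell types, and log-scale Gaussian noise of sd 0.2.
#'
#' @param seed integer seed.
#' @param n_genes size of the gene universe (genes named `g0001`, ...).
#' @param n_datasets number of cancer/CAF dataset pairs.
#' @param replicates_per_condition samples per condition (mono, co), >= 2.
#' @param planted_program named numeric vector: gene id -> log2 fold change in
#'   co-culture. `NULL` plants the default +1.5 program on the first
#'   `n_planted` genes.
#' @param n_planted number of planted genes when `planted_program` is NULL.
#' @param planted_lfc log2 fold change for the default program.
#' @param noise_sd per-replicate Gaussian noise sd on the log2 scale.
#' @param baseline_log_mean_range range of per-gene baseline log2 means.
#' @return a `coculture_sim_config` list.
#' @export
coculture_sim_config <- function(seed = 1L, n_genes = 200L, n_datasets = 3L,
                                 replicates_per_condition = 4L,
                                 planted_program = NULL, n_planted = 20L,
                                 planted_lfc = 1.5, noise_sd = 0.2,
                                 baseline_log_mean_range = c(2, 8)) {
  if (replicates_per_condition < 2L) stop("need >= 2 replicates per condition")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(planted_program)) {
    planted_program <- stats::setNames(rep(planted_lfc, n_planted), genes[seq_len(n_planted)])
  }
  if (!all(names(planted_program) %in% genes)) {
    stop("planted_program contains genes outside the simulated universe")
  }
  structure(list(seed = as.integer(seed), genes = genes,
                 n_datasets = as.integer(n_datasets),
                 replicates_per_condition = as.integer(replicates_per_condition),
                 planted_program = planted_program, noise_sd = noise_sd,
                 baseline_log_mean_range = baseline_log_mean_range),
            class = "coculture_sim_config")
}

#' Simulate paired mono-/co-culture experiments with a planted program
#'
#' For each dataset pair and each cell type (cancer, caf), draws a
#' dataset-specific per-gene baseline on the log2 scale, then generates mono
#' and co-culture replicates; co-culture samples carry the planted program's
#' log2 fold changes on top of the baseline. Noise is Gaussian on the log2
#' scale (log-normal multiplicative on the linear scale). With `noise_sd = 0`
#' every planted gene's realized linear fold change is exactly
#' `2^lfc`. Deterministic given `cfg$seed`.
#'
#' @param cfg a [coculture_sim_config()].
#' @return a list of [culture_experiment()] objects, one per
#'   (dataset, cell type), each with linear-scale expression, plus the planted
#'   program as attribute `planted_program`.
#' @export
simulate_coculture_experiments <- function(cfg) {
  stopifnot(inherits(cfg, "coculture_sim_config"))
  n_rep <- cfg$replicates_per_condition
  genes <- cfg$genes
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  lfc[names(cfg$planted_program)] <- cfg$planted_program
  out <- list()
  with_seed(child_seed(cfg$seed, 101L), {
    for (d in seq_len(cfg$n_datasets)) {
      for (ct in c("cancer", "caf")) {
        base <- stats::runif(length(genes), cfg$baseline_log_mean_range[1L],
                             cfg$baseline_log_mean_range[2L])
        logexpr <- matrix(NA_real_, length(genes), 2L * n_rep)
        cond <- rep(c("mono", "co"), each = n_rep)
        for (k in seq_len(2L * n_rep)) {
          mu <- base + if (cond[k] == "co") lfc else 0
          logexpr[, k] <- mu + stats::rnorm(length(genes), 0, cfg$noise_sd)
        }
        dimnames(logexpr) <- list(genes, sprintf("d%d_%s_%s_r%d", d, ct, cond,
                                                 rep(seq_len(n_rep), 2L)))
        mat <- expression_matrix(2^logexpr, "linear")
        out[[sprintf("dataset%d_%s", d, ct)]] <-
          culture_experiment(sprintf("dataset%d", d), ct, mat, cond)
      }
    }
  })
  attr(out, "planted_program") <- cfg$planted_program
  out
}

#' Simulate a synthetic gene-set collection around a planted program
#'
#' Builds a hallmark-collection-scale fixture for testing pathway-frequency
#' signature derivation: `n_signal` sets each contain a random
#' `signal_coverage` share of the planted program plus random background
#' genes; `n_noise` sets are drawn uniformly from the non-planted universe.
#'
#' @param genes gene universe (character).
#' @param planted planted program gene ids (subset of `genes`).
#' @param n_signal,n_noise numbers of signal and background sets.
#' @param set_size genes per set.
#' @param signal_coverage share of the planted program included in each
#'   signal set.
#' @param seed integer seed.
#' @return a named list of character vectors (a gene-set collection).
#' @export
simulate_gene_set_collection <- function(genes, planted, n_signal = 6L,
                                         n_noise = 9L, set_size = 30L,
                                         signal_coverage = 0.7, seed = 1L) {
  stopifnot(all(planted %in% genes))
  background <- setdiff(genes, planted)
  with_seed(child_seed(seed, 202L), {
    sets <- list()
    for (i in seq_len(n_signal)) {
      hit <- sample(planted, max(1L, round(signal_coverage * length(planted))))
      fill <- sample(background, max(0L, set_size - length(hit)))
      sets[[sprintf("SIGNAL_%02d", i)]] <- c(hit, fill)
    }
    for (i in seq_len(n_noise)) {
      sets[[sprintf("BACKGROUND_%02d", i)]] <- sample(background, set_size)
    }
    sets
  })
}

#' Simulate a contaminated sorted co-culture sample
#'
#' Returns the convex mixture `(1 - alpha) * mono_a + alpha * mono_b` with
#' multiplicative log-normal noise, emulating a sorted sample of lineage A
#' contaminated by a fraction `alpha` of lineage B.
#'
#' @param mono_a,mono_b named numeric vectors on the linear scale over the
#'   same gene universe.
#' @param alpha contaminating fraction in \[0, 1\].
#' @param noise_sd log2-scale Gaussian noise sd (0 = noise-free).
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @return a named numeric profile with the true `alpha` stored as attribute
#'   `alpha`.
#' @export
simulate_contaminated_sort <- function(mono_a, mono_b, alpha, noise_sd = 0,
                                       seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.null(names(mono_a)) || is.null(names(mono_b)) ||
      !identical(names(mono_a), names(mono_b))) {
    stop("mono_a and mono_b must share an identical gene universe")
  }
  mix <- (1 - alpha) * mono_a + alpha * mono_b
  if (noise_sd > 0) {
    with_seed(child_seed(seed, 303L), {
      mix <- mix * 2^stats::rnorm(length(mix), 0, noise_sd)
    })
  }
  attr(mix, "alpha") <- alpha
  mix
}

#' Simulate a pair of lineage mono-culture profiles with marker structure
#'
#' Generates linear-scale expression profiles for a carcinoma and a
#' fibroblast mono-culture over a shared gene universe that includes the
#' default lineage marker panels (CDH1/EPCAM/CD24/KRT genes high in the
#' carcinoma profile and near-silent in the fibroblast one; COL1A1/COL1A2/
#' DCN/CD248/PDGFR genes the reverse) plus `n_background` non-marker genes
#' with shared expression. Used to exercise impurity estimation and
#' contamination correction.
#'
#' @param seed integer seed.
#' @param n_background number of non-marker genes.
#' @param marker_high,marker_low mean linear expression of a lineage marker
#'   in its own vs the other lineage.
#' @return list with named numeric profiles `carcinoma` and `fibroblast`.
#' @export
simulate_lineage_profiles <- function(seed = 1L, n_background = 100L,
                                      marker_high = 500, marker_low = 5) {
  carc_mk <- c("CDH1", "EPCAM", "CD24", "KRT5", "KRT14", "KRT17")
  fib_mk <- c("COL1A1", "COL1A2", "DCN", "CD248", "PDGFRA", "PDGFRB")
  genes <- c(carc_mk, fib_mk, sprintf("bg%04d", seq_len(n_background)))
  with_seed(child_seed(seed, 606L), {
    carc <- stats::setNames(c(stats::rgamma(length(carc_mk), 4, 4 / marker_high),
                              stats::rgamma(length(fib_mk), 4, 4 / marker_low),
                              stats::rgamma(n_background, 2, 0.02)), genes)
    fib <- stats::setNames(c(stats::rgamma(length(carc_mk), 4, 4 / marker_low),
                             stats::rgamma(length(fib_mk), 4, 4 / marker_high),
                             stats::rgamma(n_background, 2, 0.02)), genes)
    list(carcinoma = carc, fibroblast = fib)
  })
}

#' Configuration for the proportional-hazards cohort simulator
#'
#' @param seed integer seed.
#' @param n_patients cohort size.
#' @param log_hr true log hazard ratio per unit of signature score.
#' @param baseline_hazard baseline exponential hazard rate (> 0).
#' @param censoring_rate target fraction censored, in \[0, 1).
#' @param age_effect,sex_effect,stage_effect log-hazard effects of the
#'   simulated covariates (age per year, sex = 1 vs 0, stage per level 1-4).
#' @return a `survival_sim_config` list.
#' @export
survival_sim_config <- function(seed = 1L, n_patients = 500L, log_hr = log(2),
                                baseline_hazard = 0.1, censoring_rate = 0.3,
                                age_effect = 0, sex_effect = 0,
                                stage_effect = 0) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censoring_rate < 0 || censoring_rate >= 1) stop("censoring_rate must be in [0, 1)")
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 log_hr = log_hr, baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate, age_effect = age_effect,
                 sex_effect = sex_effect, stage_effect = stage_effect),
            class = "survival_sim_config")
}

#' Simulate a survival cohort whose hazard depends on a signature score
#'
#' Event times are exponential with per-patient hazard
#' `baseline * exp(log_hr * score + covariate terms)`; censoring times are
#' independent Uniform(0, b), with b chosen numerically so the expected
#' censored fraction matches `censoring_rate`. Covariates age ~ N(60, 10),
#' sex ~ Bernoulli(0.5), stage ~ uniform over 1..4 are always generated (their
#' effects default to zero). Deterministic given `cfg$seed`.
#'
#' @param cfg a [survival_sim_config()].
#' @param scores per-patient signature scores; `NULL` draws standard normals.
#' @return a cohort data.frame with columns sample_id, time, event, age, sex,
#'   stage, score.
#' @export
simulate_survival_cohort <- function(cfg, scores = NULL) {
  stopifnot(inherits(cfg, "survival_sim_config"))
  n <- cfg$n_patients
  with_seed(child_seed(cfg$seed, 404L), {
    if (is.null(scores)) scores <- stats::rnorm(n)
    if (length(scores) != n) stop("scores length must equal n_patients")
    if (!all(is.finite(scores))) stop("scores must be finite")
    age <- stats::rnorm(n, 60, 10)
    sex <- stats::rbinom(n, 1L, 0.5)
    stage <- sample(1:4, n, replace = TRUE)
    hazard <- cfg$baseline_hazard * exp(cfg$log_hr * scores +
                                        cfg$age_effect * (age - 60) +
                                        cfg$sex_effect * sex +
                                        cfg$stage_effect * (stage - 1))
    t_event <- stats::rexp(n, rate = hazard)
    if (cfg$censoring_rate == 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      # P(C < T | C ~ Unif(0,b), T ~ Exp(h)) = (1 - exp(-h b)) / (h b)
      cens_prob <- function(b) mean((1 - exp(-hazard * b)) / (hazard * b))
      b <- stats::uniroot(function(b) cens_prob(b) - cfg$censoring_rate,
                          lower = 1e-8, upper = 1e8, tol = 1e-10)$root
      t_cens <- stats::runif(n, 0, b)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    data.frame(sample_id = sprintf("p%04d", seq_len(n)), time = time,
               event = event, age = age, sex = sex, stage = stage,
               score = scores, stringsAsFactors = FALSE)
  })
}

#' Configuration for the multi-region cohort simulator
#'
#' @param seed integer seed.
#' @param n_patients number of patients.
#' @param region_count_distribution named numeric vector mapping region count
#'   to probability (must sum to 1; counts >= 1).
#' @param q_patient probability a patient's latent signature state is high.
#' @param epsilon per-region probability that the observed label flips from
#'   the patient's latent state (0 = perfectly concordant tumors; 0.5 =
#'   regions are independent fair coins).
#' @param score_means,score_sd label-conditional Gaussian score parameters
#'   (`score_means` = c(low, high)).
#' @return a `multiregion_sim_config` list.
#' @export
multiregion_sim_config <- function(seed = 1L, n_patients = 100L,
                                   region_count_distribution = c("1" = 0.2, "2" = 0.35, "3" = 0.3, "4" = 0.15),
                                   q_patient = 0.5, epsilon = 0.1,
                                   score_means = c(-2, 2), score_sd = 0.5) {
  p <- region_count_distribution
  if (abs(sum(p) - 1) > 1e-8) stop("region count probabilities must sum to 1")
  if (any(as.integer(names(p)) < 1L)) stop("region counts must be >= 1")
  if (q_patient <= 0 || q_patient >= 1) stop("q_patient must be in (0, 1)")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 region_count_distribution = p, q_patient = q_patient,
                 epsilon = epsilon, score_means = score_means,
                 score_sd = score_sd),
            class = "multiregion_sim_config")
}

#' Simulate a multi-region tumor cohort with controllable concordance
#'
#' Each patient draws a latent high/low state (P(high) = `q_patient`) and a
#' region count from `region_count_distribution`; each region's observed label
#' equals the latent state flipped independently with probability `epsilon`;
#' region scores are drawn from label-conditional Gaussians. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [multiregion_sim_config()].
#' @return a region data.frame with columns patient_id, region_id, latent
#'   (patient state), label (true region label), score.
#' @export
simulate_multiregion_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "multiregion_sim_config"))
  counts <- as.integer(names(cfg$region_count_distribution))
  with_seed(child_seed(cfg$seed, 505L), {
    rows <- vector("list", cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      n_reg <- counts[sample.int(length(counts), 1L, prob = cfg$region_count_distribution)]
      latent <- if (stats::runif(1) < cfg$q_patient) "high" else "low"
      flip <- stats::runif(n_reg) < cfg$epsilon
      lab <- ifelse(xor(latent == "high", flip), "high", "low")
      mu <- ifelse(lab == "high", cfg$score_means[2L], cfg$score_means[1L])
      rows[[i]] <- data.frame(patient_id = sprintf("pt%03d", i),
                              region_id = sprintf("pt%03d_R%d", i, seq_len(n_reg)),
                              latent = latent, label = lab,
                              score = stats::rnorm(n_reg, mu, cfg$score_sd),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
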