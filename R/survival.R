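#' Stratify samples into score quartiles
#'
#' Quartile boundaries use type-7 quantiles; samples exactly on a boundary go
#' to the lower group, so the assignment is deterministic. Q1 holds the lowest
#' scores.
#'
#' @param scores named (or unnamed) numeric vector, length >= 4.
#' @return factor of labels Q1-Q4, same length/names as `scores`.
#' @export
quartile_stratify <- function(scores) {
  if (length(scores) < 4L) stop("need >= 4 samples to stratify by quartile")
  if (max(scores) == min(scores)) stop("degenerate stratification: all scores identical")
  br <- stats::quantile(scores, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  grp <- ifelse(scores <= br[1L], "Q1",
         ifelse(scores <= br[2L], "Q2",
         ifelse(scores <= br[3L], "Q3", "Q4")))
  factor(stats::setNames(grp, names(scores)), levels = c("Q1", "Q2", "Q3", "Q4"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive event/censoring times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param at_risk_times optional time grid at which to tabulate numbers at
#'   risk (for the "numbers at risk" tables under KM plots).
#' @return list with `curve` (data.frame: time, n_risk, n_event, n_censor,
#'   survival) and, if requested, `at_risk` (data.frame: time, n_risk).
#' @export
km_estimate <- function(time, event, at_risk_times = NULL) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      survival = fit$surv)
  out <- list(curve = curve)
  if (!is.null(at_risk_times)) {
    n_risk <- vapply(at_risk_times, function(t) sum(time >= t), numeric(1L))
    out$at_risk <- data.frame(time = at_risk_times, n_risk = n_risk)
  }
  out
}

#' Two-group log-rank test
#'
#' @param time,event survival outcome vectors.
#' @param group two-level grouping vector.
#' @return list with `chi2` and `p` (chi-square with 1 df). A group with zero
#'   events triggers a warning, not an error.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2L) stop("log-rank test requires exactly two groups")
  ev <- tapply(event, group, sum)
  if (any(ev == 0)) warning("a group has zero events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards fit for a signature exposure
#'
#' Partial-likelihood fit with Efron tie handling via [survival::coxph()].
#' The exposure may be a continuous score or a two-level group (e.g. Q4 vs
#' Q1); optional covariates (e.g. age, sex, stage-as-continuous) give the
#' covariate-adjusted model. Constant covariates are dropped with a warning;
#' monotone-likelihood separation (diverging coefficient) is reported as an
#' error with guidance.
#'
#' @param cohort data.frame with columns `time`, `event`, the exposure column
#'   and any covariate columns.
#' @param exposure name of the exposure column.
#' @param covariates optional character vector of covariate column names.
#' @return list with `log_hr`, `hr`, `ci95_low`, `ci95_high`, `wald_p` for the
#'   exposure (first exposure coefficient if it is a factor), plus the full
#'   `coxph` fit as `fit`.
#' @export
cox_fit <- function(cohort, exposure = "score", covariates = NULL) {
  validate_cohort_min(cohort)
  x <- cohort[[exposure]]
  if (is.null(x)) stop("exposure column '", exposure, "' not found")
  if (length(unique(x[!is.na(x)])) < 2L) stop("exposure must take >= 2 distinct values")
  if (sum(cohort$event) < 1L) stop("no events in cohort")
  keep <- character()
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (is.null(v)) stop("covariate column '", cv, "' not found")
    if (length(unique(v[!is.na(v)])) < 2L) {
      warning("constant covariate '", cv, "' dropped")
    } else keep <- c(keep, cv)
  }
  fml <- stats::reformulate(c(sprintf("`%s`", exposure),
                              sprintf("`%s`", keep)),
                            response = "survival::Surv(time, event)")
  fit <- survival::coxph(fml, data = cohort, ties = "efron")
  beta <- stats::coef(fit)[1L]
  se <- sqrt(diag(stats::vcov(fit)))[1L]
  if (!is.finite(beta) || abs(beta) > 15) {
    stop("monotone-likelihood separation: the exposure perfectly orders events; ",
         "consider penalized regression or coarser stratification")
  }
  list(log_hr = unname(beta), hr = unname(exp(beta)),
       ci95_low = unname(exp(beta - 1.96 * se)),
       ci95_high = unname(exp(beta + 1.96 * se)),
       wald_p = unname(2 * stats::pnorm(-abs(beta / se))),
       fit = fit)
}

validate_cohort_min <- function(df) {
  if (!all(c("time", "event") %in% colnames(df))) {
    stop("cohort must have 'time' and 'event' columns")
  }
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  invisible(df)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Rank correlation with average ranks for ties; the two-sided p value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need >= 3 observations")
  if (max(x) == min(x) || max(y) == min(y)) stop("constant vector: correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Two-group Student t comparison
#'
#' Two-tailed equal-variance Student t test, independent or paired.
#'
#' @param values numeric vector.
#' @param labels two-level grouping vector (for paired tests, groups must be
#'   equal-sized and aligned by position within group).
#' @param paired paired flag.
#' @return list with `t`, `p`, and the group means.
#' @export
group_compare <- function(values, labels, paired = FALSE) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("exactly two groups required")
  g <- split(values, labels)
  if (any(lengths(g) < 2L)) stop("need >= 2 observations per group")
  if (paired && length(g[[1L]]) != length(g[[2L]])) {
    stop("paired comparison requires equal group sizes")
  }
  pooled_var <- if (paired) stats::var(g[[1L]] - g[[2L]]) else {
    n1 <- length(g[[1L]]); n2 <- length(g[[2L]])
    ((n1 - 1) * stats::var(g[[1L]]) + (n2 - 1) * stats::var(g[[2L]])) / (n1 + n2 - 2)
  }
  if (pooled_var == 0 && mean(g[[1L]]) == mean(g[[2L]])) {
    return(list(t = 0, p = 1, means = vapply(g, mean, numeric(1L))))
  }
  if (pooled_var == 0) stop("zero variance with unequal means: t undefined")
  ht <- stats::t.test(g[[1L]], g[[2L]], var.equal = TRUE, paired = paired)
  list(t = unname(ht$statistic), p = ht$p.value,
       means = vapply(g, mean, numeric(1L)))
}
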