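test_that("quartile stratification follows type-7 boundaries with ties to lower", {
  g8 <- quartile_stratify(setNames(1:8, sprintf("s%d", 1:8)))
  expect_identical(unname(g8[1:2]), factor(c("Q1", "Q1"), levels = levels(g8)))
  expect_identical(as.character(g8), c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3",
                                       "Q4", "Q4"))

  g10 <- quartile_stratify(1:10)
  expect_equal(as.integer(table(g10)), c(3L, 2L, 2L, 3L))
  # direct quantile computation agrees
  br <- quantile(1:10, c(0.25, 0.5, 0.75), type = 7)
  expect_identical(as.character(g10),
                   ifelse(1:10 <= br[1], "Q1",
                   ifelse(1:10 <= br[2], "Q2",
                   ifelse(1:10 <= br[3], "Q3", "Q4"))))

  expect_error(quartile_stratify(rep(2, 6)), "degenerate")
  expect_error(quartile_stratify(1:3), ">= 4")
})

test_that("KM estimate matches the hand product-limit computation", {
  # 3 subjects, events at t = 1, 2, 3, no censoring
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$curve$n_risk, c(3, 2, 1))

  # all censored: survival stays at 1
  km_c <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km_c$curve$survival == 1))

  # single subject with event at 5
  km_1 <- km_estimate(5, 1)
  expect_equal(km_1$curve$survival, 0)
  expect_equal(km_1$curve$time, 5)

  # numbers-at-risk grid
  km_r <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1), at_risk_times = c(0, 2.5, 5))
  expect_equal(km_r$at_risk$n_risk, c(4, 2, 0))
})

test_that("KM estimate equals the closed-form product limit on enumerable instances", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    time <- sort(sample(1:6, n, replace = TRUE))
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    km <- km_estimate(time, event)
    # closed form: S(t) = prod over distinct event times <= t of (1 - d/n_at_risk)
    for (j in seq_len(nrow(km$curve))) {
      t_j <- km$curve$time[j]
      s <- 1
      for (t in sort(unique(time[event == 1 & time <= t_j]))) {
        d <- sum(time == t & event == 1)
        at_risk <- sum(time >= t)
        s <- s * (1 - d / at_risk)
      }
      expect_equal(km$curve$survival[j], s, tolerance = 1e-12)
    }
  }
})

test_that("log-rank test matches the hypergeometric hand computation and is symmetric", {
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chi2, oracle_logrank_chi2(time, event, group),
               tolerance = 1e-9)
  lr_swapped <- logrank_test(time, event, rep(c("B", "A"), each = 3))
  expect_equal(lr$chi2, lr_swapped$chi2)

  # identical duplicated groups: no separation
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  expect_warning(logrank_test(c(1, 2, 3, 4), c(1, 1, 0, 0),
                              c("A", "A", "B", "B")), "zero events")
})

test_that("Cox fit recovers simulated hazard ratios and is invariant to record duplication", {
  coh <- simulate_survival_cohort(survival_sim_config(seed = 11, n_patients = 300))
  f <- cox_fit(coh, "score")
  expect_true(f$ci95_low < f$hr && f$hr < f$ci95_high)
  expect_gt(f$hr, 1)

  # duplication creates ties at every event time; Efron's tie correction
  # perturbs the estimate slightly, so invariance holds approximately
  dup <- rbind(coh, transform(coh, sample_id = paste0(sample_id, "_dup")))
  f_dup <- cox_fit(dup, "score")
  expect_equal(f_dup$hr, f$hr, tolerance = 0.005)

  # constant covariate dropped with a warning
  coh$flat <- 1
  expect_warning(cox_fit(coh, "score", covariates = "flat"), "constant")

  # covariate-adjusted fit still recovers the score effect
  cfg <- survival_sim_config(seed = 12, n_patients = 400, age_effect = 0.03,
                             sex_effect = 0.4, stage_effect = 0.3)
  coh2 <- simulate_survival_cohort(cfg)
  f_adj <- cox_fit(coh2, "score", covariates = c("age", "sex", "stage"))
  expect_true(f_adj$ci95_low < 2 && 2 < f_adj$ci95_high)
})

test_that("log-rank and Cox Wald p agree in ordering between null and strong-effect cohorts", {
  null_coh <- simulate_survival_cohort(
    survival_sim_config(seed = 21, n_patients = 200, log_hr = 0))
  eff_coh <- simulate_survival_cohort(
    survival_sim_config(seed = 21, n_patients = 200, log_hr = log(3)))
  p_pair <- function(coh) {
    g <- quartile_stratify(coh$score)
    sub <- coh[g %in% c("Q1", "Q4"), ]
    gl <- droplevels(g[g %in% c("Q1", "Q4")])
    c(logrank = logrank_test(sub$time, sub$event, gl)$p,
      wald = cox_fit(transform(sub, grp = as.integer(gl == "Q4")), "grp")$wald_p)
  }
  p_null <- p_pair(null_coh)
  p_eff <- p_pair(eff_coh)
  expect_lt(p_eff[["logrank"]], p_null[["logrank"]])
  expect_lt(p_eff[["wald"]], p_null[["wald"]])
})

test_that("Spearman correlation handles monotone, reversed and tied data", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  expect_error(spearman_cor(x, rep(1, 6)), "constant")

  # 8-point tied instance against the explicit rank formula
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 7)
  res <- spearman_cor(xt, yt)
  rx <- rank(xt); ry <- rank(yt)
  rho_manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$rho, rho_manual, tolerance = 1e-12)
  t_manual <- rho_manual * sqrt((8 - 2) / (1 - rho_manual^2))
  expect_equal(res$p, 2 * pt(-abs(t_manual), 6), tolerance = 1e-12)
})

test_that("two-group t comparison behaves at the null and under label swap", {
  v <- c(1, 2, 3, 1, 2, 3)
  lab <- rep(c("a", "b"), each = 3)
  res <- group_compare(v, lab)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  set.seed(30)
  v2 <- c(rnorm(10), rnorm(10, 2))
  r1 <- group_compare(v2, lab <- rep(c("a", "b"), each = 10))
  r2 <- group_compare(v2, rep(c("b", "a"), each = 10))
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)

  # all-constant equal groups degenerate gracefully to t = 0, p = 1
  r0 <- group_compare(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(c(r0$t, r0$p), c(0, 1))
  # zero pooled variance with unequal means errors
  expect_error(group_compare(c(1, 1, 2, 2), c("a", "a", "b", "b")), "zero|undefined")
})

test_that("separated-group comparison has high power at n = 50 per group", {
  hits <- 0L
  for (i in 1:40) {
    set.seed(500 + i)
    v <- c(rnorm(50, 0), rnorm(50, 1))
    p <- group_compare(v, rep(c("lo", "hi"), each = 50))$p
    if (p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})
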