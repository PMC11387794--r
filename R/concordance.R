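#' Label tumor regions high/low by the cohort-wide median score
#'
#' A region is `high` iff its score is strictly greater than the median of all
#' region scores in the cohort; ties at the median go to `low`, so the rule is
#' deterministic.
#'
#' @param regions region data.frame (columns `patient_id`, `region_id`, and
#'   the score column).
#' @param score_col name of the score column.
#' @return `regions` with an added character column `region_label`.
#' @export
classify_regions <- function(regions, score_col = "score") {
  s <- regions[[score_col]]
  if (is.null(s)) stop("score column '", score_col, "' not found")
  if (nrow(regions) < 2L) stop("need >= 2 regions")
  if (max(s) == min(s)) stop("all region scores equal: cannot stratify")
  med <- stats::median(s)
  regions$region_label <- ifelse(s > med, "high", "low")
  regions
}

#' Classify patients by cross-region signature concordance
#'
#' A multi-region patient whose regions are all high is `concordant_high`, all
#' low is `concordant_low`, mixed is `discordant`; patients with a single
#' sampled region are `single_region` (excluded from the concordance
#' denominator but still risk-labeled for survival use).
#'
#' @param labeled region data.frame with columns `patient_id` and
#'   `region_label` (from [classify_regions()]).
#' @return data.frame with one row per patient: `patient_id`, `n_regions`,
#'   `class`.
#' @export
classify_patients <- function(labeled) {
  if (!"region_label" %in% colnames(labeled)) stop("missing region_label column")
  by_pt <- split(labeled$region_label, labeled$patient_id)
  cls <- vapply(by_pt, function(lab) {
    if (length(lab) == 1L) "single_region"
    else if (all(lab == "high")) "concordant_high"
    else if (all(lab == "low")) "concordant_low"
    else "discordant"
  }, character(1L))
  data.frame(patient_id = names(by_pt),
             n_regions = lengths(by_pt),
             class = unname(cls),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expected concordant patients under a random-variation null
#'
#' If region labels varied randomly between tumor regions — i.i.d.
#' Bernoulli(`q`) for high — a patient with `n_i` regions is concordant with
#' probability `q^n_i + (1 - q)^n_i`, so the expected number of concordant
#' multi-region patients is the sum of that quantity over patients.
#'
#' @param region_counts per-patient region counts, all >= 2.
#' @param q probability a region is labeled high under the null (0.5 for a
#'   median split).
#' @return list with `expected_concordant` and `expected_discordant`.
#' @export
expected_concordant_by_chance <- function(region_counts, q = 0.5) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (any(region_counts < 2L)) stop("all region counts must be >= 2")
  ec <- sum(q^region_counts + (1 - q)^region_counts)
  list(expected_concordant = ec,
       expected_discordant = length(region_counts) - ec)
}

#' Fisher test of observed vs chance-expected concordance
#'
#' Builds the 2x2 table with rows \{observed, expected\} and columns
#' \{concordant, discordant\}; the expected concordant count is rounded to the
#' nearest integer and the expected discordant count set to the multi-region
#' total minus it (Fisher's test needs integer cells). The p value is the
#' two-sided Fisher exact probability (sum over tables with fixed margins
#' whose point probability does not exceed the observed table's).
#'
#' @param observed_concordant,observed_discordant observed patient counts.
#' @param expected_concordant,expected_discordant chance expectations from
#'   [expected_concordant_by_chance()].
#' @return list with `table` (2x2 integer matrix) and `p`.
#' @export
concordance_test <- function(observed_concordant, observed_discordant,
                             expected_concordant, expected_discordant) {
  n <- observed_concordant + observed_discordant
  if (abs(expected_concordant + expected_discordant - n) > 0.5) {
    stop("expected totals do not match the observed multi-region count")
  }
  ec <- as.integer(round(expected_concordant))
  ed <- as.integer(n - ec)
  if (min(observed_concordant, observed_discordant, ec, ed) < 0) {
    stop("negative cell in the concordance table")
  }
  tab <- matrix(c(observed_concordant, observed_discordant, ec, ed),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("observed", "expected"),
                                c("concordant", "discordant")))
  list(table = tab, p = stats::fisher.test(tab)$p.value)
}

#' Full multi-region concordance analysis
#'
#' Classifies regions by the cohort median split, classifies patients,
#' computes the analytic chance expectation over the multi-region patients'
#' region counts, and runs the observed-vs-expected Fisher test.
#'
#' @param regions region data.frame (`patient_id`, `region_id`, score column).
#' @param score_col name of the score column.
#' @param q null probability of a high region label (0.5 for a median split).
#' @return list with `patients` (per-patient classes), `counts` (named vector:
#'   concordant_high, concordant_low, discordant, single_region),
#'   `n_multiregion`, `expected_concordant`, `expected_discordant`,
#'   `fisher_table`, `fisher_p`.
#' @export
concordance_analysis <- function(regions, score_col = "score", q = 0.5) {
  labeled <- classify_regions(regions, score_col)
  patients <- classify_patients(labeled)
  counts <- vapply(c("concordant_high", "concordant_low", "discordant",
                     "single_region"),
                   function(k) sum(patients$class == k), numeric(1L))
  multi <- patients[patients$class != "single_region", , drop = FALSE]
  exp_null <- expected_concordant_by_chance(multi$n_regions, q)
  obs_conc <- counts[["concordant_high"]] + counts[["concordant_low"]]
  test <- concordance_test(obs_conc, counts[["discordant"]],
                           exp_null$expected_concordant,
                           exp_null$expected_discordant)
  list(patients = patients, counts = counts, n_multiregion = nrow(multi),
       expected_concordant = exp_null$expected_concordant,
       expected_discordant = exp_null$expected_discordant,
       fisher_table = test$table, fisher_p = test$p)
}
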