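#' Lineage marker panel for two-component purity estimation
#'
#' Default panels follow the markers used to assess sorted co-culture purity:
#' CDH1, EPCAM, CD24 and the KRT gene family for carcinoma cells; COL1A1,
#' COL1A2, DCN, CD248 and the PDGFR genes (PDGFRA/PDGFRB) for fibroblasts.
#' Prefix entries (trailing `*`) are expanded against the data's gene universe
#' by [expand_markers()].
#'
#' @param carcinoma_markers character vector; entries ending in `*` are
#'   prefixes.
#' @param fibroblast_markers character vector, same convention.
#' @return a `marker_panel` list.
#' @export
marker_panel <- function(carcinoma_markers = c("CDH1", "EPCAM", "CD24", "KRT*"),
                         fibroblast_markers = c("COL1A1", "COL1A2", "DCN",
                                                "CD248", "PDGFR*")) {
  structure(list(carcinoma_markers = carcinoma_markers,
                 fibroblast_markers = fibroblast_markers),
            class = "marker_panel")
}

#' Expand a marker panel against a gene universe
#'
#' @param panel a [marker_panel()].
#' @param genes gene universe (character).
#' @return list with `carcinoma` and `fibroblast` character vectors of genes
#'   present in `genes`; errors if either panel is empty after expansion or if
#'   the panels overlap.
#' @export
expand_markers <- function(panel, genes) {
  expand <- function(entries) {
    out <- character()
    for (e in entries) {
      if (endsWith(e, "*")) {
        out <- c(out, genes[startsWith(genes, sub("\\*$", "", e))])
      } else if (e %in% genes) {
        out <- c(out, e)
      }
    }
    unique(out)
  }
  carc <- expand(panel$carcinoma_markers)
  fib <- expand(panel$fibroblast_markers)
  if (!length(carc)) stop("no carcinoma markers found in gene universe")
  if (!length(fib)) stop("no fibroblast markers found in gene universe")
  if (length(intersect(carc, fib))) stop("marker panels must be disjoint")
  list(carcinoma = carc, fibroblast = fib)
}

#' Estimate the contaminating fraction of a sorted sample
#'
#' Models the observed linear-scale profile as the convex mixture
#' `(1 - alpha) * own_mono + alpha * other_mono` and estimates `alpha` by
#' one-parameter least squares restricted to the lineage marker genes
#' (closed form: projection of `sample - own` onto `other - own`, clipped to
#' \[0, 1\]).
#'
#' @param sample,own_mono,other_mono named numeric linear-scale profiles over
#'   a shared gene universe; `own_mono` is the mono-culture of the sorted
#'   lineage, `other_mono` the mono-culture of the contaminating lineage.
#' @param panel a [marker_panel()].
#' @return list with `alpha` (estimated contaminating fraction in \[0, 1\])
#'   and `residual` (root-mean-square marker residual at the estimate).
#' @export
estimate_impurity <- function(sample, own_mono, other_mono,
                              panel = marker_panel()) {
  genes <- names(sample)
  if (is.null(genes) || !identical(genes, names(own_mono)) ||
      !identical(genes, names(other_mono))) {
    stop("all three profiles must share an identical gene universe")
  }
  mk <- expand_markers(panel, genes)
  markers <- c(mk$carcinoma, mk$fibroblast)
  s <- sample[markers]; a <- own_mono[markers]; b <- other_mono[markers]
  d <- b - a
  denom <- sum(d^2)
  ref <- max(sum(a^2), sum(b^2))
  if (denom < 1e-12 * max(ref, 1)) {
    stop("unidentifiable mixture: mono-culture profiles are collinear on markers")
  }
  alpha <- min(1, max(0, sum((s - a) * d) / denom))
  resid <- sqrt(mean((s - ((1 - alpha) * a + alpha * b))^2))
  list(alpha = alpha, residual = resid)
}

#' Correct a sorted profile for estimated contamination
#'
#' Inverts the two-component mixture: given the contaminating fraction
#' `alpha`, the corrected profile is
#' `(observed - alpha * other_mono) / (1 - alpha)` per gene, with negatives
#' clipped to zero (the number of clipped genes is reported via a message).
#' Correction is done on the linear scale, where mixing of transcript
#' abundance is linear.
#'
#' @param sample named numeric linear-scale profile (the contaminated sample).
#' @param other_mono mono-culture profile of the contaminating lineage.
#' @param alpha contaminating fraction, `0 <= alpha < alpha_max`.
#' @param alpha_max correction-stability bound; at high contamination the
#'   `1/(1 - alpha)` inflation makes the correction unreliable.
#' @return the corrected named numeric profile (non-negative).
#' @export
correct_contamination <- function(sample, other_mono, alpha, alpha_max = 0.9) {
  if (!identical(names(sample), names(other_mono))) {
    stop("profiles must share an identical gene universe")
  }
  if (alpha < 0) stop("alpha must be >= 0")
  if (alpha >= alpha_max) {
    stop("correction unstable: alpha = ", signif(alpha, 3), " >= alpha_max = ",
         alpha_max)
  }
  corrected <- (sample - alpha * other_mono) / (1 - alpha)
  clipped <- sum(corrected < 0)
  if (clipped > 0) {
    message(clipped, " gene(s) corrected below zero and clipped")
    corrected <- pmax(corrected, 0)
  }
  attr(corrected, "alpha") <- NULL
  corrected
}
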