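#' Construct an expression matrix with a declared scale
#'
#' Wraps a genes-by-samples numeric matrix together with the scale its values
#' are on. Downstream operations that are scale-sensitive (fold changes,
#' mixture correction: linear; ranking, scoring: log2(x+1)) convert
#' explicitly via [as_linear()] / [as_log2p1()] rather than guessing.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimnames must be set, unique and non-missing.
#' @param scale `"linear"` (e.g. TPM, RSEM-normalized counts) or `"log2p1"`
#'   (log2 of linear value plus one).
#' @return an object of class `expr_matrix`: the matrix with a `scale`
#'   attribute.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' em <- expression_matrix(m, "linear")
#' expr_scale(em)
#' @export
expression_matrix <- function(values, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if ((is.null(gene_ids) && nrow(values) > 0L) ||
      (is.null(sample_ids) && ncol(values) > 0L)) {
    stop("`values` must have both row (gene) and column (sample) names")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("expression values must all be finite")
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale expression values must be non-negative")
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) stop("not an expr_matrix: no scale attribute")
  sc
}

#' Convert an expression matrix between linear and log2(x+1) scales
#'
#' @param x an `expr_matrix`.
#' @return an `expr_matrix` on the requested scale (identity if already there).
#' @export
as_log2p1 <- function(x) {
  if (expr_scale(x) == "log2p1") return(x)
  expression_matrix(log2(unclass_expr(x) + 1), "log2p1")
}

#' @rdname as_log2p1
#' @export
as_linear <- function(x) {
  if (expr_scale(x) == "linear") return(x)
  expression_matrix(pmax(2^unclass_expr(x) - 1, 0), "linear")
}

# strip class/attrs down to a plain matrix (keeps dimnames)
unclass_expr <- function(x) {
  y <- unclass(x)
  attr(y, "scale") <- NULL
  y
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  sc <- expr_scale(x)
  y <- unclass_expr(x)[i, j, drop = drop]
  if (is.matrix(y)) expression_matrix(y, sc) else y
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}
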