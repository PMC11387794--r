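#' Read a genes-by-samples expression table
#'
#' The canonical format is TSV with a header row of sample ids and gene ids in
#' the first column (as exported by RSEM/TPM pipelines); comma-separated files
#' are accepted by sniffing the delimiter of the header line. Every cell must
#' be numeric; duplicate gene or sample ids are rejected.
#'
#' @param path path to the TSV/CSV file.
#' @param scale scale the stored values are on, `"linear"` or `"log2p1"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  header <- readLines(path, n = 1L)
  sep <- if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("expression table needs a gene column plus >=1 sample")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(is.na(col) | col == "NA"))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad[1L]], gene_ids[bad[1L]], sample_ids[j]))
    }
    if (anyNA(num)) {
      stop(sprintf("missing value at gene '%s', sample '%s'",
                   gene_ids[which(is.na(num))[1L]], sample_ids[j]))
    }
    vals[, j] <- num
  }
  expression_matrix(vals, scale)
}

#' Write an expression matrix as TSV
#'
#' @param mat an [expression_matrix()].
#' @param path output path.
#' @param gene_col name for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, gene_col = "gene_id") {
  stopifnot(inherits(mat, "expr_matrix"))
  df <- data.frame(rownames(mat), unclass_expr(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Broad dialect: one set per line, tab-separated fields
#' `name, description, gene, gene, ...`. Duplicate genes within a line are
#' collapsed (keeping first occurrence) with a warning; gene order is
#' otherwise preserved.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors, with a `descriptions` attribute
#'   (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(fields)))
    }
    nms[i] <- fields[1L]
    desc[i] <- fields[2L]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate genes collapsed (%s)", fields[1L],
                      paste(unique(genes[duplicated(genes)]), collapse = ", ")))
      genes <- genes[!duplicated(genes)]
    }
    if (!length(genes)) stop(sprintf("GMT set '%s' (line %d) is empty", fields[1L], i))
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    stop("duplicate set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  names(desc) <- nms
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors (optionally with a
#'   `descriptions` attribute as produced by [read_gmt()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical cohort table
#'
#' Requires columns `sample_id`, `time`, `event`; any further columns
#' (covariates, abundance or signature scores) are carried through. Rows with
#' missing time or event are dropped with a message; missing covariate values
#' are kept as NA.
#'
#' @param path path to the TSV file.
#' @return a data.frame validated against the cohort invariants
#'   (unique sample ids, time > 0, event in \{0, 1\}).
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "time", "event")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  drop <- is.na(df$time) | is.na(df$event)
  if (any(drop)) {
    message(sum(drop), " row(s) with missing time/event dropped")
    df <- df[!drop, , drop = FALSE]
  }
  validate_cohort(df)
  df
}

validate_cohort <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in cohort table")
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  invisible(df)
}

#' Read a multi-region table
#'
#' Requires columns `patient_id` and `region_id`; score/expression columns are
#' carried through. (`patient_id`, `region_id`) pairs must be unique.
#'
#' @param path path to the TSV file.
#' @return a data.frame.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("patient_id", "region_id")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("region table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[, req])) stop("duplicate (patient_id, region_id) pairs")
  df
}

#' Filter genes by minimum expression prevalence
#'
#' Retains genes expressed at `min_level` or more in at least a `min_fraction`
#' of samples — the standard cohort filter of "at least 1 TPM in at least 20%
#' of samples". Both comparisons are inclusive; the required sample count is
#' `ceiling(min_fraction * n_samples)`.
#'
#' @param mat a linear-scale [expression_matrix()].
#' @param min_level minimum expression level (same units as `mat`).
#' @param min_fraction minimum fraction of samples, in \[0, 1\].
#' @return the filtered `expr_matrix` (possibly with zero rows, with a warning).
#' @export
filter_expressed_genes <- function(mat, min_level = 1, min_fraction = 0.2) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (expr_scale(mat) != "linear") stop("filter requires linear-scale expression")
  if (min_fraction < 0 || min_fraction > 1) stop("min_fraction must be in [0, 1]")
  need <- ceiling(min_fraction * ncol(mat))
  keep <- rowSums(unclass_expr(mat) >= min_level) >= need
  if (!any(keep)) warning("no genes pass the expression filter")
  mat[keep, , drop = FALSE]
}
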