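#' A crosstalk gene signature with per-cell-type provenance
#'
#' The signature is the union of the genes selected independently for the
#' cancer cells and for the CAFs, so its size is
#' `|cancer| + |caf| - |cancer ∩ caf|` (e.g. lists of 5 and 4 sharing one gene
#' give an 8-gene signature).
#'
#' @param name signature name.
#' @param cancer_list genes selected from the cancer-cell comparisons.
#' @param caf_list genes selected from the CAF comparisons.
#' @return a `signature_def` list with fields `name`, `genes` (the union),
#'   `cancer_list`, `caf_list`.
#' @export
signature_definition <- function(name, cancer_list, caf_list) {
  cancer_list <- unique(as.character(cancer_list))
  caf_list <- unique(as.character(caf_list))
  structure(list(name = name, genes = union(cancer_list, caf_list),
                 cancer_list = cancer_list, caf_list = caf_list),
            class = "signature_def")
}

#' @export
print.signature_def <- function(x, ...) {
  cat(sprintf("signature '%s': %d genes (%d cancer, %d CAF, %d shared)\n",
              x$name, length(x$genes), length(x$cancer_list),
              length(x$caf_list), length(intersect(x$cancer_list, x$caf_list))))
  invisible(x)
}

#' Thresholds for signature derivation
#'
#' @param fdr_threshold FDR cutoff for calling a gene set enriched (upregulated
#'   sets with `fdr_q < fdr_threshold` and ES > 0).
#' @param pathway_frequency_threshold minimum share of a dataset's enriched
#'   pathways a gene must belong to ("present in 20% or more of the enriched
#'   pathways"); inclusive, with required count
#'   `ceiling(threshold * n_enriched)`.
#' @param fold_change_threshold minimum linear co/mono fold change
#'   ("1.5 or higher"); inclusive.
#' @return a `derivation_params` list.
#' @export
derivation_params <- function(fdr_threshold = 0.05,
                              pathway_frequency_threshold = 0.20,
                              fold_change_threshold = 1.5) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            pathway_frequency_threshold > 0, pathway_frequency_threshold <= 1,
            fold_change_threshold > 0)
  structure(list(fdr_threshold = fdr_threshold,
                 pathway_frequency_threshold = pathway_frequency_threshold,
                 fold_change_threshold = fold_change_threshold),
            class = "derivation_params")
}

# per-dataset pathway-frequency gene selection:
#   enriched = upregulated sets with fdr_q < threshold and ES > 0
#   pool     = union of their leading-edge genes
#   keep pool genes belonging to >= ceiling(freq * n_enriched) enriched sets
#   (membership counted against full set membership)
frequency_select <- function(enrich, sets, params) {
  up <- enrich[!is.na(enrich$fdr_q) & enrich$fdr_q < params$fdr_threshold &
               enrich$es > 0, , drop = FALSE]
  if (!nrow(up)) return(character())
  pool <- unique(unlist(up$leading_edge))
  members <- sets[up$set]
  need <- ceiling(params$pathway_frequency_threshold * nrow(up))
  counts <- vapply(pool, function(g) {
    sum(vapply(members, function(s) g %in% s, logical(1L)))
  }, integer(1L))
  pool[counts >= need]
}

#' Derive a signature by pathway-frequency selection (CoCu8-style rule)
#'
#' For each dataset and cell type, runs over that dataset's enrichment
#' results: sets enriched in co-culture (FDR < `fdr_threshold`, ES > 0) define
#' an upregulated gene pool (union of leading edges); genes present in at
#' least `pathway_frequency_threshold` of the enriched sets are kept. Kept
#' lists are then intersected across all datasets of each cell type, and the
#' two cell-type lists are unioned into the signature.
#'
#' @param enrichments list of entries, one per (dataset, cell type), each a
#'   list with fields `dataset_id`, `cell_type` (`"cancer"`/`"caf"`), and
#'   `result` (a [gsea()] data.frame).
#' @param sets the gene-set collection the enrichments were computed against
#'   (full membership is used for frequency counting).
#' @param params a [derivation_params()].
#' @param name signature name.
#' @return a [signature_definition()]; empty (with a warning) if any dataset
#'   of a cell type has no enriched sets and the other cell type yields
#'   nothing either.
#' @export
derive_frequency_signature <- function(enrichments, sets,
                                       params = derivation_params(),
                                       name = "frequency_signature") {
  per_ct <- split(enrichments,
                  vapply(enrichments, `[[`, character(1L), "cell_type"))
  lists <- lapply(c(cancer = "cancer", caf = "caf"), function(ct) {
    entries <- per_ct[[ct]]
    if (is.null(entries)) return(character())
    kept <- lapply(entries, function(e) frequency_select(e$result, sets, params))
    Reduce(intersect, kept)
  })
  sig <- signature_definition(name, lists$cancer, lists$caf)
  if (!length(sig$genes)) warning("derived signature is empty")
  sig
}

#' Derive a signature by fold-change intersection (CoCu30-style rule)
#'
#' For each experiment, keeps genes whose co/mono linear fold change is at
#' least `fold_change_threshold`; kept lists are intersected across all
#' datasets of each cell type and the two cell-type lists unioned.
#'
#' @param experiments list of [culture_experiment()] objects covering both
#'   cell types.
#' @param params a [derivation_params()].
#' @param name signature name.
#' @return a [signature_definition()].
#' @export
derive_foldchange_signature <- function(experiments,
                                        params = derivation_params(),
                                        name = "foldchange_signature") {
  ct <- vapply(experiments, `[[`, character(1L), "cell_type")
  lists <- lapply(c(cancer = "cancer", caf = "caf"), function(type) {
    exps <- experiments[ct == type]
    if (!length(exps)) return(character())
    kept <- lapply(exps, function(e) {
      fc <- fold_changes(e)
      names(fc)[!is.nan(fc) & fc >= params$fold_change_threshold]
    })
    Reduce(intersect, kept)
  })
  sig <- signature_definition(name, lists$cancer, lists$caf)
  if (!length(sig$genes)) warning("derived signature is empty")
  sig
}

#' Score samples against a gene signature
#'
#' Per-sample signature score: each signature gene present in the matrix is
#' z-scored across samples on the log2(x+1) scale, and the score is the mean
#' of those z-scores. Genes with zero variance across samples contribute 0;
#' signature genes absent from the matrix are reported via a message. The
#' score is invariant under gene-wise affine transforms of the log expression
#' and makes quartile stratification scale-free.
#'
#' @param mat an [expression_matrix()] (converted to log2p1 internally).
#' @param sig a [signature_definition()] or plain character vector of genes.
#' @return named numeric vector of per-sample scores.
#' @export
score_signature <- function(mat, sig) {
  genes <- if (inherits(sig, "signature_def")) sig$genes else as.character(sig)
  vals <- unclass_expr(as_log2p1(mat))
  present <- intersect(genes, rownames(vals))
  if (!length(present)) stop("no signature genes present in the expression matrix")
  if (length(present) < length(genes)) {
    message(length(genes) - length(present), " signature gene(s) absent from matrix")
  }
  sub <- vals[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sdev <- apply(sub, 1L, stats::sd)
  z <- (sub - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  colMeans(z)
}

#' Write / read a signature definition as JSON
#'
#' @param sig a [signature_definition()].
#' @param path file path.
#' @return `path` invisibly (write) or a `signature_def` (read).
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_def"))
  jsonlite::write_json(unclass(sig), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  signature_definition(x$name, x$cancer_list, x$caf_list)
}
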