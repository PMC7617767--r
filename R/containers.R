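#' Construct a gene set
#'
#' A gene set is a named, duplicate-free collection of gene identifiers.
#' Identifiers are treated as case-sensitive opaque strings throughout the
#' package: no implicit case folding or symbol mapping ever happens (see
#' [map_orthologs()] for explicit cross-species mapping).
#'
#' @param name Non-empty set name.
#' @param members Character vector of gene identifiers; duplicates are
#'   collapsed with a warning.
#' @param description Free-text description (GMT column 2).
#' @return An object of class `gene_set` with elements `name`, `description`
#'   and `members`.
#' @export
gene_set <- function(name, members, description = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name)) stop("gene set name must be non-empty")
  members <- as.character(members)
  if (length(members) == 0L) stop("gene set '", name, "' has no members")
  if (anyDuplicated(members)) {
    warning("gene set '", name, "' contains duplicate members; de-duplicated")
    members <- unique(members)
  }
  structure(list(name = name, description = as.character(description)[1L],
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Construct a gene set collection
#'
#' An ordered list of [gene_set()] objects with unique names, mirroring the
#' structure of a GMT file.
#'
#' @param sets A list of `gene_set` objects.
#' @return An object of class `gene_set_collection`: a list of gene sets
#'   named by their set names.
#' @export
gene_set_collection <- function(sets) {
  if (!is.list(sets) || !all(vapply(sets, inherits, logical(1), "gene_set")))
    stop("'sets' must be a list of gene_set objects")
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate set names in collection: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets\n", length(x)))
  invisible(x)
}

#' Construct a differential-expression result table
#'
#' Carrier for per-gene differential-expression statistics (typically DESeq2
#' or limma output read from disk): log2 fold change, p-value and FDR-adjusted
#' p-value. Gene identifiers must be unique; use [read_de_table()] to apply
#' the duplicate-resolution policy when loading raw files.
#'
#' @param gene Character vector of unique gene identifiers.
#' @param log2fc Finite log2 fold changes.
#' @param pvalue,fdr Values in `[0, 1]` (NA allowed).
#' @param comparison Name of the comparison the table describes.
#' @return A `data.frame` with columns `gene`, `log2fc`, `pvalue`, `fdr` and
#'   attribute `comparison`.
#' @export
de_table <- function(gene, log2fc, pvalue, fdr, comparison = "comparison") {
  gene <- as.character(gene)
  if (anyDuplicated(gene))
    stop("duplicate gene identifiers in DE table: ",
         paste(utils::head(unique(gene[duplicated(gene)]), 5), collapse = ", "))
  log2fc <- as.numeric(log2fc); pvalue <- as.numeric(pvalue); fdr <- as.numeric(fdr)
  if (any(!is.finite(log2fc)))
    stop("log2fc must be finite")
  for (nm in c("pvalue", "fdr")) {
    v <- get(nm)
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop(nm, " must lie in [0, 1]")
  }
  out <- data.frame(gene = gene, log2fc = log2fc, pvalue = pvalue, fdr = fdr,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  out
}

#' Construct a ranked gene list
#'
#' Ordered (gene, metric) pairs sorted by metric descending -- the input
#' format of pre-ranked GSEA. Ties in the metric are ordered by gene
#' identifier ascending (C-locale) for determinism.
#'
#' @param gene Character vector of unique gene identifiers.
#' @param metric Real ranking metric (finite).
#' @param extra Optional data.frame of additional per-gene columns
#'   (e.g. p-values from a marker test), aligned with `gene`.
#' @return A `data.frame` of class `ranked_list` with columns `gene`,
#'   `metric` (plus any `extra` columns), rows sorted by `metric` descending.
#' @export
ranked_list <- function(gene, metric, extra = NULL) {
  gene <- as.character(gene)
  metric <- as.numeric(metric)
  stopifnot(length(gene) == length(metric))
  if (anyDuplicated(gene))
    stop("duplicate genes in ranked list")
  if (any(!is.finite(metric))) stop("ranking metric must be finite")
  out <- data.frame(gene = gene, metric = metric, stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == length(gene))
    out <- cbind(out, extra)
  }
  ord <- order(-metric, c_rank(gene))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

# C-locale rank of a character vector (deterministic, locale-independent
# tie-breaking used everywhere identifiers break ties).
c_rank <- function(x) {
  ord <- order(x, method = "radix")
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

#' Per-cell AUC score table
#'
#' @param cell Character vector of cell identifiers.
#' @param auc AUC values in `[0, 1]`.
#' @param max_rank The rank cutoff used (aucMaxRank).
#' @param signature_name Name of the signature scored.
#' @param n_signature_in_universe Number of signature genes found in the
#'   expression universe.
#' @return A `data.frame` of class `cell_score` with columns `cell`, `auc`
#'   and the cutoff metadata stored as attributes.
#' @export
cell_score <- function(cell, auc, max_rank, signature_name,
                       n_signature_in_universe) {
  stopifnot(length(cell) == length(auc))
  if (any(auc < -1e-12 | auc > 1 + 1e-12)) stop("auc must lie in [0, 1]")
  out <- data.frame(cell = as.character(cell), auc = pmin(pmax(auc, 0), 1),
                    stringsAsFactors = FALSE)
  attr(out, "max_rank") <- as.integer(max_rank)
  attr(out, "signature_name") <- signature_name
  attr(out, "n_signature_in_universe") <- as.integer(n_signature_in_universe)
  class(out) <- c("cell_score", "data.frame")
  out
}

# shared validator for expression/count matrices
check_matrix_ids <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must carry gene (row) and sample/cell (column) identifiers")
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate sample/cell identifiers")
  invisible(m)
}
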