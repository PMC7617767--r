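#' Read a GMT gene-set file
#'
#' Parses the MSigDB GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are collapsed with a warning; duplicate set names across
#' lines are an error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("malformed GMT line %d: no members", i))
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): duplicate members de-duplicated",
                      i, fields[1]))
      members <- unique(members)
    }
    sets[[i]] <- gene_set(fields[1], members, fields[2])
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A [gene_set_collection()] (a single [gene_set()] is
#'   also accepted).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  if (inherits(collection, "gene_set"))
    collection <- gene_set_collection(list(collection))
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Loads a tab-delimited DE result file (e.g. DESeq2 / limma output) into a
#' validated [de_table()]. Rows whose mapped numeric columns fail to parse
#' are dropped with a message. Duplicate gene rows are resolved by keeping
#' the row with the smallest FDR (ties: smallest p-value, then first
#' occurrence); the resolution is reported.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Named character vector mapping the fields `gene`,
#'   `log2fc`, `pvalue`, `fdr` to column names in the file.
#' @param comparison Comparison name stored on the result (default: file
#'   base name).
#' @return A [de_table()].
#' @export
read_de_table <- function(path,
                          column_map = c(gene = "gene", log2fc = "log2fc",
                                         pvalue = "pvalue", fdr = "fdr"),
                          comparison = NULL) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  required <- c("gene", "log2fc", "pvalue", "fdr")
  if (!all(required %in% names(column_map)))
    stop("column_map must name columns for: ", paste(required, collapse = ", "))
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(unname(column_map[required]), names(raw))
  if (length(missing))
    stop("mapped column(s) not in file: ", paste(missing, collapse = ", "),
         "; available columns: ", paste(names(raw), collapse = ", "))
  gene <- as.character(raw[[column_map[["gene"]]]])
  num <- lapply(c("log2fc", "pvalue", "fdr"), function(f)
    suppressWarnings(as.numeric(raw[[column_map[[f]]]])))
  names(num) <- c("log2fc", "pvalue", "fdr")
  bad <- !is.finite(num$log2fc) | is.na(num$pvalue) | is.na(num$fdr)
  if (any(bad)) {
    message(sum(bad), " row(s) with unparseable numeric values dropped")
    gene <- gene[!bad]; num <- lapply(num, `[`, !bad)
  }
  if (anyDuplicated(gene)) {
    n_dup <- sum(duplicated(gene))
    message(n_dup, " duplicate gene row(s) resolved by min FDR, then min p, then first occurrence")
    ord <- order(num$fdr, num$pvalue, seq_along(gene))
    keep_first <- !duplicated(gene[ord])
    keep <- sort(ord[keep_first])
    gene <- gene[keep]; num <- lapply(num, `[`, keep)
  }
  if (is.null(comparison)) comparison <- basename(path)
  de_table(gene, num$log2fc, num$pvalue, num$fdr, comparison = comparison)
}

#' Read an expression or count matrix
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{`tsv_dense`}{Tab-delimited, header row of sample/cell identifiers,
#'     first column of gene identifiers.}
#'   \item{`mtx_triplet`}{Matrix Market coordinate format (the 10X/Cell Ranger
#'     sparse interchange) with sidecar identifier files, one id per line:
#'     `row_ids` (genes) and `col_ids` (cells). Entries absent from the
#'     triplet list are zero.}
#' }
#'
#' @param path Path to the matrix file.
#' @param format `"tsv_dense"` or `"mtx_triplet"`.
#' @param row_ids,col_ids Paths to the sidecar identifier files (required for
#'   `mtx_triplet`).
#' @param counts If `TRUE`, validate the matrix as a count matrix (all values
#'   non-negative integers); negative or fractional entries are an error.
#'   Defaults to `TRUE` for `mtx_triplet`.
#' @return For `tsv_dense`, a dense numeric matrix (genes x samples) with
#'   `value_scale` attribute `"linear"`; for `mtx_triplet`, a sparse
#'   `dgCMatrix` (genes x cells).
#' @export
read_expression_matrix <- function(path, format = c("tsv_dense", "mtx_triplet"),
                                   row_ids = NULL, col_ids = NULL,
                                   counts = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (format == "tsv_dense") {
    if (is.null(counts)) counts <- FALSE
    raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE)
    m <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(raw[[1]])
    if (anyNA(m)) stop("missing or non-numeric values in dense matrix")
  } else {
    if (is.null(counts)) counts <- TRUE
    if (is.null(row_ids) || is.null(col_ids))
      stop("mtx_triplet format requires row_ids and col_ids sidecar files")
    if (!file.exists(row_ids)) stop("row identifier file not found: ", row_ids)
    if (!file.exists(col_ids)) stop("column identifier file not found: ", col_ids)
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    rid <- readLines(row_ids, warn = FALSE)
    cid <- readLines(col_ids, warn = FALSE)
    if (length(rid) != nrow(m))
      stop(sprintf("row identifier file has %d ids but matrix header declares %d rows",
                   length(rid), nrow(m)))
    if (length(cid) != ncol(m))
      stop(sprintf("column identifier file has %d ids but matrix header declares %d columns",
                   length(cid), ncol(m)))
    dimnames(m) <- list(rid, cid)
  }
  check_matrix_ids(m)
  if (counts) {
    v <- if (methods::is(m, "sparseMatrix")) m@x else m
    if (any(v < 0)) stop("negative values are not valid counts")
    if (any(v != round(v))) stop("non-integer values are not valid counts")
  }
  if (!methods::is(m, "sparseMatrix")) attr(m, "value_scale") <- "linear"
  m
}

#' Write a ranked list in RNK format
#'
#' One `gene<TAB>metric` line per gene, descending metric, no header -- the
#' input format of pre-ranked GSEA tools. Metrics are printed with a full
#' round-trippable decimal representation (`%.17g`), so
#' `read_rnk(write_rnk(x))` reproduces `x` exactly.
#'
#' @param ranked A [ranked_list()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (nrow(ranked) == 0L) {
    warning("writing an empty ranked list to ", path)
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%.17g", ranked$gene, ranked$metric)
  writeLines(lines, path)
  invisible(path)
}

#' Read an RNK ranked-list file
#'
#' @param path Path to a two-column tab-separated file (gene, metric), no
#'   header, metric descending.
#' @return A [ranked_list()].
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) stop("RNK file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(ranked_list(character(0), numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed RNK line(s): expected exactly two tab-separated fields")
  gene <- vapply(parts, `[[`, character(1), 1L)
  metric <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (anyNA(metric)) stop("non-numeric metric in RNK file")
  ranked_list(gene, metric)
}
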