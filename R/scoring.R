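#' Z-score a matrix gene-wise
#'
#' Centers and scales each gene row to mean 0 and sample standard deviation 1
#' (divisor n - 1) across samples. Zero-variance genes cannot be scaled and
#' are removed with a warning listing them.
#'
#' @param m Dense numeric matrix, genes x samples, with at least 2 samples.
#' @return The z-scored matrix with `value_scale` attribute `"zscore"`.
#' @export
zscore_genes <- function(m) {
  m <- as.matrix(m)
  check_matrix_ids(m)
  if (ncol(m) < 2L) stop("z-scoring requires at least 2 samples")
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  zero <- s == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) removed: ",
            paste(utils::head(rownames(m)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
    m <- m[!zero, , drop = FALSE]; mu <- mu[!zero]; s <- s[!zero]
  }
  if (nrow(m) == 0L) stop("all genes have zero variance")
  z <- (m - mu) / s
  attr(z, "value_scale") <- "zscore"
  z
}

#' Per-sample mean-Z signature score
#'
#' The score of a sample is the arithmetic mean of its z-scored expression
#' values over the signature genes present in the matrix. Signature genes
#' absent from the matrix shrink the effective signature with a warning;
#' an empty intersection is an error.
#'
#' @param z A z-scored matrix from [zscore_genes()].
#' @param sig A [gene_set()].
#' @return A `data.frame` with columns `sample` and `score`, plus attributes
#'   `signature_name` and `n_genes_used`.
#' @export
mean_z_signature_score <- function(z, sig) {
  stopifnot(inherits(sig, "gene_set"))
  check_matrix_ids(z)
  vs <- attr(z, "value_scale")
  if (!is.null(vs) && !identical(vs, "zscore"))
    warning("matrix value_scale is '", vs, "', not 'zscore'; scores assume z-scored input")
  common <- intersect(sig$members, rownames(z))
  if (length(common) == 0L)
    stop("no gene of '", sig$name, "' is present in the matrix")
  if (length(common) < length(sig$members))
    warning(length(sig$members) - length(common), " gene(s) of '", sig$name,
            "' absent from the matrix; scoring over ", length(common), " gene(s)")
  score <- colMeans(z[common, , drop = FALSE])
  out <- data.frame(sample = colnames(z), score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "signature_name") <- sig$name
  attr(out, "n_genes_used") <- length(common)
  out
}

#' Rank-recovery AUC signature score per cell (AUCell-style)
#'
#' For each cell, all `N` universe genes are ranked by decreasing expression
#' (ties broken by gene identifier ascending by default, or by a seeded
#' random order). With rank cutoff `m = ceiling(auc_max_frac * N)` and
#' `g` signature genes in the universe, the recovery curve
#' `H(k)` counts signature genes at rank `<= k`, and
#' `auc = sum_{k=1..m} H(k) / sum_{k=1..m} min(k, g)` -- the area under the
#' early recovery curve normalised by its perfect-recovery value. The score
#' is 1 iff the signature occupies the top `g` ranks and 0 iff no signature
#' gene lies within the top `m`. Because it is rank-based, the score is
#' invariant under any strictly monotone transform of a cell's expression
#' values (so raw counts and log-normalised values give identical scores).
#'
#' @param expr Genes x cells matrix (dense or sparse `dgCMatrix`; counts or
#'   any expression scale).
#' @param sig A [gene_set()]; genes absent from the universe shrink `g`
#'   (empty intersection is an error).
#' @param auc_max_frac Fraction of the universe integrated (default 0.10,
#'   the aucMaxRank = 10% convention).
#' @param ties How to break expression ties: `"identifier"` (deterministic,
#'   default) or `"random"` (seeded).
#' @param seed Seed for `ties = "random"`.
#' @return A [cell_score()] table.
#' @export
aucell_score <- function(expr, sig, auc_max_frac = 0.10,
                         ties = c("identifier", "random"), seed = 1L) {
  ties <- match.arg(ties)
  stopifnot(inherits(sig, "gene_set"))
  check_matrix_ids(expr)
  if (!(auc_max_frac > 0 && auc_max_frac <= 1))
    stop("auc_max_frac must lie in (0, 1]")
  genes <- rownames(expr)
  n <- length(genes)
  in_sig <- genes %in% sig$members
  g <- sum(in_sig)
  if (g == 0L) stop("no gene of '", sig$name, "' is present in the universe")
  m <- as.integer(ceiling(auc_max_frac * n))
  tie_break <- if (ties == "identifier") {
    c_rank(genes)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    tb <- sample.int(n)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    tb
  }
  denom <- if (m >= g) g * m - g * (g - 1) / 2 else m * (m + 1) / 2
  sparse <- methods::is(expr, "sparseMatrix")
  auc <- vapply(seq_len(ncol(expr)), function(j) {
    v <- if (sparse) expr[, j] else expr[, j]
    v <- as.numeric(v)
    ord <- order(-v, tie_break)
    pos <- which(in_sig[ord])        # ranks occupied by signature genes
    pos <- pos[pos <= m]
    sum(m - pos + 1) / denom
  }, numeric(1))
  cell_score(colnames(expr), auc, max_rank = m, signature_name = sig$name,
             n_signature_in_universe = g)
}

#' Immunofluorescence H-score
#'
#' Summarises per-nucleus staining-intensity categories into the standard
#' 0-300 H-score: `100 * (1*f_weak + 2*f_moderate + 3*f_strong)` where the
#' fractions are over all nuclei including negatives.
#'
#' @param n_negative,n_weak,n_moderate,n_strong Non-negative nucleus counts
#'   (total must be positive).
#' @return The H-score, a number in `[0, 300]`.
#' @export
h_score <- function(n_negative, n_weak, n_moderate, n_strong) {
  counts <- c(n_negative, n_weak, n_moderate, n_strong)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("nucleus counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stop("total nucleus count must be positive")
  100 * (1 * n_weak + 2 * n_moderate + 3 * n_strong) / total
}
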