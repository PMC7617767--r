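#' Single-cell pipeline configuration
#'
#' QC, normalisation and classification parameters for the single-cell
#' stages. Defaults are the study conditions: cells kept with 200-9000
#' unique features (inclusive) and mitochondrial percentage strictly below
#' 10; features kept when detected in at least 5 cells of at least one
#' sample; a cluster is tumor when strictly more than 20% of its cells are
#' CellTag-positive; "endo-high" is the top 5% of cells by endo-score;
#' log-normalisation scales each cell to `norm_scale` total counts.
#'
#' @param min_features,max_features Inclusive bounds on per-cell unique
#'   feature counts.
#' @param max_mito_pct Strict upper bound on mitochondrial percentage.
#' @param min_cells_per_feature Detection threshold (inclusive) per sample.
#' @param celltag_min_frac Strict lower bound on the CellTag-positive
#'   fraction of a tumor cluster.
#' @param endo_top_frac Fraction of cells classified endo-high.
#' @param norm_scale Library-size scaling constant.
#' @param pseudocount Pseudocount inside the log (log1p convention).
#' @return A list of class `sc_config`.
#' @export
sc_config <- function(min_features = 200L, max_features = 9000L,
                      max_mito_pct = 10, min_cells_per_feature = 5L,
                      celltag_min_frac = 0.20, endo_top_frac = 0.05,
                      norm_scale = 1e4, pseudocount = 1) {
  stopifnot(min_features <= max_features, norm_scale > 0,
            celltag_min_frac > 0, celltag_min_frac < 1,
            endo_top_frac > 0, endo_top_frac < 1)
  structure(list(min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 max_mito_pct = max_mito_pct,
                 min_cells_per_feature = as.integer(min_cells_per_feature),
                 celltag_min_frac = celltag_min_frac,
                 endo_top_frac = endo_top_frac,
                 norm_scale = norm_scale, pseudocount = pseudocount),
            class = "sc_config")
}

check_annotation <- function(counts, ann) {
  req <- c("cell", "sample", "cluster", "n_features", "mito_pct", "celltag_positive")
  missing <- setdiff(req, names(ann))
  if (length(missing))
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(ann$cell)) stop("duplicate cells in annotation")
  if (any(ann$mito_pct < 0 | ann$mito_pct > 100)) stop("mito_pct must lie in [0, 100]")
  uncovered <- setdiff(colnames(counts), ann$cell)
  if (length(uncovered))
    stop(length(uncovered), " cell(s) of the count matrix missing from the annotation")
  ann[match(colnames(counts), ann$cell), , drop = FALSE]
}

#' Quality-control filtering of cells and features
#'
#' Cells are kept when their unique feature count lies within
#' `[min_features, max_features]` (inclusive) and their mitochondrial
#' percentage is strictly below `max_mito_pct`. Features are then kept when
#' detected (count > 0) in at least `min_cells_per_feature` cells of at
#' least one sample (a per-sample rule applied before merging, so a feature
#' surviving in any sample survives overall). A filtering report is
#' emitted as messages. The operation is idempotent.
#'
#' @param counts Genes x cells count matrix (sparse or dense).
#' @param ann Cell annotation data.frame with columns `cell`, `sample`,
#'   `cluster`, `n_features`, `mito_pct`, `celltag_positive`, covering all
#'   cells of `counts`.
#' @param cfg An [sc_config()].
#' @return A list with elements `counts` and `annotation`, both filtered.
#' @export
qc_filter <- function(counts, ann, cfg = sc_config()) {
  check_matrix_ids(counts)
  ann <- check_annotation(counts, ann)
  keep_cell <- ann$n_features >= cfg$min_features &
    ann$n_features <= cfg$max_features &
    ann$mito_pct < cfg$max_mito_pct
  message("qc_filter: ", sum(!keep_cell), " of ", ncol(counts), " cell(s) removed")
  if (!any(keep_cell)) stop("no cell survives QC")
  counts <- counts[, keep_cell, drop = FALSE]
  ann <- ann[keep_cell, , drop = FALSE]
  detected <- counts > 0
  samples <- unique(ann$sample)
  keep_feature <- rep(FALSE, nrow(counts))
  for (s in samples) {
    cells_s <- ann$cell[ann$sample == s]
    det_s <- Matrix::rowSums(detected[, cells_s, drop = FALSE])
    keep_feature <- keep_feature | det_s >= cfg$min_cells_per_feature
  }
  message("qc_filter: ", sum(!keep_feature), " of ", nrow(counts),
          " feature(s) below detection threshold removed")
  if (!any(keep_feature)) stop("no feature survives QC")
  list(counts = counts[keep_feature, , drop = FALSE],
       annotation = ann)
}

#' Library-size log-normalisation
#'
#' `value(g, c) = log(1 + count(g, c) * norm_scale / total(c))`, the
#' standard log1p of counts-per-`norm_scale`. Zeros map to zeros, so
#' sparsity is preserved; multiplying all counts of a cell by a constant
#' leaves its normalised values unchanged. This simple compositional
#' normalisation stands upstream of the rank-based AUC scoring, which is
#' insensitive to any within-cell monotone transform.
#'
#' @param counts Genes x cells count matrix (sparse `dgCMatrix` or dense);
#'   every cell must have a positive total.
#' @param cfg An [sc_config()] (supplies `norm_scale`).
#' @return Log-scale expression matrix of the same class and dimensions.
#' @export
lognormalize <- function(counts, cfg = sc_config()) {
  check_matrix_ids(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(counts)[totals == 0], 5), collapse = ", "))
  if (methods::is(counts, "CsparseMatrix")) {
    out <- counts
    percol <- rep.int(totals, diff(counts@p))
    out@x <- log1p(counts@x * cfg$norm_scale / percol)
    out
  } else {
    m <- log1p(sweep(as.matrix(counts), 2, totals, "/") * cfg$norm_scale)
    attr(m, "value_scale") <- "log"
    m
  }
}

#' Classify clusters as tumor by CellTag fraction
#'
#' A cluster is called tumor when strictly more than `celltag_min_frac` of
#' its cells carry the CellTag lineage marker.
#'
#' @param ann Cell annotation with `cluster` and `celltag_positive` columns.
#' @param cfg An [sc_config()].
#' @return Named character vector, cluster label -> `"tumor"` /
#'   `"non_tumor"`.
#' @export
classify_tumor_clusters <- function(ann, cfg = sc_config()) {
  stopifnot(all(c("cluster", "celltag_positive") %in% names(ann)))
  if (nrow(ann) == 0L || all(is.na(ann$cluster)) || length(unique(ann$cluster)) == 0L)
    stop("no cluster labels present")
  frac <- tapply(as.logical(ann$celltag_positive), as.character(ann$cluster), mean)
  out <- ifelse(frac > cfg$celltag_min_frac, "tumor", "non_tumor")
  stats::setNames(as.character(out), names(frac))
}

#' Classify endo-high cells
#'
#' Selects the `k = ceiling(endo_top_frac * n)` cells with the highest AUC
#' scores within the selection universe (`within`, default all scored
#' cells); boundary ties resolve by cell identifier ascending with a
#' warning. The threshold returned is the lowest selected score.
#'
#' @param scores A [cell_score()] table.
#' @param cfg An [sc_config()].
#' @param within Optional character vector of cell identifiers restricting
#'   the selection universe (e.g. tumor cells of the treated samples).
#' @return A list with `labels` (named character vector,
#'   `"endo_high"`/`"rest"`, over the selection universe) and `threshold`.
#' @export
classify_endo_high <- function(scores, cfg = sc_config(), within = NULL) {
  stopifnot(inherits(scores, "data.frame"), all(c("cell", "auc") %in% names(scores)))
  s <- scores
  if (!is.null(within)) {
    missing <- setdiff(within, s$cell)
    if (length(missing))
      stop(length(missing), " cell(s) of 'within' have no score")
    s <- s[s$cell %in% within, , drop = FALSE]
  }
  n <- nrow(s)
  if (n == 0L) stop("empty selection universe")
  if (n < 20L)
    warning("selection universe has only ", n, " cells; top-fraction selection is coarse")
  k <- as.integer(ceiling(cfg$endo_top_frac * n))
  ord <- order(-s$auc, c_rank(s$cell))
  sel <- ord[seq_len(k)]
  threshold <- min(s$auc[sel])
  if (any(s$auc[ord[-seq_len(k)]] == threshold))
    warning("tie at the selection boundary broken by cell identifier")
  labels <- stats::setNames(rep("rest", n), s$cell)
  labels[s$cell[sel]] <- "endo_high"
  list(labels = labels, threshold = threshold)
}

#' Fraction of cells above a score cutoff, by group
#'
#' Per group, the fraction of scored cells with AUC strictly above
#' `cutoff`. Groups with no scored cells report `NA` with a warning.
#'
#' @param scores A [cell_score()] table.
#' @param ann Cell annotation covering the scored cells.
#' @param cutoff Numeric cutoff in `[0, 1]`.
#' @param group_by Annotation column to group by (default `"sample"`).
#' @return A `data.frame` with columns `group` and `fraction`.
#' @export
fraction_above_cutoff <- function(scores, ann, cutoff, group_by = "sample") {
  stopifnot(cutoff >= 0, cutoff <= 1, group_by %in% names(ann))
  idx <- match(scores$cell, ann$cell)
  if (anyNA(idx)) stop("scored cell(s) missing from annotation")
  grp <- as.character(ann[[group_by]][idx])
  groups <- unique(as.character(ann[[group_by]]))
  frac <- vapply(groups, function(g) {
    v <- scores$auc[grp == g]
    if (length(v) == 0L) {
      warning("group '", g, "' has no scored cells; fraction undefined")
      return(NA_real_)
    }
    mean(v > cutoff)
  }, numeric(1))
  data.frame(group = groups, fraction = unname(frac), stringsAsFactors = FALSE)
}

#' Rank marker genes between endo-high and remaining cells
#'
#' Per gene, the ranking metric is the log2 ratio of linearised group means:
#' `log2((mean(expm1(x)) in endo_high + pc) / (mean in rest + pc))` with a
#' small rate pseudocount `pc` (default `1/norm_scale`, i.e. one count per
#' scaled library). Per-gene two-sided rank-sum p-values (tie-corrected
#' normal approximation) and BH q-values accompany the metric. No
#' minimum-expression prefilter is applied, so the full universe stays in
#' the ranked list for downstream enrichment.
#'
#' @param expr Log-scale genes x cells matrix from [lognormalize()].
#' @param labels Named character vector (`"endo_high"`/`"rest"`) as returned
#'   by [classify_endo_high()]; only labelled cells are used.
#' @param pseudocount_rate Rate pseudocount (default 1e-4).
#' @return A [ranked_list()] with extra columns `pvalue` and `fdr`.
#' @export
rank_markers <- function(expr, labels, pseudocount_rate = 1e-4) {
  check_matrix_ids(expr)
  labels <- labels[names(labels) %in% colnames(expr)]
  a <- names(labels)[labels == "endo_high"]
  b <- names(labels)[labels == "rest"]
  if (length(a) == 0L) stop("no endo_high cells")
  if (length(b) == 0L) stop("no rest cells")
  lin <- expr[, c(a, b), drop = FALSE]
  if (methods::is(lin, "CsparseMatrix")) {
    lin@x <- expm1(lin@x)
  } else {
    lin <- expm1(lin)
  }
  mean_a <- Matrix::rowMeans(lin[, a, drop = FALSE])
  mean_b <- Matrix::rowMeans(lin[, b, drop = FALSE])
  metric <- log2((mean_a + pseudocount_rate) / (mean_b + pseudocount_rate))
  grp_a <- c(rep(TRUE, length(a)), rep(FALSE, length(b)))
  p <- ranksum_rows(expr[, c(a, b), drop = FALSE], grp_a)
  q <- bh_fdr(p)
  ranked_list(rownames(expr), unname(metric),
              extra = data.frame(pvalue = unname(p), fdr = unname(q)))
}

# two-sided rank-sum p per row: tie-corrected normal approximation with
# continuity correction, chunked so sparse input never densifies whole.
ranksum_rows <- function(x, grp_a) {
  n1 <- sum(grp_a); n2 <- sum(!grp_a); n <- n1 + n2
  p <- numeric(nrow(x))
  chunk <- 1000L
  for (start in seq(1L, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(x))
    block <- as.matrix(x[idx, , drop = FALSE])
    p[idx] <- apply(block, 1, function(v) {
      r <- rank(v)
      w <- sum(r[grp_a]) - n1 * (n1 + 1) / 2          # Mann-Whitney U
      mu <- n1 * n2 / 2
      tie_tab <- table(v)
      sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
      if (sigma2 <= 0) return(1)
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      min(1, 2 * stats::pnorm(-abs(z)))
    })
  }
  p
}

#' Pseudo-bulk aggregation of a cluster
#'
#' Sums counts over the cells of one cluster, per sample: entry (g, s) is
#' the total count of gene g across the cluster's cells belonging to sample
#' s. Total counts are conserved exactly.
#'
#' @param counts Genes x cells count matrix.
#' @param ann Cell annotation covering the cells of `counts`.
#' @param cluster Cluster label to aggregate.
#' @return Dense genes x samples matrix of summed counts (`value_scale`
#'   `"linear"`).
#' @export
pseudo_bulk <- function(counts, ann, cluster) {
  check_matrix_ids(counts)
  ann <- check_annotation(counts, ann)
  cells <- ann$cell[as.character(ann$cluster) == as.character(cluster)]
  if (length(cells) == 0L) stop("cluster '", cluster, "' has no cells")
  cell_sample <- as.character(ann$sample[match(cells, ann$cell)])
  samples <- unique(cell_sample)
  ind <- 1 * outer(cell_sample, samples, "==")
  out <- as.matrix(counts[, cells, drop = FALSE] %*% ind)
  colnames(out) <- samples
  attr(out, "value_scale") <- "linear"
  out
}
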