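#' Rank genes by correlation with a core-signature score
#'
#' Mirrors the cohort analysis used to discover genes travelling with a
#' small core signature: the matrix is z-scored gene-wise, a per-sample
#' mean-Z core score is computed, and every gene's expression row is
#' correlated with that score vector. The correlation coefficients are the
#' ranking metric. Core genes are retained in the list by default (their
#' self-correlation places them near the top, which is the intended signal
#' for downstream enrichment); set `exclude_core = TRUE` to drop them.
#'
#' @param m Dense genes x samples expression matrix (>= 3 samples).
#' @param core A [gene_set()] used for the mean-Z score.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param exclude_core Drop core genes from the output list.
#' @param use_zscored Correlate z-scored rather than raw rows (for Pearson
#'   the per-gene correlation is identical up to sign of the scaling;
#'   exposed because both conventions appear in practice).
#' @return A [ranked_list()] sorted by correlation descending; zero-variance
#'   genes (undefined correlation) are excluded with a warning.
#' @export
rank_by_correlation <- function(m, core, method = c("pearson", "spearman"),
                                exclude_core = FALSE, use_zscored = FALSE) {
  method <- match.arg(method)
  m <- as.matrix(m)
  check_matrix_ids(m)
  if (ncol(m) < 3L) stop("correlation ranking requires >= 3 samples")
  z <- suppressWarnings(zscore_genes(m))
  score <- mean_z_signature_score(z, core)$score
  basis <- if (use_zscored) z else m
  cc <- suppressWarnings(as.numeric(stats::cor(t(basis), score, method = method)))
  names(cc) <- rownames(basis)
  bad <- !is.finite(cc)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with undefined correlation excluded")
    cc <- cc[!bad]
  }
  if (exclude_core) cc <- cc[!names(cc) %in% core$members]
  ranked_list(names(cc), unname(cc))
}

#' Rank genes by target-group median minus global median
#'
#' The ranking metric used to contrast a curated group of samples (e.g.
#' VM-proficient cell lines) against an entire panel: per gene, the median
#' over the target-group samples minus the median over all samples.
#'
#' @param m Dense genes x samples expression matrix.
#' @param group Named character vector of group labels (names are sample
#'   identifiers present in `m`).
#' @param target_label The group forming the numerator median.
#' @return A [ranked_list()] sorted descending.
#' @export
rank_by_median_diff <- function(m, group, target_label) {
  m <- as.matrix(m)
  check_matrix_ids(m)
  group <- check_group_labels(m, group)
  target <- names(group)[group == target_label]
  if (length(target) == 0L) stop("unknown or empty target group: ", target_label)
  if (ncol(m) < 2L) stop("median-difference ranking requires >= 2 samples")
  med_target <- apply(m[, target, drop = FALSE], 1, stats::median)
  med_all <- apply(m, 1, stats::median)
  ranked_list(rownames(m), med_target - med_all)
}

#' Rank genes by mean-Z difference between two groups
#'
#' Per gene, the mean z-scored value over group `label_a` minus the mean
#' over group `label_b` (the proteomics-style ranking metric).
#'
#' @param z A z-scored matrix from [zscore_genes()].
#' @param group Named character vector of group labels.
#' @param label_a,label_b Group labels (both must be non-empty).
#' @return A [ranked_list()] sorted descending.
#' @export
rank_by_mean_z_diff <- function(z, group, label_a, label_b) {
  check_matrix_ids(z)
  group <- check_group_labels(z, group)
  a <- names(group)[group == label_a]
  b <- names(group)[group == label_b]
  if (length(a) == 0L) stop("unknown or empty group: ", label_a)
  if (length(b) == 0L) stop("unknown or empty group: ", label_b)
  metric <- rowMeans(z[, a, drop = FALSE]) - rowMeans(z[, b, drop = FALSE])
  ranked_list(rownames(z), unname(metric))
}

#' Two-sided Wilcoxon rank-sum comparison of signature scores
#'
#' Compares per-sample signature scores between two groups with the
#' two-sided Mann-Whitney/Wilcoxon rank-sum test: exact enumeration when
#' both groups are small (min(n) <= 8) and tie-free, otherwise the
#' tie-corrected normal approximation with continuity correction. Warns
#' below a total of 8 samples, where the test has little power.
#'
#' @param scores A score table from [mean_z_signature_score()] (any
#'   data.frame with columns `sample` and `score`).
#' @param group Named character vector of group labels.
#' @param label_a,label_b Group labels.
#' @return A list with `statistic` (rank-sum W), `p_two_sided`, `n_a`, `n_b`.
#' @export
compare_groups_ranksum <- function(scores, group, label_a, label_b) {
  stopifnot(all(c("sample", "score") %in% names(scores)))
  group <- group[names(group) %in% scores$sample]
  sa <- scores$score[match(names(group)[group == label_a], scores$sample)]
  sb <- scores$score[match(names(group)[group == label_b], scores$sample)]
  n_a <- length(sa); n_b <- length(sb)
  if (n_a == 0L) stop("group '", label_a, "' has no scored samples")
  if (n_b == 0L) stop("group '", label_b, "' has no scored samples")
  if (n_a + n_b < 8L)
    warning("total n = ", n_a + n_b, " < 8; rank-sum test has little power")
  has_ties <- anyDuplicated(c(sa, sb)) > 0L
  use_exact <- min(n_a, n_b) <= 8L && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(sa, sb, alternative = "two.sided",
                                            exact = use_exact, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(statistic = unname(wt$statistic), p_two_sided = min(p, 1),
       n_a = n_a, n_b = n_b)
}

# validate sample -> label mapping against a matrix
check_group_labels <- function(m, group) {
  if (is.null(names(group))) stop("group labels must be named by sample identifier")
  unknown <- setdiff(names(group), colnames(m))
  if (length(unknown))
    stop("labelled sample(s) absent from matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  group
}
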