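#' Pre-ranked GSEA configuration
#'
#' Defaults mirror the classic pre-ranked GSEA conventions: metric weight
#' p = 1 (weighted KS statistic), 1000 gene-set permutations, set-size
#' window [5, 2000] applied to the matched (post-intersection) size.
#'
#' @param weight_p Non-negative exponent on |metric| in the hit increments
#'   (0 gives the classical unweighted KS statistic).
#' @param n_perm Number of gene-set permutations (>= 10).
#' @param seed Integer seed for the permutation null.
#' @param min_set_size,max_set_size Matched-size filter bounds.
#' @return A list of class `gsea_config`.
#' @export
gsea_config <- function(weight_p = 1, n_perm = 1000L, seed = 1L,
                        min_set_size = 5L, max_set_size = 2000L) {
  stopifnot(weight_p >= 0, n_perm >= 10, min_set_size <= max_set_size)
  structure(list(weight_p = weight_p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size)),
            class = "gsea_config")
}

# Weighted KS walk over hit positions only (O(g) after the O(N) weight
# lookup is done by the caller). `pos` are sorted 1-based hit ranks,
# `w` their |metric|^p weights, `n` the list length.
# The running deviation P_hit - P_miss increases by w_i/N_R at each hit and
# decreases by 1/(N - g) at each miss; its maximum is attained at a hit
# position and its minimum just before a hit (or is 0 at the list ends).
# Tie between equal-magnitude positive and negative extremes: positive wins.
ks_walk <- function(pos, w, n) {
  g <- length(pos)
  n_miss <- n - g
  nr <- sum(w)
  p_hit <- if (nr > 0) cumsum(w) / nr else seq_len(g) / g
  p_miss_at <- (pos - seq_len(g)) / n_miss
  d_hit <- p_hit - p_miss_at                      # value at each hit
  d_pre <- c(0, p_hit[-g]) - p_miss_at            # value just before each hit
  i_max <- which.max(d_hit)
  pos_max <- d_hit[i_max]
  i_min <- which.min(d_pre)
  neg_min <- min(d_pre[i_min], 0)
  # the tie comparison carries a small tolerance so mathematically exact
  # magnitude ties resolve to the positive extreme regardless of summation
  # rounding
  if (pos_max >= -neg_min - 1e-12) {
    list(es = pos_max, at = pos[i_max], le_idx = seq_len(i_max))
  } else {
    list(es = neg_min, at = pos[i_min] - 1L, le_idx = seq.int(i_min, g))
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|metric|^weight_p / N_R` at signature
#' genes ("hits") and `1 / (N - N_S)` at all other genes ("misses"); the
#' enrichment score is the deviation of the running sum `P_hit - P_miss`
#' with maximal absolute value (a tie between equal-magnitude positive and
#' negative extremes resolves to the positive one). The leading edge
#' contains the matched signature genes at or before the extremum when
#' `es > 0`, and at or after it when `es < 0`.
#'
#' @param ranked A [ranked_list()].
#' @param sig A [gene_set()]; its intersection with the list must be
#'   non-empty and a proper subset of the list.
#' @param weight_p Non-negative metric weight (default 1).
#' @param return_profile If `TRUE`, also return the full running deviation
#'   profile (one value per list position).
#' @return A list with elements `es`, `leading_edge` (character vector),
#'   `at` (list position of the extremum), `n_genes_matched`, and (if
#'   requested) `profile`.
#' @export
enrichment_score <- function(ranked, sig, weight_p = 1, return_profile = FALSE) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(sig, "gene_set"),
            weight_p >= 0)
  n <- nrow(ranked)
  hit <- ranked$gene %in% sig$members
  g <- sum(hit)
  if (g == 0L) stop("no gene of '", sig$name, "' is present in the ranked list")
  if (g == n) stop("'", sig$name, "' covers the whole ranked list; complement is empty")
  pos <- which(hit)
  w <- abs(ranked$metric[pos])^weight_p
  walk <- ks_walk(pos, w, n)
  out <- list(es = walk$es,
              leading_edge = ranked$gene[pos[walk$le_idx]],
              at = walk$at,
              n_genes_matched = g)
  if (return_profile) {
    nr <- sum(w)
    inc <- rep(-1 / (n - g), n)
    inc[pos] <- if (nr > 0) w / nr else 1 / g
    out$profile <- cumsum(inc)
  }
  out
}

#' Pre-ranked GSEA with gene-set-permutation null
#'
#' For each gene set (size-filtered on its matched size), computes the
#' weighted KS enrichment score, then builds a null distribution from
#' `n_perm` random same-size gene draws from the ranked universe. The
#' normalised enrichment score divides the observed ES by the mean absolute
#' null ES of matching sign; the nominal p-value is the add-one-corrected
#' fraction of same-sign null ES at least as extreme; the FDR q-value
#' follows the normalised-null ratio procedure of the original GSEA method
#' (the fraction of pooled null NES at least as extreme, divided by the
#' fraction of observed NES at least as extreme, clamped to [0, 1]).
#' Results are deterministic given `cfg$seed`.
#'
#' @param ranked A [ranked_list()].
#' @param sets A [gene_set_collection()] (or a single [gene_set()]).
#' @param cfg A [gsea_config()].
#' @return A `data.frame` with one row per retained set: `set`, `size`,
#'   `es`, `nes`, `p_nominal`, `fdr_q`, `signed_log10_q`, and a list column
#'   `leading_edge`; attribute `n_perm` records the permutation count.
#' @export
gsea_preranked <- function(ranked, sets, cfg = gsea_config()) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (inherits(sets, "gene_set")) sets <- gene_set_collection(list(sets))
  stopifnot(inherits(sets, "gene_set_collection"))
  n <- nrow(ranked)
  if (n < cfg$min_set_size + 1L)
    stop("ranked list too short for min_set_size = ", cfg$min_set_size)
  sizes <- vapply(sets, function(s) sum(ranked$gene %in% s$members), integer(1))
  keep <- sizes >= cfg$min_set_size & sizes <= cfg$max_set_size & sizes < n
  if (!any(keep))
    stop("all gene sets filtered out by matched-size window [",
         cfg$min_set_size, ", ", cfg$max_set_size, "]")
  sets <- sets[keep]; sizes <- sizes[keep]
  absw <- abs(ranked$metric)^cfg$weight_p

  set.seed(cfg$seed)
  n_sets <- length(sets)
  es <- numeric(n_sets); le <- vector("list", n_sets)
  nes <- numeric(n_sets); p_nom <- numeric(n_sets)
  null_nes <- vector("list", n_sets)

  for (i in seq_len(n_sets)) {
    hit <- ranked$gene %in% sets[[i]]$members
    pos <- which(hit)
    walk <- ks_walk(pos, absw[pos], n)
    es[i] <- walk$es
    le[[i]] <- ranked$gene[pos[walk$le_idx]]
    g <- sizes[i]
    null_es <- vapply(seq_len(cfg$n_perm), function(b) {
      p <- sort.int(sample.int(n, g))
      ks_walk(p, absw[p], n)$es
    }, numeric(1))
    pos_null <- null_es[null_es >= 0]
    neg_null <- null_es[null_es < 0]
    mean_pos <- if (length(pos_null)) mean(pos_null) else NA_real_
    mean_neg <- if (length(neg_null)) mean(abs(neg_null)) else NA_real_
    if (es[i] >= 0) {
      nes[i] <- if (is.na(mean_pos) || mean_pos == 0) NA_real_ else es[i] / mean_pos
      p_nom[i] <- (sum(pos_null >= es[i]) + 1) / (length(pos_null) + 1)
    } else {
      nes[i] <- if (is.na(mean_neg) || mean_neg == 0) NA_real_ else es[i] / mean_neg
      p_nom[i] <- (sum(neg_null <= es[i]) + 1) / (length(neg_null) + 1)
    }
    # same-sign mean-normalised null NES for the FDR pool
    null_nes[[i]] <- c(if (length(pos_null) && !is.na(mean_pos) && mean_pos > 0)
                         pos_null / mean_pos,
                       if (length(neg_null) && !is.na(mean_neg) && mean_neg > 0)
                         neg_null / mean_neg)
  }

  pool <- unlist(null_nes)
  fdr_q <- vapply(seq_len(n_sets), function(i) {
    x <- nes[i]
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      n_pool <- sum(pool >= 0)
      num <- if (n_pool) sum(pool >= x) / n_pool else 0
      n_obs <- sum(nes >= 0, na.rm = TRUE)
      den <- sum(nes >= x, na.rm = TRUE) / n_obs
    } else {
      n_pool <- sum(pool < 0)
      num <- if (n_pool) sum(pool <= x) / n_pool else 0
      n_obs <- sum(nes < 0, na.rm = TRUE)
      den <- sum(nes <= x, na.rm = TRUE) / n_obs
    }
    min(1, max(0, if (den > 0) num / den else 0))
  }, numeric(1))

  out <- data.frame(set = names(sets), size = sizes, es = es, nes = nes,
                    p_nominal = p_nom, fdr_q = fdr_q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$signed_log10_q <- sign(es) * -log10(pmax(fdr_q, 1 / (cfg$n_perm + 1)))
  out$leading_edge <- I(le)
  attr(out, "n_perm") <- cfg$n_perm
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust(method = "BH")`), with
#' input validation: every p must lie in `[0, 1]`.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Q-values in input order, each in `[p, 1]`.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Signed -log10 FDR summary
#'
#' Compresses an enrichment result to a single signed scale:
#' `sign(es) * -log10(max(fdr_q, q_floor))`, positive for enrichment among
#' up-regulated genes and negative among down-regulated genes. The default
#' floor `1 / (n_perm + 1)` is the resolution limit of the permutation FDR.
#'
#' @param res A result from [gsea_preranked()] (any data.frame with columns
#'   `es` and `fdr_q`).
#' @param q_floor Smallest representable q; defaults to `1 / (n_perm + 1)`
#'   using the `n_perm` attribute of `res`.
#' @return Numeric vector, one value per row of `res`.
#' @export
signed_log10_q <- function(res, q_floor = NULL) {
  stopifnot(all(c("es", "fdr_q") %in% names(res)))
  if (any(res$fdr_q < 0 | res$fdr_q > 1, na.rm = TRUE))
    stop("fdr_q must lie in [0, 1]")
  if (is.null(q_floor)) {
    n_perm <- attr(res, "n_perm")
    if (is.null(n_perm)) stop("q_floor not given and result carries no n_perm attribute")
    q_floor <- 1 / (n_perm + 1)
  }
  sign(res$es) * -log10(pmax(res$fdr_q, q_floor))
}
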