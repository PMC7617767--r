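#' Signature-derivation configuration
#'
#' Thresholds used when deriving target gene sets from differential-expression
#' tables. Defaults follow the derivation recipe of the source study: the top
#' 100 up-regulated genes for the broad set, FDR < 0.05 as "significant",
#' log2 fold change > 0.5 in auxiliary comparisons, FDR < 1e-5 in the ranking
#' comparison, and a final core of 5 genes. All threshold comparisons are
#' strict, matching the recipe as printed.
#'
#' @param top_n Number of genes in the broad top-up set.
#' @param alpha_sig FDR threshold defining "significant" (in (0, 1)).
#' @param aux_lfc_min Minimum log2 fold change in auxiliary comparisons
#'   (strictly exceeded).
#' @param core_fdr_max FDR threshold in the ranking comparison (in (0, 1)).
#' @param core_k Size of the high-confidence core set.
#' @return A list of class `derivation_config`.
#' @export
derivation_config <- function(top_n = 100L, alpha_sig = 0.05,
                              aux_lfc_min = 0.5, core_fdr_max = 1e-5,
                              core_k = 5L) {
  stopifnot(top_n >= 1, core_k >= 1,
            alpha_sig > 0, alpha_sig < 1,
            core_fdr_max > 0, core_fdr_max < 1)
  structure(list(top_n = as.integer(top_n), alpha_sig = alpha_sig,
                 aux_lfc_min = aux_lfc_min, core_fdr_max = core_fdr_max,
                 core_k = as.integer(core_k)),
            class = "derivation_config")
}

#' Top up-regulated genes of a comparison
#'
#' Among genes significantly up-regulated (FDR < `alpha_sig` and
#' log2FC > 0), the `top_n` ranked by descending log2 fold change (ties
#' broken by gene identifier ascending). Fold-change ranking is used rather
#' than significance ranking because downstream ranked lists are themselves
#' fold-change based.
#'
#' @param de A [de_table()].
#' @param cfg A [derivation_config()].
#' @param name Name for the resulting set.
#' @return A [gene_set()].
#' @export
derive_top_up <- function(de, cfg = derivation_config(), name = NULL) {
  stopifnot(nrow(de) > 0)
  qual <- !is.na(de$fdr) & de$fdr < cfg$alpha_sig & de$log2fc > 0
  if (!any(qual))
    stop("no gene passes FDR < ", cfg$alpha_sig, " with log2fc > 0")
  d <- de[qual, , drop = FALSE]
  d <- d[order(-d$log2fc, c_rank(d$gene)), , drop = FALSE]
  if (nrow(d) < cfg$top_n)
    warning("only ", nrow(d), " genes qualify (top_n = ", cfg$top_n, "); returning all")
  if (is.null(name))
    name <- paste0("top", cfg$top_n, "_up_", attr(de, "comparison"))
  gene_set(name, utils::head(d$gene, cfg$top_n))
}

#' Concordant up/down target genes
#'
#' Genes significantly up-regulated in the over-expression comparison
#' (FDR < `alpha_sig`, log2FC > 0 in `de_up`) and significantly
#' down-regulated in the knockdown comparison (FDR < `alpha_sig`,
#' log2FC < 0 in `de_down`).
#'
#' @param de_up,de_down [de_table()]s for the over-expression and knockdown
#'   comparisons.
#' @param cfg A [derivation_config()].
#' @param name Name for the resulting set.
#' @return A [gene_set()].
#' @export
derive_concordant <- function(de_up, de_down, cfg = derivation_config(),
                              name = "concordant_targets") {
  stopifnot(nrow(de_up) > 0, nrow(de_down) > 0)
  up <- de_up$gene[!is.na(de_up$fdr) & de_up$fdr < cfg$alpha_sig & de_up$log2fc > 0]
  dn <- de_down$gene[!is.na(de_down$fdr) & de_down$fdr < cfg$alpha_sig & de_down$log2fc < 0]
  common <- intersect(up, dn)
  if (length(common) == 0L)
    stop("no gene is concordantly up in '", attr(de_up, "comparison"),
         "' and down in '", attr(de_down, "comparison"), "'")
  gene_set(name, common)
}

#' High-confidence core target genes
#'
#' Filters the concordant set down to genes with log2 fold change strictly
#' above `aux_lfc_min` in BOTH auxiliary comparisons and FDR strictly below
#' `core_fdr_max` (with positive log2FC) in the ranking comparison, then
#' ranks survivors by the ranking-comparison log2 fold change (descending,
#' ties by identifier) and returns the top `core_k`. Genes absent from any
#' auxiliary or ranking table fail that filter (conservative), with the
#' count reported.
#'
#' @param concordant A [gene_set()] from [derive_concordant()].
#' @param aux1,aux2 Auxiliary [de_table()]s (fold-change filters).
#' @param rank_table [de_table()] supplying the significance filter and the
#'   final ranking metric.
#' @param cfg A [derivation_config()].
#' @param name Name for the resulting set.
#' @return A [gene_set()] of at most `core_k` genes.
#' @export
derive_core <- function(concordant, aux1, aux2, rank_table,
                        cfg = derivation_config(), name = "core_targets") {
  stopifnot(inherits(concordant, "gene_set"),
            nrow(aux1) > 0, nrow(aux2) > 0, nrow(rank_table) > 0)
  g <- concordant$members
  aux_pass <- function(tab, genes) {
    idx <- match(genes, tab$gene)
    ok <- !is.na(idx) & tab$log2fc[idx] > cfg$aux_lfc_min
    n_missing <- sum(is.na(idx))
    if (n_missing > 0)
      message(n_missing, " gene(s) absent from '", attr(tab, "comparison"),
              "' fail its filter")
    ok
  }
  keep <- aux_pass(aux1, g) & aux_pass(aux2, g)
  idx <- match(g, rank_table$gene)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0)
    message(n_missing, " gene(s) absent from ranking table fail its filter")
  keep <- keep & !is.na(idx) &
    !is.na(rank_table$fdr[idx]) & rank_table$fdr[idx] < cfg$core_fdr_max &
    rank_table$log2fc[idx] > 0
  survivors <- g[keep]
  if (length(survivors) == 0L)
    stop("no concordant gene survives the core filters")
  lfc <- rank_table$log2fc[match(survivors, rank_table$gene)]
  survivors <- survivors[order(-lfc, c_rank(survivors))]
  if (length(survivors) < cfg$core_k)
    warning("only ", length(survivors), " survivor(s) (core_k = ", cfg$core_k,
            "); returning all")
  gene_set(name, utils::head(survivors, cfg$core_k))
}

#' Set difference of gene sets
#'
#' Removes the members of `removed` from `base` (e.g. stripping mesenchymal
#' genes from an endothelial-enriched list).
#'
#' @param base,removed [gene_set()]s; `removed` may also be a character
#'   vector.
#' @param new_name Name of the resulting set.
#' @return A [gene_set()].
#' @export
subtract_gene_set <- function(base, removed, new_name) {
  stopifnot(inherits(base, "gene_set"))
  rem <- if (inherits(removed, "gene_set")) removed$members else as.character(removed)
  out <- setdiff(base$members, rem)
  if (length(out) == 0L)
    stop("subtraction removed every member of '", base$name, "'")
  gene_set(new_name, out)
}

#' Refine a gene set by cluster expression statistics
#'
#' Keeps genes of `base` with log2 fold change (target cluster vs background
#' cluster) strictly above `lfc_min` and expressed in strictly fewer than
#' `pct_max` percent of background-cluster cells. This is the refinement
#' that turns a broad endothelial-enriched list into a stringent set absent
#' from fibroblasts. Genes of `base` missing from `stats` are dropped with a
#' reported count.
#'
#' @param base A [gene_set()].
#' @param stats A data.frame with columns `gene`,
#'   `log2fc_target_vs_background` and `pct_expressed_background`
#'   (percent, in `[0, 100]`).
#' @param lfc_min,pct_max Strict thresholds (defaults 0.5 and 30).
#' @param new_name Name of the refined set (default: base name + "_refined").
#' @return A [gene_set()].
#' @export
refine_by_cluster_stats <- function(base, stats, lfc_min = 0.5, pct_max = 30,
                                    new_name = NULL) {
  stopifnot(inherits(base, "gene_set"),
            all(c("gene", "log2fc_target_vs_background",
                  "pct_expressed_background") %in% names(stats)))
  if (anyDuplicated(stats$gene)) stop("duplicate genes in cluster stats")
  if (any(stats$pct_expressed_background < 0 | stats$pct_expressed_background > 100))
    stop("pct_expressed_background must lie in [0, 100]")
  idx <- match(base$members, stats$gene)
  n_missing <- sum(is.na(idx))
  if (n_missing == length(base$members))
    stop("cluster stats cover no gene of '", base$name, "'")
  if (n_missing > 0)
    message(n_missing, " gene(s) of '", base$name, "' absent from cluster stats dropped")
  present <- !is.na(idx)
  keep <- present &
    stats$log2fc_target_vs_background[ifelse(present, idx, 1L)] > lfc_min &
    stats$pct_expressed_background[ifelse(present, idx, 1L)] < pct_max
  out <- base$members[keep]
  if (length(out) == 0L) stop("no gene of '", base$name, "' survives refinement")
  if (is.null(new_name)) new_name <- paste0(base$name, "_refined")
  gene_set(new_name, out)
}

#' Map a gene set through an ortholog table
#'
#' Explicit cross-species identifier mapping (e.g. mouse symbols to human
#' symbols via biomart-style annotations). Each source identifier may map to
#' several targets; the result is the union of targets of mapped members.
#' Unmapped members are counted and reported with a warning.
#'
#' @param set_in A [gene_set()].
#' @param ortholog_table A data.frame with columns `source` and `target`.
#' @param new_name Name of the mapped set (default: base name + "_mapped").
#' @return A [gene_set()].
#' @export
map_orthologs <- function(set_in, ortholog_table, new_name = NULL) {
  stopifnot(inherits(set_in, "gene_set"),
            all(c("source", "target") %in% names(ortholog_table)))
  hits <- ortholog_table[ortholog_table$source %in% set_in$members, , drop = FALSE]
  n_unmapped <- sum(!set_in$members %in% ortholog_table$source)
  if (nrow(hits) == 0L)
    stop("no member of '", set_in$name, "' has an ortholog mapping")
  if (n_unmapped > 0)
    warning(n_unmapped, " member(s) of '", set_in$name, "' unmapped and dropped")
  if (is.null(new_name)) new_name <- paste0(set_in$name, "_mapped")
  gene_set(new_name, unique(as.character(hits$target)))
}
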