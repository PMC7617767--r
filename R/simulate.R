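#' Specification for a synthetic differential-expression quartet
#'
#' Describes four DE tables emulating the comparisons behind a core-target
#' derivation: an over-expression table (targets up), a knockdown table
#' (targets down), one auxiliary fold-change comparison, and a second
#' auxiliary comparison that doubles as the ranking table. `n_core` genes
#' are planted to pass every derivation filter with margin;
#' `n_concordant_extra` genes pass concordance but fail at least one
#' downstream filter; all remaining genes are null (uniform p-values, small
#' fold changes). FDR columns are Benjamini-Hochberg adjustments of the
#' generated p-values.
#'
#' @param n_genes Total genes per table.
#' @param n_core Planted high-confidence core genes.
#' @param n_concordant_extra Concordant decoys failing a core filter.
#' @param lfc_core Ranking-table log2FC of the planted core (large).
#' @param lfc_decoy Auxiliary log2FC given to decoys failing a fold-change
#'   filter (must be below the 0.5 filter).
#' @param fdr_core Target FDR magnitude for planted core p-values.
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return A list of class `de_quartet_spec`.
#' @export
de_quartet_spec <- function(n_genes = 2000L, n_core = 5L,
                            n_concordant_extra = 45L, lfc_core = 3,
                            lfc_decoy = 0.3, fdr_core = 1e-8, seed = 0L) {
  stopifnot(n_core + n_concordant_extra < n_genes,
            lfc_core > 0.5, lfc_decoy < 0.5, lfc_decoy >= 0,
            fdr_core > 0, fdr_core < 1)
  structure(list(n_genes = as.integer(n_genes), n_core = as.integer(n_core),
                 n_concordant_extra = as.integer(n_concordant_extra),
                 lfc_core = lfc_core, lfc_decoy = lfc_decoy,
                 fdr_core = fdr_core, seed = as.integer(seed)),
            class = "de_quartet_spec")
}

#' Generate a synthetic DE quartet with planted core targets
#'
#' @param spec A [de_quartet_spec()].
#' @return A list with `tables` (named list of [de_table()]s:
#'   `overexpression`, `knockdown`, `aux1`, `aux2` -- the latter also serves
#'   as ranking table) and `truth` (list with `core` and `concordant`
#'   [gene_set()]s).
#' @export
gen_de_quartet <- function(spec = de_quartet_spec()) {
  stopifnot(inherits(spec, "de_quartet_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  i_core <- seq_len(spec$n_core)
  i_extra <- if (spec$n_concordant_extra > 0)
    spec$n_core + seq_len(spec$n_concordant_extra) else integer(0)
  planted <- c(i_core, i_extra)
  p_sig <- spec$fdr_core / n      # BH-safe: q <= p * n <= fdr_core

  null_tab <- function() {
    lfc <- stats::rnorm(n, 0, 0.2)
    p <- stats::runif(n)
    list(lfc = lfc, p = p)
  }
  finalize <- function(t, comparison) {
    de_table(genes, t$lfc, t$p, bh_fdr(t$p), comparison = comparison)
  }

  # over-expression: planted genes significantly up
  up <- null_tab()
  up$lfc[planted] <- stats::runif(length(planted), 1, 3)
  up$p[planted] <- p_sig
  # knockdown: planted genes significantly down
  dn <- null_tab()
  dn$lfc[planted] <- -stats::runif(length(planted), 1, 3)
  dn$p[planted] <- p_sig

  # decoys split across the three core filters
  fail_mode <- if (length(i_extra))
    rep_len(c("aux1", "aux2", "rank"), length(i_extra)) else character(0)

  aux1 <- null_tab()
  aux1$lfc[i_core] <- stats::runif(spec$n_core, 1, 2)
  aux1$lfc[i_extra] <- ifelse(fail_mode == "aux1", spec$lfc_decoy,
                              stats::runif(length(i_extra), 1, 2))

  aux2 <- null_tab()
  # spread core fold changes so the final ranking is well defined
  aux2$lfc[i_core] <- spec$lfc_core + 0.1 * rev(seq_len(spec$n_core))
  aux2$p[i_core] <- p_sig
  aux2$lfc[i_extra] <- ifelse(fail_mode == "aux2", spec$lfc_decoy,
                              stats::runif(length(i_extra), 1, 2))
  aux2$p[i_extra] <- ifelse(fail_mode == "rank", 0.5, p_sig)

  list(tables = list(overexpression = finalize(up, "overexpression_up"),
                     knockdown = finalize(dn, "knockdown_down"),
                     aux1 = finalize(aux1, "aux1"),
                     aux2 = finalize(aux2, "aux2_rank")),
       truth = list(core = gene_set("planted_core", genes[i_core]),
                    concordant = gene_set("planted_concordant", genes[planted])))
}

#' Specification for a synthetic expression cohort
#'
#' A genes x samples matrix with a planted correlated gene module driven by
#' a latent factor, and two balanced subtype groups ("aggressive" vs
#' "other") in which the factor mean is shifted. Module genes have unit
#' variance and within-subtype pairwise correlation approximately
#' `module_loading^2`; non-module genes are independent standard normals.
#'
#' @param n_samples,n_genes,n_module_genes Dimensions.
#' @param module_loading Latent-factor loading in (0, 1).
#' @param subtype_shift Shift (in factor SD units) of the latent factor in
#'   the aggressive subtype.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 500L, n_genes = 3000L,
                        n_module_genes = 50L, module_loading = 0.8,
                        subtype_shift = 1.0, seed = 0L) {
  stopifnot(n_module_genes < n_genes, module_loading > 0, module_loading < 1,
            n_samples >= 4)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_module_genes = as.integer(n_module_genes),
                 module_loading = module_loading,
                 subtype_shift = subtype_shift, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with a planted correlated module
#'
#' @param spec A [cohort_spec()].
#' @return A list with `matrix` (dense genes x samples, linear scale),
#'   `groups` (named character vector, `"aggressive"`/`"other"`) and
#'   `module` (ground-truth [gene_set()]).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ns <- spec$n_samples; ng <- spec$n_genes; nm <- spec$n_module_genes
  genes <- sprintf("G%05d", seq_len(ng))
  samples <- sprintf("S%04d", seq_len(ns))
  n_agg <- ns %/% 2L
  groups <- stats::setNames(rep(c("aggressive", "other"),
                                c(n_agg, ns - n_agg)), samples)
  f <- stats::rnorm(ns) + spec$subtype_shift * (groups == "aggressive")
  x <- matrix(stats::rnorm(ng * ns), nrow = ng,
              dimnames = list(genes, samples))
  lam <- spec$module_loading
  x[seq_len(nm), ] <- lam * matrix(f, nrow = nm, ncol = ns, byrow = TRUE) +
    sqrt(1 - lam^2) * x[seq_len(nm), ]
  attr(x, "value_scale") <- "linear"
  list(matrix = x, groups = groups,
       module = gene_set("planted_module", genes[seq_len(nm)]))
}

#' Specification for a synthetic single-cell dataset
#'
#' Negative-binomial counts (per-gene mean, common dispersion; dispersion is
#' the inverse of the NB size parameter) for three cell populations --
#' tumor, endothelial and fibroblast -- across replicate samples.
#' An endothelial gene signature is elevated `endo_fold`-fold in endothelial
#' cells and in a planted endothelial-like fraction of tumor cells, which
#' also co-elevate a second "TF-program" gene set (so marker-based
#' enrichment downstream has planted signal). Mitochondrial genes are
#' planted and per-cell `mito_pct` is computed exactly from their counts; a
#' CellTag marker gene is detected in tumor cells with fixed probability.
#' QC-violator cells are planted among non-endothelial-like tumor cells,
#' each failing exactly one QC rule, so filter reports are exactly
#' predictable.
#'
#' @param n_genes Universe size (must exceed the 9000-feature QC bound so
#'   the high-feature violator is constructible).
#' @param n_tumor,n_endothelial,n_fibroblast Cells per population.
#' @param endo_like_frac Fraction of tumor cells planted endothelial-like.
#' @param endo_set_size,program_set_size Planted signature sizes.
#' @param endo_fold Mean multiplier on endothelial genes in endothelial and
#'   endothelial-like tumor cells.
#' @param program_fold Mean multiplier on program genes in endothelial-like
#'   tumor cells.
#' @param dispersion NB dispersion (inverse size).
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline gene
#'   means.
#' @param n_mito Planted mitochondrial genes.
#' @param mito_mean_factor Mean multiplier for mitochondrial genes (they are
#'   highly expressed housekeeping genes).
#' @param celltag_detection Detection probability of the CellTag marker in
#'   tumor cells.
#' @param n_samples Replicate samples (cells split evenly).
#' @param qc_violators Named integer vector: planted violator cells per rule
#'   (`low_features`, `high_features`, `high_mito`).
#' @param seed Integer seed.
#' @return A list of class `sc_spec`.
#' @export
sc_spec <- function(n_genes = 10000L, n_tumor = 1500L, n_endothelial = 300L,
                    n_fibroblast = 300L, endo_like_frac = 0.05,
                    endo_set_size = 100L, program_set_size = 50L,
                    endo_fold = 4, program_fold = 3, dispersion = 0.5,
                    base_meanlog = log(0.2), base_sdlog = 1,
                    n_mito = 10L, mito_mean_factor = 20,
                    celltag_detection = 0.6, n_samples = 2L,
                    qc_violators = c(low_features = 3L, high_features = 3L,
                                     high_mito = 3L),
                    seed = 0L) {
  stopifnot(endo_like_frac > 0, endo_like_frac < 1,
            celltag_detection > 0, celltag_detection <= 1,
            dispersion > 0, endo_fold > 1, program_fold > 1,
            n_genes > 9000,
            all(c("low_features", "high_features", "high_mito") %in%
                  names(qc_violators)))
  structure(list(n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
                 n_endothelial = as.integer(n_endothelial),
                 n_fibroblast = as.integer(n_fibroblast),
                 endo_like_frac = endo_like_frac,
                 endo_set_size = as.integer(endo_set_size),
                 program_set_size = as.integer(program_set_size),
                 endo_fold = endo_fold, program_fold = program_fold,
                 dispersion = dispersion, base_meanlog = base_meanlog,
                 base_sdlog = base_sdlog, n_mito = as.integer(n_mito),
                 mito_mean_factor = mito_mean_factor,
                 celltag_detection = celltag_detection,
                 n_samples = as.integer(n_samples),
                 qc_violators = vapply(qc_violators, as.integer, integer(1)),
                 seed = as.integer(seed)),
            class = "sc_spec")
}

#' Generate a synthetic single-cell dataset with a planted
#' endothelial-like tumor subpopulation
#'
#' @param spec An [sc_spec()].
#' @return A list with `counts` (sparse genes x cells `dgCMatrix`),
#'   `annotation` (cell annotation data.frame with `cell`, `sample`,
#'   `cluster`, `n_features`, `mito_pct`, `celltag_positive`) and `truth`
#'   (list: `cell_type` named vector incl. `"tumor_endo_like"`,
#'   `endo_like_cells`, `qc_violators` named by rule, `endo_set`,
#'   `program_set` [gene_set()]s, `mito_genes`, `celltag_gene`).
#' @export
gen_sc_dataset <- function(spec = sc_spec()) {
  stopifnot(inherits(spec, "sc_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  size <- 1 / spec$dispersion

  # gene universe: mito genes, CellTag marker, then regular genes
  genes <- sprintf("Gene%05d", seq_len(ng))
  i_mito <- seq_len(spec$n_mito)
  genes[i_mito] <- sprintf("mt-Gene%02d", seq_len(spec$n_mito))
  i_celltag <- spec$n_mito + 1L
  genes[i_celltag] <- "CellTag"
  i_endo <- i_celltag + seq_len(spec$endo_set_size)
  i_prog <- i_celltag + spec$endo_set_size + seq_len(spec$program_set_size)

  base_mu <- stats::rlnorm(ng, spec$base_meanlog, spec$base_sdlog)
  base_mu[i_mito] <- base_mu[i_mito] * spec$mito_mean_factor
  base_mu[i_celltag] <- 0   # CellTag counts are drawn separately

  n_cells <- spec$n_tumor + spec$n_endothelial + spec$n_fibroblast
  cells <- sprintf("Cell%05d", seq_len(n_cells))
  cell_type <- rep(c("tumor", "endothelial", "fibroblast"),
                   c(spec$n_tumor, spec$n_endothelial, spec$n_fibroblast))
  n_endo_like <- as.integer(round(spec$endo_like_frac * spec$n_tumor))
  n_viol <- sum(spec$qc_violators)
  stopifnot(n_endo_like + n_viol <= spec$n_tumor)
  # endo-like tumor cells and QC violators are disjoint tumor cells
  i_endo_like <- seq_len(n_endo_like)                       # within tumor block
  i_viol <- n_endo_like + seq_len(n_viol)
  viol_rule <- rep(names(spec$qc_violators), spec$qc_violators)
  cell_type[i_endo_like] <- "tumor_endo_like"

  # per-cell mean profiles
  mu_for_cell <- function(ct, rule) {
    mu <- base_mu
    if (ct %in% c("endothelial", "tumor_endo_like"))
      mu[i_endo] <- mu[i_endo] * spec$endo_fold
    if (ct == "tumor_endo_like")
      mu[i_prog] <- mu[i_prog] * spec$program_fold
    if (!is.na(rule)) {
      if (rule == "low_features") mu <- mu * 0.005
      if (rule == "high_mito") mu[i_mito] <- mu[i_mito] * 15
    }
    mu
  }
  rule_of_cell <- rep(NA_character_, n_cells)
  rule_of_cell[i_viol] <- viol_rule

  # draw counts in blocks of identical profiles to keep this fast
  profile_key <- paste(cell_type, ifelse(is.na(rule_of_cell), "", rule_of_cell))
  counts_cols <- vector("list", n_cells)
  for (key in unique(profile_key)) {
    idx <- which(profile_key == key)
    mu <- mu_for_cell(cell_type[idx[1]], rule_of_cell[idx[1]])
    block <- matrix(stats::rnbinom(ng * length(idx), mu = mu, size = size),
                    nrow = ng)
    if (rule_of_cell[idx[1]] %in% "high_features") {
      # force > 9000 detected features without disturbing mito fractions much
      for (j in seq_along(idx)) {
        extra <- sample.int(ng, 9300L)
        block[extra, j] <- block[extra, j] + 1L
      }
    }
    for (j in seq_along(idx)) counts_cols[[idx[j]]] <- block[, j]
  }
  counts <- do.call(cbind, counts_cols)
  dimnames(counts) <- list(genes, cells)

  # CellTag marker: detected in tumor-lineage cells with fixed probability
  is_tumor_lineage <- cell_type %in% c("tumor", "tumor_endo_like")
  tag_detect <- is_tumor_lineage &
    stats::runif(n_cells) < spec$celltag_detection
  counts[i_celltag, tag_detect] <- 1L + stats::rpois(sum(tag_detect), 2)

  ann <- data.frame(
    cell = cells,
    sample = rep_len(sprintf("S%d", seq_len(spec$n_samples)), n_cells),
    cluster = ifelse(is_tumor_lineage, "tumor", cell_type),
    n_features = unname(colSums(counts > 0)),
    mito_pct = unname(100 * colSums(counts[i_mito, , drop = FALSE]) / colSums(counts)),
    celltag_positive = unname(counts[i_celltag, ] > 0),
    stringsAsFactors = FALSE
  )
  rownames(ann) <- NULL

  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  list(counts = counts, annotation = ann,
       truth = list(
         cell_type = stats::setNames(cell_type, cells),
         endo_like_cells = cells[i_endo_like],
         qc_violators = stats::setNames(cells[i_viol], viol_rule),
         endo_set = gene_set("planted_endo_set", genes[i_endo]),
         program_set = gene_set("planted_program_set", genes[i_prog]),
         mito_genes = genes[i_mito],
         celltag_gene = genes[i_celltag]))
}
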