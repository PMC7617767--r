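# module-level checks of the generators; the heavier end-to-end recoveries
# live in test-acceptance.R

small_sc_spec <- function(seed = 0L) {
  sc_spec(n_genes = 9500L, n_tumor = 300L, n_endothelial = 60L,
          n_fibroblast = 60L, endo_set_size = 50L, program_set_size = 25L,
          qc_violators = c(low_features = 1L, high_features = 1L,
                           high_mito = 1L),
          seed = seed)
}

test_that("generators are pure functions of spec and seed", {
  q1 <- gen_de_quartet(de_quartet_spec(n_genes = 300L, seed = 4))
  q2 <- gen_de_quartet(de_quartet_spec(n_genes = 300L, seed = 4))
  expect_identical(q1, q2)
  q3 <- gen_de_quartet(de_quartet_spec(n_genes = 300L, seed = 5))
  expect_false(identical(q1$tables$overexpression, q3$tables$overexpression))

  c1 <- gen_cohort(cohort_spec(n_samples = 40L, n_genes = 200L,
                               n_module_genes = 10L, seed = 4))
  c2 <- gen_cohort(cohort_spec(n_samples = 40L, n_genes = 200L,
                               n_module_genes = 10L, seed = 4))
  expect_identical(c1, c2)

  s1 <- gen_sc_dataset(small_sc_spec(seed = 2))
  s2 <- gen_sc_dataset(small_sc_spec(seed = 2))
  expect_identical(s1$annotation, s2$annotation)
  expect_true(all(s1$counts == s2$counts))
})

test_that("DE quartet plants exactly the advertised structure", {
  spec <- de_quartet_spec(n_genes = 500L, n_core = 4L,
                          n_concordant_extra = 12L, seed = 6)
  q <- gen_de_quartet(spec)
  expect_length(q$truth$core$members, 4)
  expect_length(q$truth$concordant$members, 16)
  expect_true(all(q$truth$core$members %in% q$truth$concordant$members))
  for (tab in q$tables) {
    expect_identical(nrow(tab), 500L)
    expect_false(anyDuplicated(tab$gene) > 0)
    expect_true(all(tab$fdr >= tab$pvalue - 1e-15))
  }
  # planted genes carry the concordant sign pattern
  up <- q$tables$overexpression; dn <- q$tables$knockdown
  pl <- q$truth$concordant$members
  expect_true(all(up$log2fc[match(pl, up$gene)] > 0))
  expect_true(all(dn$log2fc[match(pl, dn$gene)] < 0))
  expect_true(all(up$fdr[match(pl, up$gene)] < 0.05))
})

test_that("cohort generator plants the stated correlation structure", {
  co <- gen_cohort(cohort_spec(seed = 9))
  expect_equal(dim(co$matrix), c(3000, 500))
  agg <- names(co$groups)[co$groups == "aggressive"]
  cm <- cor(t(co$matrix[co$module$members, agg]))
  mean_pair <- mean(cm[upper.tri(cm)])
  expect_equal(mean_pair, 0.8^2, tolerance = 0.05)
  # non-module genes are uncorrelated with the module score
  z <- suppressWarnings(zscore_genes(co$matrix))
  score <- mean_z_signature_score(z, co$module)$score
  others <- setdiff(rownames(co$matrix), co$module$members)[1:200]
  cc <- as.numeric(cor(t(co$matrix[others, ]), score))
  expect_lt(abs(mean(cc)), 0.05)
  # aggressive subtype carries the planted module shift
  sig <- mean_z_signature_score(z, co$module)
  grp_means <- tapply(sig$score, co$groups[sig$sample], mean)
  expect_gt(grp_means[["aggressive"]], grp_means[["other"]])
})

test_that("single-cell generator annotation is consistent with its counts", {
  sim <- gen_sc_dataset(small_sc_spec())
  counts <- sim$counts; ann <- sim$annotation
  expect_identical(ncol(counts), 420L)
  expect_identical(ann$cell, colnames(counts))
  # mito_pct is exactly the planted mito-gene share of each cell's counts
  mito <- sim$truth$mito_genes
  expect_equal(ann$mito_pct,
               unname(100 * Matrix::colSums(counts[mito, ]) / Matrix::colSums(counts)))
  expect_equal(ann$n_features, unname(Matrix::colSums(counts > 0)))
  # CellTag flag matches the marker gene and only tumor-lineage cells carry it
  expect_equal(ann$celltag_positive,
               unname(counts[sim$truth$celltag_gene, ] > 0))
  tagged <- ann$cell[ann$celltag_positive]
  expect_true(all(sim$truth$cell_type[tagged] %in% c("tumor", "tumor_endo_like")))
})

test_that("planted QC violators are exactly the cells QC removes", {
  sim <- gen_sc_dataset(small_sc_spec(seed = 1))
  suppressMessages(f <- qc_filter(sim$counts, sim$annotation))
  removed <- setdiff(colnames(sim$counts), colnames(f$counts))
  expect_setequal(removed, sim$truth$qc_violators)
  cfg <- sc_config()
  ann <- sim$annotation
  viol <- sim$truth$qc_violators
  # each violator fails exactly the rule it was planted for
  expect_lt(ann$n_features[ann$cell == viol[["low_features"]]], cfg$min_features)
  expect_gt(ann$n_features[ann$cell == viol[["high_features"]]], cfg$max_features)
  expect_gte(ann$mito_pct[ann$cell == viol[["high_mito"]]], cfg$max_mito_pct)
  expect_lt(ann$mito_pct[ann$cell == viol[["low_features"]]], cfg$max_mito_pct)
})
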