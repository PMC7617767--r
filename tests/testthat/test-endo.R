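# small deterministic dataset used across the pipeline tests
qc_fixture <- function() {
  set.seed(13)
  counts <- matrix(rpois(10 * 5, 4), nrow = 10,
                   dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:5)))
  ann <- data.frame(cell = colnames(counts), sample = "S1", cluster = "t",
                    n_features = c(150L, 200L, 5000L, 9000L, 9500L),
                    mito_pct = c(1, 12, 5, 5, 5),
                    celltag_positive = TRUE, stringsAsFactors = FALSE)
  list(counts = counts, ann = ann)
}

test_that("QC filtering applies the feature-count and mito rules by hand", {
  fx <- qc_fixture()
  cfg <- sc_config(min_cells_per_feature = 1)
  suppressMessages(out <- qc_filter(fx$counts, fx$ann, cfg))
  # c1 too few features, c2 mito 12 >= 10, c5 too many features
  expect_identical(colnames(out$counts), c("c3", "c4"))
  expect_identical(out$annotation$cell, c("c3", "c4"))

  # idempotent: a second pass changes nothing
  suppressMessages(out2 <- qc_filter(out$counts, out$annotation, cfg))
  expect_identical(as.matrix(out2$counts), as.matrix(out$counts))

  # boundary: detected in exactly min_cells_per_feature cells is kept
  cts <- matrix(0L, nrow = 2, ncol = 5,
                dimnames = list(c("gA", "gB"), sprintf("c%d", 1:5)))
  cts["gA", 1:5] <- 1L
  ann <- data.frame(cell = colnames(cts), sample = "S1", cluster = "t",
                    n_features = 300L, mito_pct = 1, celltag_positive = TRUE)
  suppressMessages(kept <- qc_filter(cts, ann, sc_config(min_cells_per_feature = 5,
                                                         min_features = 1)))
  expect_identical(rownames(kept$counts), "gA")  # gB all zeros dropped
})

test_that("log-normalisation is compositional and zero-preserving", {
  counts <- Matrix::Matrix(matrix(c(0, 10, 5, 5), nrow = 2,
                                  dimnames = list(c("g1", "g2"), c("c1", "c2"))),
                           sparse = TRUE)
  cfg <- sc_config(norm_scale = 100)
  e <- lognormalize(counts, cfg)
  expect_equal(e["g1", "c1"], 0)
  expect_equal(e["g2", "c1"], log(1 + 100))
  doubled <- lognormalize(counts * 2, cfg)
  expect_equal(as.matrix(doubled), as.matrix(e))

  zero <- counts; zero[, 1] <- 0
  expect_error(lognormalize(methods::as(zero, "CsparseMatrix"), cfg), "c1")
})

test_that("tumor clusters are called by the strict CellTag fraction rule", {
  ann <- data.frame(cell = sprintf("c%02d", 1:30),
                    cluster = rep(c("k1", "k2", "k3"), each = 10),
                    celltag_positive = c(rep(TRUE, 3), rep(FALSE, 7),    # 30%
                                         rep(TRUE, 2), rep(FALSE, 8),    # 20%
                                         rep(FALSE, 10)))                # 0%
  out <- classify_tumor_clusters(ann)
  expect_identical(out[["k1"]], "tumor")
  expect_identical(out[["k2"]], "non_tumor")  # 20% exactly fails strict >
  expect_identical(out[["k3"]], "non_tumor")
})

test_that("endo-high selection takes the ceiling top fraction with id ties", {
  sc <- cell_score(sprintf("c%03d", 1:100), (1:100) / 100, 10, "endo", 5)
  out <- classify_endo_high(sc)
  expect_setequal(names(out$labels)[out$labels == "endo_high"],
                  sprintf("c%03d", 96:100))
  expect_equal(out$threshold, 0.96)

  sc20 <- cell_score(sprintf("c%02d", 1:20), (1:20) / 20, 5, "endo", 5)
  out20 <- classify_endo_high(sc20)
  expect_identical(sum(out20$labels == "endo_high"), 1L)  # ceiling(0.05*20)

  flat <- cell_score(sprintf("c%02d", 1:40), rep(0.5, 40), 5, "endo", 5)
  expect_warning(tied <- classify_endo_high(flat), "tie")
  expect_identical(names(tied$labels)[tied$labels == "endo_high"],
                   c("c01", "c02"))

  within <- sprintf("c%03d", 1:40)
  outw <- classify_endo_high(sc, within = within)
  expect_identical(sum(outw$labels == "endo_high"), 2L)
  expect_true(all(names(outw$labels) %in% within))
})

test_that("fraction above cutoff counts strictly and is monotone in cutoff", {
  sc <- cell_score(c("a", "b", "c"), c(0.1, 0.2, 0.3), 5, "endo", 5)
  ann <- data.frame(cell = c("a", "b", "c"), sample = "S1", cluster = "t",
                    n_features = 300L, mito_pct = 1, celltag_positive = TRUE)
  expect_equal(fraction_above_cutoff(sc, ann, 0.15)$fraction, 2 / 3)
  expect_equal(fraction_above_cutoff(sc, ann, 1)$fraction, 0)
  cuts <- seq(0, 1, by = 0.05)
  fr <- vapply(cuts, function(ct) fraction_above_cutoff(sc, ann, ct)$fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("marker ranking uses linearised mean ratios and is antisymmetric", {
  # two genes: one elevated in group A, one flat
  rate_a <- 3; rate_b <- 1
  expr <- rbind(up = log1p(c(rep(rate_a, 10), rep(rate_b, 10))),
                flat = log1p(rep(2, 20)))
  colnames(expr) <- sprintf("c%02d", 1:20)
  labels <- setNames(rep(c("endo_high", "rest"), each = 10), colnames(expr))
  mk <- rank_markers(expr, labels, pseudocount_rate = 1)
  expect_equal(mk$metric[mk$gene == "up"], log2(4 / 2))
  expect_equal(mk$metric[mk$gene == "flat"], 0)
  expect_gte(mk$pvalue[mk$gene == "flat"], 0.99)

  swapped <- setNames(ifelse(labels == "endo_high", "rest", "endo_high"),
                      names(labels))
  mk2 <- rank_markers(expr, swapped, pseudocount_rate = 1)
  expect_equal(mk2$metric[match(mk$gene, mk2$gene)], -mk$metric)
  expect_error(rank_markers(expr, setNames(rep("rest", 20), colnames(expr))),
               "no endo_high")
})

test_that("pseudo-bulk aggregation sums per sample and conserves counts", {
  counts <- toy_counts(6, 4)
  ann <- data.frame(cell = colnames(counts),
                    sample = c("S1", "S1", "S2", "S2"),
                    cluster = c("t", "t", "t", "other"),
                    n_features = 300L, mito_pct = 1, celltag_positive = TRUE)
  pb <- pseudo_bulk(counts, ann, "t")
  expect_equal(pb[, "S1"], counts[, "c01"] + counts[, "c02"])
  expect_equal(pb[, "S2"], counts[, "c03"])
  expect_equal(sum(pb), sum(counts[, 1:3]))  # exact conservation
  expect_error(pseudo_bulk(counts, ann, "ghost"), "no cells")
})
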