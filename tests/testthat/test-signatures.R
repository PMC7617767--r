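cfg <- derivation_config()

make_de <- function(gene, log2fc, fdr, p = fdr, comparison = "cmp") {
  de_table(gene, log2fc, p, fdr, comparison = comparison)
}

test_that("derive_top_up ranks significant up-regulated genes by fold change", {
  de <- make_de(c("A", "B", "C", "D"), c(2, 1, 3, 5), c(0.01, 0.01, 0.01, 0.5))
  top2 <- derive_top_up(de, derivation_config(top_n = 2))
  expect_setequal(top2$members, c("C", "A"))  # lfc 3 and 2; D not significant

  expect_warning(all3 <- derive_top_up(de, derivation_config(top_n = 10)),
                 "only 3")
  expect_length(all3$members, 3)

  de_ns <- make_de(c("A", "B"), c(1, 2), c(0.5, 0.9))
  expect_error(derive_top_up(de_ns, cfg), "no gene passes")
})

test_that("derive_concordant requires significance and opposite signs", {
  up <- make_de(c("G", "H", "K"), c(2, 1, 1), c(0.01, 0.01, 0.01))
  dn <- make_de(c("G", "H", "K"), c(-1, 1, -1), c(0.01, 0.01, 0.2))
  out <- derive_concordant(up, dn, cfg)
  expect_identical(out$members, "G")  # H wrong sign, K not significant down

  dn_all_up <- make_de("G", 1, 0.01)
  expect_error(derive_concordant(up, dn_all_up, cfg), "no gene")
})

test_that("derive_core applies strict auxiliary and ranking filters", {
  conc <- gene_set("conc", sprintf("g%d", 1:8))
  aux_ok <- make_de(sprintf("g%d", 1:8), rep(1, 8), rep(0.5, 8))
  # g7 fails aux1 at the boundary (0.5 exactly); g8 absent from aux2
  aux1 <- make_de(sprintf("g%d", 1:8), c(rep(1, 6), 0.5, 1), rep(0.5, 8))
  aux2 <- make_de(sprintf("g%d", 1:7), rep(1, 7), rep(0.5, 7))
  rank_tab <- make_de(sprintf("g%d", 1:8), c(5, 4, 3, 2, 1.5, 1, 9, 9),
                      rep(1e-8, 8))
  expect_message(core <- derive_core(conc, aux1, aux2, rank_tab,
                                     derivation_config(core_k = 5)),
                 "absent")
  expect_identical(core$members, c("g1", "g2", "g3", "g4", "g5"))

  # fewer survivors than core_k is a warning, not an error
  expect_warning(expect_message(
    small <- derive_core(gene_set("c", c("g1", "g2", "g8")), aux1, aux2,
                         rank_tab, derivation_config(core_k = 5))),
    "survivor")
  expect_setequal(small$members, c("g1", "g2"))
})

test_that("core derivation nests inside concordance and is monotone in its thresholds", {
  q <- gen_de_quartet(de_quartet_spec(seed = 3))
  conc <- derive_concordant(q$tables$overexpression, q$tables$knockdown, cfg)
  core <- suppressMessages(derive_core(conc, q$tables$aux1, q$tables$aux2,
                                       q$tables$aux2, cfg))
  expect_true(all(core$members %in% conc$members))

  loose <- derive_concordant(q$tables$overexpression, q$tables$knockdown,
                             derivation_config(alpha_sig = 0.2))
  expect_true(all(conc$members %in% loose$members))

  bigger <- suppressMessages(suppressWarnings(
    derive_core(conc, q$tables$aux1, q$tables$aux2, q$tables$aux2,
                derivation_config(core_k = 10))))
  expect_true(all(core$members %in% bigger$members))
})

test_that("set subtraction and cluster-stat refinement apply strict rules", {
  expect_setequal(subtract_gene_set(gene_set("s", c("A", "B", "C")),
                                    gene_set("r", "B"), "d")$members, c("A", "C"))
  expect_error(subtract_gene_set(gene_set("s", "A"), gene_set("r", "A"), "d"),
               "every member")

  stats <- data.frame(gene = c("A", "B", "C", "D"),
                      log2fc_target_vs_background = c(0.8, 0.8, 0.5, 2),
                      pct_expressed_background = c(10, 30, 5, 5))
  base <- gene_set("endo", c("A", "B", "C", "D", "E"))
  expect_message(ref <- refine_by_cluster_stats(base, stats), "absent")
  # B fails pct (30 not < 30), C fails lfc (0.5 not > 0.5), E missing
  expect_setequal(ref$members, c("A", "D"))
})

test_that("ortholog mapping unions targets and reports unmapped members", {
  tab <- data.frame(source = c("Foxc2", "Pecam1", "Pecam1"),
                    target = c("FOXC2", "PECAM1", "PECAM1B"))
  out <- map_orthologs(gene_set("m", c("Foxc2", "Pecam1")), tab)
  expect_setequal(out$members, c("FOXC2", "PECAM1", "PECAM1B"))

  expect_warning(out2 <- map_orthologs(gene_set("m", c("Foxc2", "Xyz1")), tab),
                 "1 member")
  expect_identical(out2$members, "FOXC2")
  expect_error(map_orthologs(gene_set("m", "Qqq"), tab), "no member")
})
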