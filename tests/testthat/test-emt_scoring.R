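test_that("relative fold change follows the (x - ref) / ref formula", {
  expect_equal(relative_fold_change(15, 10), 0.5)
  expect_equal(relative_fold_change(10, 10), 0)
  expect_equal(relative_fold_change(0, 10), -1)
  expect_error(relative_fold_change(5, 0), "positive")
})

test_that("fold_change_table drops zero-reference genes and reports them", {
  expr <- rbind(g1 = c(20, 10, 10), g2 = c(5, 10, 10), g3 = c(7, 0, 0))
  colnames(expr) <- c("case_1", "control_1", "control_2")
  fc <- fold_change_table(expr, "case_1", c("control_1", "control_2"))
  expect_equal(fc$fold_change[fc$gene == "g1"], 1)
  expect_equal(fc$fold_change[fc$gene == "g2"], -0.5)
  expect_identical(attr(fc, "dropped"), "g3")
})

test_that("DEG filtering applies strict thresholds on both criteria", {
  expect_equal(nrow(filter_degs(
    data.frame(gene = "a", fold_change = 1.2, adjusted_p = 0.005),
    p_cut = 0.01, fc_cut = 1)), 1)
  # boundary fold change of exactly 1 is dropped under the strict rule
  expect_equal(nrow(filter_degs(
    data.frame(gene = "a", fold_change = 1.0, adjusted_p = 0.001),
    p_cut = 0.01, fc_cut = 1)), 0)

  # six-gene table at the 0.5 cutoff, survivors enumerated by hand:
  # a (fc 0.6, p 0.001) keep; b (fc -0.7, p 0.005) keep;
  # c (fc 0.5, p 0.001) drop (|fc| not > 0.5); d (fc 2, p 0.01) drop (p not < 0.01);
  # e (fc 0.2, p 0.0001) drop; f (fc -3, p NA) drop (missing p)
  tab <- data.frame(
    gene = letters[1:6],
    fold_change = c(0.6, -0.7, 0.5, 2, 0.2, -3),
    adjusted_p = c(0.001, 0.005, 0.001, 0.01, 0.0001, NA)
  )
  kept <- filter_degs(tab, p_cut = 0.01, fc_cut = 0.5)
  expect_identical(kept$gene, c("a", "b"))
  expect_equal(attr(kept, "n_missing_p"), 1)

  # output is a subset of input and filtering is idempotent
  again <- filter_degs(kept, p_cut = 0.01, fc_cut = 0.5)
  expect_identical(again$gene, kept$gene)
  expect_error(filter_degs(tab, p_cut = 0, fc_cut = 1), "p_cut")
})

test_that("EMT trajectory score follows the epithelial-subtracted formula", {
  fc <- c(E1 = 0.2, E2 = 0.4, H1 = 0.5, H2 = 0.7, M1 = 1.0)
  sets <- list(epithelial = c("E1", "E2"), hEMT = c("H1", "H2"),
               mesenchymal = "M1")
  sc <- emt_trajectory_score(fc, sets)
  expect_equal(sc$epithelial, 0.3)
  expect_equal(sc$hEMT, 0.3)
  expect_equal(sc$mesenchymal, 0.7)
  expect_equal(unname(sc$n_genes_used), c(2L, 2L, 1L))

  # all-zero fold changes give all-zero scores
  sc0 <- emt_trajectory_score(setNames(rep(0, 5), names(fc)), sets)
  expect_equal(c(sc0$epithelial, sc0$hEMT, sc0$mesenchymal), c(0, 0, 0))
})

test_that("trajectory score ignores gene order and out-of-set genes", {
  fc <- c(E1 = 0.2, E2 = 0.4, H1 = 0.5, H2 = 0.7, M1 = 1.0,
          X1 = 50, X2 = -50)
  sets <- list(epithelial = c("E1", "E2"), hEMT = c("H1", "H2"),
               mesenchymal = "M1")
  sc <- emt_trajectory_score(fc, sets)
  sc_perm <- emt_trajectory_score(fc[sample(names(fc))], sets)
  expect_equal(sc[1:3], sc_perm[1:3])
  expect_equal(sc$mesenchymal, 0.7)

  # shifting every fold change by a constant moves only the epithelial score
  shift <- emt_trajectory_score(fc + 2, sets)
  expect_equal(shift$epithelial, sc$epithelial + 2)
  expect_equal(shift$hEMT, sc$hEMT)
  expect_equal(shift$mesenchymal, sc$mesenchymal)

  # a category with no gene present is flagged, not imputed
  sc_na <- emt_trajectory_score(fc[c("E1", "E2", "H1")],
                                list(epithelial = c("E1", "E2"),
                                     hEMT = "H1", mesenchymal = "M1"))
  expect_true(is.na(sc_na$mesenchymal))
  expect_match(sc_na$flags, "mesenchymal")
})

test_that("IL6 category score is the summed case-minus-control difference", {
  genes <- paste0("g", 1:6)
  case <- matrix(100, 6, 3, dimnames = list(genes, NULL))
  control <- case
  sets <- list(`motility/adhesion` = genes[1:5], inflammation = genes[6])
  sc <- il6_gene_score(case, control, sets)
  expect_equal(unname(sc$scores), c(0, 0))

  # doubling five motility genes (means 100 -> 200) adds 5 x 100
  case2 <- case
  case2[1:5, ] <- 200
  sc2 <- il6_gene_score(case2, control, sets)
  expect_equal(unname(sc2$scores[["motility/adhesion"]]), 500)
  expect_equal(unname(sc2$scores[["inflammation"]]), 0)
  expect_equal(unname(sc2$n_genes_used["motility/adhesion"]), 5L)

  sc3 <- il6_gene_score(case, control, list(empty_cat = "absent_gene"))
  expect_true(is.na(sc3$scores[["empty_cat"]]))
})

test_that("planted mesenchymal upshift yields a positive mesenchymal score", {
  sets <- example_emt_gene_sets()
  sim <- simulate_expression(300, 6, 20, gene_sets = sets,
                             effects = list(mesenchymal = 3),
                             base_mean = 100, dispersion = 0.05, seed = 77)
  fc <- fold_change_table(sim$matrix,
                          grep("^case_", colnames(sim$matrix)),
                          grep("^control_", colnames(sim$matrix)))
  sc <- emt_trajectory_score(fc, sets)
  expect_gt(sc$mesenchymal, 0)
  expect_gt(sc$mesenchymal, sc$epithelial)
})
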