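test_that("cosine similarity matches hand computations", {
  v <- runif(96)
  expect_equal(cosine_similarity(v, v), 1)
  a <- c(1, 1, rep(0, 94))
  b <- c(1, 0, rep(0, 94))
  expect_equal(cosine_similarity(a, b), 1 / sqrt(2))
  expect_equal(cosine_similarity(a, c(0, 0, 1, rep(0, 93))), 0)
  expect_error(cosine_similarity(a, rep(0, 96)), "zero vector")
})

test_that("refitting a pure signature recovers it with near-zero residual", {
  ref <- reference_signatures()
  cm <- matrix(100 * ref[, "SBS2"], ncol = 1,
               dimnames = list(rownames(ref), "s1"))
  fit <- fit_exposures(cm, ref)
  expect_equal(unname(fit$relative["SBS2", "s1"]), 1, tolerance = 1e-8)
  expect_lt(fit$reconstruction_residual[["s1"]], 1e-8)
  expect_equal(unname(fit$cosine_to_data[["s1"]]), 1, tolerance = 1e-8)
})

test_that("refitting disjoint-support mixtures agrees with the simplex grid oracle", {
  toy <- disjoint_toy_signatures()
  cm <- matrix(60 * toy[, "sigA"] + 40 * toy[, "sigB"], ncol = 1,
               dimnames = list(rownames(toy), "s1"))
  fit <- fit_exposures(cm, toy)
  expect_equal(unname(fit$relative[, "s1"]), c(0.6, 0.4), tolerance = 1e-9)
  oracle <- grid_refit(cm[, 1], toy, step = 1e-3)
  expect_equal(unname(fit$relative[, "s1"]), unname(oracle),
               tolerance = 2e-3)
})

test_that("degenerate refit inputs are handled", {
  ref <- reference_signatures()
  expect_error(fit_exposures(matrix(1, 96, 1), ref[, 0]), "at least one")
  cm <- matrix(0, 96, 1, dimnames = list(rownames(ref), "empty"))
  fit <- fit_exposures(cm, ref)
  expect_true(all(fit$absolute == 0))
  expect_true(all(is.na(fit$relative)))
  expect_true(is.na(fit$cosine_to_data[["empty"]]))
})

test_that("relative contributions sum the requested subset", {
  rel <- matrix(c(0.10, 0.10, 0.80), ncol = 1,
                dimnames = list(c("SBS2", "SBS13", "SBS5"), "s1"))
  exposures <- structure(list(relative = rel), class = "exposure_result")
  expect_equal(unname(relative_contribution(exposures, c("SBS2", "SBS13"))),
               0.2)
  expect_equal(unname(relative_contribution(exposures,
                                            c("SBS2", "SBS13", "SBS5"))), 1)
  expect_equal(unname(apobec_fraction(exposures)), 0.2)
  expect_error(relative_contribution(exposures, "SBS99"), "unknown")
})

test_that("exposures are scale-equivariant and relative fractions scale-invariant", {
  ref <- reference_signatures()
  set.seed(5)
  w <- c(0.2, 0.1, 0.3, 0.3, 0.1)
  cm <- matrix(5000 * as.vector(ref %*% w), ncol = 1,
               dimnames = list(rownames(ref), "s1"))
  fit1 <- fit_exposures(cm, ref)
  fit3 <- fit_exposures(cm * 3, ref)
  expect_equal(fit3$absolute, fit1$absolute * 3, tolerance = 1e-6)
  expect_equal(fit3$relative, fit1$relative, tolerance = 1e-8)
})

test_that("adding signatures never worsens the refit residual", {
  ref <- reference_signatures()
  set.seed(8)
  counts <- as.vector(stats::rmultinom(1, 3000, ref %*% rep(0.2, 5)))
  cm <- matrix(counts, ncol = 1, dimnames = list(rownames(ref), "s1"))
  full <- fit_exposures(cm, ref)$reconstruction_residual[["s1"]]
  singles <- vapply(colnames(ref), function(nm) {
    fit_exposures(cm, ref[, nm, drop = FALSE])$reconstruction_residual[["s1"]]
  }, numeric(1))
  expect_lte(full, min(singles) + 1e-12)
})

test_that("rank-1 KL-NMF recovers the pooled normalized spectrum", {
  ref <- shared_test_reference()
  v <- sample_variants(ref, reference_signatures()[, "SBS2"], 3000, seed = 2)
  cm <- build_catalog(v[, 1:5], ref)
  res <- suppressWarnings(nmf_extract(cm, 1, n_restarts = 2,
                                      max_iter = 500, seed = 4))
  pooled <- rowSums(cm) / sum(cm)
  expect_gt(cosine_similarity(res$signatures[, 1], pooled), 0.9999)
  expect_equal(sum(res$signatures[, 1]), 1, tolerance = 1e-9)
  expect_true(all(diff(res$objective_trace) <= 1e-8))
  # exposures keep mutation units: reconstruction matches column totals
  expect_equal(sum(res$exposures), sum(cm), tolerance = 0.01 * sum(cm))
})

test_that("nmf_extract validates its rank", {
  cm <- matrix(1, 96, 3, dimnames = list(sbs_channels(), paste0("s", 1:3)))
  expect_error(nmf_extract(cm, 0), "rank")
  expect_error(nmf_extract(cm, 4), "rank")
})

test_that("matching recovers a permuted reference exactly", {
  ref <- reference_signatures()
  perm <- c(3, 1, 5, 2, 4)
  dn <- ref[, perm]
  colnames(dn) <- paste0("DN", 1:5)
  m <- match_signatures(dn, ref)
  expect_identical(m$reference, colnames(ref)[perm])
  expect_equal(m$cosine, rep(1, 5), tolerance = 1e-12)
  expect_true(all(m$assigned))
})

test_that("a single de novo signature matches by argmax cosine", {
  ref <- reference_signatures()
  dn <- ref[, "SBS13", drop = FALSE]
  colnames(dn) <- "DN1"
  m <- match_signatures(dn, ref)
  expect_identical(m$reference, "SBS13")
})

test_that("backward elimination keeps the signatures the data support", {
  ref <- reference_signatures()
  set.seed(12)
  mix <- as.vector(ref %*% c(0.45, 0.45, 0, 0.10, 0))
  counts <- as.vector(stats::rmultinom(1, 8000, mix))
  cm <- matrix(counts, ncol = 1, dimnames = list(rownames(ref), "s1"))
  fit <- prune_reference_refit(cm, ref, max_delta_cosine = 0.005)
  retained <- attr(fit, "retained")
  expect_true(all(c("SBS2", "SBS13") %in% retained))
  expect_lt(length(retained), 5)
})
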