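test_that("the same spec and seed reproduce the cohort bit for bit", {
  spec <- simulation_spec(n_genes = 200, n_sets = 5, set_size = 10,
                          n_planted_up = 1, n_planted_down = 1,
                          n_controls = 4, n_cases = 4, seed = 123)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
  # and the generator leaves the caller's RNG stream untouched
  set.seed(1)
  before <- stats::runif(1)
  set.seed(1)
  invisible(simulate_cohort(spec))
  expect_identical(stats::runif(1), before)
})

test_that("spec invariants are enforced", {
  expect_error(simulation_spec(n_genes = 10, n_sets = 5, set_size = 10,
                               n_planted_up = 1, n_planted_down = 1),
               "disjoint")
  expect_error(simulation_spec(n_sets = 4, n_planted_up = 3,
                               n_planted_down = 2))
  expect_error(simulate_trace("linear", n = 3), ">= 5")
})

test_that("generated cohorts satisfy their own contracts", {
  spec <- simulation_spec(n_genes = 300, n_sets = 8, set_size = 12,
                          n_planted_up = 2, n_planted_down = 2,
                          n_controls = 5, n_cases = 7, seed = 11)
  sim <- simulate_cohort(spec)
  expect_equal(dim(sim$expression), c(300L, 13L))
  expect_true(all(as.matrix(sim$expression[-1]) >= 0))
  expect_equal(nrow(sim$phenotypes), 12L)
  # disjoint sets
  expect_false(anyDuplicated(sim$sets$gene) > 0)
  expect_equal(table(sim$sets$set) |> as.integer(), rep(12L, 8))
  # linear severity is strictly increasing with the case index
  expect_true(all(diff(sim$truth$severity$severity) > 0))
  expect_equal(max(sim$truth$severity$severity), 1)
})

test_that("planted sets separate case from control scores in the right direction", {
  for (s in 1:5) {
    sim <- simulate_cohort(simulation_spec(effect = 1, seed = 200 + s))
    norm <- normalize_expression(sim$expression)
    scores <- score_gene_sets(norm, sim$sets)
    m <- as.matrix(scores[-1]); rownames(m) <- scores$set
    grp <- sim$phenotypes$group[match(colnames(m), sim$phenotypes$sample)]
    for (up in sim$truth$planted_up) {
      expect_gt(mean(m[up, grp == "case"]), mean(m[up, grp == "control"]))
    }
    for (dn in sim$truth$planted_down) {
      expect_lt(mean(m[dn, grp == "case"]), mean(m[dn, grp == "control"]))
    }
  }
})

test_that("mean planted-set case score rises monotonically with severity", {
  rhos <- vapply(1:5, function(s) {
    sim <- simulate_cohort(simulation_spec(effect = 1.5, noise_sd = 0.3,
                                           seed = 300 + s))
    norm <- normalize_expression(sim$expression)
    scores <- score_gene_sets(norm, sim$sets)
    m <- as.matrix(scores[-1]); rownames(m) <- scores$set
    cases <- sim$truth$severity$sample
    up_mean <- colMeans(m[sim$truth$planted_up, cases, drop = FALSE])
    stats::cor(up_mean, sim$truth$severity$severity, method = "spearman")
  }, numeric(1))
  expect_gt(stats::median(rhos), 0.9)
})

test_that("null cohorts give super-uniform (conservative) Fisher p-values", {
  ps <- unlist(lapply(1:3, function(s) {
    sim <- simulate_cohort(simulation_spec(
      n_genes = 3000, n_sets = 200, set_size = 15,
      n_planted_up = 0, n_planted_down = 0, effect = 0, seed = 400 + s
    ))
    run_enrichment(sim$expression, sim$sets, sim$phenotypes)$p
  }))
  for (t in c(0.01, 0.05, 0.1, 0.2)) {
    se <- sqrt(t * (1 - t) / length(ps))
    expect_lte(mean(ps <= t), t + 3 * se)
  }
})

test_that("trace fixtures are reproducible and shaped as advertised", {
  a <- simulate_trace("two_arc", n = 21, seed = 5)
  b <- simulate_trace("two_arc", n = 21, seed = 5)
  expect_identical(a, b)
  expect_equal(attr(a, "junction"), 10L)
  lin <- simulate_trace("linear", n = 15, seed = 2)
  expect_length(lin, 15)
  expect_true(is.na(attr(lin, "junction")))
})
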