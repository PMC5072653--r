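test_that("contingency counts split strictly-positive scores by group", {
  scores <- tibble::tibble(set = "S",
                           a1 = 0.1, a2 = 0.2, a3 = -0.3,
                           b1 = -0.1, b2 = -0.2)
  pheno <- tibble::tibble(sample = c("a1", "a2", "a3", "b1", "b2"),
                          group = c("case", "case", "case",
                                    "control", "control"))
  tab <- build_contingency(scores, pheno, "S")
  expect_equal(unlist(tab[-1]),
               c(n_case_up = 2, n_case_down = 1,
                 n_ctrl_up = 0, n_ctrl_down = 2))
  expect_error(build_contingency(scores, pheno, "nope"), "unknown")
})

test_that("scores of exactly zero count as not-above-average", {
  scores <- tibble::tibble(set = "S", a1 = 0, a2 = 0, b1 = 0)
  pheno <- tibble::tibble(sample = c("a1", "a2", "b1"),
                          group = c("case", "case", "control"))
  expect_message(tab <- build_contingency(scores, pheno, "S"), "exactly 0")
  expect_equal(unlist(tab[-1]),
               c(n_case_up = 0, n_case_down = 2,
                 n_ctrl_up = 0, n_ctrl_down = 1))
})

test_that("two-sided Fisher p matches hand-enumerated values", {
  expect_equal(fisher_exact_two_sided(2, 2, 2, 2), 1)
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(1, 0, 0, 1), 1)
  # degenerate margins
  expect_equal(fisher_exact_two_sided(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_two_sided(2, 0, 3, 0), 1)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "nonnegative")
})

test_that("swapping the up/down columns leaves the Fisher p unchanged", {
  set.seed(3)
  for (i in 1:50) {
    x <- sample(0:8, 4, replace = TRUE)
    expect_equal(fisher_exact_two_sided(x[1], x[2], x[3], x[4]),
                 fisher_exact_two_sided(x[2], x[1], x[4], x[3]))
  }
})

test_that("BH adjustment matches the definitional step-up oracle", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(diff(sort(adj)[order(order(sort(p)))]) >= -1e-15))
  }
})

test_that("direction labels follow the case/control up-fraction comparison", {
  expect_equal(classify_direction(9, 1, 2, 8, fdr = 0.001), "SUP")
  expect_equal(classify_direction(1, 9, 8, 2, fdr = 0.001), "SDP")
  expect_equal(classify_direction(9, 1, 2, 8, fdr = 0.5), "none")
  expect_warning(
    out <- classify_direction(5, 5, 5, 5, fdr = 0.005),
    "tied"
  )
  expect_equal(out, "none")
})

test_that("a strongly planted up-set is the unique SUP", {
  sim <- simulate_cohort(simulation_spec(
    n_genes = 400, n_sets = 10, set_size = 20, n_planted_up = 1,
    n_planted_down = 0, effect = 3, severity = "constant",
    n_controls = 10, n_cases = 10, seed = 99
  ))
  enr <- run_enrichment(sim$expression, sim$sets, sim$phenotypes)
  sups <- enr$set[enr$direction == "SUP"]
  expect_equal(sups, sim$truth$planted_up)
  planted <- enr[enr$set == sim$truth$planted_up, ]
  expect_equal(planted$n_case_up, 10)
  expect_equal(planted$n_ctrl_up, 0)
})

test_that("swapping group labels swaps SUP/SDP but not the p-values", {
  sim <- simulate_cohort(simulation_spec(
    n_genes = 400, n_sets = 10, set_size = 20, n_planted_up = 1,
    n_planted_down = 1, effect = 3, severity = "constant",
    n_controls = 10, n_cases = 10, seed = 7
  ))
  enr1 <- run_enrichment(sim$expression, sim$sets, sim$phenotypes)
  flipped <- dplyr::mutate(
    sim$phenotypes,
    group = ifelse(.data$group == "case", "control", "case")
  )
  enr2 <- run_enrichment(sim$expression, sim$sets, flipped)
  m <- match(enr1$set, enr2$set)
  expect_equal(enr1$p, enr2$p[m])
  swap <- c(SUP = "SDP", SDP = "SUP", none = "none")
  expect_equal(unname(swap[enr1$direction]), enr2$direction[m])
})
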