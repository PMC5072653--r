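test_that("start seed is the control mean profile, or zero in gene-set mode", {
  scores <- tibble::tibble(set = c("S1", "S2"),
                           c1 = c(0.2, -0.1), c2 = c(-0.2, 0.1),
                           s1 = c(1, 1))
  pheno <- tibble::tibble(sample = c("c1", "c2", "s1"),
                          group = c("control", "control", "case"))
  expect_equal(make_start_seed(scores, pheno),
               c(S1 = 0, S2 = 0))
  one_ctrl <- dplyr::mutate(
    pheno, group = ifelse(.data$sample == "c1", "case", .data$group)
  )
  expect_equal(make_start_seed(scores, one_ctrl),
               c(S1 = -0.2, S2 = 0.1))
  expect_equal(make_start_seed(scores, pheno, mode = "genesets"),
               c(c1 = 0, c2 = 0, s1 = 0))
})

test_that("a single candidate yields a one-step ordering with its seed similarity", {
  v <- matrix(c(1, -1, 2), ncol = 1, dimnames = list(NULL, "only"))
  seed <- c(2, -3, 1)
  res <- accumulate_cluster(v, seed)
  expect_equal(res$ordered_ids, "only")
  expect_equal(res$trace, smic(v[, 1], seed))
})

test_that("greedy ordering matches the literal step-by-step oracle", {
  set.seed(23)
  for (method in c("smic_mle", "euclidean")) {
    simfun <- if (method == "smic_mle") {
      function(u, v) smic(u, v)
    } else {
      function(u, v) baseline_similarity(u, v, "euclidean")
    }
    for (i in 1:40) {
      k <- sample(2:6, 1)
      m <- sample(4:12, 1)
      vec <- matrix(random_score_vector(k * m), m, k,
                    dimnames = list(NULL, sprintf("id%02d", sample(99, k))))
      seed <- random_score_vector(m)
      got <- suppressMessages(accumulate_cluster(vec, seed, method = method))
      want <- oracle_greedy(vec, seed, simfun)
      expect_equal(got$ordered_ids, want$ordered_ids)
      expect_equal(got$trace, want$trace)
      expect_setequal(got$ordered_ids, colnames(vec))
    }
  }
})

test_that("reordering input candidates does not change the result", {
  set.seed(29)
  vec <- matrix(random_score_vector(8 * 10), 10, 8,
                dimnames = list(NULL, sprintf("c%02d", 1:8)))
  seed <- random_score_vector(10)
  ref <- suppressMessages(accumulate_cluster(vec, seed))
  for (i in 1:10) {
    shuf <- vec[, sample(ncol(vec)), drop = FALSE]
    got <- suppressMessages(accumulate_cluster(shuf, seed))
    expect_identical(got$ordered_ids, ref$ordered_ids)
    expect_identical(got$trace, ref$trace)
  }
})

test_that("input validation catches unnamed and mismatched vectors", {
  v <- matrix(1:6, 3, 2)
  expect_error(accumulate_cluster(v, c(1, 2, 3)), "named")
  colnames(v) <- c("a", "b")
  expect_error(accumulate_cluster(v, c(1, 2)), "length")
})

test_that("double clustering reorders the sign markers consistently", {
  sim <- simulate_cohort(simulation_spec(
    n_genes = 300, n_sets = 6, set_size = 15, n_planted_up = 2,
    n_planted_down = 1, effect = 2, n_controls = 6, n_cases = 8, seed = 31
  ))
  enr <- run_enrichment(sim$expression, sim$sets, sim$phenotypes,
                        fdr_threshold = 0.05)
  scores <- attr(enr, "scores")
  sig <- enr$set[enr$direction != "none"]
  dbl <- suppressMessages(double_cluster(scores, sim$phenotypes, sig))
  expect_setequal(rownames(dbl$markers), sig)
  cases <- sim$phenotypes$sample[sim$phenotypes$group == "case"]
  expect_setequal(colnames(dbl$markers), cases)
  # reindexing oracle: markers equal direct indexing of score > 0
  sm <- as.matrix(scores[-1])
  rownames(sm) <- scores$set
  for (s in rownames(dbl$markers)) {
    for (j in colnames(dbl$markers)) {
      expect_identical(dbl$markers[s, j], unname(sm[s, j] > 0))
    }
  }
})

test_that("single-set single-case double clustering degenerates cleanly", {
  scores <- tibble::tibble(set = "S1", c1 = -0.5, s1 = 0.25)
  pheno <- tibble::tibble(sample = c("c1", "s1"),
                          group = c("control", "case"))
  dbl <- double_cluster(scores, pheno, "S1")
  expect_equal(dim(dbl$markers), c(1L, 1L))
  expect_true(dbl$markers[1, 1])
  expect_equal(dbl$samples$ordered_ids, "s1")
  expect_equal(dbl$sets$ordered_ids, "S1")
})

test_that("tidy and glance expose the clustering as tables", {
  set.seed(37)
  vec <- matrix(random_score_vector(5 * 8), 8, 5,
                dimnames = list(NULL, sprintf("c%d", 1:5)))
  res <- suppressMessages(accumulate_cluster(vec, random_score_vector(8)))
  td <- tidy(res)
  expect_equal(names(td), c("rank", "sample_id", "avg_similarity", "class"))
  expect_equal(td$rank, 1:5)
  expect_true(all(is.na(td$class)))
  gl <- glance(res)
  expect_equal(gl$n, 5L)
  expect_equal(gl$method, "smic_mle")
})
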