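# Independent oracles used across the suite. Each is a deliberately
# literal, unoptimized implementation kept separate from the package's
# code paths.

# Two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins, comparing exactly representable integer numerators
# (products of binomial coefficients; exact in doubles for totals <= 24).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  num <- choose(r1, ks) * choose(r2, c1 - ks)
  obs <- choose(r1, a) * choose(r2, c)
  sum(num[num <= obs]) / choose(n, c1)
}

# Definitional BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# SMIC MLE by dense theta-grid maximization of L(theta).
oracle_smic_grid <- function(u, v, step = 1e-3) {
  pr <- u * v
  n_cgs <- sum(pr > 0)
  n_dgs <- sum(pr < 0)
  th <- seq(0.5, 1, by = step)
  max(n_cgs * th + n_dgs * (1 - th))
}

# Literal transcription of the accumulating-clustering steps: keep a seed
# list and a candidate set; each round score every candidate by its mean
# similarity over all seeds, move the best (lexicographic on ties) across.
oracle_greedy <- function(vectors, start_seed, simfun) {
  seeds <- list(start_seed)
  candidates <- sort(colnames(vectors))
  ordered <- character(0)
  trace <- numeric(0)
  while (length(candidates) > 0) {
    avg <- vapply(candidates, function(id) {
      mean(vapply(seeds, function(s) simfun(vectors[, id], s), numeric(1)))
    }, numeric(1))
    best <- candidates[avg == max(avg)]
    pick <- sort(best)[1]
    ordered <- c(ordered, pick)
    trace <- c(trace, max(avg))
    seeds <- c(seeds, list(vectors[, pick]))
    candidates <- setdiff(candidates, pick)
  }
  list(ordered_ids = ordered, trace = trace)
}

# random sign-pattern score vector (continuous, no exact zeros)
random_score_vector <- function(m) {
  stats::runif(m, -1, 1)
}

# small deterministic cohort: 6 genes x 5 samples, 2 controls + 3 cases
tiny_cohort <- function() {
  expr <- tibble::tibble(
    gene = paste0("g", 1:6),
    c1 = c(5.0, 6.0, 4.0, 7.0, 5.5, 6.5),
    c2 = c(5.2, 5.8, 4.2, 6.8, 5.6, 6.4),
    s1 = c(7.0, 4.0, 6.0, 5.0, 7.5, 4.5),
    s2 = c(7.2, 3.8, 6.2, 4.8, 7.6, 4.4),
    s3 = c(6.8, 4.2, 5.8, 5.2, 7.4, 4.6)
  )
  pheno <- tibble::tibble(
    sample = c("c1", "c2", "s1", "s2", "s3"),
    group = c("control", "control", "case", "case", "case")
  )
  sets <- tibble::tibble(
    set = rep(c("up_set", "down_set", "mixed"), each = 2),
    description = "fixture",
    gene = c("g1", "g5", "g2", "g6", "g3", "g4")
  )
  list(expression = expr, phenotypes = pheno, sets = sets)
}

# wrap a bare trace as an igsa_clustering object for segmentation tests
trace_result <- function(trace, ids = sprintf("s%03d", seq_along(trace))) {
  structure(
    list(ordered_ids = ids, trace = as.numeric(trace), start_seed = NULL,
         method = "precomputed", classes = NULL,
         flex_points = integer(0), segmentation = NULL),
    class = "igsa_clustering"
  )
}
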