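#' Build the sign 2x2 contingency table for one gene set
#'
#' Counts, separately in cases and controls, the samples whose score for
#' `set_name` is strictly above zero ("up") versus at or below zero
#' ("down"). Zero is the reference because set scores are means of
#' normalized values whose cross-sample average is exactly zero. A score of
#' exactly 0 counts as "down" (not above average); such ties are reported
#' with a message since they are measure-zero for real data.
#'
#' @param scores Score tibble from [score_gene_sets()].
#' @param pheno Phenotype tibble (columns `sample`, `group`).
#' @param set_name Name of one set present in `scores`.
#' @return A one-row tibble: `set`, `n_case_up`, `n_case_down`,
#'   `n_ctrl_up`, `n_ctrl_down`.
#' @export
build_contingency <- function(scores, pheno, set_name) {
  if (!set_name %in% scores$set) {
    stop("unknown gene set: ", set_name, call. = FALSE)
  }
  s <- expr_values(scores, "set")[set_name, , drop = TRUE]
  pheno <- validate_phenotypes(pheno, names(s))
  grp <- pheno$group[match(names(s), pheno$sample)]
  if (any(s == 0)) {
    message(sum(s == 0), " sample score(s) exactly 0 for set '", set_name,
            "'; counted as not-above-average")
  }
  up <- s > 0
  tibble::tibble(
    set = set_name,
    n_case_up = sum(up & grp == "case"),
    n_case_down = sum(!up & grp == "case"),
    n_ctrl_up = sum(up & grp == "control"),
    n_ctrl_down = sum(!up & grp == "control")
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The standard minimum-likelihood two-sided p: with margins fixed, sum the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one. Degenerate margins (an empty row or column) give p = 1.
#' Vectorized over the four count arguments.
#'
#' @param n_case_up,n_case_down,n_ctrl_up,n_ctrl_down Nonnegative integer
#'   counts (recycled to a common length).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
fisher_exact_two_sided <- function(n_case_up, n_case_down,
                                   n_ctrl_up, n_ctrl_down) {
  tab <- cbind(n_case_up, n_case_down, n_ctrl_up, n_ctrl_down)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("contingency counts must be nonnegative integers", call. = FALSE)
  }
  apply(tab, 1L, function(x) {
    if ((x[1] + x[2]) == 0 || (x[3] + x[4]) == 0 ||
        (x[1] + x[3]) == 0 || (x[2] + x[4]) == 0) {
      return(1)
    }
    stats::fisher.test(matrix(x, nrow = 2L, byrow = TRUE))$p.value
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input and clipped to 1.
#' The more conservative Benjamini-Yekutieli variant (valid under arbitrary
#' dependence) is available via `method = "BY"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Classify a significant set as up- or down-regulated
#'
#' A set significant at `fdr < threshold` is a SUP (significantly
#' up-regulated pathway) when the fraction of cases scoring above zero
#' exceeds the fraction of controls doing so, and an SDP when it is lower.
#' An exact tie in the fractions yields `"none"` with a warning.
#'
#' @param n_case_up,n_case_down,n_ctrl_up,n_ctrl_down Counts (vectorized).
#' @param fdr Adjusted p-value(s).
#' @param threshold Significance threshold on `fdr` (default 0.01).
#' @return Character vector in `c("SUP", "SDP", "none")`.
#' @export
classify_direction <- function(n_case_up, n_case_down, n_ctrl_up,
                               n_ctrl_down, fdr, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  f_case <- n_case_up / (n_case_up + n_case_down)
  f_ctrl <- n_ctrl_up / (n_ctrl_up + n_ctrl_down)
  out <- rep("none", length(fdr))
  sig <- fdr < threshold
  out[sig & f_case > f_ctrl] <- "SUP"
  out[sig & f_case < f_ctrl] <- "SDP"
  tied <- sig & f_case == f_ctrl
  if (any(tied)) {
    warning(sum(tied), " significant set(s) with tied up-fractions left ",
            "unclassified", call. = FALSE)
  }
  out
}

#' Sign-based gene-set enrichment
#'
#' Runs the full enrichment stage: normalize expression, score every gene
#' set per sample, count above/below-zero scores in cases vs controls,
#' test each 2x2 table with Fisher's exact test, adjust by FDR, and label
#' significant sets SUP or SDP.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param sets Gene-set tibble from [read_gmt()].
#' @param pheno Phenotype tibble (columns `sample`, `group`).
#' @param fdr_threshold Significance threshold on the adjusted p
#'   (default 0.01).
#' @param min_support Minimum set-matrix intersection size, see
#'   [score_gene_sets()].
#' @param fdr_method `"BH"` or `"BY"`, see [bh_fdr()].
#' @return A tibble with one row per retained set, sorted by `p` then set
#'   name: `set`, `n_case_up`, `n_case_down`, `n_ctrl_up`, `n_ctrl_down`,
#'   `p`, `fdr`, `direction`. The per-sample score matrix is attached as
#'   attribute `scores`.
#' @examples
#' sim <- simulate_cohort(simulation_spec(seed = 1))
#' head(run_enrichment(sim$expression, sim$sets, sim$phenotypes))
#' @export
run_enrichment <- function(expr, sets, pheno, fdr_threshold = 0.01,
                           min_support = 1L, fdr_method = "BH") {
  norm <- normalize_expression(expr)
  scores <- score_gene_sets(norm, sets, min_support = min_support)
  pheno <- validate_phenotypes(pheno, setdiff(names(scores), "set"))
  m <- expr_values(scores, "set")
  grp <- pheno$group[match(colnames(m), pheno$sample)]
  up <- m > 0
  res <- tibble::tibble(
    set = rownames(m),
    n_case_up = unname(rowSums(up[, grp == "case", drop = FALSE])),
    n_case_down = unname(rowSums(!up[, grp == "case", drop = FALSE])),
    n_ctrl_up = unname(rowSums(up[, grp == "control", drop = FALSE])),
    n_ctrl_down = unname(rowSums(!up[, grp == "control", drop = FALSE]))
  )
  res$p <- fisher_exact_two_sided(res$n_case_up, res$n_case_down,
                                  res$n_ctrl_up, res$n_ctrl_down)
  res$fdr <- bh_fdr(res$p, method = fdr_method)
  res$direction <- classify_direction(res$n_case_up, res$n_case_down,
                                      res$n_ctrl_up, res$n_ctrl_down,
                                      res$fdr, threshold = fdr_threshold)
  res <- dplyr::arrange(res, .data$p, .data$set)
  attr(res, "scores") <- scores
  res
}
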