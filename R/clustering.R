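#' Build the start seed for accumulating clustering
#'
#' In `"samples"` mode the start seed is the average score of each gene set
#' over the control samples — the typical healthy profile, so the first
#' sample absorbed is the one most control-like. In `"genesets"` mode
#' (clustering gene sets rather than samples) there is no healthy/diseased
#' tag on a gene set, so the start seed is the zero vector with one entry
#' per sample.
#'
#' @param scores Score tibble from [score_gene_sets()].
#' @param pheno Phenotype tibble (columns `sample`, `group`).
#' @param mode `"samples"` (default) or `"genesets"`.
#' @return A named numeric vector: per-set control means (`"samples"`) or a
#'   zero vector named by samples (`"genesets"`).
#' @export
make_start_seed <- function(scores, pheno, mode = c("samples", "genesets")) {
  mode <- match.arg(mode)
  m <- expr_values(scores, "set")
  pheno <- validate_phenotypes(pheno, colnames(m))
  if (mode == "genesets") {
    return(stats::setNames(numeric(ncol(m)), colnames(m)))
  }
  ctrl <- pheno$sample[pheno$group == "control"]
  rowMeans(m[, ctrl, drop = FALSE])
}

#' Greedy accumulating clustering
#'
#' Orders candidates by greedy accumulation into a seed set. Starting from
#' `start_seed` alone, each step computes every remaining candidate's
#' average similarity to all current seeds (start seed included on equal
#' footing) and absorbs the candidate with the highest average; its score
#' at selection time is recorded in the trace. Ties are broken by
#' lexicographic candidate id, with a message, so the procedure is fully
#' deterministic.
#'
#' @param vectors Numeric matrix with one column per candidate (column
#'   names are the candidate ids), or a named list of equal-length numeric
#'   vectors. Rows/elements must align with `start_seed`.
#' @param start_seed Numeric vector of the same length as the candidate
#'   vectors.
#' @param method Similarity: one of `"smic_mle"`, `"smic_fixed"`,
#'   `"euclidean"`, `"pearson"`, `"spearman"`.
#' @param theta Concordance weight for `"smic_fixed"`, see [smic()].
#' @return An object of class `igsa_clustering`: a list with `ordered_ids`
#'   (permutation of candidate ids), `trace` (the winner's average
#'   similarity at each step), `start_seed`, `method`, and `classes`
#'   (`NULL` until [segment_trace()] is applied).
#' @seealso [cluster_samples()] for the data-frame-level interface,
#'   [segment_trace()], [tidy.igsa_clustering()], [autoplot.igsa_clustering()]
#' @export
accumulate_cluster <- function(vectors, start_seed,
                               method = "smic_mle", theta = NULL) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    vectors <- do.call(cbind, vectors)
  }
  vectors <- as.matrix(vectors)
  if (is.null(colnames(vectors))) {
    stop("candidate vectors must be named", call. = FALSE)
  }
  if (nrow(vectors) != length(start_seed)) {
    stop("start seed length (", length(start_seed),
         ") does not match candidate vector length (", nrow(vectors), ")",
         call. = FALSE)
  }
  if (ncol(vectors) < 1L) {
    stop("at least one candidate is required", call. = FALSE)
  }
  sim <- similarity_fun(method, theta)
  ids <- colnames(vectors)
  k <- length(ids)

  # precompute candidate-candidate and candidate-seed similarities
  seed_sim <- vapply(ids, \(i) sim(vectors[, i], start_seed), numeric(1L))
  pair_sim <- matrix(0, k, k, dimnames = list(ids, ids))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        pair_sim[i, j] <- pair_sim[j, i] <- sim(vectors[, i], vectors[, j])
      }
    }
  }

  candidates <- ids
  sim_sum <- seed_sim          # running sum of similarity to current seeds
  n_seeds <- 1L
  ordered <- character(0L)
  trace <- numeric(0L)
  any_tie <- FALSE
  while (length(candidates) > 0L) {
    avg <- sim_sum[candidates] / n_seeds
    best <- max(avg)
    tied <- candidates[avg == best]
    if (length(tied) > 1L) any_tie <- TRUE
    pick <- sort(tied)[1L]
    ordered <- c(ordered, pick)
    trace <- c(trace, best)
    candidates <- setdiff(candidates, pick)
    sim_sum <- sim_sum + pair_sim[pick, ]
    n_seeds <- n_seeds + 1L
  }
  if (any_tie) {
    message("similarity ties encountered; broken by lexicographic id")
  }
  structure(
    list(ordered_ids = ordered, trace = unname(trace),
         start_seed = start_seed, method = method, theta = theta,
         classes = NULL, flex_points = integer(0L),
         segmentation = NULL),
    class = "igsa_clustering"
  )
}

#' Severity-ordered clustering of case samples
#'
#' The data-frame-level front end to [accumulate_cluster()]: restricts the
#' score matrix to the significant sets, builds the control-profile start
#' seed, orders the case samples by greedy accumulation, and (by default)
#' segments the similarity trace into severity classes. Samples absorbed
#' early resemble the control profile (mild); late ones deviate most
#' (severe).
#'
#' @inheritParams make_start_seed
#' @inheritParams accumulate_cluster
#' @param significant Character vector of set names to cluster on
#'   (typically the SUP/SDP sets from [run_enrichment()]); `NULL` uses all
#'   sets in `scores`.
#' @param segment Apply [segment_trace()] to the result (default `TRUE`).
#' @param loess_span,min_class_size Segmentation controls, see
#'   [segment_trace()].
#' @return An `igsa_clustering` object (see [accumulate_cluster()]).
#' @examples
#' sim <- simulate_cohort(simulation_spec(seed = 1))
#' enr <- run_enrichment(sim$expression, sim$sets, sim$phenotypes,
#'                       fdr_threshold = 0.05)
#' cl <- cluster_samples(attr(enr, "scores"), sim$phenotypes,
#'                       significant = enr$set[enr$direction != "none"])
#' tidy(cl)
#' @export
cluster_samples <- function(scores, pheno, significant = NULL,
                            method = "smic_mle", theta = NULL,
                            segment = TRUE, loess_span = 0.5,
                            min_class_size = 3L) {
  m <- expr_values(scores, "set")
  pheno <- validate_phenotypes(pheno, colnames(m))
  if (!is.null(significant)) {
    missing <- setdiff(significant, rownames(m))
    if (length(missing) > 0L) {
      stop("set(s) not present in scores: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    m <- m[significant, , drop = FALSE]
  }
  seed <- rowMeans(m[, pheno$sample[pheno$group == "control"], drop = FALSE])
  cases <- pheno$sample[pheno$group == "case"]
  res <- accumulate_cluster(m[, cases, drop = FALSE], seed,
                            method = method, theta = theta)
  if (segment) {
    res <- segment_trace(res, loess_span = loess_span,
                         min_class_size = min_class_size)
  }
  res
}

#' Double clustering of samples and gene sets
#'
#' Orders case samples (control-profile start seed) and significant gene
#' sets (zero start seed, vectors over all samples) by accumulating
#' clustering, and returns the sign marker matrix — which ordered set is
#' above average in which ordered case sample — for pathway-by-sample
#' profile displays.
#'
#' @inheritParams cluster_samples
#' @param significant Character vector of significant set names (subset of
#'   `scores$set`).
#' @return A list with `samples` and `sets` (`igsa_clustering` objects,
#'   unsegmented) and `markers`, a logical matrix (ordered sets x ordered
#'   case samples) of `score > 0`.
#' @seealso [plot_markers()]
#' @export
double_cluster <- function(scores, pheno, significant, method = "smic_mle",
                           theta = NULL) {
  m <- expr_values(scores, "set")
  pheno <- validate_phenotypes(pheno, colnames(m))
  missing <- setdiff(significant, rownames(m))
  if (length(missing) > 0L) {
    stop("set(s) not present in scores: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  msig <- m[significant, , drop = FALSE]
  sample_cl <- cluster_samples(scores, pheno, significant = significant,
                               method = method, theta = theta,
                               segment = FALSE)
  # gene-set mode: candidates are the sets, vectors span all samples,
  # start seed is the zero vector (no control/case tag on a set)
  set_cl <- accumulate_cluster(t(msig),
                               stats::setNames(numeric(ncol(msig)),
                                               colnames(msig)),
                               method = method, theta = theta)
  markers <- msig[set_cl$ordered_ids, sample_cl$ordered_ids, drop = FALSE] > 0
  list(samples = sample_cl, sets = set_cl, markers = markers)
}

#' @export
print.igsa_clustering <- function(x, ...) {
  cat("Accumulating clustering (", x$method, "), ",
      length(x$ordered_ids), " candidates\n", sep = "")
  if (!is.null(x$classes)) {
    cat("classes:", paste(tabulate(x$classes), collapse = " / "),
        "(boundaries at flex points", paste(x$flex_points, collapse = ", "),
        ")\n")
  }
  cat("order: ", paste(utils::head(x$ordered_ids, 8L), collapse = " > "),
      if (length(x$ordered_ids) > 8L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Tidy an accumulating-clustering result
#'
#' @param x An `igsa_clustering` object.
#' @param ... Unused.
#' @return A tibble with one row per clustered candidate, in absorption
#'   order: `rank`, `sample_id`, `avg_similarity`, `class` (`NA` until
#'   [segment_trace()] has been applied).
#' @method tidy igsa_clustering
#' @export
tidy.igsa_clustering <- function(x, ...) {
  tibble::tibble(
    rank = seq_along(x$ordered_ids),
    sample_id = x$ordered_ids,
    avg_similarity = x$trace,
    class = if (is.null(x$classes)) NA_integer_ else x$classes
  )
}

#' One-row summary of a clustering result
#'
#' @param x An `igsa_clustering` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `method`, `n_classes`,
#'   `mean_similarity`, `first_id`, `last_id`.
#' @method glance igsa_clustering
#' @export
glance.igsa_clustering <- function(x, ...) {
  tibble::tibble(
    n = length(x$ordered_ids),
    method = x$method,
    n_classes = if (is.null(x$classes)) NA_integer_ else max(x$classes),
    mean_similarity = mean(x$trace),
    first_id = x$ordered_ids[1L],
    last_id = x$ordered_ids[length(x$ordered_ids)]
  )
}
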