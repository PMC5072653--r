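#' Normalize expression to deviation-from-average proportions
#'
#' For gene \eqn{i} with log-scale value \eqn{g_{ij}} in sample \eqn{j} and
#' \eqn{N} samples, the normalized value is
#' \deqn{g_{ij} / \sum_j g_{ij} - 1/N,}
#' i.e. the gene's share of its own total across samples, centred so that
#' the cross-sample average contribution is zero. Positive values mean the
#' gene is above its average level in that sample (up-regulated there),
#' negative below. Every retained gene's normalized row sums to exactly
#' zero across samples.
#'
#' Genes whose raw row sum is zero carry no between-sample signal and the
#' proportion is undefined; they are dropped with a warning and recorded in
#' the `dropped_genes` attribute of the result.
#'
#' @param expr Expression tibble (`gene` column + numeric sample columns),
#'   nonnegative log-scale values, at least 2 samples.
#' @return A tibble of the same shape restricted to retained genes, with
#'   attribute `dropped_genes` (character vector, possibly empty).
#' @examples
#' expr <- tibble::tibble(gene = c("A", "B"), s1 = c(1, 2), s2 = c(3, 2))
#' normalize_expression(expr)
#' @export
normalize_expression <- function(expr) {
  expr <- validate_expression(expr)
  m <- expr_values(expr)
  n <- ncol(m)
  if (n < 2L) {
    stop("normalization requires at least 2 samples", call. = FALSE)
  }
  rs <- rowSums(m)
  drop <- rs == 0
  if (any(drop)) {
    warning(sum(drop), " gene(s) with zero row sum dropped: ",
            paste(utils::head(rownames(m)[drop], 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ..." else "", call. = FALSE)
  }
  keep <- m[!drop, , drop = FALSE]
  norm <- keep / rowSums(keep) - 1 / n
  out <- values_to_tbl(norm, "gene")
  attr(out, "dropped_genes") <- rownames(m)[drop]
  out
}

#' Score gene sets per sample
#'
#' The score of gene set \eqn{Q_i} in sample \eqn{j} is the arithmetic mean
#' of the normalized expression values over \eqn{Q_i \cap S_j}, the set
#' members present in the (normalized) matrix. Because normalized values
#' are centred at zero per gene, a positive set score marks above-average
#' activity of that set in that sample.
#'
#' Sets whose intersection with the matrix has fewer than `min_support`
#' genes give unstably averaged scores and are excluded from the output;
#' their names are recorded in the `excluded_sets` attribute.
#'
#' @param norm Normalized expression tibble from [normalize_expression()].
#' @param sets Gene-set tibble from [read_gmt()] (columns `set`, `gene`).
#' @param min_support Minimum intersection size for a set to be scored
#'   (default 1).
#' @return A tibble with a `set` column plus one numeric column per sample,
#'   with attributes `excluded_sets` (character) and `support` (named
#'   integer vector of intersection sizes for retained sets).
#' @export
score_gene_sets <- function(norm, sets, min_support = 1L) {
  stopifnot(is.data.frame(sets), all(c("set", "gene") %in% names(sets)))
  if (nrow(sets) == 0L) {
    stop("empty gene-set collection", call. = FALSE)
  }
  stopifnot(min_support >= 1L)
  m <- expr_values(norm)
  members <- geneset_list(sets)
  support <- vapply(members, \(g) sum(g %in% rownames(m)), integer(1L))
  keep <- support >= min_support
  if (!any(keep)) {
    stop("no gene set has >= ", min_support,
         " member(s) present in the expression matrix", call. = FALSE)
  }
  scores <- t(vapply(
    members[keep],
    \(g) colMeans(m[rownames(m) %in% g, , drop = FALSE]),
    numeric(ncol(m))
  ))
  # preserve the collection's original set order
  ord <- intersect(unique(sets$set), names(members[keep]))
  scores <- scores[ord, , drop = FALSE]
  out <- values_to_tbl(scores, "set")
  attr(out, "excluded_sets") <- setdiff(unique(sets$set), ord)
  attr(out, "support") <- support[ord]
  out
}
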