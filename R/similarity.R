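#' Count sign-concordant and sign-discordant positions
#'
#' For two score vectors over the same gene sets, a position is a CGS
#' (co-expressed gene set) when both values lie on the same side of zero
#' (`u*v > 0`), a DGS (differentially expressed gene set) when they lie on
#' opposite sides (`u*v < 0`), and tied when either value is exactly zero
#' (zero has no direction).
#'
#' @param u,v Numeric vectors of equal length >= 1.
#' @return A one-row tibble: `n_cgs`, `n_dgs`, `n_tied`.
#' @export
count_signs <- function(u, v) {
  if (length(u) != length(v)) {
    stop("sign vectors must have equal length", call. = FALSE)
  }
  stopifnot(length(u) >= 1L)
  prod <- u * v
  tibble::tibble(
    n_cgs = sum(prod > 0),
    n_dgs = sum(prod < 0),
    n_tied = sum(prod == 0)
  )
}

#' SMIC sign-concordance similarity
#'
#' The similarity between two samples is a weighted count of concordant and
#' discordant gene-set positions,
#' \deqn{L(\theta) = N_{cgs}\,\theta + N_{dgs}\,(1 - \theta),}
#' where \eqn{\theta \in [0.5, 1]} is the probability that an observed
#' concordance is not a random event. `method = "smic_fixed"` evaluates
#' \eqn{L} at a user-supplied `theta`; `method = "smic_mle"` (default)
#' profiles \eqn{\theta} out by maximizing the linear form over
#' \eqn{[0.5, 1]}, which is attained at an endpoint:
#' \deqn{\max(N_{cgs},\ (N_{cgs} + N_{dgs})/2).}
#' The measure is symmetric in its arguments and bounded by the vector
#' length; positions where either value is exactly zero contribute nothing.
#'
#' @param u,v Numeric vectors of equal length.
#' @param method `"smic_mle"` (default) or `"smic_fixed"`.
#' @param theta Concordance weight in `[0.5, 1]`, used by `"smic_fixed"`.
#' @return A single similarity value (higher = more alike in sign).
#' @examples
#' smic(c(1, 2, -1), c(2, 1, -3))        # all concordant -> 3
#' smic(c(1, 2, -1), c(-2, -1, 3))       # all discordant -> 1.5
#' @export
smic <- function(u, v, method = c("smic_mle", "smic_fixed"), theta = NULL) {
  method <- match.arg(method)
  n <- count_signs(u, v)
  if (method == "smic_fixed") {
    if (is.null(theta) || theta < 0.5 || theta > 1) {
      stop("smic_fixed requires theta in [0.5, 1]", call. = FALSE)
    }
    n$n_cgs * theta + n$n_dgs * (1 - theta)
  } else {
    max(n$n_cgs, (n$n_cgs + n$n_dgs) / 2)
  }
}

#' Baseline similarity measures
#'
#' Conventional alternatives to [smic()], oriented so that higher always
#' means more similar: `"euclidean"` returns the negated Euclidean
#' distance; `"pearson"` and `"spearman"` return the correlation
#' coefficient. A zero-variance vector makes the correlations undefined;
#' those return 0 with a warning.
#'
#' @param u,v Numeric vectors of equal length.
#' @param method `"euclidean"`, `"pearson"` or `"spearman"`.
#' @return A single similarity value.
#' @export
baseline_similarity <- function(u, v,
                                method = c("euclidean", "pearson",
                                           "spearman")) {
  method <- match.arg(method)
  if (length(u) != length(v)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (method == "euclidean") {
    return(-sqrt(sum((u - v)^2)))
  }
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    warning("zero-variance vector; ", method, " similarity set to 0",
            call. = FALSE)
    return(0)
  }
  stats::cor(u, v, method = method)
}

# valid similarity method names
similarity_methods <- function() {
  c("smic_mle", "smic_fixed", "euclidean", "pearson", "spearman")
}

# similarity closure for a method name (+ theta for smic_fixed)
similarity_fun <- function(method = "smic_mle", theta = NULL) {
  method <- match.arg(method, similarity_methods())
  if (method %in% c("smic_mle", "smic_fixed")) {
    function(u, v) smic(u, v, method = method, theta = theta)
  } else {
    function(u, v) baseline_similarity(u, v, method = method)
  }
}
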