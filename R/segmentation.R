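#' Segment a similarity trace into severity classes
#'
#' Fits a loess curve to the clustering trace (average similarity at
#' absorption vs rank) and places class boundaries at the flex points —
#' the ranks where the second difference of the fitted curve changes sign,
#' i.e. where the trace switches between concave and convex. Boundaries
#' that would create a class smaller than `min_class_size` are merged
#' away. A trace with no curvature change (or too short to fit) yields a
#' single class.
#'
#' Residual loess wiggle on an essentially straight trace produces sign
#' flips of negligible magnitude; curvature values below `curvature_tol`
#' are therefore treated as flat. The default floor scales as the fitted
#' range over \eqn{n^2} — the curvature a whole-trace arc of about a
#' quarter of the range would have — so genuine arcs pass and noise does
#' not.
#'
#' @param result An `igsa_clustering` object from [accumulate_cluster()]
#'   or [cluster_samples()].
#' @param loess_span Loess smoothing span in `(0, 1]` (default 0.5; larger
#'   = smoother curve, fewer flex points).
#' @param min_class_size Minimum number of samples per class (default 3).
#' @param curvature_tol Absolute second-difference floor below which the
#'   fitted curve counts as flat; `NULL` (default) uses
#'   `2 * diff(range(fitted)) / n^2`.
#' @return The same object with `classes` (contiguous integer class index
#'   per ordered candidate, 1 = mildest), `flex_points` (the boundary
#'   ranks; a boundary at rank r splits between r and r + 1), and
#'   `segmentation` (the loess-fitted values) filled in.
#' @export
segment_trace <- function(result, loess_span = 0.5, min_class_size = 3L,
                          curvature_tol = NULL) {
  stopifnot(inherits(result, "igsa_clustering"),
            loess_span > 0, loess_span <= 1, min_class_size >= 1L)
  n <- length(result$trace)
  rank <- seq_len(n)
  fitted <- tryCatch({
    fit <- stats::loess(result$trace ~ rank, span = loess_span,
                        degree = 2L,
                        control = stats::loess.control(surface = "direct"))
    unname(stats::predict(fit, data.frame(rank = rank)))
  }, error = function(e) NULL, warning = function(w) NULL)

  boundaries <- integer(0L)
  if (!is.null(fitted) && n >= 3L && all(is.finite(fitted))) {
    d2 <- diff(fitted, differences = 2L)  # curvature at ranks 2..(n-1)
    if (is.null(curvature_tol)) {
      curvature_tol <- max(2 * diff(range(fitted)) / n^2,
                           sqrt(.Machine$double.eps))
    }
    s <- sign(d2) * (abs(d2) >= curvature_tol)
    # carry the last nonzero sign across flat stretches
    for (i in seq_along(s)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
    flips <- which(s[-1L] * s[-length(s)] < 0)
    # a flip between curvature indices i and i+1 is a break after rank i+1
    boundaries <- flips + 1L
    boundaries <- enforce_min_class(boundaries, n, min_class_size)
  }
  classes <- rep.int(1L, n)
  if (length(boundaries) > 0L) {
    classes <- findInterval(rank, boundaries + 1L) + 1L
  }
  result$classes <- classes
  result$flex_points <- boundaries
  result$segmentation <- fitted
  result
}

# drop boundaries until every class has >= min_class_size members
enforce_min_class <- function(boundaries, n, min_class_size) {
  boundaries <- sort(unique(boundaries))
  boundaries <- boundaries[boundaries >= 1L & boundaries < n]
  repeat {
    if (length(boundaries) == 0L) return(boundaries)
    sizes <- diff(c(0L, boundaries, n))
    if (all(sizes >= min_class_size)) return(boundaries)
    worst <- which.min(sizes)
    # merge the smallest class into a neighbour by removing one of its
    # delimiting boundaries (prefer the interior one nearest the class)
    drop_idx <- if (worst == 1L) 1L else worst - 1L
    boundaries <- boundaries[-drop_idx]
  }
}
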