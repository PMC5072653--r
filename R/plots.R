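#' Plot a clustering trace with its loess fit and class boundaries
#'
#' Shows the average similarity of each absorbed sample at selection time
#' (points and line), the loess curve used for segmentation (if
#' [segment_trace()] has been applied), and vertical lines at the flex
#' points dividing the severity classes.
#'
#' @param object An `igsa_clustering` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot igsa_clustering
#' @export
autoplot.igsa_clustering <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank,
                                       y = .data$avg_similarity)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$class)),
                        size = 1.8) +
    ggplot2::labs(x = "absorption rank (mild to severe)",
                  y = "average similarity to seed set",
                  colour = "class") +
    ggplot2::theme_minimal()
  if (!is.null(object$segmentation)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(rank = d$rank, fit = object$segmentation),
      ggplot2::aes(x = .data$rank, y = .data$fit),
      colour = "firebrick", linewidth = 0.8, inherit.aes = FALSE
    )
  }
  if (length(object$flex_points) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = object$flex_points + 0.5,
                                 colour = "grey40", linetype = "dashed")
  }
  p
}

#' Dot display of a double-clustering marker matrix
#'
#' One dot per (gene set, case sample) pair whose set score is above
#' average, with both axes in accumulating-clustering order: samples run
#' mild to severe left to right, so the rightward thickening of dots shows
#' pathways switching on as disease progresses.
#'
#' @param dbl Result of [double_cluster()].
#' @return A ggplot object.
#' @export
plot_markers <- function(dbl) {
  stopifnot(is.list(dbl), !is.null(dbl$markers))
  m <- dbl$markers
  d <- tibble::tibble(
    set = factor(rep(rownames(m), times = ncol(m)),
                 levels = rev(rownames(m))),
    sample = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    up = as.vector(m),
    rank = rep(seq_len(ncol(m)), each = nrow(m))
  )
  ggplot2::ggplot(dplyr::filter(d, .data$up),
                  ggplot2::aes(x = .data$sample, y = .data$set,
                               colour = .data$rank)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_gradient(low = "steelblue", high = "seagreen") +
    ggplot2::labs(x = "case samples (mild to severe)", y = NULL,
                  colour = "severity\nrank") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
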