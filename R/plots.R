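# ggplot2 visualisations for scan profiles, rule sets and rankings.

#' Plot a sliding-window scan profile
#'
#' Scores by window start position; known site starts, when supplied, are
#' drawn as vertical dashed marks so hits and misses are visible at a
#' glance.
#'
#' @param object A `scan_scores` tibble from [scan_sequence()].
#' @param true_starts Optional integer vector of known site starts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scan_scores
#' @export
autoplot.scan_scores <- function(object, true_starts = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$start, yend = 0),
                          colour = "grey30") +
    ggplot2::labs(x = "window start (nt)", y = "rule score") +
    ggplot2::theme_minimal()
  if (!is.null(true_starts) && length(true_starts)) {
    p <- p + ggplot2::geom_vline(xintercept = true_starts,
                                 linetype = "dashed", colour = "firebrick",
                                 alpha = 0.6)
  }
  p
}

#' Plot rule popularity
#'
#' @param object A `scored_rules` object.
#' @param ... Unused.
#' @return A ggplot object with one bar per rule (cube on the axis),
#'   ordered by score.
#' @method autoplot scored_rules
#' @export
autoplot.scored_rules <- function(object, ...) {
  df <- object$rules %>%
    mutate(cube = factor(.data$cube, levels = rev(.data$cube)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$cube)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "training popularity (score)", y = "rule cube") +
    ggplot2::theme_minimal()
}

#' Plot the RFE selection criterion of the kept variables
#'
#' @param object A `feature_ranking`.
#' @param ... Unused.
#' @return A ggplot object of squared SVM weights by selection rank.
#' @method autoplot feature_ranking
#' @export
autoplot.feature_ranking <- function(object, ...) {
  df <- tidy(object)
  df$criterion <- as.numeric(object$criterion[as.character(df$variable)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$criterion)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "RFE rank (1 = most informative)",
                  y = expression(w[i]^2)) +
    ggplot2::theme_minimal()
}
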