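# ggplot2 views of the main result objects.

#' ECDF comparison of reported and predicted affect
#'
#' Cumulative distributions of reported affect at responses and predicted
#' affect at predicted responses / nonresponses; a right-shifted
#' nonresponse curve means a receptivity trigger would under-sample
#' negative states.
#'
#' @param object An `affect_distributions`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot affect_distributions
#' @export
autoplot.affect_distributions <- function(object, ...) {
  ggplot2::ggplot(object$ecdf,
                  ggplot2::aes(x = .data$score, y = .data$cdf,
                               colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Composite affect score (13-91, higher = more negative)",
                  y = "Cumulative probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Density of predicted affect at nonresponses
#'
#' Kernel density (Silverman bandwidth) of the uncertainty-filtered
#' predicted scores at predicted nonresponses; two modes indicate the
#' two-cause mixture of ordinary-state and negative-state misses.
#'
#' @param predicted_nonresponse Numeric vector of predicted scores.
#' @return A ggplot.
#' @export
plot_nonresponse_density <- function(predicted_nonresponse) {
  ggplot2::ggplot(tibble::tibble(score = predicted_nonresponse),
                  ggplot2::aes(x = .data$score)) +
    ggplot2::geom_density(bw = "nrd0", fill = "grey80") +
    ggplot2::labs(x = "Predicted affect at nonresponses",
                  y = "Density") +
    ggplot2::theme_minimal()
}

#' Cluster receptivity and affect profile
#'
#' @param object A `cluster_profile`.
#' @param ... Unused.
#' @return A ggplot: per-cluster receptivity rate and mean composite.
#' @method autoplot cluster_profile
#' @export
autoplot.cluster_profile <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$profile[c("cluster", "receptivity_rate", "mean_composite")],
    cols = c("receptivity_rate", "mean_composite"),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$cluster),
                                  y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Cluster", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
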