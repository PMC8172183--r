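#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_line facet_wrap
#'   labs theme_minimal position_dodge autoplot
NULL

#' @export
ggplot2::autoplot

#' Scatter plot of a t-SNE embedding, colored by condition
#'
#' @param object An `eeg_embedding` from [tsne_embed()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_embedding <- function(object, ...) {
  p <- ggplot(as_tibble(object), aes(.data$dim1, .data$dim2))
  if ("condition" %in% names(object)) {
    p <- p + geom_point(aes(colour = .data$condition), alpha = 0.7, size = 1)
  } else {
    p <- p + geom_point(alpha = 0.7, size = 1)
  }
  p + labs(x = "t-SNE 1", y = "t-SNE 2") + theme_minimal()
}

#' Mean accuracy per classifier, faceted by feature set
#'
#' @param object An `eeg_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_benchmark <- function(object, ...) {
  summary <- report_benchmark(object)
  ggplot(summary, aes(.data$classifier, .data$mean_accuracy,
                      fill = .data$representation)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~ .data$feature_set) +
    labs(y = "mean 5-fold accuracy", x = NULL) +
    theme_minimal()
}

#' Training-loss trace of an autoencoder
#'
#' @param object An `eeg_autoencoder` from [ae_train()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_autoencoder <- function(object, ...) {
  ggplot(object$trace, aes(.data$epoch, .data$loss)) +
    geom_line() +
    labs(y = "reconstruction RMSE", x = "epoch") +
    theme_minimal()
}

#' Per-condition feature means with population-sd error bars
#'
#' @param features A feature tibble.
#' @return A ggplot object.
#' @export
plot_feature_summary <- function(features) {
  s <- feature_summary(features)
  ggplot(s, aes(.data$condition, .data$mean)) +
    geom_col() +
    ggplot2::geom_errorbar(aes(ymin = .data$mean - .data$sd,
                               ymax = .data$mean + .data$sd), width = 0.2) +
    facet_wrap(~ .data$feature, scales = "free_y") +
    labs(x = NULL, y = "mean ± sd") +
    theme_minimal()
}
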