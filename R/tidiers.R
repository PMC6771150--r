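#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers and plots for fitted objects and results
#'
#' Broom-style methods: `tidy()` returns the per-component tibble of an
#' object (training history for fitted networks, long-form confusion matrix
#' for a selection result, pairwise values for an FST matrix), `glance()` a
#' one-row model summary, and `autoplot()` a ggplot2 figure.
#'
#' @param x A fitted object or result.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.cnn_classifier <- function(x, ...) x$history

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.cnn_classifier <- function(x, ...) {
  tibble::tibble(n_train = x$n_train,
                 n_classes = length(x$classes),
                 epochs = nrow(x$history),
                 final_loss = x$history$loss[nrow(x$history)],
                 overall_train_accuracy =
                   x$history$accuracy[nrow(x$history)])
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.cnn_regressor <- function(x, ...) x$history

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.cnn_regressor <- function(x, ...) {
  tibble::tibble(n_train = x$n_train,
                 n_targets = length(x$parameters),
                 epochs = nrow(x$history),
                 final_loss = x$history$loss[nrow(x$history)])
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.model_selection_result <- function(x, ...) {
  d <- as.data.frame.table(x$confusion, responseName = "n")
  d$fraction <- d$n / rowSums(x$confusion)[as.character(d$true)]
  tibble::as_tibble(d)
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.model_selection_result <- function(x, ...) {
  tibble::tibble(overall_train_accuracy = x$overall_train_accuracy,
                 overall_test_accuracy = x$overall_test_accuracy,
                 n_test = x$n_test)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.fst_matrix <- function(x, ...) {
  m <- unclass(x)
  pops <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(pop1 = pops[idx[, 1]], pop2 = pops[idx[, 2]],
                 fst = m[idx])
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.pcoa_result <- function(x, ...) x$coordinates

#' @rdname tidiers
#' @exportS3Method ggplot2::autoplot
autoplot.model_selection_result <- function(x, ...) {
  d <- tidy(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$true,
                                  fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$fraction))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted scenario", y = "true scenario",
                  fill = "fraction",
                  title = sprintf("held-out accuracy %.1f%%",
                                  100 * x$overall_test_accuracy)) +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_result <- function(x, ...) {
  ggplot2::ggplot(x$coordinates,
                  ggplot2::aes(x = .data$axis1, y = .data$axis2,
                               colour = .data$pop)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PCo 1 (%.1f%%)", 100 * x$explained[1]),
                  y = sprintf("PCo 2 (%.1f%%)", 100 * x$explained[2]),
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @exportS3Method ggplot2::autoplot
autoplot.param_estimate <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$parameter, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "estimate (natural units)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
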