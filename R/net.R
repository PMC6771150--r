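#' Network configuration
#'
#' Architecture and training protocol of the convolutional network used for
#' scenario classification and parameter regression: two 3x3 convolution
#' layers with ReLU activations, each followed by max-pooling, then a ReLU
#' dense layer and a softmax (classification) or linear (regression) head,
#' trained with Adam on mini-batches. Defaults follow the study protocol of
#' 25 epochs with mini-batches of 250 images.
#'
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param task `"classify"` or `"regress"`.
#' @param filters Filter counts of the two convolution layers.
#' @param pool1,pool2 (rows, cols) max-pooling windows after each convolution.
#' @param hidden Units of the dense layer.
#' @param dropout Dropout probability on the dense layer during training
#'   (inverted dropout; 0 disables).
#' @param learning_rate Adam learning rate.
#' @param lr_decay Per-epoch multiplicative learning-rate decay (1 = none).
#' @param rng_seed Seed for weight initialization and batch shuffling; training
#'   is reproducible given it (single-threaded BLAS for bit-reproducibility).
#' @return An object of class `net_config`.
#' @export
net_config <- function(epochs = 25, batch_size = 250,
                       task = c("classify", "regress"),
                       filters = c(8, 16), pool1 = c(2, 4), pool2 = c(2, 4),
                       hidden = 64, dropout = 0.25,
                       learning_rate = 1e-3, lr_decay = 1,
                       rng_seed = 1) {
  if (epochs < 1 || batch_size < 1) {
    stop("`epochs` and `batch_size` must be >= 1", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 task = match.arg(task),
                 filters = as.integer(filters),
                 pool1 = as.integer(pool1), pool2 = as.integer(pool2),
                 hidden = as.integer(hidden),
                 dropout = dropout,
                 learning_rate = learning_rate,
                 lr_decay = lr_decay,
                 rng_seed = as.integer(rng_seed)),
            class = "net_config")
}

cpp_cfg <- function(ts, config, nout) {
  list(rows = ts$rows, cols = ts$cols, cin = ts$channels,
       f1 = config$filters[1], f2 = config$filters[2],
       p1r = config$pool1[1], p1c = config$pool1[2],
       p2r = config$pool2[1], p2c = config$pool2[2],
       hidden = config$hidden, nout = as.integer(nout),
       epochs = config$epochs, batch = config$batch_size,
       task = if (config$task == "classify") 0L else 1L,
       lr = config$learning_rate,
       lr_decay = if (is.null(config$lr_decay)) 1 else config$lr_decay,
       dropout = if (is.null(config$dropout)) 0 else config$dropout,
       seed = as.double(config$rng_seed))
}

check_tensor_shape <- function(fit, ts) {
  if (ts$rows != fit$rows || ts$cols != fit$cols ||
      ts$channels != fit$channels) {
    stop(sprintf("tensor shape %dx%dx%d does not match the fitted %dx%dx%d",
                 ts$rows, ts$cols, ts$channels,
                 fit$rows, fit$cols, fit$channels), call. = FALSE)
  }
}

as_tensor_input <- function(x, fit = NULL) {
  if (inherits(x, "snp_image")) {
    d <- dim(x)
    channels <- if (length(d) == 3L) d[3] else 1L
    x <- new_tensor_set(matrix(quantize_image(x), ncol = 1),
                        d[1], d[2], channels, NULL, NULL, NULL)
  }
  stopifnot(inherits(x, "tensor_set"))
  if (!is.null(fit)) check_tensor_shape(fit, x)
  x
}

#' Train the scenario classifier
#'
#' Fits the convolutional network to a labeled training tensor set (softmax
#' cross-entropy). Classes should be balanced; a warning is issued otherwise.
#'
#' @param train A labeled `tensor_set`.
#' @param config A [net_config()] with `task = "classify"`.
#' @return An object of class `cnn_classifier` carrying the weights, the
#'   per-epoch training history, the class labels and the input shape.
#' @export
train_classifier <- function(train, config = net_config()) {
  stopifnot(inherits(train, "tensor_set"))
  if (is.null(train$labels)) stop("`train` has no labels", call. = FALSE)
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L) {
    stop("training data contain a single class", call. = FALSE)
  }
  tab <- table(train$labels)
  if (max(tab) > 2 * min(tab)) {
    warning("classes are strongly unbalanced; accuracies may be distorted")
  }
  k <- length(classes)
  y <- matrix(0, n_images(train), k)
  y[cbind(seq_len(n_images(train)), match(train$labels, classes))] <- 1
  fit <- .cnn_train(train$x, y, cpp_cfg(train, config, k))
  structure(list(weights = fit[setdiff(names(fit), "history")],
                 history = tibble::tibble(epoch = seq_len(config$epochs),
                                          loss = fit$history[, 1],
                                          accuracy = fit$history[, 2]),
                 config = config, classes = classes,
                 rows = train$rows, cols = train$cols,
                 channels = train$channels,
                 encoder = train$config,
                 n_train = n_images(train)),
            class = "cnn_classifier")
}

#' @export
print.cnn_classifier <- function(x, ...) {
  cat(sprintf(paste0("<cnn_classifier> %d classes, %d epochs, final training",
                     " accuracy %.3f\n"),
              length(x$classes), nrow(x$history),
              x$history$accuracy[nrow(x$history)]))
  invisible(x)
}

#' @export
predict.cnn_classifier <- function(object, newdata, ...) {
  ts <- as_tensor_input(newdata, object)
  p <- .cnn_predict(object$weights, ts$x,
                    cpp_cfg(ts, object$config, length(object$classes)))
  colnames(p) <- paste0("model_", object$classes)
  p
}

#' Evaluate the classifier on a held-out tensor set
#'
#' Computes the confusion matrix over argmax predictions, per-class accuracies
#' (confusion diagonal over row sums) and the overall held-out accuracy.
#'
#' @param fit A `cnn_classifier`.
#' @param test A labeled `tensor_set`.
#' @return An object of class `model_selection_result`.
#' @export
evaluate_classifier <- function(fit, test) {
  stopifnot(inherits(fit, "cnn_classifier"))
  ts <- as_tensor_input(test, fit)
  if (is.null(ts$labels)) stop("`test` has no labels", call. = FALSE)
  p <- predict(fit, ts)
  pred <- fit$classes[max.col(p, ties.method = "first")]
  confusion <- table(factor(ts$labels, levels = fit$classes),
                     factor(pred, levels = fit$classes))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(true = fit$classes, predicted = fit$classes)
  per_class <- diag(confusion) / rowSums(confusion)
  names(per_class) <- fit$classes
  structure(list(confusion = confusion,
                 per_class_accuracy = per_class,
                 overall_test_accuracy = sum(diag(confusion)) /
                   sum(confusion),
                 overall_train_accuracy =
                   fit$history$accuracy[nrow(fit$history)],
                 n_test = sum(confusion),
                 empirical_posteriors = NULL),
            class = "model_selection_result")
}

#' @export
print.model_selection_result <- function(x, ...) {
  cat(sprintf("<model_selection_result> held-out accuracy %.3f (train %.3f)\n",
              x$overall_test_accuracy, x$overall_train_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Class posteriors for one dataset
#'
#' Applies the trained classifier to a single encoded dataset and reports the
#' softmax outputs as class posterior probabilities; the selected scenario is
#' the argmax.
#'
#' @param fit A `cnn_classifier`.
#' @param x An `snp_image` or a one-image `tensor_set` shaped like the
#'   training tensors.
#' @return A tibble with `model_id` and `posterior` (summing to 1), ordered as
#'   the classifier's classes.
#' @export
select_model <- function(fit, x) {
  stopifnot(inherits(fit, "cnn_classifier"))
  ts <- as_tensor_input(x, fit)
  p <- predict(fit, ts)
  tibble::tibble(model_id = fit$classes, posterior = as.numeric(p[1, ]))
}

# ---- parameter normalization --------------------------------------------

#' Normalization of regression targets
#'
#' Maps the four demographic parameters onto `[0, 1]`: \eqn{N_e} via log10
#' then min-max over its prior range, DT via linear min-max (its prior includes
#' 0), and the two ratios via linear min-max. RMSE computed on this scale is
#' comparable across parameters.
#'
#' @param config The [prior_config()] whose ranges define the mapping.
#' @return An object of class `param_normalization` with `normalize()` and
#'   `denormalize()` semantics via [normalize_params()] and
#'   [denormalize_params()].
#' @export
param_normalization <- function(config = prior_config()) {
  structure(list(
    ne = c(log10(config$ne_range[1]), log10(config$ne_range[2])),
    dt = config$dt_range,
    founder_ratio = config$founder_ratio_range,
    growth_ratio = config$growth_ratio_range
  ), class = "param_normalization")
}

#' @rdname param_normalization
#' @param params A data frame with columns `ne`, `dt`, `founder_ratio`,
#'   `growth_ratio`.
#' @param norm A `param_normalization`.
#' @export
normalize_params <- function(params, norm) {
  stopifnot(inherits(norm, "param_normalization"))
  mm <- function(x, r) (x - r[1]) / (r[2] - r[1])
  cbind(ne = mm(log10(params$ne), norm$ne),
        dt = mm(params$dt, norm$dt),
        founder_ratio = mm(params$founder_ratio, norm$founder_ratio),
        growth_ratio = mm(params$growth_ratio, norm$growth_ratio))
}

#' @rdname param_normalization
#' @param z A numeric matrix with the four normalized columns.
#' @export
denormalize_params <- function(z, norm) {
  stopifnot(inherits(norm, "param_normalization"))
  inv <- function(x, r) x * (r[2] - r[1]) + r[1]
  tibble::tibble(
    ne = 10^inv(z[, "ne"], norm$ne),
    dt = inv(z[, "dt"], norm$dt),
    founder_ratio = inv(z[, "founder_ratio"], norm$founder_ratio),
    growth_ratio = inv(z[, "growth_ratio"], norm$growth_ratio))
}

#' Train the parameter regressor
#'
#' Fits the same convolutional architecture with a 4-output linear head to
#' simulations of a single scenario, regressing the normalized parameters
#' (\eqn{N_e}, DT, founder ratio, growth ratio) with a mean-squared-error
#' loss.
#'
#' @param train A `tensor_set` whose `params` slot carries the generating
#'   parameters (as produced by [simulate_tensors()] under one model).
#' @param config A [net_config()]; the task is forced to `"regress"`.
#' @param norm A [param_normalization()]; defaults to the ranges of
#'   [prior_config()].
#' @return An object of class `cnn_regressor`.
#' @export
train_regressor <- function(train, config = net_config(task = "regress"),
                            norm = param_normalization()) {
  stopifnot(inherits(train, "tensor_set"))
  if (is.null(train$params)) {
    stop("`train` carries no parameter targets", call. = FALSE)
  }
  config$task <- "regress"
  y <- normalize_params(train$params, norm)
  if (anyNA(y)) stop("targets contain NA (are all images from models 3/4?)",
                     call. = FALSE)
  if (any(apply(y, 2, stats::sd) == 0)) {
    stop("at least one target is constant", call. = FALSE)
  }
  fit <- .cnn_train(train$x, y, cpp_cfg(train, config, ncol(y)))
  structure(list(weights = fit[setdiff(names(fit), "history")],
                 history = tibble::tibble(epoch = seq_len(config$epochs),
                                          loss = fit$history[, 1]),
                 config = config, norm = norm,
                 parameters = colnames(y),
                 rows = train$rows, cols = train$cols,
                 channels = train$channels,
                 encoder = train$config,
                 n_train = n_images(train)),
            class = "cnn_regressor")
}

#' @export
print.cnn_regressor <- function(x, ...) {
  cat(sprintf("<cnn_regressor> %d targets, %d epochs, final training MSE %.4g\n",
              length(x$parameters), nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
predict.cnn_regressor <- function(object, newdata, natural = FALSE, ...) {
  ts <- as_tensor_input(newdata, object)
  z <- .cnn_predict(object$weights, ts$x,
                    cpp_cfg(ts, object$config, length(object$parameters)))
  colnames(z) <- object$parameters
  if (natural) denormalize_params(z, object$norm) else z
}

#' Score regression predictions
#'
#' Per-parameter root-mean-squared error (on whatever scale the inputs are on;
#' the package reports it on the normalized scale) and Spearman's rank
#' correlation with average ranks for ties. A constant prediction vector has no
#' defined rank correlation and is reported as `NA`.
#'
#' @param predictions,truths Numeric matrices or data frames with matching
#'   columns, one row per held-out simulation (`n >= 3`).
#' @return A tibble with `parameter`, `rmse`, `spearman_rho`.
#' @export
score_regression <- function(predictions, truths) {
  predictions <- as.matrix(predictions)
  truths <- as.matrix(truths)
  if (!all(dim(predictions) == dim(truths))) {
    stop("`predictions` and `truths` must have matching dimensions",
         call. = FALSE)
  }
  if (nrow(predictions) < 3L) stop("need at least 3 rows", call. = FALSE)
  nm <- colnames(predictions)
  if (is.null(nm)) nm <- paste0("p", seq_len(ncol(predictions)))
  tibble::tibble(
    parameter = nm,
    rmse = vapply(seq_along(nm), function(j) {
      sqrt(mean((predictions[, j] - truths[, j])^2))
    }, numeric(1)),
    spearman_rho = vapply(seq_along(nm), function(j) {
      if (stats::sd(predictions[, j]) == 0 || stats::sd(truths[, j]) == 0) {
        return(NA_real_)
      }
      stats::cor(predictions[, j], truths[, j], method = "spearman")
    }, numeric(1)))
}

#' Estimate demographic parameters for one empirical dataset
#'
#' Applies the trained regressor to the encoded dataset and to `n_bootstrap`
#' re-encodings in which loci (columns) are resampled with replacement; point
#' estimates are de-normalized to natural units and summarized by the median
#' and the 2.5--97.5 percentile interval across bootstrap replicates.
#'
#' @param fit A `cnn_regressor`.
#' @param x A `genotype_matrix` or `haplotype_dataset` (the raw matrix is
#'   needed for column resampling).
#' @param n_bootstrap Number of bootstrap replicates (>= 2).
#' @param rng_seed Integer seed.
#' @return A tibble of class `param_estimate` with `parameter`, `point`,
#'   `median`, `lower`, `upper` in natural units.
#' @export
estimate_params <- function(fit, x, n_bootstrap = 100, rng_seed = NULL) {
  stopifnot(inherits(fit, "cnn_regressor"))
  if (n_bootstrap < 2) stop("`n_bootstrap` must be >= 2", call. = FALSE)
  enc <- fit$encoder
  if (is.null(enc)) {
    stop("the regressor carries no encoder configuration", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  resample_cols <- function(obj) {
    idx <- sort(sample.int(n_loci_of(obj), replace = TRUE))
    subset_loci(obj, idx)
  }
  imgs <- vector("list", n_bootstrap + 1L)
  imgs[[1]] <- matrix_to_image(x, enc)
  for (b in seq_len(n_bootstrap)) {
    imgs[[b + 1L]] <- matrix_to_image(resample_cols(x), enc)
  }
  d <- fit$rows * fit$cols * fit$channels
  xs <- vapply(imgs, quantize_image, raw(d))
  ts <- new_tensor_set(xs, fit$rows, fit$cols, fit$channels, NULL, NULL, enc)
  z <- predict(fit, ts, natural = TRUE)
  boot <- z[-1, , drop = FALSE]
  out <- tibble::tibble(
    parameter = fit$parameters,
    point = as.numeric(unlist(z[1, ])),
    median = vapply(boot, stats::median, numeric(1)),
    lower = vapply(boot, stats::quantile, numeric(1), probs = 0.025,
                   names = FALSE),
    upper = vapply(boot, stats::quantile, numeric(1), probs = 0.975,
                   names = FALSE))
  class(out) <- c("param_estimate", class(out))
  out
}

n_loci_of <- function(x) {
  if (inherits(x, "haplotype_dataset")) ncol(x$matrix)
  else if (inherits(x, "genotype_matrix")) ncol(x$genotypes)
  else stop("unsupported input", call. = FALSE)
}

subset_loci <- function(x, idx) {
  if (inherits(x, "haplotype_dataset")) {
    x$matrix <- x$matrix[, idx, drop = FALSE]
    x$positions <- x$positions[idx]
  } else {
    x$genotypes <- x$genotypes[, idx, drop = FALSE]
  }
  x
}
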