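#' Training configuration
#'
#' Adam optimization of the mean squared error (regression head) or binary
#' cross-entropy (classification head), with mean absolute error /
#' accuracy as the monitored metric, a reduce-on-plateau learning-rate
#' schedule, and best-validation-loss checkpointing (the best weights are
#' restored after the final epoch).
#'
#' @param epochs Number of epochs.
#' @param batch_size Minibatch size (64 by default).
#' @param learning_rate Initial Adam learning rate (1e-4 by default).
#' @param plateau_factor Multiplier applied to the learning rate when the
#'   validation loss fails to improve for `patience` epochs.
#' @param patience Epochs without improvement before the rate is reduced.
#' @param min_lr Lower bound for the learning rate.
#' @param seed Seed controlling shuffling (and, together with the model
#'   config seed, all training randomness).
#' @param verbose Print per-epoch progress.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 15L, batch_size = 64L,
                            learning_rate = 1e-4, plateau_factor = 0.5,
                            patience = 5L, min_lr = 1e-6, seed = 1L,
                            verbose = FALSE) {
  if (batch_size < 1L) abort("`batch_size` must be >= 1")
  if (epochs < 1L) abort("`epochs` must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 plateau_factor = plateau_factor,
                 patience = as.integer(patience),
                 min_lr = min_lr, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "training_config")
}

#' 3:1:1 train/validation/test split
#'
#' Sizes follow the 3:1:1 ratio with largest-remainder rounding (60%/20%/20%
#' exactly when N is divisible by 5); the shuffle is reproducible under the
#' seed and the three index sets are disjoint.
#'
#' @param data An `hdgs_dataset` (or an integer N).
#' @param seed Shuffle seed.
#' @return A list of integer index vectors `train`, `val`, `test`.
#' @export
split_311 <- function(data, seed = 1L) {
  n <- if (inherits(data, "hdgs_dataset")) length(data) else as.integer(data)
  if (n < 5L) abort("need at least 5 samples for a 3:1:1 split")
  quota <- n * c(train = 3, val = 1, test = 1) / 5
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, c(3, 2, 1), decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  set.seed(seed)
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(base[1])]),
       val = sort(idx[base[1] + seq_len(base[2])]),
       test = sort(idx[base[1] + base[2] + seq_len(base[3])]))
}

#' Fit a network on an encoded dataset
#'
#' Runs minibatch Adam with the loss matching the model head, evaluating the
#' validation set each epoch; the learning rate is multiplied by
#' `plateau_factor` whenever validation loss fails to improve for `patience`
#' epochs, and the weights from the best validation epoch are restored at
#' the end. Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model An `hdgs_model` (its head selects MSE or cross-entropy).
#' @param data An `hdgs_dataset`.
#' @param split A list with integer index vectors `train` and (optionally)
#'   `val`, e.g. from [split_311()]; by default all samples train with no
#'   validation monitor.
#' @param config A [training_config()].
#' @return An object of class `hdgs_fit`: the model plus the per-epoch
#'   history (see [tidy.hdgs_fit()]), `best_epoch` and `best_val_loss`.
#' @export
fit_hdgs <- function(model, data, split = NULL, config = training_config()) {
  stopifnot(inherits(model, "hdgs_model"), inherits(data, "hdgs_dataset"))
  if (is.null(split)) split <- list(train = seq_len(length(data)), val = integer(0))
  if (length(split$train) == 0) abort("empty training split")
  res <- .hdgs_train_cpp(model$ptr, data$features, data$labels,
                         as.integer(split$train) - 1L,
                         as.integer(split$val %||% integer(0)) - 1L,
                         config$epochs, config$batch_size,
                         config$learning_rate, config$plateau_factor,
                         config$patience, config$min_lr, config$seed,
                         config$verbose)
  structure(list(model = model,
                 history = as_tibble(res$history),
                 best_epoch = res$best_epoch,
                 best_val_loss = res$best_val_loss,
                 config = config),
            class = "hdgs_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hdgs_fit <- function(x, ...) {
  cat("<hdgs_fit>", nrow(x$history), "epochs; best epoch", x$best_epoch,
      "(val loss", signif(x$best_val_loss, 4), ")\n")
  invisible(x)
}

#' Tidy the training history
#'
#' @param x An `hdgs_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `lr`, `loss`, `metric`
#'   (MAE or accuracy), `val_loss`, `val_metric`.
#' @method tidy hdgs_fit
#' @export
tidy.hdgs_fit <- function(x, ...) x$history

#' One-row fit summary
#'
#' @param x An `hdgs_fit`.
#' @param ... Unused.
#' @return A tibble with `epochs`, `best_epoch`, `best_val_loss`,
#'   `final_lr`.
#' @method glance hdgs_fit
#' @export
glance.hdgs_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         best_val_loss = x$best_val_loss,
         final_lr = x$history$lr[nrow(x$history)])
}

#' Plot training curves
#'
#' @param object An `hdgs_fit`.
#' @param ... Unused.
#' @return A ggplot of training/validation loss by epoch.
#' @method autoplot hdgs_fit
#' @export
autoplot.hdgs_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history[c("epoch", "loss", "val_loss")],
                           -"epoch", names_to = "set", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL)
}

#' Stratified k-fold cross-validation of the classification head
#'
#' Builds a fresh model per fold from `model_config` (head forced to
#' classification), trains on the remaining folds and reports held-out
#' accuracy. Folds are stratified by class and reproducible under the seed.
#'
#' @param model_config An [hdgs_config()]; its head is set to
#'   `"classification"`.
#' @param data An `hdgs_dataset` whose labels are 0/1 class indicators
#'   (both classes present).
#' @param k Number of folds (default 5); must not exceed the minority class
#'   count.
#' @param seed Fold assignment seed.
#' @param config A [training_config()] used for every fold.
#' @return A tibble with one row per fold (`fold`, `n`, `accuracy`) plus
#'   attribute `"mean_accuracy"`.
#' @export
crossvalidate_classifier <- function(model_config, data, k = 5L, seed = 1L,
                                     config = training_config()) {
  stopifnot(inherits(data, "hdgs_dataset"))
  y <- data$labels
  if (!all(y %in% c(0, 1))) abort("labels must be 0/1 class indicators")
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) abort("both classes must be present")
  if (k > min(counts))
    abort(sprintf("k = %d exceeds the minority class count (%d)",
                  k, min(counts)))
  model_config$head <- "classification"
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in c(0, 1)) {
    ii <- sample(which(y == cl))
    fold[ii] <- rep_len(seq_len(k), length(ii))
  }
  rows <- lapply(seq_len(k), function(f) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    cfg <- model_config
    cfg$seed <- model_config$seed + f
    m <- hdgs_build(cfg)
    fit_hdgs(m, data, split = list(train = train_idx, val = integer(0)),
             config = config)
    pred <- .hdgs_forward_cpp(m$ptr, data$features,
                              as.integer(test_idx) - 1L, FALSE, 256L)
    tibble(fold = f, n = length(test_idx),
           accuracy = mean((pred > 0.5) == (y[test_idx] > 0.5)))
  })
  out <- bind_rows(rows)
  attr(out, "mean_accuracy") <- mean(out$accuracy)
  out
}

#' Export per-site predictions as bedGraph
#'
#' @param predictions A tibble with `chrom`, `pos`, `prediction` (e.g. from
#'   [predict.hdgs_model()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_bedgraph <- function(predictions, path) {
  readr::write_tsv(tibble(predictions$chrom, predictions$pos,
                          predictions$pos + 1L, predictions$prediction),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
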