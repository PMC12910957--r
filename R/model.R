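#' Describe one convolutional branch of a module
#'
#' @param type `"gc"` for a gated branch (linear feature path multiplied by a
#'   sigmoid gate path) or `"dc"` for a dilated branch followed by ReLU.
#' @param kernel Odd kernel width (the `K` of a 1 x K kernel).
#' @param dilation Dilation rate (tap spacing); 1 is a standard convolution.
#' @param channels Output channels of the branch.
#' @param separable Use a depthwise-separable factorization (per-channel 1 x K
#'   depthwise stage without bias, then a 1 x 1 pointwise stage with bias).
#'   Gated separable branches duplicate both stages for the gate path.
#' @return A named list describing the branch.
#' @export
hdgs_branch <- function(type = c("gc", "dc"), kernel, dilation = 1L,
                        channels, separable = FALSE) {
  type <- match.arg(type)
  kernel <- as.integer(kernel)
  dilation <- as.integer(dilation)
  channels <- as.integer(channels)
  if (kernel < 1L || kernel %% 2L == 0L)
    abort("`kernel` must be a positive odd integer (1 x K kernels are centred)")
  if (dilation < 1L) abort("`dilation` must be a positive integer")
  if (channels < 1L) abort("`channels` must be a positive integer")
  list(type = type, kernel = kernel, dilation = dilation,
       channels = channels, separable = isTRUE(separable))
}

#' Reference network configuration
#'
#' Builds the declarative description of the hybrid dilated/gated/separable
#' architecture: two levels of the five-branch Module A (1x1, 1x3, 1x7 gated;
#' 1x7 dilated at rate 3; 1x11 dilated at rate 5; 128 channels per branch),
#' the four-branch Module B (128 channels per branch), and the three-branch
#' Module C (1x1, 1x3 gated; 1x3 dilated at rate 2; 64 channels per branch,
#' K > 1 branches depthwise separable), each followed by batch normalization,
#' 40% dropout and a 1x3 stride-3 max pool, then a fully connected
#' 256 -> 32 -> 1 head. At `scale = 1` the trainable parameter count is
#' ~6.6 million and the stage shapes are 16 x 48 x 640, 16 x 16 x 640,
#' 16 x 5 x 512 and 16 x 1 x 192.
#'
#' @param scale Integer divisor applied to every channel width (convolutional
#'   branch channels and fully connected hidden widths). `scale = 8` is the
#'   desk-scale configuration used throughout the tests; the width trace is
#'   unchanged.
#' @param head `"regression"` (ReLU output, non-negative occupancy) or
#'   `"classification"` (sigmoid output in \[0, 1\]).
#' @param dropout Dropout rate applied after each module's normalization.
#' @param input_width,input_height Input feature-matrix shape (146 positions
#'   by 16 dinucleotide rows for 147-bp windows).
#' @param seed Seed for weight initialization (and dropout) in [build_hdgs()].
#' @return An object of class `hdgs_config`.
#' @export
hdgs_config <- function(scale = 1L, head = c("regression", "classification"),
                        dropout = 0.4, input_width = 146L, input_height = 16L,
                        seed = 42L) {
  head <- match.arg(head)
  scale <- as.integer(scale)
  if (scale < 1L) abort("`scale` must be a positive integer")
  chans <- c(a = 128L, b = 128L, c = 64L)
  fc <- c(256L, 32L)
  if (any(chans %% scale != 0L) || any(fc %% scale != 0L))
    abort("`scale` must divide all channel widths (128, 128, 64, 256, 32)")
  chans <- chans %/% scale
  fc <- fc %/% scale
  module_a <- list(branches = list(
    hdgs_branch("gc", 1L, 1L, chans[["a"]]),
    hdgs_branch("gc", 3L, 1L, chans[["a"]]),
    hdgs_branch("gc", 7L, 1L, chans[["a"]]),
    hdgs_branch("dc", 7L, 3L, chans[["a"]]),
    hdgs_branch("dc", 11L, 5L, chans[["a"]])))
  module_b <- list(branches = list(
    hdgs_branch("gc", 1L, 1L, chans[["b"]]),
    hdgs_branch("gc", 3L, 1L, chans[["b"]]),
    hdgs_branch("gc", 7L, 1L, chans[["b"]]),
    hdgs_branch("dc", 7L, 3L, chans[["b"]])))
  module_c <- list(branches = list(
    hdgs_branch("gc", 1L, 1L, chans[["c"]]),
    hdgs_branch("gc", 3L, 1L, chans[["c"]], separable = TRUE),
    hdgs_branch("dc", 3L, 2L, chans[["c"]], separable = TRUE)))
  structure(list(
    input_height = as.integer(input_height),
    input_width = as.integer(input_width),
    dropout = dropout,
    head = head,
    fc = as.integer(fc),
    seed = as.integer(seed),
    scale = scale,
    modules = list(module_a, module_a, module_b, module_c)
  ), class = "hdgs_config")
}

#' Build a network from a configuration
#'
#' Instantiates the compiled network described by `config` with
#' Glorot-uniform initial weights drawn deterministically from
#' `config$seed`. Fails with the offending stage name if pooling would
#' collapse the width below the 1 x 3 pooling footprint.
#'
#' @param config An [hdgs_config()] object (or a compatible list with fields
#'   `input_height`, `input_width`, `dropout`, `head`, `fc`, `seed`,
#'   `modules`).
#' @return An object of class `hdgs_model`.
#' @export
hdgs_build <- function(config) {
  stopifnot(is.list(config))
  needed <- c("input_height", "input_width", "dropout", "head", "fc",
              "seed", "modules")
  missing <- setdiff(needed, names(config))
  if (length(missing) > 0)
    abort(paste0("config lacks field(s): ", paste(missing, collapse = ", ")))
  ptr <- .hdgs_build_cpp(config)
  structure(list(ptr = ptr, config = config), class = "hdgs_model")
}

#' @export
print.hdgs_model <- function(x, ...) {
  tr <- shape_trace(x)
  cat("<hdgs_model> head:", x$config$head,
      "| trainable parameters:", format(count_parameters(x), big.mark = ","), "\n")
  cat("stage trace (width x channels):",
      paste(sprintf("%s %dx%d", tr$stage, tr$width, tr$channels), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' Counts every trainable parameter: convolution kernels and biases, gate
#' kernels and biases, depthwise/pointwise stages, batch-norm scale/shift and
#' fully connected weights and biases. Batch-norm running statistics are
#' buffers, not parameters.
#'
#' @param model An `hdgs_model`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "hdgs_model"))
  .hdgs_nparams_cpp(model$ptr)
}

#' Per-parameter manifest
#'
#' @param model An `hdgs_model`.
#' @return A tibble with one row per parameter tensor (`parameter`, `count`),
#'   suitable for export as TSV.
#' @export
parameter_manifest <- function(model) {
  stopifnot(inherits(model, "hdgs_model"))
  as_tibble(.hdgs_manifest_cpp(model$ptr))
}

#' Stage shape trace
#'
#' Width and channel count after each module's pooling stage (the input row
#' count 16 is preserved throughout since all kernels are 1 x K).
#'
#' @param model An `hdgs_model`.
#' @return A tibble with columns `stage`, `width`, `channels`.
#' @export
shape_trace <- function(model) {
  stopifnot(inherits(model, "hdgs_model"))
  as_tibble(.hdgs_shape_trace_cpp(model$ptr))
}

#' Predict occupancy for encoded samples
#'
#' @param object An `hdgs_model`.
#' @param data An `hdgs_dataset` (see [hdgs_dataset()]) or a bare
#'   `N x 16 x 146` feature array.
#' @param mode `"eval"` (deterministic: dropout off, batch-norm running
#'   statistics) or `"train"` (stochastic forward, used only for diagnostics).
#' @param ... Unused.
#' @return For an `hdgs_dataset`, a tibble `chrom`, `pos`, `strand`,
#'   `prediction` aligned to the input order; for a bare array, a numeric
#'   vector. Regression predictions are non-negative; classification
#'   predictions lie in \[0, 1\].
#' @export
predict.hdgs_model <- function(object, data, mode = c("eval", "train"), ...) {
  mode <- match.arg(mode)
  feats <- if (inherits(data, "hdgs_dataset")) data$features else data
  if (length(dim(feats)) != 3L)
    abort("features must be an N x 16 x 146 array")
  n <- dim(feats)[1]
  pred <- if (n == 0L) numeric(0) else
    .hdgs_forward_cpp(object$ptr, ensure_int_array(feats),
                      seq_len(n) - 1L, mode == "train", 128L)
  if (inherits(data, "hdgs_dataset")) {
    out <- data$coords
    out$prediction <- pred
    out
  } else {
    pred
  }
}

# features arrays are stored as integer; coerce defensively without copying
# when already integer
ensure_int_array <- function(x) {
  if (is.integer(x)) return(x)
  y <- as.integer(x)
  dim(y) <- dim(x)
  y
}

#' Extract or restore network weights
#'
#' `hdgs_weights()` returns all trainable parameters (named matrices) plus
#' batch-norm running buffers; `hdgs_set_weights()` loads them back into a
#' model built from the same configuration. Together with [saveRDS()] this is
#' the checkpoint format.
#'
#' @param model An `hdgs_model`.
#' @param weights A list as returned by `hdgs_weights()`.
#' @return `hdgs_weights()`: a list with elements `trainable` and `buffers`;
#'   `hdgs_set_weights()`: the model, invisibly.
#' @export
hdgs_weights <- function(model) {
  stopifnot(inherits(model, "hdgs_model"))
  .hdgs_get_weights_cpp(model$ptr)
}

#' @rdname hdgs_weights
#' @export
hdgs_set_weights <- function(model, weights) {
  stopifnot(inherits(model, "hdgs_model"))
  .hdgs_set_weights_cpp(model$ptr, weights)
  invisible(model)
}
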