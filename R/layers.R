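#' Dilated 1-D convolution
#'
#' Computes `(f *_l k)(x) = sum_y f(x + l*y) k(y)` with taps spaced `l`
#' positions apart. For odd kernels the taps are centred
#' (`y` in `-r..r`, `K = 2r + 1`); for even kernels they run causally
#' (`y` in `0..K-1`). With `l = 1` this is the standard convolution.
#'
#' @param f Numeric input signal.
#' @param k Numeric kernel weights.
#' @param l Dilation rate (positive integer).
#' @param padding `"valid"` (only positions where every tap is in range) or
#'   `"same"` (zero padding, output as long as the input; odd kernels only).
#' @return Numeric vector of convolution values.
#' @export
dilated_conv <- function(f, k, l = 1L, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  l <- as.integer(l)
  if (length(l) != 1L || is.na(l) || l < 1L)
    abort("dilation rate `l` must be a positive integer")
  K <- length(k)
  if (K < 1L) abort("kernel must be non-empty")
  n <- length(f)
  offs <- if (K %% 2L == 1L) l * (seq_len(K) - 1L - (K - 1L) %/% 2L) else l * (seq_len(K) - 1L)
  if (padding == "same") {
    if (K %% 2L == 0L) abort("`same` padding requires an odd kernel width")
    pad <- max(abs(offs))
    fp <- c(rep(0, pad), f, rep(0, pad))
    xs <- seq_len(n) + pad
  } else {
    lo <- 1L - min(offs)
    hi <- n - max(offs)
    if (hi < lo) return(numeric(0))
    fp <- f
    xs <- lo:hi
  }
  out <- numeric(length(xs))
  for (j in seq_len(K)) out <- out + k[j] * fp[xs + offs[j]]
  out
}

#' Gated convolution
#'
#' `Y = (X * W + b) . sigmoid(X * V + c)`: the elementwise product of a linear
#' feature path and a sigmoid-activated gate path sharing the same input. The
#' gate lies in (0, 1), so `|Y| <= |X * W + b|` everywhere.
#'
#' @param x Input: a numeric vector (single channel) or a `C_in x width`
#'   matrix.
#' @param w,v Feature and gate kernels. For vector input, numeric vectors of
#'   odd length K; for matrix input, arrays of dim `(C_out, C_in, K)`.
#' @param b,c Feature and gate biases (length `C_out`, recycled scalars
#'   allowed).
#' @param l Dilation rate shared by both paths.
#' @param padding Passed to [dilated_conv()]; the network uses `"same"`.
#' @return A numeric vector (vector input) or `C_out x width'` matrix.
#' @export
gated_conv <- function(x, w, v, b = 0, c = 0, l = 1L,
                       padding = c("same", "valid")) {
  padding <- match.arg(padding)
  vec_in <- is.null(dim(x))
  if (vec_in) {
    x <- matrix(x, nrow = 1L)
    w <- array(w, dim = c(1L, 1L, length(w)))
    v <- array(v, dim = c(1L, 1L, length(v)))
  }
  stopifnot(length(dim(w)) == 3L, length(dim(v)) == 3L,
            dim(w)[2] == nrow(x), all(dim(w) == dim(v)))
  c_out <- dim(w)[1]
  b <- rep_len(b, c_out)
  c <- rep_len(c, c_out)
  conv_path <- function(kern, bias) {
    out <- NULL
    for (o in seq_len(c_out)) {
      acc <- 0
      for (ci in seq_len(nrow(x))) {
        val <- dilated_conv(x[ci, ], kern[o, ci, ], l = l, padding = padding)
        acc <- acc + val
      }
      out <- rbind(out, acc + bias[o])
    }
    out
  }
  feat <- conv_path(w, b)
  gate <- 1 / (1 + exp(-conv_path(v, c)))
  y <- feat * gate
  if (vec_in) drop(y) else y
}

#' Depthwise-separable convolution parameter accounting
#'
#' Parameter counts of a depthwise-separable convolution: the depthwise stage
#' contributes `K^2 * C_in` (square 2-D kernels) or `K * C_in` (the 1 x K
#' kernels used here), the pointwise stage `C_in * C_out`. A full convolution
#' of the same footprint costs `K^2 * C_in * C_out` (or `K * C_in * C_out`),
#' so the factorization saves parameters whenever `K > 1` and `C_out > 1`
#' (strictly when `(K - 1) * (C_out - 1) > 1`; at `K = C_out = 2` the two
#' counts coincide). Bias terms are excluded on both sides of the
#' comparison.
#'
#' @param K Kernel size (positive integer, vectorized).
#' @param C_in,C_out Input/output channel counts (positive integers,
#'   vectorized).
#' @return A tibble with columns `K`, `C_in`, `C_out`, `depthwise_2d`,
#'   `depthwise_1d`, `pointwise`, `total_2d`, `total_1d`, `full_2d`,
#'   `full_1d`.
#' @export
separable_params <- function(K, C_in, C_out) {
  n <- max(length(K), length(C_in), length(C_out))
  K <- rep_len(as.numeric(K), n)
  C_in <- rep_len(as.numeric(C_in), n)
  C_out <- rep_len(as.numeric(C_out), n)
  if (any(K < 1 | C_in < 1 | C_out < 1) ||
      any(K != floor(K) | C_in != floor(C_in) | C_out != floor(C_out)))
    abort("K, C_in and C_out must be positive integers")
  tibble(
    K = K, C_in = C_in, C_out = C_out,
    depthwise_2d = K^2 * C_in,
    depthwise_1d = K * C_in,
    pointwise = C_in * C_out,
    total_2d = K^2 * C_in + C_in * C_out,
    total_1d = K * C_in + C_in * C_out,
    full_2d = K^2 * C_in * C_out,
    full_1d = K * C_in * C_out
  )
}
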