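# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# brute-force same-padded dilated 1-D convolution (centred odd kernel):
# out[x] = sum_y f[x + l*(y - r)] * k[y], zero outside the signal
brute_conv_same <- function(f, k, l = 1L) {
  K <- length(k)
  r <- (K - 1L) %/% 2L
  n <- length(f)
  out <- numeric(n)
  for (x in seq_len(n)) {
    acc <- 0
    for (y in seq_len(K)) {
      src <- x + l * (y - 1L - r)
      if (src >= 1L && src <= n) acc <- acc + f[src] * k[y]
    }
    out[x] <- acc
  }
  out
}

# brute-force valid dilated convolution with causal (uncentred) even taps
brute_conv_valid <- function(f, k, l = 1L) {
  K <- length(k)
  offs <- if (K %% 2L == 1L) l * (seq_len(K) - 1L - (K - 1L) %/% 2L)
          else l * (seq_len(K) - 1L)
  lo <- 1L - min(offs)
  hi <- length(f) - max(offs)
  if (hi < lo) return(numeric(0))
  vapply(lo:hi, function(x) sum(f[x + offs] * k), 0)
}

# closed-form trainable-parameter count of the reference architecture,
# summed layer by layer from the declared structure (channel widths per
# branch, full convolutions in the first three modules, depthwise-separable
# K>1 branches in the last, batch-norm scale/shift, dense 3072->256->32->1).
# `scale` divides all channel widths.
reference_param_count <- function(scale = 1) {
  ca <- 128 / scale; cb <- 128 / scale; cc <- 64 / scale
  gc_full <- function(K, cin, cout) 2 * (K * cin * cout + cout)
  dc_full <- function(K, cin, cout) K * cin * cout + cout
  sep1 <- function(K, cin, cout) K * cin + cin * cout + cout
  bn <- function(C) 2 * C
  # module A level 1 (input 1 channel) and level 2 (input 5*ca)
  a_convs <- function(cin) gc_full(1, cin, ca) + gc_full(3, cin, ca) +
    gc_full(7, cin, ca) + dc_full(7, cin, ca) + dc_full(11, cin, ca)
  b_convs <- function(cin) gc_full(1, cin, cb) + gc_full(3, cin, cb) +
    gc_full(7, cin, cb) + dc_full(7, cin, cb)
  c_convs <- function(cin) gc_full(1, cin, cc) + 2 * sep1(3, cin, cc) +
    sep1(3, cin, cc)
  flat <- 16 * 1 * (3 * cc)
  fc1 <- 256 / scale; fc2 <- 32 / scale
  dense <- flat * fc1 + fc1 + fc1 * fc2 + fc2 + fc2 * 1 + 1
  2 +                                  # input-level batch norm
    a_convs(1) + bn(5 * ca) +
    a_convs(5 * ca) + bn(5 * ca) +
    b_convs(5 * ca) + bn(4 * cb) +
    c_convs(4 * cb) + bn(3 * cc) +
    dense
}

# textbook Pearson correlation
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  num / den
}

# random ACGT string under the current RNG state
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
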