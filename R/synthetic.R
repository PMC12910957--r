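#' Synthetic data specification
#'
#' Parameters of the synthetic genome/occupancy generator used to exercise
#' the whole pipeline without downloads. The genome is a concatenation of
#' GC-content blocks (geometric lengths); occupancy follows a lognormal
#' model in which the latent log-occupancy of each 147-bp window rises with
#' its GC-type dinucleotide frequency and falls with its AT-type frequency,
#' reproducing the left-skewed, non-negative occupancy distribution and the
#' GC/AT composition contrast that the real maps show. The default effect
#' weights (alpha = beta = 2 with noise 0.3) are calibrated so the
#' normalized track looks like a real dMean map: values spanning roughly
#' 0-4 around a genome mean of 1, with fewer than 5% of positions above the
#' boxplot outlier threshold. This is declared test infrastructure, not a
#' biological claim.
#'
#' @param genome_length Bases per chromosome.
#' @param block_mean_length Mean GC-block length (geometric), bases.
#' @param gc_range Range to which the Beta(2,2)-distributed block GC
#'   content is rescaled.
#' @param alpha Weight of the GC-type dinucleotide frequency (GG/CC/GC/CG)
#'   in the latent log-occupancy.
#' @param beta Weight (negative sign) of the AT-type frequency
#'   (AA/TT/AT/TA).
#' @param noise_sd Standard deviation of the lognormal noise.
#' @param read_depth Optional Poisson read-sampling depth (reads per unit
#'   occupancy); `NULL` keeps the noiseless-count track.
#' @param n_tss Number of TSS annotations to place.
#' @param chroms Chromosome names to generate.
#' @param seed Master seed; all stages derive from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(genome_length = 200000L, block_mean_length = 500L,
                           gc_range = c(0.2, 0.8), alpha = 2, beta = 2,
                           noise_sd = 0.3, read_depth = NULL, n_tss = 20L,
                           chroms = "chr1", seed = 1L) {
  if (genome_length < 1L) abort("`genome_length` must be positive")
  if (block_mean_length < 1L) abort("`block_mean_length` must be positive")
  if (length(gc_range) != 2L || gc_range[1] > gc_range[2] ||
      gc_range[1] <= 0 || gc_range[2] >= 1)
    abort("`gc_range` must be an increasing pair inside (0, 1)")
  if (alpha < 0 || beta < 0 || noise_sd < 0) abort("weights and noise_sd must be >= 0")
  structure(list(genome_length = as.integer(genome_length),
                 block_mean_length = as.integer(block_mean_length),
                 gc_range = gc_range, alpha = alpha, beta = beta,
                 noise_sd = noise_sd, read_depth = read_depth,
                 n_tss = as.integer(n_tss), chroms = chroms,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a block-structured synthetic genome
#'
#' Each chromosome is a concatenation of blocks with geometric lengths
#' (mean `block_mean_length`); within a block, bases are independent with
#' `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`, where the block GC
#' content is Beta(2,2) rescaled to `gc_range`. Fully reproducible under
#' the generator seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A genome tibble (`chrom`, `seq`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  rows <- lapply(seq_along(spec$chroms), function(ci) {
    L <- spec$genome_length
    n_blocks <- ceiling(2 * L / spec$block_mean_length) + 10L
    lens <- rgeom(n_blocks, 1 / spec$block_mean_length) + 1L
    while (sum(lens) < L)
      lens <- c(lens, rgeom(n_blocks, 1 / spec$block_mean_length) + 1L)
    lens <- lens[cumsum(lens) - lens < L]
    gcs <- spec$gc_range[1] + diff(spec$gc_range) * rbeta(length(lens), 2, 2)
    gc_per_base <- rep(gcs, times = lens)[seq_len(L)]
    u <- runif(L)
    v <- runif(L)
    base <- ifelse(u < gc_per_base,
                   ifelse(v < 0.5, "G", "C"),
                   ifelse(v < 0.5, "A", "T"))
    tibble(chrom = spec$chroms[ci], seq = paste(base, collapse = ""))
  })
  bind_rows(rows)
}

# rolling window dinucleotide-class frequencies: for every in-bounds centre
# p (0-based), the fraction of GC-type / AT-type dinucleotides among the 146
# dinucleotides of the 147-bp window [p - flank, p + flank]
window_class_freq <- function(seq, flank = 73L) {
  b <- base_codes(seq)
  dc <- dinuc_codes(b)
  gc_codes <- match(GC_TYPE, DINUCS) - 1L
  at_codes <- match(AT_TYPE, DINUCS) - 1L
  is_gc <- as.integer(dc %in% gc_codes)
  is_at <- as.integer(dc %in% at_codes)
  width <- 2L * flank
  cs_gc <- cumsum(c(0L, is_gc))
  cs_at <- cumsum(c(0L, is_at))
  L <- length(b)
  centers <- flank:(L - 1L - flank)
  i0 <- centers - flank # 0-based index of first dinuc in window
  tibble(pos = centers,
         f_gc = (cs_gc[i0 + width + 1L] - cs_gc[i0 + 1L]) / width,
         f_at = (cs_at[i0 + width + 1L] - cs_at[i0 + 1L]) / width)
}

#' Generate a synthetic occupancy track for a genome
#'
#' For every centre p with a full 147-bp window, the latent signal is
#' `s(p) = alpha * f_GC(p) - beta * f_AT(p)` (window frequencies of
#' GC-type and AT-type dinucleotides); occupancy is
#' `exp(s(p) + eps)`, `eps ~ N(0, noise_sd^2)` i.i.d., optionally passed
#' through `reads ~ Poisson(read_depth * occupancy) / read_depth`. The
#' first and last 73 bases carry occupancy 0 and are flagged uncovered; the
#' final track is dMean-normalized (covered mean exactly 1).
#'
#' @param genome A genome tibble (each chromosome >= 147 bases).
#' @param spec A [synthetic_spec()].
#' @return A normalized occupancy track.
#' @export
generate_occupancy <- function(genome, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (any(nchar(genome$seq) < 147L))
    abort("every chromosome must be at least one 147-bp window long")
  set.seed(spec$seed + 1L)
  vals <- list(); cov <- list()
  for (i in seq_len(nrow(genome))) {
    L <- nchar(genome$seq[i])
    wf <- window_class_freq(genome$seq[i])
    s <- spec$alpha * wf$f_gc - spec$beta * wf$f_at
    occ <- exp(s + rnorm(length(s), 0, spec$noise_sd))
    if (!is.null(spec$read_depth))
      occ <- rpois(length(occ), spec$read_depth * occ) / spec$read_depth
    v <- numeric(L)
    cv <- logical(L)
    v[wf$pos + 1L] <- occ
    cv[wf$pos + 1L] <- TRUE
    vals[[genome$chrom[i]]] <- v
    cov[[genome$chrom[i]]] <- cv
  }
  dmean_normalize(new_track(genome$chrom, vals, cov, normalized = FALSE))
}

#' Place synthetic TSS annotations
#'
#' TSS positions are uniform with at least 1000 bp clearance from both
#' chromosome ends (so the full ±1000 bp window grid fits), with random
#' strand, reproducible under the generator seed.
#'
#' @param genome A genome tibble.
#' @param spec A [synthetic_spec()] (`n_tss` sites per chromosome).
#' @return A site tibble (`chrom`, `pos`, `strand`) sorted by position.
#' @export
generate_tss <- function(genome, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  clearance <- 1000L + 73L
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    L <- nchar(genome$seq[i])
    if (L < 2L * clearance + 1L)
      abort(sprintf("chromosome %s too short for ±1000 bp TSS clearance",
                    genome$chrom[i]))
    pos <- sort(sample(seq.int(clearance, L - 1L - clearance), spec$n_tss,
                       replace = FALSE))
    tibble(chrom = genome$chrom[i], pos = pos,
           strand = sample(c("+", "-"), spec$n_tss, replace = TRUE))
  })
  bind_rows(rows)
}
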