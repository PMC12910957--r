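#' Boxplot statistics of occupancy values
#'
#' Quartiles are computed by linear interpolation between order statistics
#' (the standard type-7 rule); the outlier threshold is the boxplot whisker
#' `Q3 + 1.5 * IQR` used to split high-occupancy positions from the bulk of
#' the distribution.
#'
#' @param values Numeric vector (>= 4 finite values).
#' @return A one-row tibble with `q1`, `q2`, `q3`, `iqr`,
#'   `outlier_threshold`.
#' @export
boxplot_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) abort("need at least 4 finite values")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  tibble(q1 = q[1], q2 = q[2], q3 = q[3], iqr = q[3] - q[1],
         outlier_threshold = q[3] + 1.5 * (q[3] - q[1]))
}

#' Per-chromosome boxplot statistics of a track
#'
#' @param track An occupancy track; only covered bases are used.
#' @return A tibble with one row per chromosome and the [boxplot_stats()]
#'   columns.
#' @export
track_boxplot_stats <- function(track) {
  tr <- track[track$covered, , drop = FALSE]
  bind_rows(lapply(unique(tr$chrom), function(ch) {
    dplyr::bind_cols(tibble(chrom = ch),
                     boxplot_stats(tr$value[tr$chrom == ch]))
  }))
}

#' Stratified sampling policy
#'
#' "1:k" sampling retains one site per k eligible sites. Systematic mode
#' keeps every k-th eligible position in coordinate order (exactly
#' `ceiling(n/k)` sites per stratum); Bernoulli mode keeps each with
#' probability 1/k under the seed.
#'
#' @param high_ratio Sampling ratio k for the high-occupancy stratum
#'   (default 3, i.e. 1:3).
#' @param normal_ratio Sampling ratio k for the remaining positions
#'   (default 30, i.e. 1:30).
#' @param mode `"systematic"` or `"bernoulli"`.
#' @param seed Seed for Bernoulli mode.
#' @return A `stratification_policy` list.
#' @export
stratification_policy <- function(high_ratio = 3L, normal_ratio = 30L,
                                  mode = c("systematic", "bernoulli"),
                                  seed = 1L) {
  mode <- match.arg(mode)
  high_ratio <- as.integer(high_ratio)
  normal_ratio <- as.integer(normal_ratio)
  if (is.na(high_ratio) || high_ratio < 1L || is.na(normal_ratio) ||
      normal_ratio < 1L)
    abort("sampling ratios must be integers >= 1")
  structure(list(high_ratio = high_ratio, normal_ratio = normal_ratio,
                 mode = mode, seed = as.integer(seed)),
            class = "stratification_policy")
}

#' Stratified site selection from an occupancy track
#'
#' Positions with occupancy strictly above the boxplot outlier threshold
#' form the high stratum and are sampled at 1:`high_ratio`; all other
#' covered positions are sampled at 1:`normal_ratio`. Statistics are taken
#' per chromosome by default (each chromosome gets its own threshold), or
#' globally.
#'
#' @param track A dMean-normalized occupancy track.
#' @param policy A [stratification_policy()].
#' @param stats Optional precomputed statistics: a [track_boxplot_stats()]
#'   tibble (per-chromosome) or a [boxplot_stats()] row (global).
#' @param per_chromosome Compute thresholds per chromosome (default) or from
#'   the pooled values.
#' @return A tibble `chrom`, `pos`, `stratum` sorted by (chrom, pos).
#' @export
stratified_select <- function(track, policy = stratification_policy(),
                              stats = NULL, per_chromosome = TRUE) {
  if (!inherits(policy, "stratification_policy"))
    abort("`policy` must be a stratification_policy()")
  if (!is_normalized(track)) abort("track must be dMean-normalized first")
  tr <- track[track$covered, , drop = FALSE]
  if (is.null(stats)) {
    stats <- if (per_chromosome) track_boxplot_stats(track)
             else boxplot_stats(tr$value)
  }
  thr_for <- function(ch) {
    if ("chrom" %in% names(stats)) {
      i <- match(ch, stats$chrom)
      if (is.na(i)) abort(paste0("no statistics for chromosome ", ch))
      stats$outlier_threshold[i]
    } else stats$outlier_threshold[1]
  }
  if (policy$mode == "bernoulli") set.seed(policy$seed)
  pick <- function(pos, k) {
    n <- length(pos)
    if (n == 0L) return(integer(0))
    if (policy$mode == "systematic") pos[seq.int(1L, n, by = k)]
    else pos[runif(n) < 1 / k]
  }
  out <- lapply(unique(tr$chrom), function(ch) {
    sub <- tr[tr$chrom == ch, , drop = FALSE]
    thr <- thr_for(ch)
    hi <- sub$pos[sub$value > thr]
    no <- sub$pos[sub$value <= thr]
    bind_rows(tibble(chrom = ch, pos = pick(hi, policy$high_ratio),
                     stratum = "high"),
              tibble(chrom = ch, pos = pick(no, policy$normal_ratio),
                     stratum = "normal"))
  })
  arrange(bind_rows(out), .data$chrom, .data$pos)
}

#' Leakage-free train/test partition of sites
#'
#' Splits sites into train and test sets with mutually exclusive genomic
#' coordinates: either whole chromosomes are held out, or a fraction of
#' coordinates is held out under a seed.
#'
#' @param sites Tibble with `chrom`, `pos`; must be unique by (chrom, pos).
#' @param holdout_chroms Character vector of chromosomes to hold out.
#' @param holdout_fraction Alternatively, the fraction of sites to hold out.
#' @param seed Seed for fraction mode.
#' @return A list with elements `train` and `test` (site tibbles).
#' @export
partition_holdout <- function(sites, holdout_chroms = NULL,
                              holdout_fraction = NULL, seed = 1L) {
  sites <- as_tibble(sites)
  if (anyDuplicated(sites[c("chrom", "pos")]))
    abort("sites must be unique by (chrom, pos)")
  if (is.null(holdout_chroms) == is.null(holdout_fraction))
    abort("give exactly one of `holdout_chroms` or `holdout_fraction`")
  if (!is.null(holdout_chroms)) {
    missing <- setdiff(holdout_chroms, unique(sites$chrom))
    if (length(missing) > 0)
      abort(paste0("holdout chromosome(s) absent: ",
                   paste(missing, collapse = ", ")))
    test <- sites$chrom %in% holdout_chroms
  } else {
    if (holdout_fraction <= 0 || holdout_fraction >= 1)
      abort("`holdout_fraction` must be in (0, 1)")
    set.seed(seed)
    n_test <- round(nrow(sites) * holdout_fraction)
    test <- logical(nrow(sites))
    test[sample.int(nrow(sites), n_test)] <- TRUE
  }
  list(train = sites[!test, , drop = FALSE],
       test = sites[test, , drop = FALSE])
}

#' Remove sites falling in blacklist regions
#'
#' @param sites Tibble with `chrom`, `pos`.
#' @param blacklist Tibble with `chrom`, `start`, `end` (0-based half-open
#'   intervals).
#' @return Sites outside every blacklist interval; the number removed is in
#'   attribute `"removed"`.
#' @export
exclude_regions <- function(sites, blacklist) {
  sites <- as_tibble(sites)
  blacklist <- as_tibble(blacklist)
  if (nrow(blacklist) > 0 && any(blacklist$end <= blacklist$start))
    abort("malformed blacklist interval (end <= start)")
  drop <- logical(nrow(sites))
  for (i in seq_len(nrow(blacklist)))
    drop <- drop | (sites$chrom == blacklist$chrom[i] &
                      sites$pos >= blacklist$start[i] &
                      sites$pos < blacklist$end[i])
  out <- sites[!drop, , drop = FALSE]
  attr(out, "removed") <- sum(drop)
  out
}
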