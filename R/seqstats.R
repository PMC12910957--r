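#' Dinucleotide class table
#'
#' Classifies the 16 dinucleotides the way occupancy analyses group them:
#' GC-type (GG, CC, GC, CG; favour nucleosome binding), AT-type (AA, TT,
#' AT, TA; disfavour it) and mixed (one strong + one weak base).
#'
#' @return A tibble with columns `dinuc`, `class`.
#' @export
dinucleotide_classes <- function() {
  tibble(dinuc = DINUCS,
         class = dplyr::case_when(DINUCS %in% GC_TYPE ~ "gc_type",
                                  DINUCS %in% AT_TYPE ~ "at_type",
                                  TRUE ~ "mixed"))
}

new_groups <- function(value, group, levels, method) {
  structure(tibble(id = seq_along(value), value = value,
                   group = factor(group, levels = levels)),
            method = method,
            class = c("occupancy_groups", class(tibble())))
}

#' Quartile high/low occupancy grouping
#'
#' High group: values strictly above Q3; low group: strictly below Q1; the
#' middle half is left unassigned and excluded from composition contrasts.
#' Quartiles use the type-7 interpolation rule.
#'
#' @param values Numeric occupancy values (>= 8).
#' @return An `occupancy_groups` tibble (`id`, `value`, `group` with levels
#'   high > low; middle values have `NA` group).
#' @export
group_by_quartile <- function(values) {
  if (length(values) < 8L) abort("need at least 8 values")
  q <- quantile(values, c(0.25, 0.75), type = 7)
  if (q[1] == q[2]) abort("degenerate distribution: Q1 equals Q3")
  grp <- ifelse(values > q[2], "high", ifelse(values < q[1], "low", NA))
  g <- new_groups(values, grp, c("high", "low"), "quartile")
  attr(g, "q1") <- unname(q[1]); attr(g, "q3") <- unname(q[2])
  g
}

#' K-means occupancy grouping (k = 3)
#'
#' One-dimensional k-means into three clusters, relabelled
#' high/medium/low by descending cluster centre; deterministic under the
#' seed.
#'
#' @param values Numeric occupancy values with >= 3 distinct values.
#' @param seed RNG seed for the k-means starts.
#' @return An `occupancy_groups` tibble with levels high > medium > low.
#' @export
group_by_kmeans3 <- function(values, seed = 1L) {
  if (length(unique(values)) < 3L) abort("need at least 3 distinct values")
  set.seed(seed)
  km <- kmeans(values, centers = 3L, nstart = 10L)
  ord <- order(km$centers[, 1], decreasing = TRUE)
  lab <- c("high", "medium", "low")[match(km$cluster, ord)]
  new_groups(values, lab, c("high", "medium", "low"), "kmeans3")
}

#' Decile occupancy grouping
#'
#' Sorts by occupancy in descending order and splits into ten contiguous
#' groups G1 (highest) .. G10 (lowest) whose sizes differ by at most one;
#' ties are broken by original position (value descending, index
#' ascending). Any extra elements go to the highest groups.
#'
#' @param values Numeric occupancy values (>= 10).
#' @return An `occupancy_groups` tibble with levels G1..G10.
#' @export
group_by_decile <- function(values) {
  n <- length(values)
  if (n < 10L) abort("need at least 10 values")
  sizes <- rep(n %/% 10L, 10L)
  extra <- n %% 10L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(-values, seq_len(n))
  grp <- character(n)
  grp[ord] <- rep(paste0("G", 1:10), times = sizes)
  new_groups(values, grp, paste0("G", 1:10), "decile")
}

#' Pooled mono- and dinucleotide composition of a sequence group
#'
#' @param seqs Non-empty character vector of equal-length ACGT sequences.
#' @return A list with tibbles `mono` (`base`, `freq`; sums to 1) and `di`
#'   (`dinuc`, `freq`; sums to 1).
#' @export
composition <- function(seqs) {
  if (length(seqs) == 0) abort("empty sequence group")
  L <- nchar(seqs)
  if (length(unique(L)) != 1L) abort("sequences must have equal length")
  codes <- lapply(seqs, base_codes)
  if (anyNA(unlist(codes))) abort("sequences must be ACGT only")
  bc <- tabulate(unlist(codes) + 1L, 4L)
  dc <- tabulate(unlist(lapply(codes, dinuc_codes)) + 1L, 16L)
  list(mono = tibble(base = BASES, freq = bc / sum(bc)),
       di = tibble(dinuc = DINUCS, freq = dc / sum(dc)))
}

#' Positional dinucleotide frequency matrix
#'
#' For a group of 147-bp sequences, entry (d, j) is the fraction of group
#' members whose dinucleotide at position j is d; every column sums to 1.
#' This is the matrix behind the positional frequency heatmaps (a single
#' sequence gives back its own one-hot encoding).
#'
#' @param seqs Character vector of 147-bp ACGT sequences.
#' @param width Expected sequence length (147).
#' @return A 16 x (width - 1) matrix of class `freq_matrix` (rownames
#'   AA..TT).
#' @export
positional_matrix <- function(seqs, width = 147L) {
  if (length(seqs) == 0) abort("empty sequence group")
  if (any(nchar(seqs) != width))
    abort(sprintf("all sequences must have length %d", width))
  m <- matrix(0, nrow = 16L, ncol = width - 1L,
              dimnames = list(DINUCS, NULL))
  for (s in seqs) {
    b <- base_codes(s)
    if (anyNA(b)) abort("sequences must be ACGT only")
    w <- dinuc_codes(b)
    ix <- cbind(w + 1L, seq_len(width - 1L))
    m[ix] <- m[ix] + 1
  }
  structure(m / length(seqs), class = c("freq_matrix", "matrix", "array"))
}

#' Heatmap of a positional frequency matrix
#'
#' @param object A `freq_matrix`.
#' @param ... Unused.
#' @return A ggplot tile heatmap (dinucleotides by position).
#' @method autoplot freq_matrix
#' @export
autoplot.freq_matrix <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(unclass(object)), dinuc = rownames(object)),
    -"dinuc", names_to = "position", values_to = "freq")
  df$position <- as.integer(sub("^V", "", df$position))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$dinuc,
                                   fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "position", y = NULL, fill = "freq")
}

#' Write a frequency matrix as TSV
#'
#' @param m A `freq_matrix` (or any matrix with rownames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(unclass(m))
  names(df) <- paste0("pos", seq_len(ncol(df)))
  readr::write_tsv(dplyr::bind_cols(tibble(dinuc = rownames(m)), df), path,
                   progress = FALSE)
  invisible(path)
}

#' Two-proportion enrichment test
#'
#' Two-sided two-proportion z-test (continuity-uncorrected) for the
#' enrichment of a nucleotide feature in group A versus group B.
#'
#' @param count_a,n_a Feature count and total in group A.
#' @param count_b,n_b Feature count and total in group B.
#' @return An object of class `htest` with the z statistic and p-value.
#' @export
enrichment_test <- function(count_a, n_a, count_b, n_b) {
  if (n_a <= 0 || n_b <= 0) abort("group totals must be positive")
  if (count_a > n_a || count_b > n_b) abort("counts cannot exceed totals")
  p1 <- count_a / n_a
  p2 <- count_b / n_b
  pp <- (count_a + count_b) / (n_a + n_b)
  se <- sqrt(pp * (1 - pp) * (1 / n_a + 1 / n_b))
  if (se == 0) {
    z <- 0
    p <- 1
  } else {
    z <- (p1 - p2) / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(prop_a = p1, prop_b = p2),
                 method = "two-proportion z-test (uncorrected, two-sided)",
                 data.name = sprintf("%d/%d vs %d/%d",
                                     count_a, n_a, count_b, n_b)),
            class = "htest")
}
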