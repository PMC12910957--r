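#' Pearson correlation coefficient
#'
#' Standard product-moment correlation, with explicit errors for the
#' degenerate cases where the coefficient is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 2, each non-constant.
#' @return The correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2L) abort("need at least 2 observations")
  if (sd(x) == 0 || sd(y) == 0)
    abort("correlation undefined for a constant vector")
  cor(x, y, method = "pearson")
}

#' Per-chromosome evaluation of predictions against a track
#'
#' Mirrors the genome-wide evaluation tables: a Pearson correlation per
#' chromosome between predicted and experimental occupancy, the unweighted
#' mean correlation over the non-excluded chromosomes, and MAE / R^2 pooled
#' over all non-excluded sites. Excluded chromosomes (e.g. ones with known
#' systematic bias) keep their per-chromosome r but do not enter the
#' summaries.
#'
#' @param predictions Tibble with `chrom`, `pos`, `prediction`.
#' @param track The dMean-normalized truth track.
#' @param excluded Character vector of chromosomes left out of the mean.
#' @param weighted Use a site-weighted mean of per-chromosome r instead of
#'   the unweighted mean.
#' @return An object of class `hdgs_eval` with elements `per_chromosome`
#'   (tibble `chrom`, `n`, `r`, `excluded`), `mean_r`, `mae`, `r2`,
#'   `excluded`.
#' @export
evaluate_by_chromosome <- function(predictions, track, excluded = character(),
                                   weighted = FALSE) {
  stopifnot(all(c("chrom", "pos", "prediction") %in% names(predictions)))
  if (!is_normalized(track)) abort("track must be dMean-normalized")
  dense <- track_dense(track)
  predictions <- as_tibble(predictions)
  predictions$truth <- vapply(seq_len(nrow(predictions)), function(i) {
    dense[[predictions$chrom[i]]][predictions$pos[i] + 1L]
  }, 0)
  per <- lapply(unique(predictions$chrom), function(ch) {
    sub <- predictions[predictions$chrom == ch, , drop = FALSE]
    r <- if (nrow(sub) < 2L || sd(sub$prediction) == 0 || sd(sub$truth) == 0) {
      warn(paste0("chromosome ", ch,
                  ": correlation undefined (too few or constant values); skipped"))
      NA_real_
    } else {
      cor(sub$prediction, sub$truth)
    }
    tibble(chrom = ch, n = nrow(sub), r = r, excluded = ch %in% excluded)
  })
  per <- bind_rows(per)
  used <- per[!per$excluded & !is.na(per$r), , drop = FALSE]
  mean_r <- if (weighted) sum(used$r * used$n) / sum(used$n) else mean(used$r)
  keep <- !(predictions$chrom %in% excluded)
  err <- predictions$prediction[keep] - predictions$truth[keep]
  truth <- predictions$truth[keep]
  structure(list(per_chromosome = per,
                 mean_r = mean_r,
                 mae = mean(abs(err)),
                 r2 = 1 - sum(err^2) / sum((truth - mean(truth))^2),
                 excluded = excluded),
            class = "hdgs_eval")
}

#' @export
print.hdgs_eval <- function(x, ...) {
  cat("<hdgs_eval> mean r =", signif(x$mean_r, 4),
      "| MAE =", signif(x$mae, 4), "| R2 =", signif(x$r2, 4), "\n")
  print(x$per_chromosome)
  invisible(x)
}

#' Per-chromosome evaluation rows
#'
#' @param x An `hdgs_eval`.
#' @param ... Unused.
#' @return The per-chromosome tibble (`chrom`, `n`, `r`, `excluded`), the
#'   same layout as the genome-wide correlation tables.
#' @method tidy hdgs_eval
#' @export
tidy.hdgs_eval <- function(x, ...) x$per_chromosome

#' One-row evaluation summary
#'
#' @param x An `hdgs_eval`.
#' @param ... Unused.
#' @return A tibble with `mean_r`, `mae`, `r2`, `n_chromosomes`.
#' @method glance hdgs_eval
#' @export
glance.hdgs_eval <- function(x, ...) {
  tibble(mean_r = x$mean_r, mae = x$mae, r2 = x$r2,
         n_chromosomes = sum(!x$per_chromosome$excluded))
}

#' Plot per-chromosome correlations
#'
#' @param object An `hdgs_eval`.
#' @param ... Unused.
#' @return A ggplot bar chart of r by chromosome.
#' @method autoplot hdgs_eval
#' @export
autoplot.hdgs_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_chromosome,
                  ggplot2::aes(.data$chrom, .data$r, fill = .data$excluded)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Pearson r", fill = "excluded")
}
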