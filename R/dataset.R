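#' Encoded sample container
#'
#' Bundles the three parallel arrays of an encoded dataset: binary
#' dinucleotide one-hot feature matrices (`N x 16 x 146`), regression or
#' classification labels, and genomic coordinates. The three components must
#' agree on N.
#'
#' @param features Integer (0/1) array of dim `N x 16 x 146`.
#' @param labels Numeric vector of length N, non-negative.
#' @param coords Tibble with N rows and columns `chrom`, `pos`, `strand`
#'   (extra columns such as TSS offsets are preserved).
#' @return An object of class `hdgs_dataset`.
#' @export
hdgs_dataset <- function(features, labels, coords) {
  d <- dim(features)
  if (length(d) != 3L)
    abort("`features` must be a 3-d array (N x 16 x 146)")
  if (d[2] != 16L || !(d[3] >= 1L))
    abort("`features` must have 16 dinucleotide rows")
  n <- d[1]
  if (length(labels) != n)
    abort(sprintf("labels (%d) and features (%d) disagree on N",
                  length(labels), n))
  if (any(labels < 0)) abort("labels must be non-negative")
  coords <- as_tibble(coords)
  if (nrow(coords) != n)
    abort(sprintf("coords (%d) and features (%d) disagree on N",
                  nrow(coords), n))
  if (!all(c("chrom", "pos", "strand") %in% names(coords)))
    abort("coords needs columns chrom, pos, strand")
  structure(list(features = ensure_int_array(features),
                 labels = as.numeric(labels),
                 coords = coords),
            class = "hdgs_dataset")
}

#' @export
print.hdgs_dataset <- function(x, ...) {
  d <- dim(x$features)
  cat("<hdgs_dataset>", d[1], "samples,", d[2], "x", d[3], "feature matrices\n")
  invisible(x)
}

#' @export
length.hdgs_dataset <- function(x) dim(x$features)[1]

#' Subset an encoded dataset by sample index
#'
#' @param data An `hdgs_dataset`.
#' @param idx Integer indices (1-based), order-preserving.
#' @return The subsetted `hdgs_dataset`.
#' @export
dataset_subset <- function(data, idx) {
  stopifnot(inherits(data, "hdgs_dataset"))
  hdgs_dataset(data$features[idx, , , drop = FALSE],
               data$labels[idx],
               data$coords[idx, , drop = FALSE])
}

#' Concatenate encoded datasets
#'
#' @param ... `hdgs_dataset` objects with identical feature dimensions.
#' @return One combined `hdgs_dataset` in argument order.
#' @export
dataset_bind <- function(...) {
  ds <- list(...)
  stopifnot(length(ds) > 0, all(vapply(ds, inherits, TRUE, "hdgs_dataset")))
  dims <- vapply(ds, function(d) dim(d$features)[2:3], integer(2))
  if (!all(dims == dims[, 1])) abort("feature dimensions differ")
  n <- vapply(ds, length, 0L)
  out <- array(0L, c(sum(n), dims[1, 1], dims[2, 1]))
  at <- 0L
  for (d in ds) {
    if (length(d) > 0) out[at + seq_len(length(d)), , ] <- d$features
    at <- at + length(d)
  }
  hdgs_dataset(out, unlist(lapply(ds, `[[`, "labels")),
               bind_rows(lapply(ds, `[[`, "coords")))
}

#' Write / read an encoded dataset container
#'
#' The container is serialized with all three parallel arrays
#' (`/features`, `/labels`, `/coords`) plus a format version; a write
#' followed by a read is bit-identical. Reading a file that lacks any of the
#' three components is an error.
#'
#' @param data An `hdgs_dataset`.
#' @param path File path.
#' @return `write_dataset()`: `path` invisibly; `read_dataset()`: the
#'   `hdgs_dataset`.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "hdgs_dataset"))
  saveRDS(list(format = "hdgs_dataset", version = 1L,
               features = data$features, labels = data$labels,
               coords = data$coords),
          path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  obj <- readRDS(path)
  missing <- setdiff(c("features", "labels", "coords"), names(obj))
  if (length(missing) > 0)
    abort(paste0(path, ": dataset container lacks component(s): ",
                 paste(missing, collapse = ", ")))
  hdgs_dataset(obj$features, obj$labels, obj$coords)
}
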