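#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercase-normalized; any symbol outside A/C/G/T is mapped
#' to N. Windows containing N are rejected downstream by the encoder, which
#' has no N channel.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with columns `chrom` (record identifier, first word of
#'   the header) and `seq`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) abort(paste0(path, ": empty FASTA file (line 1)"))
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">"))
    abort(paste0(path, ": line ", first, ": expected a '>' FASTA header"))
  # read as raw letters first: the DNA reader would silently drop symbols
  # outside its alphabet, but they must be preserved (as N)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) abort(paste0(path, ": no sequence records (line 1)"))
  if (any(Biostrings::width(ss) == 0))
    abort(paste0(path, ": record '", names(ss)[Biostrings::width(ss) == 0][1],
                 "' has an empty sequence"))
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  tibble(chrom = vapply(strsplit(names(ss), "\\s+"), `[`, "", 1),
         seq = unname(seqs))
}

#' Write genome sequences to FASTA
#'
#' @param genome A tibble with columns `chrom`, `seq`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(setNames(genome$seq, genome$chrom))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# internal constructor for the per-base occupancy track representation:
# a tibble chrom/pos/value/covered with 0-based contiguous positions per
# chromosome and a `normalized` attribute
new_track <- function(chrom, value, covered = NULL, normalized = FALSE) {
  stopifnot(is.list(value))
  tb <- bind_rows(lapply(seq_along(value), function(i) {
    v <- value[[i]]
    cv <- if (is.null(covered)) rep(TRUE, length(v)) else covered[[i]]
    tibble(chrom = chrom[i], pos = seq_along(v) - 1L, value = v, covered = cv)
  }))
  structure(tb, normalized = normalized,
            class = c("occupancy_track", class(tb)))
}

#' Is a track dMean-normalized?
#' @param track An occupancy track.
#' @return Logical flag.
#' @export
is_normalized <- function(track) isTRUE(attr(track, "normalized"))

# dense per-chromosome value vectors (index = pos + 1)
track_dense <- function(track) {
  split(track$value, factor(track$chrom, levels = unique(track$chrom)))
}

#' Read a per-base occupancy track
#'
#' Reads a coverage/occupancy track and expands it to per-base resolution.
#' bedGraph intervals are 0-based half-open; fixedStep WIG starts are 1-based
#' (a value at WIG position p lands at 0-based index p - 1). Bases not
#' covered by any interval are filled with 0, flagged uncovered, and counted
#' in the coverage report attached as attribute `"coverage_report"`.
#'
#' @param path Input file.
#' @param format `"bedgraph"` or `"wig_fixedstep"`.
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   omitted, each chromosome extends to its last covered base.
#' @return An occupancy track tibble (`chrom`, `pos`, `value`, `covered`)
#'   with attribute `normalized = FALSE`.
#' @export
read_occupancy <- function(path, format = c("bedgraph", "wig_fixedstep"),
                           chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- if (format == "bedgraph")
    rtracklayer::import(path, format = "bedGraph")
  else
    rtracklayer::import(path, format = "wig")
  if (length(gr) == 0) abort(paste0(path, ": no intervals"))
  score <- gr$score
  if (any(score < 0)) abort(paste0(path, ": negative occupancy values"))
  hits <- GenomicRanges::countOverlaps(gr, gr)
  if (any(hits > 1)) abort(paste0(path, ": overlapping intervals"))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L # to 0-based
  end0 <- GenomicRanges::end(gr)          # half-open end
  uchrom <- unique(chroms)
  vals <- list(); cov <- list()
  for (ch in uchrom) {
    sel <- chroms == ch
    L <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      as.integer(chrom_lengths[[ch]]) else max(end0[sel])
    v <- numeric(L); cv <- logical(L)
    for (i in which(sel)) {
      ix <- (start0[i] + 1L):min(end0[i], L)
      v[ix] <- score[i]
      cv[ix] <- TRUE
    }
    vals[[ch]] <- v; cov[[ch]] <- cv
  }
  tr <- new_track(uchrom, vals, cov, normalized = FALSE)
  report <- tibble(chrom = uchrom,
                   covered = unname(vapply(cov, sum, 0L)),
                   uncovered = unname(vapply(cov, function(x) sum(!x), 0L)))
  attr(tr, "coverage_report") <- report
  tr
}

#' Write an occupancy track
#'
#' Covered bases are written; for bedGraph, runs of equal value are merged
#' into intervals. Reading the file back reproduces the per-base track.
#'
#' @param track An occupancy track.
#' @param path Output file.
#' @param format `"bedgraph"` or `"wig_fixedstep"`.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(track, path, format = c("bedgraph", "wig_fixedstep")) {
  format <- match.arg(format)
  tr <- track[track$covered, , drop = FALSE]
  if (format == "bedgraph") {
    lines <- character(0)
    for (ch in unique(tr$chrom)) {
      sub <- tr[tr$chrom == ch, , drop = FALSE]
      brk <- c(TRUE, diff(sub$pos) != 1L | diff(sub$value) != 0)
      run <- cumsum(brk)
      st <- tapply(sub$pos, run, min)
      en <- tapply(sub$pos, run, max) + 1L
      vl <- tapply(sub$value, run, `[`, 1L)
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", ch, st, en,
                                formatC(vl, format = "g", digits = 15)))
    }
    writeLines(lines, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (ch in unique(tr$chrom)) {
      sub <- tr[tr$chrom == ch, , drop = FALSE]
      brk <- c(TRUE, diff(sub$pos) != 1L)
      run <- cumsum(brk)
      for (r in unique(run)) {
        blk <- sub[run == r, , drop = FALSE]
        writeLines(sprintf("fixedStep chrom=%s start=%d step=1", ch,
                           blk$pos[1] + 1L), con)
        writeLines(formatC(blk$value, format = "g", digits = 15), con)
      }
    }
  }
  invisible(path)
}

#' dMean normalization
#'
#' Divides every value by the single global mean over all covered bases of
#' all supplied chromosomes jointly, so that the genome-wide average
#' occupancy is exactly 1. Uncovered (zero-filled) bases are excluded from
#' the mean and stay at 0.
#'
#' @param track An occupancy track (not yet normalized).
#' @return The normalized track (`normalized` attribute set; global covered
#'   mean equal to 1 within 1e-9 relative tolerance).
#' @export
dmean_normalize <- function(track) {
  if (is_normalized(track)) abort("track is already dMean-normalized")
  v <- track$value[track$covered]
  if (length(v) == 0 || all(v == 0))
    abort("dMean undefined: track has no nonzero covered values")
  if (any(v < 0)) abort("occupancy values must be non-negative")
  m <- mean(v)
  track$value <- track$value / m
  attr(track, "normalized") <- TRUE
  track
}

#' Read site annotations from BED6
#'
#' @param path BED file; column 6 is the strand. Coordinates are 0-based
#'   (the BED `start` is taken as the site position).
#' @return A tibble with columns `chrom`, `pos`, `strand`.
#' @export
read_sites_bed <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(tb) < 3) abort(paste0(path, ": BED needs at least 3 columns"))
  tibble(chrom = as.character(tb[[1]]),
         pos = as.integer(tb[[2]]),
         strand = if (ncol(tb) >= 6) as.character(tb[[6]]) else "+")
}

#' Write site annotations as BED6
#'
#' @param sites A tibble with `chrom`, `pos` and optionally `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  strand <- if ("strand" %in% names(sites)) sites$strand else "+"
  readr::write_tsv(tibble(sites$chrom, sites$pos, sites$pos + 1L,
                          ".", 0L, strand),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
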