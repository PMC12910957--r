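# dinucleotide alphabet in lexicographic order: AA=0, AC=1, ..., TT=15
BASES <- c("A", "C", "G", "T")
DINUCS <- paste0(rep(BASES, each = 4), rep(BASES, 4))
GC_TYPE <- c("GG", "CC", "GC", "CG")
AT_TYPE <- c("AA", "TT", "AT", "TA")

# base codes 0..3 (A,C,G,T), NA for anything else
base_codes <- function(seq) {
  m <- match(strsplit(seq, "")[[1]], BASES) - 1L
  m
}

# overlapping dinucleotide codes 0..15 of a chromosome-scale code vector;
# code i covers bases (i-1, i) in 0-based coordinates
dinuc_codes <- function(codes) {
  n <- length(codes)
  if (n < 2L) return(integer(0))
  4L * codes[-n] + codes[-1L]
}

# reverse-complement lookup for dinucleotide codes:
# (a,b) -> (comp(b), comp(a)); comp swaps A<->T, C<->G (code 3 - x)
RC_DINUC <- {
  a <- rep(0:3, each = 4)
  b <- rep(0:3, 4)
  4L * (3L - b) + (3L - a)
}

#' Dinucleotide one-hot encoding
#'
#' Maps each of the `len - 1` overlapping dinucleotides of a DNA sequence to
#' a 16-dimensional one-hot column, rows ordered lexicographically
#' (AA, AC, ..., TT). A 147-base window therefore becomes a 16 x 146 binary
#' matrix in which every column sums to exactly 1.
#'
#' @param seq A single ACGT string of length >= 2.
#' @return An integer 0/1 matrix with 16 rows (rownames AA..TT) and
#'   `nchar(seq) - 1` columns.
#' @export
dinucleotide_onehot <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 2L) abort("sequence must have length >= 2")
  b <- base_codes(seq)
  if (anyNA(b))
    abort(sprintf("non-ACGT symbol at offset %d", which(is.na(b))[1] - 1L))
  code <- dinuc_codes(b)
  m <- matrix(0L, nrow = 16L, ncol = length(code),
              dimnames = list(DINUCS, NULL))
  m[cbind(code + 1L, seq_along(code))] <- 1L
  m
}

#' Decode a dinucleotide one-hot matrix back to its sequence
#'
#' The overlap between adjacent dinucleotides makes the encoding invertible:
#' `decode_onehot(dinucleotide_onehot(s))` returns `s`.
#'
#' @param m A 16-row one-hot matrix (each column sums to 1).
#' @return The decoded ACGT string of length `ncol(m) + 1`.
#' @export
decode_onehot <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 16L, ncol(m) >= 1L)
  if (!all(colSums(m) == 1L)) abort("matrix columns must be one-hot")
  code <- max.col(t(m), ties.method = "first") - 1L
  first <- code %/% 4L
  second <- code %% 4L
  # consistency of the overlap: first base of column j+1 = second of column j
  if (length(code) > 1L && !all(first[-1] == second[-length(second)]))
    abort("matrix is not a valid overlapping dinucleotide encoding")
  paste0(paste0(BASES[first[1] + 1L], collapse = ""),
         paste0(BASES[second + 1L], collapse = ""))
}

#' Reverse complement
#'
#' @param x Character vector of DNA strings.
#' @return Reverse-complemented strings (5'->3' reading of the opposite
#'   strand).
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a strand-aware window around a genomic site
#'
#' Returns the `2*flank + 1` bases centred on `center` (0-based); for minus
#' strand sites the reverse complement is returned, so the window always
#' reads 5'->3' along the annotated strand.
#'
#' @param genome Genome tibble (`chrom`, `seq`).
#' @param chrom Chromosome identifier.
#' @param center 0-based centre position.
#' @param strand `"+"` or `"-"`.
#' @param flank Bases on each side (73 for the 147-bp nucleosome window).
#' @return A character string of length `2*flank + 1`.
#' @export
extract_window <- function(genome, chrom, center, strand = "+", flank = 73L) {
  i <- match(chrom, genome$chrom)
  if (is.na(i)) abort(paste0("chromosome not in genome: ", chrom))
  L <- nchar(genome$seq[i])
  if (center - flank < 0L || center + flank > L - 1L)
    abort(sprintf("window [%d, %d] out of bounds for %s (length %d)",
                  center - flank, center + flank, chrom, L))
  s <- substr(genome$seq[i], center - flank + 1L, center + flank + 1L)
  if (identical(strand, "-")) reverse_complement(s) else s
}

# vectorized encoder core shared by build_samples() and
# build_tss_windows(): encodes 147-bp windows at the given sites (order
# preserved), skipping out-of-bounds and N-containing windows with a report.
# `sites` needs chrom/pos/strand; extra columns ride along into coords.
encode_sites <- function(genome, track, sites, flank = 73L) {
  if (!is_normalized(track)) abort("track must be dMean-normalized first")
  dense <- track_dense(track)
  width <- 2L * flank # dinucleotide columns per window
  n <- nrow(sites)
  keep <- logical(n)
  reason <- character(n)
  codes_by_chrom <- list()
  nbad_by_chrom <- list()
  for (ch in unique(sites$chrom)) {
    i <- match(ch, genome$chrom)
    if (is.na(i)) {
      sel <- sites$chrom == ch
      reason[sel] <- "chromosome_missing"
      next
    }
    b <- base_codes(genome$seq[i])
    dc <- dinuc_codes(b)
    codes_by_chrom[[ch]] <- dc
    nbad_by_chrom[[ch]] <- cumsum(c(0L, is.na(dc))) # prefix count of bad dinucs
  }
  Ls <- setNames(nchar(genome$seq), genome$chrom)
  for (j in seq_len(n)) {
    ch <- sites$chrom[j]
    if (!ch %in% names(codes_by_chrom)) next
    p <- sites$pos[j]
    L <- Ls[[ch]]
    if (p - flank < 0L || p + flank > L - 1L) {
      reason[j] <- "out_of_bounds"
      next
    }
    nb <- nbad_by_chrom[[ch]]
    i0 <- p - flank + 1L # first dinuc index (1-based) in window
    if (nb[i0 + width] - nb[i0] > 0L) {
      reason[j] <- "contains_N"
      next
    }
    keep[j] <- TRUE
  }
  kept <- which(keep)
  feats <- array(0L, c(length(kept), 16L, width))
  labels <- numeric(length(kept))
  for (kk in seq_along(kept)) {
    j <- kept[kk]
    ch <- sites$chrom[j]
    p <- sites$pos[j]
    w <- codes_by_chrom[[ch]][(p - flank + 1L):(p + flank)]
    if (identical(sites$strand[j], "-")) w <- rev(RC_DINUC[w + 1L])
    feats[cbind(kk, w + 1L, seq_len(width))] <- 1L
    labels[kk] <- dense[[ch]][p + 1L]
  }
  coords <- sites[kept, , drop = FALSE]
  skip <- sites[!keep, , drop = FALSE]
  skip$reason <- reason[!keep]
  ds <- hdgs_dataset(feats, labels, coords)
  attr(ds, "skip_report") <- as_tibble(skip)
  ds
}

#' Build encoded samples for a set of genomic sites
#'
#' Extracts the strand-aware 147-bp window around each site, encodes it as a
#' 16 x 146 dinucleotide one-hot matrix, and labels it with the normalized
#' occupancy (dMean) value at the window centre. Sites whose window leaves
#' the chromosome or contains an N are skipped (not an error) and listed in
#' the `"skip_report"` attribute; the output preserves input site order.
#'
#' @param genome Genome tibble (`chrom`, `seq`).
#' @param track A dMean-normalized occupancy track.
#' @param sites Tibble with `chrom`, `pos` (0-based) and optionally `strand`
#'   (defaults to `"+"`).
#' @return An [hdgs_dataset()] with attribute `"skip_report"` (tibble of
#'   skipped sites and reasons).
#' @export
build_samples <- function(genome, track, sites) {
  sites <- as_tibble(sites)
  if (!"strand" %in% names(sites)) sites$strand <- "+"
  encode_sites(genome, track, sites, flank = 73L)
}

# encode bare 147-bp windows (no track/labels); used by classifier inputs
# and sequence statistics
encode_windows <- function(seqs, flank = 73L) {
  width <- 2L * flank
  feats <- array(0L, c(length(seqs), 16L, width))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) != 2L * flank + 1L)
      abort(sprintf("window %d has length %d, expected %d",
                    i, nchar(seqs[i]), 2L * flank + 1L))
    b <- base_codes(seqs[i])
    if (anyNA(b))
      abort(sprintf("window %d: non-ACGT symbol at offset %d",
                    i, which(is.na(b))[1] - 1L))
    w <- dinuc_codes(b)
    feats[cbind(i, w + 1L, seq_len(width))] <- 1L
  }
  feats
}
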