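#' TSS-centred strand-aware window construction
#'
#' For every TSS, centres are laid on a 10-bp grid spanning ±1000 bp in
#' strand-oriented coordinates (201 centres for an interior TSS, endpoints
#' included; a strand-oriented offset of +10 on a minus-strand TSS lies at
#' genomic coordinate TSS - 10). Each centre contributes the encoded
#' 147-bp window extracted with the TSS strand (reverse complement on the
#' minus strand) labelled with the occupancy at the centre; centres whose
#' window leaves the chromosome or contains an N are skipped and reported.
#'
#' @param genome Genome tibble (`chrom`, `seq`).
#' @param track A dMean-normalized occupancy track.
#' @param tss Site tibble (`chrom`, `pos`, `strand`).
#' @param max_offset Half-span of the grid in bp (default 1000).
#' @param step Grid step in bp (default 10).
#' @return An [hdgs_dataset()] whose coords carry `tss_id` and the
#'   strand-oriented `offset`, plus attribute `"skip_report"`.
#' @export
build_tss_windows <- function(genome, track, tss, max_offset = 1000L,
                              step = 10L) {
  tss <- as_tibble(tss)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tss)))
  offsets <- seq.int(-max_offset, max_offset, by = step)
  grid <- bind_rows(lapply(seq_len(nrow(tss)), function(i) {
    sgn <- if (tss$strand[i] == "-") -1L else 1L
    tibble(chrom = tss$chrom[i],
           pos = tss$pos[i] + sgn * offsets,
           strand = tss$strand[i],
           tss_id = i,
           offset = offsets)
  }))
  ds <- encode_sites(genome, track, grid, flank = 73L)
  skip <- attr(ds, "skip_report")
  dropped_tss <- setdiff(seq_len(nrow(tss)), unique(ds$coords$tss_id))
  if (length(dropped_tss) > 0)
    warn(paste0("all centres skipped for TSS: ",
                paste(dropped_tss, collapse = ", ")))
  attr(ds, "skip_report") <- skip
  ds
}
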