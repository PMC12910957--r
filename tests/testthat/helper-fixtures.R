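# small programmatic fixtures shared across test files

# a normalized track over explicit per-chromosome value vectors
make_track <- function(values, chroms = paste0("chr", seq_along(values)),
                       normalize = TRUE) {
  tr <- hdgsnet:::new_track(chroms, values)
  if (normalize) dmean_normalize(tr) else tr
}

# genome tibble from raw strings
make_genome <- function(seqs, chroms = paste0("chr", seq_along(seqs))) {
  tibble::tibble(chrom = chroms, seq = seqs)
}

# a small all-ACGT genome + flat normalized track covering it
flat_world <- function(seq) {
  g <- make_genome(seq)
  tr <- make_track(list(rep(1, nchar(seq))))
  list(genome = g, track = tr)
}

# tiny network configuration: one two-branch module + minimal head; input
# width stays 146 so encoded samples feed it directly
tiny_config <- function(head = "regression", seed = 1L, channels = 4L) {
  cfg <- hdgs_config(scale = 8L, head = head, seed = seed)
  cfg$modules <- list(list(branches = list(
    hdgs_branch("gc", 3L, 1L, channels),
    hdgs_branch("dc", 7L, 3L, channels))))
  cfg$fc <- c(8L)
  cfg
}

# random one-hot feature array (valid overlapping encodings)
random_features <- function(n, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) random_dna(147L), "")
  hdgsnet:::encode_windows(seqs)
}

tmpfile <- function(ext) tempfile(fileext = ext)
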