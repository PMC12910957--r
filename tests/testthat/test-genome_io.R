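test_that("read_genome_fasta normalizes case, handles multiple records, rejects junk", {
  p <- tmpfile(".fa")
  writeLines(c(">c1", "acgt"), p)
  g <- read_genome_fasta(p)
  expect_equal(g$chrom, "c1")
  expect_equal(g$seq, "ACGT")

  writeLines(c(">c1", "ACGT", ">c2", "TT"), p)
  g <- read_genome_fasta(p)
  expect_equal(nchar(g$seq), c(4L, 2L))

  writeLines("ACGT", p)
  expect_error(read_genome_fasta(p), "header")

  writeLines(character(0), p)
  expect_error(read_genome_fasta(p), "empty")

  # non-ACGT symbols become N
  writeLines(c(">c1", "ACxGT"), p)
  expect_equal(read_genome_fasta(p)$seq, "ACNGT")
})

test_that("FASTA round trip preserves sequences", {
  g <- make_genome(c("ACGTACGTAC", "TTAACC"), c("a", "b"))
  p <- tmpfile(".fa")
  write_genome_fasta(g, p)
  expect_equal(read_genome_fasta(p), g)
})

test_that("bedGraph reading expands intervals per base with 0-based half-open coords", {
  p <- tmpfile(".bg")
  writeLines("c1\t0\t3\t2.0", p)
  tr <- read_occupancy(p, "bedgraph")
  expect_equal(tr$pos, 0:2)
  expect_equal(tr$value, rep(2, 3))
  expect_false(is_normalized(tr))

  # uncovered gap filled with 0 and reported
  writeLines(c("c1\t0\t2\t1.0", "c1\t4\t6\t3.0"), p)
  tr <- read_occupancy(p, "bedgraph")
  expect_equal(tr$value, c(1, 1, 0, 0, 3, 3))
  expect_equal(tr$covered, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  rep_ <- attr(tr, "coverage_report")
  expect_equal(rep_$uncovered, 2L)

  writeLines("c1\t2\t1\t5.0", p)
  expect_error(read_occupancy(p, "bedgraph"))

  writeLines("c1\t0\t3\t-1.0", p)
  expect_error(read_occupancy(p, "bedgraph"), "negative")

  writeLines(c("c1\t0\t3\t1.0", "c1\t2\t4\t2.0"), p)
  expect_error(read_occupancy(p, "bedgraph"), "overlap")
})

test_that("fixedStep WIG positions convert from 1-based to 0-based", {
  p <- tmpfile(".wig")
  writeLines(c("fixedStep chrom=c1 start=1 step=1", "1", "2"), p)
  tr <- read_occupancy(p, "wig_fixedstep")
  expect_equal(tr$pos, 0:1)
  expect_equal(tr$value, c(1, 2))

  # a value at WIG position p lands at 0-based index p - 1
  writeLines(c("fixedStep chrom=c1 start=5 step=1", "9"), p)
  tr <- read_occupancy(p, "wig_fixedstep")
  expect_equal(tr$value[tr$pos == 4L], 9)
})

test_that("track write-back round trips per format", {
  set.seed(42)
  v <- round(runif(40, 0, 5), 3)
  v[10:14] <- 0 # a zero run still round-trips as covered bases
  tr <- make_track(list(v, round(runif(12), 3)), c("cA", "cB"),
                   normalize = FALSE)
  for (fmt in c("bedgraph", "wig_fixedstep")) {
    p <- tmpfile(".txt")
    write_occupancy(tr, p, fmt)
    back <- read_occupancy(p, fmt)
    expect_equal(back$value, tr$value, tolerance = 1e-12)
    expect_equal(back$chrom, tr$chrom)
    expect_equal(back$pos, tr$pos)
  }
})

test_that("dMean divides by the joint mean over all chromosomes", {
  tr <- make_track(list(c(2, 4, 6)), normalize = FALSE)
  nm <- dmean_normalize(tr)
  expect_equal(nm$value, c(0.5, 1, 1.5))
  expect_true(is_normalized(nm))

  # global mean, not per chromosome
  tr2 <- make_track(list(c(1, 1), c(3, 3)), normalize = FALSE)
  nm2 <- dmean_normalize(tr2)
  expect_equal(nm2$value, c(0.5, 0.5, 1.5, 1.5))
  expect_equal(mean(nm2$value[nm2$covered]), 1, tolerance = 1e-9)

  expect_error(dmean_normalize(make_track(list(c(0, 0, 0)), normalize = FALSE)),
               "nonzero")
  expect_error(dmean_normalize(nm), "already")
})

test_that("dataset container round trips bit-identically and validates on read", {
  feats <- random_features(5, seed = 1)
  ds <- hdgs_dataset(feats, runif(5),
                     tibble::tibble(chrom = "c1", pos = 100:104, strand = "+"))
  p <- tmpfile(".rds")
  write_dataset(ds, p)
  back <- read_dataset(p)
  expect_identical(back$features, ds$features)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$coords, ds$coords)

  # empty container round trips with N = 0
  e <- hdgs_dataset(array(0L, c(0, 16, 146)), numeric(0),
                    tibble::tibble(chrom = character(0), pos = integer(0),
                                   strand = character(0)))
  write_dataset(e, p)
  expect_equal(length(read_dataset(p)), 0L)

  # missing component on read is an error
  saveRDS(list(features = feats, coords = ds$coords), p)
  expect_error(read_dataset(p), "labels")

  # shape mismatch on construction is an error
  expect_error(hdgs_dataset(feats, runif(4), ds$coords), "disagree")
  expect_error(hdgs_dataset(feats, c(-1, runif(4)), ds$coords),
               "non-negative")
})

test_that("BED6 site lists round trip with strand", {
  s <- tibble::tibble(chrom = c("c1", "c2"), pos = c(5L, 9L),
                      strand = c("+", "-"))
  p <- tmpfile(".bed")
  write_sites_bed(s, p)
  expect_equal(read_sites_bed(p), s)
})
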