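test_that("quartile grouping takes strict tails under the type-7 rule", {
  g <- group_by_quartile(1:100)
  q <- quantile(1:100, c(.25, .75), type = 7) # independent oracle: 25.75, 75.25
  expect_equal(sum(g$group == "high", na.rm = TRUE), sum(1:100 > q[2]))
  expect_equal(sum(g$group == "low", na.rm = TRUE), sum(1:100 < q[1]))
  expect_true(all(g$value[which(g$group == "high")] > 75.25))
  expect_true(all(g$value[which(g$group == "low")] < 25.75))

  g8 <- group_by_quartile(c(10, 20, 30, 40, 50, 60, 70, 80))
  expect_equal(sum(g8$group == "high", na.rm = TRUE), 2L)
  expect_equal(sum(g8$group == "low", na.rm = TRUE), 2L)

  expect_error(group_by_quartile(rep(5, 20)), "degenerate")
  expect_error(group_by_quartile(1:5), "at least 8")
})

test_that("k-means grouping is ordered by centroid and seed-deterministic", {
  v <- c(0, 0.1, 1, 1.1, 5, 5.1)
  g <- group_by_kmeans3(v, seed = 1)
  expect_equal(as.character(g$group[g$value >= 5]), rep("high", 2))
  expect_equal(as.character(g$group[g$value >= 1 & g$value < 5]),
               rep("medium", 2))
  expect_equal(as.character(g$group[g$value < 1]), rep("low", 2))
  expect_identical(group_by_kmeans3(v, seed = 7), group_by_kmeans3(v, seed = 7))
  # exactly three nonempty groups on any valid input
  set.seed(71)
  gg <- group_by_kmeans3(rlnorm(200), seed = 2)
  expect_equal(sort(unique(as.character(gg$group))),
               c("high", "low", "medium"))
  expect_error(group_by_kmeans3(c(0, 0, 0)), "distinct")
})

test_that("decile grouping partitions exactly with contiguous sorted blocks", {
  g <- group_by_decile(1:100)
  expect_equal(as.vector(table(g$group)), rep(10L, 10))
  expect_equal(as.character(g$group[which.max(g$value)]), "G1")
  expect_equal(as.character(g$group[which.min(g$value)]), "G10")

  g2 <- group_by_decile(runif(105))
  sizes <- as.vector(table(g2$group))
  expect_equal(sort(sizes, decreasing = TRUE), c(rep(11L, 5), rep(10L, 5)))
  expect_equal(sum(sizes), 105L)

  # ties at a boundary break by original index (value desc, index asc)
  vt <- c(rep(2, 6), rep(1, 6), rep(2, 8)) # 20 values, ties across boundary
  gt <- group_by_decile(vt)
  first_ids <- gt$id[gt$group == "G1"]
  expect_equal(first_ids, c(1L, 2L)) # earliest tied indices go highest
  expect_error(group_by_decile(1:9), "at least 10")
})

test_that("composition pools sequences into normalized mono/di tables", {
  co <- composition("AAAA")
  expect_equal(co$mono$freq[co$mono$base == "A"], 1)
  expect_equal(co$di$freq[co$di$dinuc == "AA"], 1)

  co2 <- composition("ACGT")
  expect_equal(co2$mono$freq, rep(0.25, 4))
  expect_equal(co2$di$freq[co2$di$dinuc %in% c("AC", "CG", "GT")],
               rep(1 / 3, 3))
  expect_equal(sum(co2$di$freq), 1)

  expect_error(composition(c("AC", "ACG")), "equal length")
  expect_error(composition(character(0)), "empty")
})

test_that("positional matrices are column-normalized frequencies", {
  allA <- strrep("A", 147)
  pm <- positional_matrix(rep(allA, 3))
  expect_equal(dim(pm), c(16L, 146L))
  expect_equal(unname(pm["AA", ]), rep(1, 146))
  expect_equal(colSums(pm), rep(1, 146), tolerance = 1e-9)

  set.seed(72)
  s <- random_dna(147)
  pm1 <- positional_matrix(s)
  expect_equal(unclass(pm1), dinucleotide_onehot(s) + 0, ignore_attr = TRUE)

  s2 <- chartr("ACGT", "CAGT", s) # differs from s wherever A or C occurs
  pm2 <- positional_matrix(c(strrep("A", 147), strrep("C", 147)))
  expect_true(all(pm2[pm2 > 0] == 0.5))

  expect_error(positional_matrix("ACGT"), "length 147")
})

test_that("column sums stay 1 for arbitrary random groups", {
  set.seed(73)
  seqs <- vapply(1:25, function(i) random_dna(147), "")
  pm <- positional_matrix(seqs)
  expect_equal(colSums(pm), rep(1, 146), tolerance = 1e-9)
})

test_that("two-proportion z-test matches the standard-normal tail oracle", {
  ht <- enrichment_test(90, 100, 10, 100)
  # oracle: z from pooled proportions, p from the normal tail
  pp <- 100 / 200
  z <- (0.9 - 0.1) / sqrt(pp * (1 - pp) * (2 / 100))
  expect_equal(unname(ht$statistic), z)
  expect_equal(ht$p.value, 2 * pnorm(-abs(z)))
  expect_lt(ht$p.value, 0.001)

  expect_equal(enrichment_test(50, 100, 50, 100)$p.value, 1)
  expect_equal(enrichment_test(0, 10, 0, 10)$p.value, 1)
  expect_error(enrichment_test(5, 0, 1, 10), "positive")
  expect_error(enrichment_test(11, 10, 1, 10), "exceed")
})

test_that("GC-driven occupancy yields GC-enriched high groups on synthetic windows", {
  # construction guarantees the direction: occupancy is exp in GC frequency
  spec <- synthetic_spec(genome_length = 30000L, seed = 5L)
  g <- generate_genome(spec)
  tr <- generate_occupancy(g, spec)
  cov <- tr[tr$covered, ]
  set.seed(74)
  pick <- cov[sample(nrow(cov), 600), ]
  seqs <- vapply(seq_len(nrow(pick)), function(i)
    extract_window(g, pick$chrom[i], pick$pos[i]), "")
  grp <- group_by_quartile(pick$value)
  hi <- composition(seqs[which(grp$group == "high")])
  lo <- composition(seqs[which(grp$group == "low")])
  gc_freq <- function(co) sum(co$di$freq[co$di$dinuc %in%
                                           c("GG", "CC", "GC", "CG")])
  expect_gt(gc_freq(hi), gc_freq(lo))
  # and the enrichment is detectable by the z-test
  n_hi <- 146 * sum(grp$group == "high", na.rm = TRUE)
  n_lo <- 146 * sum(grp$group == "low", na.rm = TRUE)
  ht <- enrichment_test(round(gc_freq(hi) * n_hi), n_hi,
                        round(gc_freq(lo) * n_lo), n_lo)
  expect_lt(ht$p.value, 0.001)
})
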