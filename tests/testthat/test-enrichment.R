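# Permutation enrichment machinery and GC comparison.

mk_cnvrs <- function(chrom, start, end, type = "loss") {
  data.frame(chrom = chrom, start = start, end = end, type = type,
             n_animals = 1L, animals = "a", stringsAsFactors = FALSE)
}

test_that("overlap_count basics: disjoint, self, worked fraction", {
  cn <- mk_cnvrs("chr1", c(0, 1e4, 2e4), c(5e3, 1.5e4, 2.5e4))
  far <- data.frame(chrom = "chr1", start = 9e5, end = 9.1e5)
  expect_equal(overlap_count(cn, far)$count, 0)
  self <- cn[, c("chrom", "start", "end")]
  expect_equal(overlap_count(cn, self)$count, 3)
  expect_equal(overlap_count(cn, self)$fraction, 1.0)
  expect_equal(overlap_count(cn, cn[2, c("chrom", "start", "end")])$fraction,
               1 / 3)
  g <- tiny_genome()
  expect_error(overlap_count(cn, data.frame(chrom = "chrZ", start = 0,
                                            end = 10), g), "chrZ")
})

test_that("features covering the genome saturate the test at p = 1", {
  g <- tiny_genome(c(1e5))
  cn <- mk_cnvrs("chr1", c(1e4, 5e4), c(2e4, 6e4))
  all_feat <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  r <- permutation_test(cn, all_feat, g, n_perm = 200, seed = 1)
  expect_equal(r$observed, 2)
  expect_true(all(r$null == 2))
  expect_equal(r$p_value, 1)
})

test_that("permutation test is reproducible given a seed", {
  g <- tiny_genome(c(1e5))
  cn <- mk_cnvrs("chr1", c(1e4, 5e4), c(2e4, 6e4))
  feat <- data.frame(chrom = "chr1", start = c(3e4, 8e4), end = c(3.5e4, 9e4))
  r1 <- permutation_test(cn, feat, g, n_perm = 500, seed = 42)
  r2 <- permutation_test(cn, feat, g, n_perm = 500, seed = 42)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("the fast placement sampler agrees with the interval route", {
  # the null machinery must compute the same hit indicator as the
  # GenomicRanges-based observed statistic, on the same placements
  g <- sim_genome(c(2e5), gap_fraction = 0.1, seed = 5)
  feat <- data.frame(chrom = "chr1", start = c(2e4, 9e4, 1.5e5),
                     end = c(2.6e4, 1.1e5, 1.55e5))
  set.seed(99)
  for (i in 1:50) {
    L <- sample(500:20000, 1)
    allowed <- cghloop:::allowed_starts(g, "chr1", L)
    s <- cghloop:::sample_starts(allowed, 1)
    placed <- mk_cnvrs("chr1", s, s + L)
    # placements avoid gaps
    expect_equal(nrow(g$gaps[g$gaps$start < s + L & g$gaps$end > s, ]), 0)
    slow <- overlap_count(placed, feat)$count
    hitiv <- cghloop:::merge_closed(feat$start - L + 1, feat$end - 1)
    k <- findInterval(s, hitiv$s)
    fast <- as.integer(k >= 1 && s <= hitiv$e[max(k, 1)])
    expect_equal(fast, slow)
  }
})

test_that("a CNVR longer than any gap-free stretch raises a placement error", {
  g <- sim_genome(5e4, gap_fraction = 0.2, n_gaps_per_mb = 100, seed = 2)
  cn <- mk_cnvrs("chr1", 0, 4.9e4)
  feat <- data.frame(chrom = "chr1", start = 0, end = 100)
  expect_error(permutation_test(cn, feat, g, n_perm = 10, seed = 1), "longer")
})

test_that("planted 3x enrichment is detected at p < 0.01", {
  g <- tiny_genome(c(1e6))
  set.seed(7)
  # features occupy ~5% of the chromosome
  fs <- sort(sample.int(9.5e5, 50))
  feat <- data.frame(chrom = "chr1", start = fs, end = fs + 1000)
  # place 40 CNVRs, forcing ~60% (vs ~20% by chance for 5 kb regions) onto
  # features
  on_feat <- sample(fs, 24)
  off <- sample.int(9e5, 16)
  cn <- mk_cnvrs("chr1", c(on_feat, off), c(on_feat, off) + 5000)
  r <- permutation_test(cn, feat, g, n_perm = 1000, seed = 8)
  expect_lt(r$p_value, 0.01)
})

test_that("exclusion-constructed CNVRs show depletion", {
  g <- tiny_genome(c(1e6))
  set.seed(9)
  fs <- seq(0, 9.9e5, by = 2e4)  # features tile 5% of the chromosome
  feat <- data.frame(chrom = "chr1", start = fs, end = fs + 1000)
  # CNVRs placed strictly between features
  cs <- fs[-length(fs)] + 5000
  cn <- mk_cnvrs("chr1", cs, cs + 8000)
  r <- permutation_test(cn, feat, g, n_perm = 1000, seed = 10,
                        mode = "depletion")
  expect_lt(r$p_value, 0.001 * 10)  # comfortably small
  expect_equal(r$observed, 0)
})

test_that("bp statistic counts overlap base pairs without double counting", {
  cn <- mk_cnvrs("chr1", 1000, 2000)
  feat <- data.frame(chrom = "chr1", start = c(900, 1400, 1400),
                     end = c(1100, 1600, 1600))  # duplicate feature
  expect_equal(overlap_bp(cn, feat), 100 + 200)
  g <- tiny_genome(c(1e5))
  r <- permutation_test(cn, feat, g, n_perm = 100, seed = 3,
                        statistic = "bp")
  expect_equal(r$observed, 300)
})

test_that("SD filtering drops unconfirmed high-identity WGAC calls only", {
  feat <- data.frame(chrom = "chr1", start = c(0, 10, 20, 30),
                     end = c(5, 15, 25, 35),
                     identity = c(96, 96, 92, 96),
                     evidence = c("WGAC", "both", "WGAC", "WSSD"),
                     stringsAsFactors = FALSE)
  out <- filter_sd_features(feat)
  expect_equal(out$start, c(10, 20, 30))
  # absent annotation columns: untouched
  plain <- feat[, 1:3]
  expect_identical(filter_sd_features(plain), plain)
})

test_that("GC comparison recovers constructed compositions", {
  g <- tiny_genome(c(5e4))
  all_gc <- sim_genome_sequence(g, gc = 1, seed = 1)
  cn <- mk_cnvrs("chr1", 1e4, 2e4)
  r <- gc_compare(cn, all_gc)
  expect_equal(r$cnvr_gc, 1.0)
  expect_equal(r$genome_gc, 1.0)

  isl <- data.frame(chrom = "chr1", start = 1e4, end = 2e4, gc = 0.6)
  seqs <- sim_genome_sequence(g, gc = 0.4, islands = isl, seed = 2)
  r2 <- gc_compare(cn, seqs)
  expect_equal(r2$cnvr_gc, 0.6, tolerance = 0.03)
  expect_equal(r2$genome_gc, 0.4 * 0.8 + 0.6 * 0.2, tolerance = 0.03)

  expect_error(gc_compare(cn[0, ], seqs), "empty")
  expect_true(is.na(gc_compare(cn[0, ], seqs, allow_empty = TRUE)$cnvr_gc))
})
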