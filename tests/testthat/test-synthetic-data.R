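# Generator: genome, probe tiling, planted CNVs, hybridization physics.

test_that("sim_genome handles the no-gap case and rejects bad lengths", {
  g <- sim_genome(1e6, gap_fraction = 0, seed = 1)
  expect_equal(nrow(g$chrom), 1)
  expect_equal(nrow(g$gaps), 0)
  expect_equal(genome_length(g), 1e6)
  expect_error(sim_genome(0), "positive")
  expect_error(sim_genome(c(1e5, -5)), "positive")
  expect_error(sim_genome(1e5, gap_fraction = 0.6), "gap_fraction")
})

test_that("realized gap content matches gap_fraction and gaps are valid", {
  g <- sim_genome(c(5e5, 3e5), gap_fraction = 0.05, seed = 7)
  gap_bp <- sum(g$gaps$end - g$gaps$start)
  expect_equal(gap_bp, 0.05 * 8e5, tolerance = 0.01)
  # gaps inside their chromosome, non-overlapping per chromosome
  for (chrom in unique(g$gaps$chrom)) {
    gg <- g$gaps[g$gaps$chrom == chrom, ]
    gg <- gg[order(gg$start), ]
    L <- g$chrom$length[g$chrom$chrom == chrom]
    expect_true(all(gg$start >= 0 & gg$end <= L & gg$start < gg$end))
    if (nrow(gg) > 1) expect_true(all(head(gg$end, -1) <= tail(gg$start, -1)))
  }
  expect_equal(genome_length(g, assayable = TRUE), 8e5 - gap_bp)
})

test_that("probe tiling is exact without jitter and within 10% with jitter", {
  g <- sim_genome(1e6, gap_fraction = 0, seed = 1)
  p <- sim_probes(g, median_spacing = 301, probe_length = 60, jitter = 0,
                  seed = 1)
  expect_equal(nrow(p), floor((1e6 - 60) / 301) + 1)
  expect_true(all(diff(p$start) == 301))
  pj <- sim_probes(g, 301, 60, jitter = 0.5, seed = 1)
  expect_lt(abs(median(diff(pj$start)) - 301) / 301, 0.10)
  expect_error(sim_probes(g, median_spacing = 50, probe_length = 60),
               "exceed")
})

test_that("probes avoid gaps and stay sorted", {
  g <- sim_genome(c(3e5, 2e5), gap_fraction = 0.1, seed = 3)
  p <- sim_probes(g, 301, 60, jitter = 0.2, seed = 4)
  expect_false(is.unsorted(p$start[p$chrom == "chr1"]))
  for (i in seq_len(nrow(g$gaps)))
    expect_equal(sum(p$chrom == g$gaps$chrom[i] &
                       p$start < g$gaps$end[i] & p$end > g$gaps$start[i]), 0)
})

test_that("theoretical_resolution follows the spacing/length arithmetic", {
  expect_equal(theoretical_resolution(300, 53, 5), 1465)
  expect_equal(theoretical_resolution(301, 60, 5), 1504)
  expect_equal(theoretical_resolution(1, 1, 1), 1)
  expect_error(theoretical_resolution(0, 50, 5), "positive")
})

test_that("planted CNVs respect count, loss fraction, placement and size", {
  panel <- sim_animals(10, n_female = 0, seed = 1)
  g <- tiny_genome(c(4e5, 4e5))
  expect_equal(nrow(sim_cnvs(panel, g, n_per_animal = 0)), 0)
  tr <- sim_cnvs(panel, g, n_per_animal = 5, size_range = c(1500, 8000),
                 loss_fraction = 0.66, seed = 3)
  expect_equal(nrow(tr), 50)
  # binomial tolerance: 3 sd around 33
  expect_lt(abs(sum(tr$copies == 1) - 33), 3 * sqrt(50 * 0.66 * 0.34) + 1)
  expect_true(all(tr$end > tr$start))
  expect_true(all(tr$end - tr$start >= 1000))
  expect_error(sim_cnvs(panel, g, 1, size_range = c(500, 900)), "1 kb")
  # determinism: identical seeds give identical truth sets
  expect_identical(tr, sim_cnvs(panel, g, 5, c(1500, 8000), 0.66, seed = 3))
})

test_that("loop design: every animal meets two partners, both orientations", {
  d <- loop_design(sim_animals(6, n_female = 0))
  expect_equal(nrow(d), 12)
  for (a in unique(c(d$cy3, d$cy5))) {
    partners <- unique(c(d$cy5[d$cy3 == a], d$cy3[d$cy5 == a]))
    expect_length(partners, 2)
  }
  # each (pair, orientation) exactly once
  expect_false(anyDuplicated(paste(d$cy3, d$cy5)) > 0)
  # swap mate has roles exchanged
  for (i in seq_len(nrow(d))) {
    mate <- d[d$array_id == d$swap_of[i], ]
    expect_equal(mate$cy3, d$cy5[i])
    expect_equal(mate$cy5, d$cy3[i])
  }
  validate_design(d)
})

test_that("hybridization physics: identity, planted shifts, chrX dosage", {
  g <- tiny_genome(c(1e5))
  probes <- sim_probes(g, 301, 60, jitter = 0, seed = 1)
  panel <- data.frame(animal_id = c("A", "B"), sex = c("male", "male"),
                      breed = "x", stringsAsFactors = FALSE)
  d <- data.frame(array_id = "H1", cy3 = "A", cy5 = "A", design_id = "D1",
                  swap_of = "H2", stringsAsFactors = FALSE)
  no_cnv <- sim_cnvs(panel, g, 0)
  # self-self, no artifacts: ratios exactly zero
  t0 <- sim_hybridization(d, probes, panel, no_cnv, noise_sd = 0,
                          dye_bias = 0, spatial_amplitude = 0, seed = 1)
  expect_true(all(t0$log2ratio == 0))

  # planted 1-copy loss: covered probes at exactly -1, others 0
  truth <- data.frame(animal_id = "A", chrom = "chr1",
                      start = 30000, end = 40000, copies = 1L)
  d2 <- data.frame(array_id = "H1", cy3 = "A", cy5 = "B", design_id = "D1",
                   swap_of = "H2", stringsAsFactors = FALSE)
  t1 <- sim_hybridization(d2, probes, panel, truth, noise_sd = 0,
                          dye_bias = 0, spatial_amplitude = 0, seed = 1)
  inside <- probes$start < 40000 & probes$end > 30000
  expect_true(all(t1$log2ratio[inside] == -1))
  expect_true(all(t1$log2ratio[!inside] == 0))
  # intensities consistent with the ratio
  expect_equal(log2(t1$intensity_cy3 / t1$intensity_cy5), t1$log2ratio)

  # male test vs female reference: chrX probes at log2(1/2)
  gx <- sim_genome(c(1e5, 5e4), names = c("chr1", "chrX"), seed = 1)
  px <- sim_probes(gx, 301, 60, jitter = 0, seed = 1)
  panel_mf <- data.frame(animal_id = c("M", "F"), sex = c("male", "female"),
                         breed = "x", stringsAsFactors = FALSE)
  dmf <- data.frame(array_id = "H1", cy3 = "M", cy5 = "F", design_id = "D1",
                    swap_of = "H2", stringsAsFactors = FALSE)
  tx <- sim_hybridization(dmf, px, panel_mf, sim_cnvs(panel_mf, gx, 0),
                          noise_sd = 0, dye_bias = 0, spatial_amplitude = 0,
                          seed = 1)
  expect_true(all(tx$log2ratio[tx$chrom == "chrX"] == -1))
  expect_true(all(tx$log2ratio[tx$chrom == "chr1"] == 0))

  expect_error(
    sim_hybridization(data.frame(array_id = "H9", cy3 = "A", cy5 = "Z",
                                 swap_of = "H1"), probes, panel, no_cnv),
    "absent")
})

test_that("dye-swap antisymmetry and zero-mean invariants hold", {
  exp0 <- sim_experiment(n_animals = 4, genome = tiny_genome(c(1e5)),
                         n_per_animal = 1, size_range = c(2000, 5000),
                         noise_sd = 0, dye_bias = 0, spatial_amplitude = 0,
                         seed = 5)
  d <- exp0$design
  for (aid in d$array_id[d$array_id < d$swap_of]) {
    mate <- d$swap_of[d$array_id == aid]
    expect_equal(exp0$tables[[aid]]$log2ratio,
                 -exp0$tables[[mate]]$log2ratio)
  }
  # non-CNV probes have mean ratio exactly 0 at zero noise/bias/spatial
  tab <- exp0$tables[[1]]
  expect_equal(mean(tab$log2ratio[tab$log2ratio > -0.5 & tab$log2ratio < 0.5]), 0)
})

test_that("generator output is byte-identical across identical seeds", {
  e1 <- sim_experiment(n_animals = 3, genome = tiny_genome(c(5e4)),
                       n_per_animal = 1, size_range = c(1500, 3000), seed = 9)
  e2 <- sim_experiment(n_animals = 3, genome = tiny_genome(c(5e4)),
                       n_per_animal = 1, size_range = c(1500, 3000), seed = 9)
  expect_identical(e1$tables, e2$tables)
  expect_identical(e1$truth, e2$truth)
})

test_that("noiseless truth-set round trip: planted shifts are recoverable", {
  exp0 <- sim_experiment(n_animals = 4, genome = tiny_genome(c(2e5)),
                         n_per_animal = 2, size_range = c(2500, 8000),
                         noise_sd = 0, dye_bias = 0, spatial_amplitude = 0,
                         seed = 13)
  d <- exp0$design
  for (i in seq_len(nrow(exp0$truth))) {
    tr <- exp0$truth[i, ]
    # this animal appears as cy3 on some array; probes under the CNV must
    # show the analytic shift against a diploid partner
    aid <- d$array_id[d$cy3 == tr$animal_id][1]
    tab <- exp0$tables[[aid]]
    inside <- tab$chrom == tr$chrom & tab$start < tr$end & tab$end > tr$start
    # default planting is globally disjoint, so the partner is diploid here
    expected <- log2(tr$copies / 2)
    expect_true(all(abs(tab$log2ratio[inside] - expected) < 1e-12))
  }
})
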