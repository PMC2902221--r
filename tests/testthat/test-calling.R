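# Dye-swap concordance and loop attribution.

two_array_design <- function(a = "A", b = "B") {
  d <- data.frame(array_id = c("H1", "H2"), cy3 = c(a, b), cy5 = c(b, a),
                  design_id = "D1", swap_of = c("H2", "H1"),
                  stringsAsFactors = FALSE)
  class(d) <- c("cgh_design", "data.frame")
  d
}

test_that("perfect concordance yields one pair call with the right direction", {
  d <- two_array_design()
  pc <- pair_concordance(cand("H1", "chr7", 100e3, 150e3, -0.8),
                         cand("H2", "chr7", 100e3, 150e3, 0.8), d)
  expect_equal(nrow(pc), 1)
  expect_equal(pc$start, 100e3)
  expect_equal(pc$end, 150e3)
  # H1 sign "-" means cy5 (B) is relatively up, i.e. test A is down
  expect_equal(pc$up_animal, "B")
})

test_that("discordant and non-flipping segments produce no pair call", {
  d <- two_array_design()
  # present on one mate only
  expect_equal(nrow(pair_concordance(cand("H1", "chr7", 100e3, 150e3, -0.8),
                                     cand("H2", "chr9", 1e6, 2e6, 0.8), d)), 0)
  # same raw sign on both mates = dye artifact
  expect_equal(nrow(pair_concordance(cand("H1", "chr7", 100e3, 150e3, 0.8),
                                     cand("H2", "chr7", 100e3, 150e3, 0.8), d)), 0)
  # insufficient reciprocal overlap
  expect_equal(nrow(pair_concordance(cand("H1", "chr7", 100e3, 150e3, -0.8),
                                     cand("H2", "chr7", 130e3, 220e3, 0.8), d)), 0)
})

test_that("pair_concordance rejects arrays that are not dye-swap mates", {
  d4 <- ring4()
  expect_error(
    pair_concordance(cand(d4$array_id[1], "chr1", 0, 1000, 0.5),
                     cand(d4$array_id[3], "chr1", 0, 1000, -0.5), d4),
    "dye-swap mates")
})

test_that("loop attribution reproduces the shared-animal deletion logic", {
  # ring of animals 2-19-6-20-17: pairs (19,6) '19 up' and (6,20) '20 up'
  # overlap on chr7; the only shared animal is 6, relatively down twice
  panel <- data.frame(animal_id = c("an02", "an19", "an06", "an20", "an17"),
                      sex = "male", breed = "x", stringsAsFactors = FALSE)
  d <- loop_design(panel)
  pc <- rbind(
    data.frame(pair = "an06|an19", animal_a = "an06", animal_b = "an19",
               chrom = "chr7", start = 100e3, end = 160e3,
               up_animal = "an19", arrays = "x", stringsAsFactors = FALSE),
    data.frame(pair = "an06|an20", animal_a = "an06", animal_b = "an20",
               chrom = "chr7", start = 105e3, end = 158e3,
               up_animal = "an20", arrays = "y", stringsAsFactors = FALSE))
  calls <- attribute_cnvs(pc, d)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$animal_id, "an06")
  expect_equal(calls$state, "loss")
  expect_equal(calls$start, 100e3)  # union of supporting intervals
  expect_equal(calls$end, 160e3)
  expect_equal(calls$n_pairs, 2L)
})

test_that("a single supporting pair is not enough", {
  d <- loop_design(sim_animals(5, n_female = 0))
  pc <- data.frame(pair = "A01|A02", animal_a = "A01", animal_b = "A02",
                   chrom = "chr1", start = 0, end = 5e3,
                   up_animal = "A01", arrays = "x", stringsAsFactors = FALSE)
  expect_equal(nrow(attribute_cnvs(pc, d)), 0)
})

test_that("contradictory directions drop the locus with a warning", {
  d <- loop_design(sim_animals(5, n_female = 0))
  pc <- rbind(
    data.frame(pair = "A01|A02", animal_a = "A01", animal_b = "A02",
               chrom = "chr1", start = 0, end = 5e3,
               up_animal = "A02", arrays = "x", stringsAsFactors = FALSE),
    data.frame(pair = "A02|A03", animal_a = "A02", animal_b = "A03",
               chrom = "chr1", start = 0, end = 5e3,
               up_animal = "A03", arrays = "y", stringsAsFactors = FALSE))
  expect_warning(calls <- attribute_cnvs(pc, d), "conflict")
  expect_equal(nrow(calls), 0)
})

test_that("noiseless 4-animal loop recovers a planted gain end-to-end", {
  g <- tiny_genome(c(2e5))
  probes <- sim_probes(g, 301, 60, jitter = 0, seed = 1)
  panel <- sim_animals(4, n_female = 0)
  d <- loop_design(panel)
  truth <- data.frame(animal_id = "A03", chrom = "chr1",
                      start = 80000, end = 100000, copies = 3L,
                      stringsAsFactors = FALSE)
  tables <- lapply(seq_len(nrow(d)), function(i)
    sim_hybridization(d[i, ], probes, panel, truth, noise_sd = 0,
                      dye_bias = 0, spatial_amplitude = 0, seed = i))
  names(tables) <- d$array_id
  res <- call_cnvs(tables, d, pipeline_config(), preprocess = FALSE)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$animal_id, "A03")
  expect_equal(res$calls$state, "gain")
  # boundaries within one probe spacing of the planted interval
  expect_lt(abs(res$calls$start - 80000), 301 + 60)
  expect_lt(abs(res$calls$end - 100000), 301 + 60)
})

test_that("relabeling dye orientations leaves CNV calls unchanged", {
  g <- tiny_genome(c(1.5e5))
  probes <- sim_probes(g, 301, 60, jitter = 0, seed = 2)
  panel <- sim_animals(4, n_female = 0)
  d <- loop_design(panel)
  truth <- data.frame(animal_id = "A02", chrom = "chr1",
                      start = 40000, end = 55000, copies = 1L,
                      stringsAsFactors = FALSE)
  mk <- function(design) {
    tabs <- lapply(seq_len(nrow(design)), function(i)
      sim_hybridization(design[i, ], probes, panel, truth, noise_sd = 0,
                        dye_bias = 0, spatial_amplitude = 0, seed = i))
    names(tabs) <- design$array_id
    call_cnvs(tabs, design, pipeline_config(), preprocess = FALSE)$calls
  }
  flipped <- d
  flipped$cy3 <- d$cy5
  flipped$cy5 <- d$cy3
  c1 <- mk(d)
  c2 <- mk(flipped)
  expect_equal(c1[c("animal_id", "chrom", "start", "end", "state")],
               c2[c("animal_id", "chrom", "start", "end", "state")])
})

test_that("every call lists >= 2 pairs and every pair call 2 arrays", {
  exp0 <- sim_experiment(n_animals = 6, genome = tiny_genome(c(3e5)),
                         n_per_animal = 2, size_range = c(2500, 9000),
                         noise_sd = 0.15, seed = 21)
  res <- call_cnvs(exp0$tables, exp0$design, pipeline_config(seed = 21))
  expect_true(all(res$calls$n_pairs >= 2))
  expect_true(all(lengths(strsplit(res$pair_calls$arrays, "+",
                                   fixed = TRUE)) == 2))
})
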