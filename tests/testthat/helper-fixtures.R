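# Shared fixture builders. Everything is generated in code; no stored data.

# a small gapless genome
tiny_genome <- function(lengths = c(2e5, 2e5), ...) {
  sim_genome(lengths, seed = 1, ...)
}

# a bare probe table with evenly spaced probes on one chromosome
bare_table <- function(n = 200, spacing = 301, probe_len = 60,
                       chrom = "chr1", lr = rep(0, n), side = NULL) {
  side <- side %||% ceiling(sqrt(n))
  cell <- seq_len(n) - 1L
  tab <- data.frame(
    probe_id = sprintf("P%05d", seq_len(n)),
    chrom = chrom,
    start = (seq_len(n) - 1L) * spacing,
    end = (seq_len(n) - 1L) * spacing + probe_len,
    x = cell %% side, y = cell %/% side,
    log2ratio = lr,
    stringsAsFactors = FALSE)
  class(tab) <- c("cgh_ratio", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# candidate-call data.frame in the shape filter_segments() emits
cand <- function(array_id, chrom, start, end, mean, n_probes = 10) {
  data.frame(array_id = array_id, chrom = chrom,
             start_idx = 1L, end_idx = n_probes,
             start = start, end = end, n_probes = n_probes, mean = mean,
             sign = ifelse(mean >= 0, "+", "-"),
             stringsAsFactors = FALSE)
}

# a 4-animal ring design (8 arrays)
ring4 <- function() loop_design(sim_animals(4, n_female = 0, seed = 1))

# brute-force minimal penalized segmentation cost by enumerating all
# 2^(n-1) breakpoint subsets; independent of the DP implementation
brute_force_cost <- function(x, penalty) {
  n <- length(x)
  css <- function(v) sum((v - mean(v))^2)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 2))) != 0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    cost <- sum(vapply(seq_along(starts),
                       function(k) css(x[starts[k]:ends[k]]), numeric(1))) +
      penalty * length(starts)
    if (cost < best) best <- cost
  }
  best
}

# brute-force optimal k-segmentation cost via enumeration of breakpoints
brute_force_cost_k <- function(x, k) {
  n <- length(x)
  css <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(css(x))
  best <- Inf
  for (cuts in asplit(utils::combn(n - 1, k - 1), 2)) {
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    cost <- sum(vapply(seq_along(starts),
                       function(m) css(x[starts[m]:ends[m]]), numeric(1)))
    if (cost < best) best <- cost
  }
  best
}
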