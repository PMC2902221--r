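# Synthetic array CGH experiments: genome, probe tiling, animal panel,
# dye-swap loop design, planted CNVs and two-channel intensities with
# dye bias, spatial artifact and Gaussian noise.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a genome model for simulation
#'
#' A genome model is the coordinate frame every other stage works in:
#' chromosome names and lengths plus (optionally) assembly-gap intervals.
#' Gaps emulate the unsequenced stretches of a draft assembly; probe tiling
#' and CNV/CNVR placement avoid them. Gap intervals are laid out by drawing
#' random inter-gap spacings so that the realized gap content equals
#' `gap_fraction` of the genome exactly (up to rounding per chromosome).
#'
#' All coordinates are 0-based, half-open.
#'
#' @param lengths integer vector of chromosome lengths in bp (all > 0)
#' @param names chromosome names; default `"chr1"..."chrN"`
#' @param gap_fraction fraction of each chromosome covered by assembly gaps,
#'   in `[0, 0.5)`. A draft mammalian assembly of the era this design targets
#'   has on the order of 5.8% of its length in gaps.
#' @param n_gaps_per_mb mean number of gaps per Mb when `gap_fraction > 0`
#' @param seed integer seed; the model is deterministic given the seed
#' @return an object of class `cgh_genome`: list with `chrom`
#'   (data.frame: chrom, length) and `gaps` (data.frame: chrom, start, end)
#' @export
sim_genome <- function(lengths, names = NULL, gap_fraction = 0,
                       n_gaps_per_mb = 5, seed = NULL) {
  if (length(lengths) < 1 || any(!is.finite(lengths)) || any(lengths <= 0))
    stop_invalid("chromosome lengths must all be positive")
  if (gap_fraction < 0 || gap_fraction >= 0.5)
    stop_invalid("gap_fraction must be in [0, 0.5)")
  lengths <- as.numeric(lengths)
  if (is.null(names)) names <- paste0("chr", seq_along(lengths))
  if (anyDuplicated(names)) stop_invalid("chromosome names must be unique")

  gaps <- with_seed(seed, {
    out <- list()
    for (i in seq_along(lengths)) {
      L <- lengths[i]
      gap_bp <- round(gap_fraction * L)
      if (gap_bp < 1) next
      n_gap <- max(1L, round(n_gaps_per_mb * L / 1e6))
      # split gap_bp into n_gap sizes and the free length into n_gap + 1
      # spacings; alternate free/gap so gaps never overlap or touch the ends
      gsz <- as.vector(round(gap_bp * prop_table(n_gap)))
      gsz[1] <- gsz[1] + (gap_bp - sum(gsz))
      if (any(gsz < 1)) gsz <- pmax(gsz, 1)
      free <- L - sum(gsz)
      if (free < n_gap + 1) stop_invalid("gap_fraction too high for chromosome %s", names[i])
      spc <- as.vector(round(free * prop_table(n_gap + 1)))
      spc[1] <- spc[1] + (free - sum(spc))
      start <- cumsum(c(0, gsz)) + cumsum(spc)
      start <- start[seq_len(n_gap)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = names[i], start = start, end = start + gsz)
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(chrom = character(), start = numeric(), end = numeric())
  })
  structure(list(chrom = data.frame(chrom = names, length = lengths,
                                    stringsAsFactors = FALSE),
                 gaps = gaps),
            class = "cgh_genome")
}

# random proportions summing to 1, bounded away from degeneracy
prop_table <- function(n) {
  w <- runif(n, 0.5, 1.5)
  w / sum(w)
}

#' @export
print.cgh_genome <- function(x, ...) {
  cat(sprintf("<cgh_genome> %d chromosome(s), %.0f bp total, %d gap(s) (%.1f%%)\n",
              nrow(x$chrom), sum(x$chrom$length), nrow(x$gaps),
              100 * sum(x$gaps$end - x$gaps$start) / sum(x$chrom$length)))
  invisible(x)
}

#' Total genome length of a genome model
#' @param genome a `cgh_genome`
#' @param assayable if TRUE, exclude assembly gaps
#' @return length in bp
#' @export
genome_length <- function(genome, assayable = FALSE) {
  tot <- sum(genome$chrom$length)
  if (assayable) tot <- tot - sum(genome$gaps$end - genome$gaps$start)
  tot
}

# non-gap intervals of one chromosome as a data.frame(start, end)
nongap_intervals <- function(genome, chrom) {
  L <- genome$chrom$length[genome$chrom$chrom == chrom]
  g <- genome$gaps[genome$gaps$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(data.frame(start = 0, end = L))
  g <- g[order(g$start), ]
  data.frame(start = c(0, g$end), end = c(g$start, L))
}

#' Tile oligo probes along a genome model
#'
#' Probes are laid start-to-start at `median_spacing` bp (the platform this
#' emulates tiles ~6.3M probes at a 301 bp median spacing), optionally
#' jittered, skipping assembly gaps. Array grid coordinates (x, y) are
#' assigned by a seeded random permutation of a near-square grid, so the
#' spatial artifact field is independent of genomic position, as on a real
#' array where neighbouring features interrogate unrelated loci.
#'
#' @param genome a `cgh_genome`
#' @param median_spacing start-to-start probe spacing in bp (> probe_length)
#' @param probe_length oligo length in bp
#' @param jitter fractional spacing jitter in `[0, 1)`: each spacing is drawn
#'   uniformly from `median_spacing * (1 +/- jitter)`
#' @param design_id physical array design label
#' @param seed integer seed
#' @return data.frame of class `cgh_probes`: probe_id, chrom, start, end,
#'   x, y, design_id; sorted by (chrom, start), 0-based half-open
#' @export
sim_probes <- function(genome, median_spacing = 301, probe_length = 60,
                       jitter = 0.1, design_id = "D1", seed = NULL) {
  stopifnot(inherits(genome, "cgh_genome"))
  if (median_spacing <= probe_length)
    stop_invalid("median_spacing (%s) must exceed probe_length (%s)",
                 median_spacing, probe_length)
  if (jitter < 0 || jitter >= 1) stop_invalid("jitter must be in [0, 1)")

  with_seed(seed, {
    rows <- list()
    for (chrom in genome$chrom$chrom) {
      iv <- nongap_intervals(genome, chrom)
      for (k in seq_len(nrow(iv))) {
        lo <- iv$start[k]; hi <- iv$end[k]
        if (hi - lo < probe_length) next
        n_max <- ceiling((hi - lo) / (median_spacing * (1 - jitter))) + 1L
        spc <- if (jitter == 0) rep(median_spacing, n_max) else
          pmax(probe_length + 1,
               round(median_spacing * runif(n_max, 1 - jitter, 1 + jitter)))
        start <- lo + cumsum(c(0, spc))
        start <- start[start + probe_length <= hi]
        if (!length(start)) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = start, end = start + probe_length,
          stringsAsFactors = FALSE)
      }
    }
    pm <- do.call(rbind, rows)
    pm <- pm[order(match(pm$chrom, genome$chrom$chrom), pm$start), ]
    n <- nrow(pm)
    side <- ceiling(sqrt(n))
    cell <- sample.int(side * side, n) - 1L
    out <- data.frame(probe_id = sprintf("P%06d", seq_len(n)),
                      chrom = pm$chrom, start = pm$start, end = pm$end,
                      x = cell %% side, y = cell %/% side,
                      design_id = design_id,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("cgh_probes", "data.frame")
    out
  })
}

#' Theoretical CNV detection resolution of a tiling platform
#'
#' The smallest event guaranteed to cover `min_probes` consecutive probes
#' spans `min_probes - 1` inter-probe spacings plus `min_probes` oligo
#' lengths: `median_spacing * (min_probes - 1) + median_probe_length *
#' min_probes`.
#'
#' @param median_spacing median start-to-start probe spacing, bp
#' @param median_probe_length median oligo length, bp
#' @param min_probes minimum consecutive probes required for a call
#' @return resolution in bp
#' @examples
#' theoretical_resolution(300, 53, 5) # 1465
#' @export
theoretical_resolution <- function(median_spacing, median_probe_length,
                                   min_probes = 5) {
  if (any(c(median_spacing, median_probe_length, min_probes) <= 0))
    stop_invalid("all resolution inputs must be positive")
  median_spacing * (min_probes - 1) + median_probe_length * min_probes
}

#' Simulate an animal panel
#'
#' @param n number of animals
#' @param n_female number of females (the rest are male); the default panel
#'   of 20 with 2 females mirrors a typical cattle CGH cohort
#' @param breeds breed labels recycled over animals (annotation only)
#' @param seed seed controlling which animals are female
#' @return data.frame: animal_id, sex, breed
#' @export
sim_animals <- function(n = 20, n_female = 2,
                        breeds = c("Holstein", "RedDanish", "Simmental", "Hereford"),
                        seed = NULL) {
  if (n < 1 || n_female < 0 || n_female > n)
    stop_invalid("need 0 <= n_female <= n and n >= 1")
  with_seed(seed, {
    sex <- rep("male", n)
    if (n_female > 0) sex[sample.int(n, n_female)] <- "female"
    data.frame(animal_id = sprintf("A%02d", seq_len(n)),
               sex = sex,
               breed = rep_len(breeds, n),
               stringsAsFactors = FALSE)
  })
}

#' Construct a dye-swap loop design
#'
#' Animals are arranged in a single ring; each animal is hybridized against
#' its two ring neighbours and every pair is run in both dye orientations
#' (Cy3/Cy5 exchanged). With n animals this yields 2n arrays: n pairs times
#' two orientations. Each array records which animal is labelled Cy3 and
#' which Cy5; the log2 ratio convention throughout the package is
#' log2(Cy3/Cy5).
#'
#' @param panel animal panel from [sim_animals()] (needs >= 3 animals for a
#'   proper ring; 2 animals give a single dye-swap pair, used for self-self
#'   or two-sample checks)
#' @param design_id physical array design label
#' @return data.frame of class `cgh_design`: array_id, cy3, cy5, design_id,
#'   swap_of (array_id of the dye-swap mate)
#' @export
loop_design <- function(panel, design_id = "D1") {
  n <- nrow(panel)
  if (n < 2) stop_invalid("loop design needs at least 2 animals")
  ids <- panel$animal_id
  a <- ids
  b <- ids[c(2:n, 1)]
  if (n == 2) { a <- a[1]; b <- b[1] }  # avoid duplicating the single pair
  m <- length(a)
  d <- data.frame(
    array_id = sprintf("H%03d", seq_len(2 * m)),
    cy3 = as.vector(rbind(a, b)),
    cy5 = as.vector(rbind(b, a)),
    design_id = design_id,
    stringsAsFactors = FALSE)
  d$swap_of <- d$array_id[c(rbind(seq(2, 2 * m, 2), seq(1, 2 * m, 2)))]
  class(d) <- c("cgh_design", "data.frame")
  d
}

#' Plant CNVs in an animal panel
#'
#' Draws per-animal gain/loss intervals to serve as the simulation truth set.
#' Sizes are log-uniform over `size_range` (real CNVR catalogues span ~1.7 kb
#' to ~2 Mb, heavily skewed small). Placement is uniform over autosomes
#' proportional to length, avoids assembly gaps, and by default avoids
#' overlap with every previously placed CNV so that loop attribution is
#' identifiable. Copy state is 1 (loss) with probability `loss_fraction`,
#' else 3 (gain); the default 0.664 matches the loss share observed in
#' cattle (202 of 304 regions).
#'
#' @param panel animal panel
#' @param genome `cgh_genome`
#' @param n_per_animal CNVs planted per animal
#' @param size_range c(min, max) CNV size in bp; min must be >= 1000 (a CNV
#'   is by definition >= 1 kb)
#' @param loss_fraction probability a planted CNV is a loss
#' @param allow_overlap if FALSE (default) planted CNVs are pairwise disjoint
#'   across the whole panel
#' @param avoid_chrx if TRUE (default) CNVs are planted on autosomes only,
#'   keeping chrX free as a sex-dosage control
#' @param max_tries placement retries per CNV before a placement error
#' @param seed integer seed
#' @return data.frame of class `cgh_truth`: animal_id, chrom, start, end,
#'   copies (1 or 3)
#' @export
sim_cnvs <- function(panel, genome, n_per_animal = 5,
                     size_range = c(2000, 50000), loss_fraction = 0.664,
                     allow_overlap = FALSE, avoid_chrx = TRUE,
                     max_tries = 1000, seed = NULL) {
  stopifnot(inherits(genome, "cgh_genome"))
  if (n_per_animal < 0) stop_invalid("n_per_animal must be >= 0")
  if (size_range[1] < 1000)
    stop_invalid("CNVs are >= 1 kb by definition; size_range[1] = %s", size_range[1])
  if (size_range[2] < size_range[1]) stop_invalid("size_range must be increasing")
  empty <- data.frame(animal_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), copies = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cgh_truth", "data.frame")
  if (n_per_animal == 0 || nrow(panel) == 0) return(empty)

  chroms <- genome$chrom
  if (avoid_chrx) chroms <- chroms[!is_chrx(chroms$chrom), , drop = FALSE]
  if (nrow(chroms) == 0) stop_invalid("no autosomes available for CNV placement")

  with_seed(seed, {
    placed <- list()
    for (aid in panel$animal_id) {
      for (j in seq_len(n_per_animal)) {
        size <- round(exp(runif(1, log(size_range[1]), log(size_range[2]))))
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          ci <- sample.int(nrow(chroms), 1, prob = chroms$length)
          chrom <- chroms$chrom[ci]
          iv <- nongap_intervals(genome, chrom)
          iv <- iv[iv$end - iv$start >= size, , drop = FALSE]
          if (nrow(iv) == 0) next
          k <- sample.int(nrow(iv), 1, prob = iv$end - iv$start - size + 1)
          start <- floor(runif(1, iv$start[k], iv$end[k] - size + 1))
          end <- start + size
          if (!allow_overlap && length(placed)) {
            clash <- vapply(placed, function(p)
              p$chrom == chrom && p$start < end && p$end > start, logical(1))
            if (any(clash)) next
          }
          placed[[length(placed) + 1L]] <- list(
            animal_id = aid, chrom = chrom, start = start, end = end,
            copies = if (runif(1) < loss_fraction) 1L else 3L)
          ok <- TRUE
          break
        }
        if (!ok) stop_invalid(
          "could not place a %d bp CNV after %d tries (genome too small or full)",
          size, max_tries)
      }
    }
    out <- do.call(rbind, lapply(placed, as.data.frame))
    out$animal_id <- as.character(out$animal_id)
    out$chrom <- as.character(out$chrom)
    class(out) <- c("cgh_truth", "data.frame")
    out
  })
}

# per-probe copy number of one animal: diploid baseline, chrX dosage by sex,
# planted CNVs override
probe_copies <- function(probes, animal, panel, truth) {
  sex <- panel$sex[match(animal, panel$animal_id)]
  if (is.na(sex)) stop_invalid("animal '%s' is not in the panel", animal)
  cp <- ifelse(is_chrx(probes$chrom) & sex == "male", 1, 2)
  tr <- truth[truth$animal_id == animal, , drop = FALSE]
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      hit <- probes$chrom == tr$chrom[i] &
        probes$start < tr$end[i] & probes$end > tr$start[i]
      cp[hit] <- tr$copies[i]
    }
  }
  cp
}

# smooth low-order polynomial field over the array grid, centred, sd = amp
spatial_field <- function(x, y, amp) {
  if (amp == 0) return(rep(0, length(x)))
  xn <- (x - mean(x)) / max(1, stats::sd(x))
  yn <- (y - mean(y)) / max(1, stats::sd(y))
  b <- rnorm(5)
  f <- b[1] * xn + b[2] * yn + b[3] * xn * yn + b[4] * xn^2 + b[5] * yn^2
  f <- f - mean(f)
  s <- stats::sd(f)
  if (s == 0) return(rep(0, length(x)))
  f * (amp / s)
}

#' Simulate one two-channel hybridization
#'
#' Generates per-probe Cy3/Cy5 intensities for one array of a design. The
#' reference channel is log-normal; the test channel multiplies it by the
#' copy ratio and by dye and spatial multipliers, so the expected log2
#' ratio at each probe is
#' `log2(copies_cy3 / copies_cy5) + dye_bias + spatial(x, y) + N(0, noise_sd)`.
#' A 1-copy loss against a diploid reference sits at log2(1/2) = -1 and a
#' 3-copy gain at log2(3/2) = +0.58. The dye-swap mate (roles exchanged,
#' fresh noise) has the copy term negated while dye bias keeps its sign --
#' the property dye-swap concordance filtering exploits.
#'
#' @param entry one row of a `cgh_design` (array_id, cy3, cy5)
#' @param probes probe map from [sim_probes()]
#' @param panel animal panel
#' @param truth planted CNVs from [sim_cnvs()]
#' @param noise_sd per-probe Gaussian noise, log2 units
#' @param dye_bias constant dye bias, log2 units
#' @param spatial_amplitude sd of the smooth spatial field, log2 units
#' @param intensity_scale median reference-channel intensity (arbitrary units)
#' @param intensity_sdlog log-sd of the reference channel
#' @param seed integer seed
#' @return data.frame of class `cgh_ratio`: probe_id, chrom, start, end, x, y,
#'   intensity_cy3, intensity_cy5, log2ratio, plus attributes array_id,
#'   cy3/cy5 animals
#' @export
sim_hybridization <- function(entry, probes, panel, truth,
                              noise_sd = 0.2, dye_bias = 0.1,
                              spatial_amplitude = 0.1,
                              intensity_scale = 1000, intensity_sdlog = 0.5,
                              seed = NULL) {
  if (!all(c(entry$cy3, entry$cy5) %in% panel$animal_id))
    stop_invalid("design entry references animals absent from the panel")
  n <- nrow(probes)
  with_seed(seed, {
    c3 <- probe_copies(probes, entry$cy3, panel, truth)
    c5 <- probe_copies(probes, entry$cy5, panel, truth)
    lr <- log2(c3 / c5) + dye_bias +
      spatial_field(probes$x, probes$y, spatial_amplitude) +
      (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
    ref <- rlnorm(n, meanlog = log(intensity_scale), sdlog = intensity_sdlog)
    out <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                      start = probes$start, end = probes$end,
                      x = probes$x, y = probes$y,
                      intensity_cy3 = ref * 2^lr, intensity_cy5 = ref,
                      log2ratio = lr, stringsAsFactors = FALSE)
    attr(out, "array_id") <- entry$array_id
    attr(out, "cy3") <- entry$cy3
    attr(out, "cy5") <- entry$cy5
    class(out) <- c("cgh_ratio", "data.frame")
    out
  })
}

#' Simulate a complete dye-swap loop experiment
#'
#' Convenience wrapper tying the generator together: genome, probe map,
#' panel, ring loop design, planted truth set, and one intensity table per
#' array. Per-array seeds are derived from `seed` so the whole experiment is
#' reproducible from a single integer.
#'
#' @param n_animals animals in the loop
#' @param genome a `cgh_genome`; default two 500 kb autosomes, no gaps
#' @param median_spacing,probe_length,jitter probe tiling parameters
#' @param n_per_animal,size_range,loss_fraction planted-CNV parameters
#' @param noise_sd,dye_bias,spatial_amplitude,intensity_scale artifact levels
#' @param n_female females in the panel
#' @param seed master seed
#' @return list with genome, probes, panel, design, truth, tables (list of
#'   `cgh_ratio`, named by array_id)
#' @export
sim_experiment <- function(n_animals = 8,
                           genome = sim_genome(c(5e5, 5e5), seed = 1),
                           median_spacing = 301, probe_length = 60,
                           jitter = 0.1,
                           n_per_animal = 4, size_range = c(2500, 20000),
                           loss_fraction = 0.664,
                           noise_sd = 0.2, dye_bias = 0.1,
                           spatial_amplitude = 0.1, intensity_scale = 1000,
                           n_female = 0, seed = NULL) {
  seed <- seed %||% 1L
  panel <- sim_animals(n_animals, n_female = n_female, seed = seed)
  probes <- sim_probes(genome, median_spacing, probe_length, jitter,
                       seed = seed + 1L)
  design <- loop_design(panel)
  truth <- sim_cnvs(panel, genome, n_per_animal, size_range, loss_fraction,
                    seed = seed + 2L)
  tables <- lapply(seq_len(nrow(design)), function(i)
    sim_hybridization(design[i, ], probes, panel, truth,
                      noise_sd = noise_sd, dye_bias = dye_bias,
                      spatial_amplitude = spatial_amplitude,
                      intensity_scale = intensity_scale,
                      seed = seed + 10L + i))
  names(tables) <- design$array_id
  list(genome = genome, probes = probes, panel = panel, design = design,
       truth = truth, tables = tables)
}
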