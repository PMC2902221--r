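# Dye-swap concordance and loop-design attribution: from per-array candidate
# segments to per-animal gain/loss CNV calls.
#
# Convention: every array's log2 ratio is Cy3/Cy5, so a "+" segment means the
# Cy3-labelled animal has relatively more copies. A true copy-number signal
# flips sign on the dye-swap mate (the animals exchange dyes); a dye artifact
# does not, which is exactly what the concordance filter removes.

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1), ov / (e2 - s2)))
}

#' Dye-swap concordance between the two arrays of a pair
#'
#' A candidate segment survives only if the dye-swap mate shows the same
#' locus aberrant in the *opposite* raw sign (the sign must flip with dye
#' orientation) with at least `min_overlap` reciprocal overlap. The emitted
#' pair call takes the conservative intersection of the two segments and
#' records which animal of the pair is relatively amplified.
#'
#' @param calls_a,calls_b filtered candidate calls ([filter_segments()]
#'   output with bp coordinates and an `array_id` column) from the two dye
#'   orientations of one pair
#' @param design the `cgh_design` the arrays belong to
#' @param min_overlap minimum reciprocal overlap fraction (default 0.5)
#' @return data.frame of class `cgh_paircalls`: pair (sorted "A|B" key),
#'   animal_a, animal_b, chrom, start, end, up_animal, arrays
#' @export
pair_concordance <- function(calls_a, calls_b, design, min_overlap = 0.5) {
  if (min_overlap <= 0 || min_overlap > 1)
    stop_invalid("min_overlap must be in (0, 1]")
  empty <- data.frame(pair = character(), animal_a = character(),
                      animal_b = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      up_animal = character(), arrays = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cgh_paircalls", "data.frame")

  ida <- unique(calls_a$array_id)
  idb <- unique(calls_b$array_id)
  if (length(ida) != 1 || length(idb) != 1) {
    if (nrow(calls_a) == 0 || nrow(calls_b) == 0) return(empty)
    stop_invalid("each call set must come from a single array")
  }
  ra <- design[design$array_id == ida, ]
  rb <- design[design$array_id == idb, ]
  if (nrow(ra) != 1 || nrow(rb) != 1)
    stop_invalid("array(s) %s, %s not found in the design", ida, idb)
  if (!identical(ra$swap_of, rb$array_id) ||
      !identical(sort(c(ra$cy3, ra$cy5)), sort(c(rb$cy3, rb$cy5))))
    stop_invalid("arrays %s and %s are not dye-swap mates", ida, idb)

  rows <- list()
  for (i in seq_len(nrow(calls_a))) {
    for (j in seq_len(nrow(calls_b))) {
      if (calls_a$chrom[i] != calls_b$chrom[j]) next
      if (calls_a$sign[i] == calls_b$sign[j]) next  # non-flipping = dye artifact
      ro <- reciprocal_overlap(calls_a$start[i], calls_a$end[i],
                               calls_b$start[j], calls_b$end[j])
      if (ro < min_overlap) next
      up <- if (calls_a$sign[i] == "+") ra$cy3 else ra$cy5
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pair_key(ra$cy3, ra$cy5),
        animal_a = min(ra$cy3, ra$cy5), animal_b = max(ra$cy3, ra$cy5),
        chrom = calls_a$chrom[i],
        start = max(calls_a$start[i], calls_b$start[j]),
        end = min(calls_a$end[i], calls_b$end[j]),
        up_animal = up,
        arrays = paste(ida, idb, sep = "+"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  class(out) <- c("cgh_paircalls", "data.frame")
  out
}

# single-linkage clusters of intervals by reciprocal overlap >= min_overlap;
# returns an integer cluster id per row
overlap_clusters <- function(df, min_overlap) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (df$chrom[i] != df$chrom[j]) next
      if (reciprocal_overlap(df$start[i], df$end[i],
                             df$start[j], df$end[j]) >= min_overlap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Attribute pair calls to individual animals via the loop design
#'
#' In a loop design each animal is hybridized with its two neighbours; a real
#' CNV in one animal therefore shows up in (at least) the two pairs
#' containing that animal, and the animal is identified as the single one
#' common to those hybridizations. Overlapping pair calls (reciprocal
#' overlap >= `min_overlap`) from at least two *different* pairs that share
#' exactly one animal, with a consistent direction relative to that animal
#' (relatively up in all supporting pairs, or down in all), yield a per-animal
#' gain or loss call spanning the union of the supporting intervals.
#' Loci with contradictory directions are dropped with a warning.
#'
#' @param pair_calls output of [pair_concordance()] over all pairs
#' @param design the `cgh_design`
#' @param min_overlap reciprocal-overlap fraction for grouping (default 0.5)
#' @return data.frame of class `cgh_calls`: animal_id, chrom, start, end,
#'   state ("gain"/"loss"), n_pairs, pairs
#' @export
attribute_cnvs <- function(pair_calls, design, min_overlap = 0.5) {
  if (min_overlap <= 0 || min_overlap > 1)
    stop_invalid("min_overlap must be in (0, 1]")
  empty <- data.frame(animal_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), state = character(),
                      n_pairs = integer(), pairs = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cgh_calls", "data.frame")
  if (nrow(pair_calls) == 0) return(empty)
  known <- unique(c(design$cy3, design$cy5))
  if (!all(c(pair_calls$animal_a, pair_calls$animal_b) %in% known))
    stop_invalid("pair calls reference animals absent from the design")

  cl <- overlap_clusters(pair_calls, min_overlap)
  rows <- list()
  for (g in unique(cl)) {
    grp <- pair_calls[cl == g, , drop = FALSE]
    if (length(unique(grp$pair)) < 2) next  # single-hybridization evidence
    members <- lapply(unique(grp$pair),
                      function(p) strsplit(p, "|", fixed = TRUE)[[1]])
    common <- Reduce(intersect, members)
    if (length(common) != 1) next  # no unique shared animal
    dir_up <- grp$up_animal == common
    if (length(unique(dir_up)) != 1) {
      warning(sprintf(
        "conflicting directions for animal %s at %s:%.0f-%.0f; locus dropped",
        common, grp$chrom[1], min(grp$start), max(grp$end)), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = common, chrom = grp$chrom[1],
      start = min(grp$start), end = max(grp$end),
      state = if (dir_up[1]) "gain" else "loss",
      n_pairs = length(unique(grp$pair)),
      pairs = paste(sort(unique(grp$pair)), collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$animal_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cgh_calls", "data.frame")
  out
}
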