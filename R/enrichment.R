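# Permutation tests for association of CNVRs with genomic feature sets and
# GC-content comparison.

features_to_granges <- function(df) {
  if (any(df$start >= df$end)) stop_invalid("features must have start < end")
  calls_to_granges(df)
}

#' Count CNVRs overlapping a feature set
#'
#' A CNVR counts as overlapping when it shares at least 1 bp with any
#' feature interval.
#'
#' @param cnvrs `cgh_cnvr` data.frame
#' @param features feature data.frame (chrom, start, end), e.g. from
#'   [read_bed()]
#' @param genome optional `cgh_genome`; when given, both sets' chromosome
#'   names are validated against it
#' @return list: count, fraction (count / number of CNVRs), total
#' @export
overlap_count <- function(cnvrs, features, genome = NULL) {
  if (!is.null(genome)) {
    bad <- setdiff(unique(c(cnvrs$chrom, features$chrom)), genome$chrom$chrom)
    if (length(bad))
      stop_invalid("chromosome(s) not in genome model: %s",
                   paste(bad, collapse = ", "))
  }
  if (nrow(cnvrs) == 0) return(list(count = 0L, fraction = 0, total = 0L))
  if (nrow(features) == 0)
    return(list(count = 0L, fraction = 0, total = nrow(cnvrs)))
  n <- GenomicRanges::countOverlaps(calls_to_granges(cnvrs),
                                    features_to_granges(features))
  list(count = sum(n > 0), fraction = sum(n > 0) / nrow(cnvrs),
       total = nrow(cnvrs))
}

# merge closed integer intervals given as two vectors; returns list(s, e)
merge_closed <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- numeric(0); me <- numeric(0)
  for (i in seq_along(s)) {
    if (length(ms) && s[i] <= me[length(me)] + 0) {
      me[length(me)] <- max(me[length(me)], e[i])
    } else {
      ms <- c(ms, s[i]); me <- c(me, e[i])
    }
  }
  list(s = ms, e = me)
}

# allowed start positions for a length-L placement on one chromosome,
# avoiding gaps: union of closed intervals [iv$start, iv$end - L]
allowed_starts <- function(genome, chrom, L) {
  iv <- nongap_intervals(genome, chrom)
  iv <- iv[iv$end - iv$start >= L, , drop = FALSE]
  if (nrow(iv) == 0) return(NULL)
  list(s = iv$start, e = iv$end - L)
}

# draw n uniform starts from a union of closed intervals
sample_starts <- function(allowed, n) {
  w <- allowed$e - allowed$s + 1
  cw <- cumsum(w)
  u <- floor(runif(n, 0, cw[length(cw)]))
  k <- findInterval(u, cw) + 1L  # cw is strictly increasing
  allowed$s[k] + (u - c(0, cw)[k])
}

#' Permutation test for CNVR-feature association
#'
#' Each permutation re-places every CNVR independently and uniformly at
#' random on its own chromosome, preserving its length and avoiding assembly
#' gaps (placements may overlap each other), and recomputes the overlap
#' statistic. The empirical p-value uses the +1 correction:
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` for enrichment, with the
#' inequality mirrored for depletion, so p is never exactly 0 and "p <
#' 0.001" at 10,000 permutations means at most 9 null exceedances.
#'
#' @param cnvrs `cgh_cnvr` data.frame
#' @param features feature data.frame (chrom, start, end)
#' @param genome `cgh_genome` providing chromosome lengths and gaps
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed; results are fully reproducible given the seed
#' @param mode "enrichment" or "depletion"
#' @param statistic "count" (CNVRs overlapping >= 1 feature, the default) or
#'   "bp" (total base pairs of CNVR-feature overlap)
#' @return list of class `cgh_perm`: observed, null (numeric vector of
#'   length n_perm), n_perm, p_value, mode, statistic
#' @export
permutation_test <- function(cnvrs, features, genome, n_perm = 10000,
                             seed = NULL, mode = c("enrichment", "depletion"),
                             statistic = c("count", "bp")) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  stopifnot(inherits(genome, "cgh_genome"))
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  bad <- setdiff(unique(c(cnvrs$chrom, features$chrom)), genome$chrom$chrom)
  if (length(bad))
    stop_invalid("chromosome(s) not in genome model: %s",
                 paste(bad, collapse = ", "))
  if (nrow(cnvrs) == 0) stop_invalid("no CNVRs to permute")

  # per-chromosome merged features and coverage prefix (for the bp statistic)
  feat <- split(features, features$chrom)
  fmerged <- lapply(feat, function(f) merge_closed(f$start, f$end))

  obs <- if (statistic == "count") overlap_count(cnvrs, features)$count
         else overlap_bp(cnvrs, features)

  null <- with_seed(seed, {
    acc <- if (statistic == "count") integer(n_perm) else numeric(n_perm)
    for (i in seq_len(nrow(cnvrs))) {
      chrom <- cnvrs$chrom[i]
      L <- cnvrs$end[i] - cnvrs$start[i]
      allowed <- allowed_starts(genome, chrom, L)
      if (is.null(allowed))
        stop_invalid("CNVR %s:%.0f-%.0f is longer than any gap-free stretch",
                     chrom, cnvrs$start[i], cnvrs$end[i])
      s <- sample_starts(allowed, n_perm)
      fm <- fmerged[[chrom]]
      if (is.null(fm) || length(fm$s) == 0) next
      if (statistic == "count") {
        # s hits a feature iff s in [f$start - L + 1, f$end - 1] (integers)
        hit <- merge_closed(fm$s - L + 1, fm$e - 1)
        idx <- findInterval(s, hit$s)
        acc <- acc + as.integer(idx >= 1 & s <= hit$e[pmax(idx, 1L)])
      } else {
        cov <- c(0, cumsum(fm$e - fm$s))
        covfun <- function(t) {
          k <- findInterval(t, fm$s)
          k1 <- pmax(k, 1L)
          v <- cov[k1] + pmin(pmax(t - fm$s[k1], 0), fm$e[k1] - fm$s[k1])
          v[k < 1] <- 0
          v
        }
        acc <- acc + (covfun(s + L) - covfun(s))
      }
    }
    acc
  })

  p <- if (mode == "enrichment") (1 + sum(null >= obs)) / (1 + n_perm)
       else (1 + sum(null <= obs)) / (1 + n_perm)
  structure(list(observed = obs, null = null, n_perm = n_perm,
                 p_value = p, mode = mode, statistic = statistic),
            class = "cgh_perm")
}

#' @export
print.cgh_perm <- function(x, ...) {
  cat(sprintf("<cgh_perm> %s (%s): observed = %.0f, null mean = %.2f, p = %.4g (%d perms)\n",
              x$mode, x$statistic, x$observed, mean(x$null), x$p_value, x$n_perm))
  invisible(x)
}

#' Total CNVR-feature overlap in base pairs
#' @param cnvrs,features interval data.frames
#' @return overlap bp, double-counting prevented by merging features first
#' @export
overlap_bp <- function(cnvrs, features) {
  if (nrow(cnvrs) == 0 || nrow(features) == 0) return(0)
  gr <- calls_to_granges(cnvrs)
  fr <- GenomicRanges::reduce(features_to_granges(features))
  hits <- GenomicRanges::findOverlaps(gr, fr)
  qs <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  sum(pmin(GenomicRanges::end(gr)[qs], GenomicRanges::end(fr)[sh]) -
        pmax(GenomicRanges::start(gr)[qs], GenomicRanges::start(fr)[sh]) + 1)
}

#' Filter a segmental-duplication feature set
#'
#' Assembly-based (WGAC) duplication calls above 94% identity are unreliable
#' unless confirmed by read-depth (WSSD): highly similar duplications are
#' often collapsed or mis-assigned in a draft assembly. Features with
#' `evidence == "WGAC"` and `identity > max_identity` are dropped; anything
#' WSSD-confirmed (`"WSSD"` or `"both"`) or below the identity cut is kept,
#' as are features without identity/evidence annotation.
#'
#' @param features data.frame with optional `identity` (percent) and
#'   `evidence` ("WGAC", "WSSD", "both") columns
#' @param max_identity identity cut (default 94)
#' @return filtered data.frame
#' @export
filter_sd_features <- function(features, max_identity = 94) {
  if (is.null(features$identity) || is.null(features$evidence))
    return(features)
  drop <- !is.na(features$identity) & !is.na(features$evidence) &
    features$identity > max_identity & features$evidence == "WGAC"
  out <- features[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GC content of CNVRs versus the whole genome
#'
#' Computes the G+C fraction over the union of CNVR intervals (regions
#' merged first, so shared base pairs are not double-counted) and over all
#' sequence. Ambiguous bases (anything outside A/C/G/T, including assembly
#' gap N runs) are excluded from numerator and denominator on both sides.
#'
#' @param cnvrs `cgh_cnvr` data.frame
#' @param seqs a [Biostrings::DNAStringSet] named by chromosome
#' @param allow_empty when TRUE an empty CNVR set yields `NA` for the CNVR
#'   GC rather than an error
#' @return list: cnvr_gc, genome_gc (fractions in [0, 1])
#' @export
gc_compare <- function(cnvrs, seqs, allow_empty = FALSE) {
  gc_of <- function(ss) {
    f <- colSums(Biostrings::letterFrequency(ss, c("G", "C", "A", "T")))
    acgt <- sum(f)
    if (acgt == 0) return(NA_real_)
    (f[["G"]] + f[["C"]]) / acgt
  }
  genome_gc <- gc_of(seqs)
  if (nrow(cnvrs) == 0) {
    if (allow_empty) return(list(cnvr_gc = NA_real_, genome_gc = genome_gc))
    stop_invalid("empty CNVR set; use allow_empty = TRUE for genome GC only")
  }
  missing <- setdiff(unique(cnvrs$chrom), names(seqs))
  if (length(missing))
    stop_invalid("no sequence for chromosome(s): %s",
                 paste(missing, collapse = ", "))
  red <- GenomicRanges::reduce(calls_to_granges(cnvrs))
  sub <- Biostrings::DNAStringSet(lapply(seq_along(red), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(red))[i]
    Biostrings::subseq(seqs[[chrom]],
                       start = GenomicRanges::start(red)[i],
                       end = GenomicRanges::end(red)[i])
  }))
  list(cnvr_gc = gc_of(sub), genome_gc = genome_gc)
}
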