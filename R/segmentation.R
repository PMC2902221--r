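# Piecewise-constant segmentation of ordered log2-ratio profiles by exact
# least-squares dynamic programming, and the |0.4| / 5-probe candidate filter.

#' Segment an ordered log2-ratio profile
#'
#' Finds the piecewise-constant segmentation minimising the total
#' within-segment sum of squared deviations plus `penalty` per segment
#' (penalized optimal partitioning), or the optimal segmentation into at
#' most `max_segments` segments when that is given instead. Both are exact
#' dynamic programs, not heuristics; ties in breakpoint placement are broken
#' toward the leftmost candidate for determinism.
#'
#' The default penalty is the classical changepoint BIC, `2 * sigma^2 *
#' log(n)` per segment, with `sigma` estimated robustly from the median
#' absolute successive difference (`mad(diff(x)) / sqrt(2)`) so isolated
#' aberrant segments do not inflate the noise estimate. Halving the penalty
#' measurably over-splits real aberrations at realistic noise, which breaks
#' dye-swap reciprocal-overlap matching downstream.
#'
#' @param x numeric vector of log2 ratios in genomic order (finite, non-empty)
#' @param penalty per-segment cost; ignored when `max_segments` is given
#' @param max_segments optional cap: return the optimal segmentation with at
#'   most this many segments
#' @return data.frame: start_idx, end_idx (1-based inclusive probe indices),
#'   n_probes, mean
#' @export
segment_profile <- function(x, penalty = NULL, max_segments = NULL) {
  if (length(x) == 0) stop_invalid("cannot segment an empty profile")
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_invalid("profile contains non-finite values")
  x <- as.numeric(x)
  n <- length(x)
  if (!is.null(max_segments)) {
    if (max_segments < 1) stop_invalid("max_segments must be >= 1")
    starts <- dp_fixedk_cpp(x, as.integer(min(max_segments, n)))
  } else {
    if (is.null(penalty)) penalty <- default_penalty(x)
    if (penalty < 0) stop_invalid("penalty must be >= 0")
    starts <- dp_penalized_cpp(x, penalty)
  }
  ends <- c(starts[-1] - 1L, n)
  means <- vapply(seq_along(starts),
                  function(k) mean(x[starts[k]:ends[k]]), numeric(1))
  data.frame(start_idx = starts, end_idx = ends,
             n_probes = ends - starts + 1L, mean = means)
}

#' @rdname segment_profile
#' @export
default_penalty <- function(x) {
  n <- length(x)
  if (n < 3) return(0)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  2 * sigma^2 * log(n)
}

#' Cost of a given segmentation (total within-segment sum of squares)
#'
#' @param x profile
#' @param starts 1-based segment start indices (first must be 1)
#' @return total residual sum of squares
#' @export
segmentation_cost <- function(x, starts) {
  ends <- c(starts[-1] - 1L, length(x))
  sum(vapply(seq_along(starts), function(k) {
    v <- x[starts[k]:ends[k]]
    sum((v - mean(v))^2)
  }, numeric(1)))
}

#' Segment every chromosome of a preprocessed array
#'
#' Chromosome boundaries always break segments; probes are taken in
#' (chrom, start) order. Segment bp coordinates span from the first probe's
#' start to the last probe's end.
#'
#' @param tab preprocessed `cgh_ratio` table
#' @param penalty,max_segments passed to [segment_profile()]
#' @return data.frame of class `cgh_segments`: array_id, chrom, start_idx,
#'   end_idx (per-chromosome probe indices), start, end (bp), n_probes, mean
#' @export
segment_ratios <- function(tab, penalty = NULL, max_segments = NULL) {
  assert_ratio_table(tab)
  lr <- ratio_column(tab)
  aid <- attr(tab, "array_id") %||% NA_character_
  out <- lapply(unique(tab$chrom), function(chrom) {
    idx <- which(tab$chrom == chrom)
    idx <- idx[order(tab$start[idx])]
    seg <- segment_profile(lr[idx], penalty = penalty,
                           max_segments = max_segments)
    data.frame(array_id = aid, chrom = chrom,
               start_idx = seg$start_idx, end_idx = seg$end_idx,
               start = tab$start[idx[seg$start_idx]],
               end = tab$end[idx[seg$end_idx]],
               n_probes = seg$n_probes, mean = seg$mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("cgh_segments", "data.frame")
  out
}

#' Retain candidate aberrant segments
#'
#' Applies the calling filter: a segment is a candidate copy-number event
#' when its |mean log2 ratio| >= `ratio_threshold` and it spans at least
#' `min_probes` consecutive probes (both comparisons inclusive). Each
#' retained segment is annotated with its sign.
#'
#' @param segments output of [segment_ratios()] (or [segment_profile()] with
#'   a `mean` and `n_probes` column)
#' @param ratio_threshold minimum |mean log2 ratio| (default 0.4)
#' @param min_probes minimum consecutive probes (default 5)
#' @return the retained rows, in input order, with a `sign` column ("+"/"-")
#' @export
filter_segments <- function(segments, ratio_threshold = 0.4, min_probes = 5) {
  if (ratio_threshold < 0) stop_invalid("ratio_threshold must be >= 0")
  if (min_probes < 1) stop_invalid("min_probes must be >= 1")
  keep <- abs(segments$mean) >= ratio_threshold &
    segments$n_probes >= min_probes
  out <- segments[keep, , drop = FALSE]
  out$sign <- ifelse(out$mean >= 0, "+", "-")
  rownames(out) <- NULL
  out
}
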