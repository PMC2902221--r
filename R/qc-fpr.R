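# False-positive-rate estimation from sex-mismatched hybridizations (chrX
# dosage expectation) and self-self hybridizations.

#' Build an FPR report from aberrant and denominator lengths
#'
#' `rate = aberrant_bp / (denominator_bp * n_arrays)`. The percent field is
#' *truncated* (not rounded) to 2 decimals: the printed convention of the
#' platform-evaluation arithmetic this reproduces (25,694,212 bp of
#' wrong-direction chrX signal over 8 arrays of an 88,516,663 bp chromosome
#' is the canonical worked example, printed as 3.62%).
#'
#' @param aberrant_bp total bp wrongly called aberrant, summed over arrays
#' @param denominator_bp assayed length per array, bp
#' @param n_arrays number of arrays contributing
#' @param method label: "sex_mismatch" or "self_self"
#' @return list of class `cgh_fpr`: method, aberrant_bp, denominator_bp,
#'   n_arrays, rate (fraction), percent (truncated to 2 decimals)
#' @export
fpr_report <- function(aberrant_bp, denominator_bp, n_arrays,
                       method = "sex_mismatch") {
  if (n_arrays < 1) stop_invalid("n_arrays must be >= 1")
  if (denominator_bp <= 0) stop_invalid("denominator_bp must be > 0")
  if (aberrant_bp < 0) stop_invalid("aberrant_bp must be >= 0")
  rate <- aberrant_bp / (denominator_bp * n_arrays)
  structure(list(method = method, aberrant_bp = aberrant_bp,
                 denominator_bp = denominator_bp, n_arrays = n_arrays,
                 rate = rate, percent = trunc(rate * 1e4) / 1e2),
            class = "cgh_fpr")
}

#' @export
print.cgh_fpr <- function(x, ...) {
  cat(sprintf("<cgh_fpr> %s: %.0f / (%.0f x %d) = %.2f%%\n",
              x$method, x$aberrant_bp, x$denominator_bp, x$n_arrays, x$percent))
  invisible(x)
}

#' False positive rate from sex-mismatched arrays
#'
#' On a male-vs-female hybridization every chrX probe carries a true dosage
#' signal in one known direction (male test over female reference: one X
#' copy over two, log2(1/2) = -1). Any chrX segment called aberrant in the
#' *opposite* direction cannot be dosage and is counted as false positive
#' territory; same-direction excursions are expected signal and are not
#' counted. The rate is the wrong-direction length summed over arrays,
#' divided by chrX length times the number of arrays.
#'
#' Either supply `aberrant_bp` directly (worked-example arithmetic) or
#' per-array candidate calls plus each array's expected sign.
#'
#' @param chrx_length length of chrX in bp
#' @param n_arrays number of sex-mismatched arrays
#' @param aberrant_bp precomputed wrong-direction length (optional)
#' @param calls_by_array list (length `n_arrays`) of filtered candidate-call
#'   data.frames, already restricted to chrX
#' @param expected_sign character vector, per array: "-" when the Cy3 (test)
#'   animal is the male (dosage signal negative), "+" when female
#' @return a `cgh_fpr` report
#' @export
sex_mismatch_fpr <- function(chrx_length, n_arrays, aberrant_bp = NULL,
                             calls_by_array = NULL, expected_sign = NULL) {
  if (n_arrays < 1) stop_invalid("n_arrays must be >= 1")
  if (is.null(aberrant_bp)) {
    if (is.null(calls_by_array) || is.null(expected_sign))
      stop_invalid("supply aberrant_bp or calls_by_array + expected_sign")
    if (length(calls_by_array) != n_arrays ||
        length(expected_sign) != n_arrays)
      stop_invalid("calls_by_array and expected_sign must have length n_arrays")
    aberrant_bp <- sum(vapply(seq_len(n_arrays), function(i) {
      calls <- calls_by_array[[i]]
      if (is.null(calls) || nrow(calls) == 0) return(0)
      wrong <- calls$sign != expected_sign[i]
      sum(calls$end[wrong] - calls$start[wrong])
    }, numeric(1)))
  }
  fpr_report(aberrant_bp, chrx_length, n_arrays, method = "sex_mismatch")
}

#' False positive rate from a self-self dye-swap pair
#'
#' A self-self hybridization has no true copy-number signal, so any called
#' length is false positive territory. Two stringencies are reported: the
#' single-array rate (all filtered candidate segments, averaged over the two
#' arrays) and the dye-swap-concordant rate (length surviving
#' [pair_concordance()], which can only be smaller).
#'
#' @param calls_a,calls_b filtered candidate calls from the two arrays of the
#'   self-self pair
#' @param design the `cgh_design` containing the pair
#' @param genome_length assayed genome length, bp
#' @param min_overlap reciprocal overlap for the concordant stringency
#' @return list with `single` and `concordant` `cgh_fpr` reports
#' @export
self_self_fpr <- function(calls_a, calls_b, design, genome_length,
                          min_overlap = 0.5) {
  ids <- unique(c(calls_a$array_id, calls_b$array_id))
  d <- design[design$array_id %in% ids, , drop = FALSE]
  if (nrow(d) && any(d$cy3 != d$cy5))
    stop_invalid("arrays are not self-self hybridizations")
  single_bp <- sum(calls_a$end - calls_a$start) +
    sum(calls_b$end - calls_b$start)
  single <- fpr_report(single_bp, genome_length, 2, method = "self_self")
  conc <- if (nrow(calls_a) && nrow(calls_b))
    pair_concordance(calls_a, calls_b, design, min_overlap = min_overlap)
  else
    data.frame(start = numeric(), end = numeric())
  concordant <- fpr_report(sum(conc$end - conc$start), genome_length, 1,
                           method = "self_self")
  list(single = single, concordant = concordant)
}
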