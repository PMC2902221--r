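# Per-array signal correction: spatial artifact removal by local regression
# on array grid coordinates, then q-spline between-channel normalization.

assert_ratio_table <- function(tab) {
  need <- c("probe_id", "chrom", "start", "x", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_invalid("probe table is missing column(s): %s", paste(miss, collapse = ", "))
  invisible(tab)
}

#' Remove position-dependent spatial artifacts from an array
#'
#' Two-color arrays show position-dependent non-uniformity of signal across
#' the slide (wash gradients, uneven hybridization). A locally weighted
#' polynomial regression (loess) surface of the log2 ratio over the array
#' grid coordinates (x, y) is fitted and subtracted, in two passes so that
#' strong aberrations pull the surface less. Correction is centred, so the
#' genome-wide mean ratio is untouched.
#'
#' @param tab a `cgh_ratio` probe table with grid coordinates and either a
#'   `log2ratio` column or both channel intensities
#' @param span loess span in (0, 1]; larger = smoother surface
#' @param passes number of fit/subtract passes
#' @return the table with `log2ratio` corrected; input is not modified
#' @export
spatial_correct <- function(tab, span = 0.3, passes = 2) {
  assert_ratio_table(tab)
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1)
    stop_invalid("span must be in (0, 1]")
  if (any(!is.finite(tab$x)) || any(!is.finite(tab$y)))
    stop_invalid("grid coordinates (x, y) must be present and finite")
  lr <- ratio_column(tab)
  total <- 0
  for (p in seq_len(passes)) {
    if (stats::sd(lr) < 1e-10) break  # flat profile: nothing to fit
    fit <- stats::loess(lr ~ x + y,
                        data = data.frame(lr = lr, x = tab$x, y = tab$y),
                        span = span, degree = 2, family = "symmetric",
                        surface = "interpolate",
                        control = stats::loess.control(trace.hat = "approximate"))
    surf <- stats::predict(fit)
    surf <- surf - mean(surf)    # mean correction ~ 0 by construction
    lr <- lr - surf
    total <- total + surf
  }
  out <- tab
  out$log2ratio <- lr
  # push the correction into the test channel so a later channel-space
  # normalization (which recomputes ratios) retains it
  if (!is.null(out$intensity_cy3))
    out$intensity_cy3 <- out$intensity_cy3 / 2^total
  out
}

ratio_column <- function(tab) {
  if (!is.null(tab$log2ratio)) {
    if (any(!is.finite(tab$log2ratio))) stop_invalid("log2ratio has non-finite values")
    return(tab$log2ratio)
  }
  if (is.null(tab$intensity_cy3) || is.null(tab$intensity_cy5))
    stop_invalid("need either a log2ratio column or both channel intensities")
  log2(tab$intensity_cy3 / tab$intensity_cy5)
}

# monotone map through paired quantile knots; linear extension with the end
# slopes outside the knot range so monotonicity holds everywhere
monotone_quantile_map <- function(xq, yq) {
  keep <- !duplicated(xq)
  xq <- xq[keep]; yq <- yq[keep]
  yq <- cummax(yq)  # enforce non-decreasing knots under sampling noise
  if (length(xq) < 2) {
    off <- yq[1] - xq[1]
    return(function(v) v + off)
  }
  f <- stats::splinefun(xq, yq, method = "hyman")
  x1 <- xq[1]; xn <- xq[length(xq)]
  s1 <- max(0, f(x1, deriv = 1)); sn <- max(0, f(xn, deriv = 1))
  function(v) {
    out <- numeric(length(v))
    lo <- v < x1; hi <- v > xn; mid <- !lo & !hi
    out[mid] <- f(v[mid])
    out[lo] <- yq[1] + (v[lo] - x1) * s1
    out[hi] <- yq[length(yq)] + (v[hi] - xn) * sn
    out
  }
}

#' Q-spline normalization of the two channels
#'
#' Fits, for each channel, a smooth monotone (Hyman-filtered cubic) spline
#' through `n_quantiles` paired empirical quantiles of the log intensities
#' against the geometric-mean pseudo-reference of the two channels, applies
#' it, and recomputes the log2 ratios. A constant dye bias or any smooth
#' monotone intensity-dependent distortion between channels is removed; the
#' quantile-quantile deviation between channels can only shrink.
#'
#' @param tab probe table with positive `intensity_cy3` and `intensity_cy5`
#' @param n_quantiles number of quantile anchor points for the spline
#' @return the table with channels rescaled and `log2ratio` recomputed
#' @export
qspline_normalize <- function(tab, n_quantiles = 100) {
  assert_ratio_table(tab)
  if (is.null(tab$intensity_cy3) || is.null(tab$intensity_cy5))
    stop_invalid("q-spline normalization needs both channel intensities")
  if (n_quantiles < 3) stop_invalid("n_quantiles must be >= 3")
  bad <- which(!(tab$intensity_cy3 > 0) | !(tab$intensity_cy5 > 0))
  if (length(bad))
    stop_invalid("non-positive intensity at probe(s): %s",
                 paste(utils::head(tab$probe_id[bad], 5), collapse = ", "))
  l3 <- log2(tab$intensity_cy3)
  l5 <- log2(tab$intensity_cy5)
  ref <- (l3 + l5) / 2  # log2 of the geometric mean pseudo-reference
  probs <- seq(0, 1, length.out = n_quantiles)
  qr <- stats::quantile(ref, probs, names = FALSE, type = 7)
  map3 <- monotone_quantile_map(stats::quantile(l3, probs, names = FALSE), qr)
  map5 <- monotone_quantile_map(stats::quantile(l5, probs, names = FALSE), qr)
  out <- tab
  out$intensity_cy3 <- 2^map3(l3)
  out$intensity_cy5 <- 2^map5(l5)
  out$log2ratio <- map3(l3) - map5(l5)
  out
}

#' Preprocess one array: spatial correction then q-spline normalization
#'
#' @param tab raw `cgh_ratio` table
#' @param span loess span for [spatial_correct()]
#' @param n_quantiles anchors for [qspline_normalize()]
#' @param drop_missing drop probes with missing/non-positive intensities
#'   (with a message) rather than erroring
#' @return preprocessed table with clean `log2ratio`
#' @export
preprocess_array <- function(tab, span = 0.3, n_quantiles = 100,
                             drop_missing = TRUE) {
  assert_ratio_table(tab)
  if (drop_missing && !is.null(tab$intensity_cy3) && !is.null(tab$intensity_cy5)) {
    ok <- is.finite(tab$intensity_cy3) & is.finite(tab$intensity_cy5) &
      tab$intensity_cy3 > 0 & tab$intensity_cy5 > 0
    if (!all(ok)) {
      message(sprintf("dropping %d probe(s) with missing or non-positive intensity",
                      sum(!ok)))
      at <- attributes(tab)
      tab <- tab[ok, , drop = FALSE]
      for (a in c("array_id", "cy3", "cy5")) attr(tab, a) <- at[[a]]
    }
  }
  corrected <- spatial_correct(tab, span = span)
  if (!is.null(corrected$intensity_cy3) && !is.null(corrected$intensity_cy5))
    qspline_normalize(corrected, n_quantiles)
  else
    corrected
}
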