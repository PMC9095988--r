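# Frequency distribution histograms (FDH) of element/parameter images and
# their central moment coefficients (CMCs) P1-P4.
#
# The FDH is a density-normalized histogram over a region of interest whose
# area is exactly 1 by construction: values falling outside the requested
# range are clipped into the edge bins rather than dropped, so no
# probability mass is lost. The CMCs are population moments: P1 the mean,
# P2 the variance, P3 the (dimensionless) skewness and P4 the raw
# (non-excess) kurtosis, so a Gaussian gives P4 = 3.

#' Frequency distribution histogram of a sample
#'
#' @param values Numeric vector (pixel values of one Mueller element or
#'   derived parameter over a region of interest). `NA`s are dropped.
#' @param bins Number of equal-width bins.
#' @param range Length-2 numeric `(lo, hi)`; defaults to the data range.
#'   Values outside are clipped into the first/last bin.
#' @return Object of class `fdh_result` with `bin_edges`, `bin_centers`,
#'   `heights` (density per bin), `peak_h = max(heights)`, and `n`.
#' @export
fdh <- function(values, bins = 256, range = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("empty sample: cannot compute an FDH")
  stopifnot(bins >= 1)
  if (is.null(range)) {
    range <- c(min(values), max(values))
    if (range[1] == range[2]) range <- range + c(-0.5, 0.5)
  }
  lo <- range[1]
  hi <- range[2]
  if (!(lo < hi)) stop("range must satisfy lo < hi")
  edges <- seq(lo, hi, length.out = bins + 1)
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)          # clips out-of-range values
  counts <- tabulate(idx, nbins = bins)
  width <- (hi - lo) / bins
  heights <- counts / (n * width)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-(bins + 1)]) / 2,
                 heights = heights, peak_h = max(heights), n = n),
            class = "fdh_result")
}

#' @export
print.fdh_result <- function(x, ...) {
  cat(sprintf("<fdh_result> %d bins over [%g, %g], n = %d, peak height %.4g\n",
              length(x$heights), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$n, x$peak_h))
  invisible(x)
}

#' Central moment coefficients P1-P4
#'
#' Population (divide-by-n) moments of a sample or of its binned FDH
#' approximation: P1 the expected value, P2 the variance, P3 the skewness
#' and P4 the raw kurtosis. For a constant sample P2 is 0 and P3/P4 are
#' reported as `NA` with `defined = FALSE` (they are 0/0).
#'
#' @param values Numeric vector; `NA`s dropped.
#' @param scale Multiplier applied to the values before taking moments
#'   (FDH domains are sometimes rescaled before reporting; default 1).
#' @param weighted_by_fdh If `TRUE`, moments are computed from bin centers
#'   weighted by FDH heights (the binned approximation) instead of the raw
#'   values.
#' @param bins,range Passed to [fdh()] when `weighted_by_fdh = TRUE`.
#' @return Object of class `cmc_set` with fields `P1`, `P2`, `P3`, `P4`,
#'   `scale`, `defined`, `n`.
#' @export
cmc <- function(values, scale = 1, weighted_by_fdh = FALSE, bins = 256,
                range = NULL) {
  values <- values[!is.na(values)] * scale
  n <- length(values)
  if (n < 2) stop("need at least 2 values for central moments")
  if (weighted_by_fdh) {
    h <- fdh(values, bins = bins, range = range)
    w <- h$heights * diff(h$bin_edges)           # probability per bin, sums to 1
    x <- h$bin_centers
    p1 <- sum(w * x)
    p2 <- sum(w * (x - p1)^2)
    m3 <- sum(w * (x - p1)^3)
    m4 <- sum(w * (x - p1)^4)
  } else {
    p1 <- mean(values)
    p2 <- mean((values - p1)^2)
    m3 <- mean((values - p1)^3)
    m4 <- mean((values - p1)^4)
  }
  defined <- p2 > 0
  structure(list(P1 = p1, P2 = p2,
                 P3 = if (defined) m3 / p2^1.5 else NA_real_,
                 P4 = if (defined) m4 / p2^2 else NA_real_,
                 scale = scale, defined = defined, n = n),
            class = "cmc_set")
}

#' @export
print.cmc_set <- function(x, ...) {
  cat(sprintf("<cmc_set> n = %d, scale = %g\n  P1 = %.4g  P2 = %.4g  P3 = %s  P4 = %s\n",
              x$n, x$scale, x$P1, x$P2,
              if (x$defined) sprintf("%.4g", x$P3) else "undefined",
              if (x$defined) sprintf("%.4g", x$P4) else "undefined"))
  invisible(x)
}

# Pull the per-pixel values of one named element/parameter as a matrix.
plane_of <- function(x, name) {
  if (inherits(x, "mueller_image")) {
    k <- match(name, ELEMENT_NAMES)
    if (is.na(k)) stop(sprintf("unknown Mueller element '%s'", name))
    return(matrix(x$m[, , k], x$height, x$width))
  }
  if (inherits(x, "parameter_maps")) {
    if (is.null(x[[name]]) || !is.matrix(x[[name]])) {
      stop(sprintf("unknown parameter '%s'", name))
    }
    return(x[[name]])
  }
  stop("x must be a mueller_image or parameter_maps")
}

#' FDH and CMC report over regions of interest
#'
#' One row per (element, ROI): FDH peak height and P1-P4, together with the
#' binning settings used, so the report is reproducible.
#'
#' @param x A `mueller_image` or `parameter_maps`.
#' @param rois Named list of logical ROI masks (image-sized), or a single
#'   mask.
#' @param elements Character vector of element/parameter names; defaults to
#'   the eight off-intensity Mueller elements in reading order.
#' @param bins,range,scale Passed through to [fdh()] and [cmc()].
#' @return Data frame with columns `roi`, `element`, `n`, `peak_h`,
#'   `P1`-`P4`, `bins`, `range_lo`, `range_hi`, `scale`.
#' @export
fdh_report <- function(x, rois, elements = NULL, bins = 256, range = NULL,
                       scale = 1) {
  if (is.null(elements)) {
    elements <- if (inherits(x, "mueller_image")) {
      c("m12", "m13", "m21", "m22", "m23", "m31", "m32", "m33")
    } else {
      c("one_minus_delta", "t")
    }
  }
  if (is.matrix(rois) && is.logical(rois)) rois <- list(roi = rois)
  stopifnot(is.list(rois), length(names(rois)) == length(rois))
  valid <- x$valid
  rows <- list()
  for (rn in names(rois)) {
    sel <- rois[[rn]] & valid
    if (!any(sel)) stop(sprintf("ROI '%s' is empty after masking", rn))
    for (el in elements) {
      v <- plane_of(x, el)[sel]
      h <- fdh(v, bins = bins, range = range)
      mom <- cmc(v, scale = scale)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = rn, element = el, n = h$n, peak_h = h$peak_h,
        P1 = mom$P1, P2 = mom$P2, P3 = mom$P3, P4 = mom$P4,
        bins = bins, range_lo = h$bin_edges[1],
        range_hi = h$bin_edges[length(h$bin_edges)], scale = scale,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
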