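# Region-of-interest summaries and group comparisons.
#
# The unit of analysis for group tests is the per-sample ROI mean (one
# number per sample per region), not the pixel, to avoid pseudo-replication
# when pixels within a sample are correlated.

#' Mean Mueller elements and parameters over a region of interest
#'
#' @param img A normalized `mueller_image`.
#' @param maps Optional `parameter_maps` computed from `img` (means of
#'   `D`, `one_minus_delta`, `delta_ret`, `t` are included when given).
#' @param roi Logical image-sized mask selecting the region.
#' @param label Region label (e.g. `"GBM"`, `"non-GBM"`).
#' @param sample_id Identifier of the sample the image came from.
#' @return One-row data frame: `sample_id`, `roi_label`, `n_pixels`, the
#'   nine element means `m11`-`m33`, and parameter means when available.
#' @export
summarize_roi <- function(img, roi, label = "roi", maps = NULL,
                          sample_id = "sample") {
  stopifnot(inherits(img, "mueller_image"),
            is.logical(roi), identical(dim(roi), c(img$height, img$width)))
  sel <- roi & img$valid
  if (!any(sel)) stop(sprintf("ROI '%s' has no valid pixels", label))
  flat <- flatten_image(img)
  out <- data.frame(sample_id = sample_id, roi_label = label,
                    n_pixels = sum(sel), stringsAsFactors = FALSE)
  for (k in seq_along(ELEMENT_NAMES)) {
    out[[ELEMENT_NAMES[k]]] <- mean(flat[as.vector(sel), k])
  }
  if (!is.null(maps)) {
    stopifnot(inherits(maps, "parameter_maps"))
    selp <- roi & maps$valid
    for (p in c("D", "one_minus_delta", "delta_ret", "t")) {
      out[[p]] <- mean(maps[[p]][selp])
    }
  }
  out
}

#' Diagonal-magnitude symmetry check
#'
#' Essentially diagonal backscattering Mueller matrices of isotropic
#' depolarizing tissue satisfy `|m22| == |m33|`; this reports how far a
#' region summary (or a single matrix) deviates from that.
#'
#' @param x A region summary row from [summarize_roi()], or a 3x3 matrix.
#' @param tol Pass threshold on the absolute magnitude difference.
#' @return List with `diff = abs(abs(m22) - abs(m33))` and `pass`.
#' @export
diagonal_symmetry <- function(x, tol = 0.02) {
  if (is.matrix(x)) {
    m22 <- x[2, 2]
    m33 <- x[3, 3]
  } else {
    m22 <- x$m22
    m33 <- x$m33
  }
  d <- abs(abs(m22) - abs(m33))
  list(diff = d, pass = d <= tol)
}

#' Compare two groups of region summaries parameter by parameter
#'
#' Two-sided t-tests (Welch unequal-variance by default) on per-sample ROI
#' means, one test per parameter. P-values are reported raw (one test per
#' parameter, as is conventional for these comparisons); an optional
#' Bonferroni adjustment is available.
#'
#' @param summaries Data frame of stacked [summarize_roi()] rows covering a
#'   cohort, with exactly two distinct `roi_label` values.
#' @param parameters Column names to test.
#' @param alpha Significance level for the `significant` flag.
#' @param var_equal `FALSE` (Welch, default) or `TRUE` (Student pooled).
#' @param bonferroni Adjust p-values for the number of parameters tested.
#' @return Data frame: `parameter`, group means/sds/sizes, `p_value`,
#'   `significant`.
#' @export
compare_groups <- function(summaries, parameters = c("m22", "m33",
                                                     "one_minus_delta", "t"),
                           alpha = 0.05, var_equal = FALSE,
                           bonferroni = FALSE) {
  labs <- unique(summaries$roi_label)
  if (length(labs) != 2) stop("summaries must contain exactly two group labels")
  g1 <- summaries[summaries$roi_label == labs[1], , drop = FALSE]
  g2 <- summaries[summaries$roi_label == labs[2], , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    stop("need at least 2 samples per group for a t-test")
  }
  rows <- lapply(parameters, function(p) {
    x <- g1[[p]]
    y <- g2[[p]]
    if (is.null(x) || is.null(y)) stop(sprintf("parameter '%s' not found", p))
    if (var(x) == 0 && var(y) == 0) {
      pv <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else {
      pv <- t.test(x, y, var.equal = var_equal)$p.value
    }
    data.frame(parameter = p,
               group1 = labs[1], mean1 = mean(x), sd1 = sd(x), n1 = length(x),
               group2 = labs[2], mean2 = mean(y), sd2 = sd(y), n2 = length(y),
               p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_value <- pmin(1, out$p_value * length(parameters))
  out$significant <- out$p_value < alpha
  out
}
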