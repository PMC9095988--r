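# Core algebra for 3x3 (linear-polarization) Mueller matrices.
#
# Convention: Stokes sub-vector (s0, s1, s2); the circular component s3 is
# dropped throughout, as appropriate for a rotating-linear-polarizer
# instrument. Angles are measured counter-clockwise from horizontal, in
# radians, with the usual 2*theta doubling on the Poincare equator.

ELEMENT_NAMES <- c("m11", "m12", "m13", "m21", "m22", "m23", "m31", "m32", "m33")

#' Construct a linear Stokes vector
#'
#' @param s0 Total intensity (must be > 0 for physical light).
#' @param s1 Horizontal-minus-vertical linear component.
#' @param s2 +45/-45 degree linear component.
#' @return Numeric vector of length 3 with class checking applied.
#' @details The degree of linear polarization `sqrt(s1^2 + s2^2)/s0` must not
#'   exceed 1 (up to a small numerical tolerance).
#' @export
stokes_lin <- function(s0, s1 = 0, s2 = 0) {
  if (!is.finite(s0) || s0 <= 0) {
    stop("s0 must be a positive finite intensity")
  }
  if (s1^2 + s2^2 > s0^2 * (1 + 1e-9)) {
    stop("degree of linear polarization exceeds 1: s1^2 + s2^2 > s0^2")
  }
  c(s0 = s0, s1 = s1, s2 = s2)
}

#' Validate a 3x3 Mueller matrix
#'
#' Checks shape, finiteness and (optionally) passive-sample physicality:
#' after m11 normalization every element must lie in `[-1 - tol, 1 + tol]`.
#' The default tolerance 0.05 absorbs measurement noise of the order of the
#' instrument's element-wise calibration error.
#'
#' @param M Numeric 3x3 matrix.
#' @param tol Physicality tolerance on normalized elements.
#' @param normalized If `TRUE`, additionally require `m11 == 1`.
#' @return `M`, invisibly, if valid; otherwise an error.
#' @export
validate_mueller3 <- function(M, tol = 0.05, normalized = FALSE) {
  if (!is.matrix(M) || !identical(dim(M), c(3L, 3L)) || !is.numeric(M)) {
    stop("M must be a numeric 3x3 matrix")
  }
  if (!all(is.finite(M))) stop("M contains non-finite elements")
  if (M[1, 1] <= 0) stop("m11 must be positive")
  if (normalized) {
    if (abs(M[1, 1] - 1) > 1e-12) stop("M is not normalized: m11 != 1")
    if (any(abs(M) > 1 + tol)) {
      stop("normalized Mueller elements exceed physical bound 1 + tol")
    }
  }
  invisible(M)
}

#' Normalize a Mueller matrix by its m11 element
#'
#' All elements are divided by m11 so that the total-intensity channel is 1,
#' the convention used when displaying element images of tissue.
#'
#' @param M Numeric 3x3 Mueller matrix with `m11 > epsilon`.
#' @param epsilon Smallest m11 treated as nonzero.
#' @return The normalized matrix (`m11 == 1`).
#' @export
normalize_by_m11 <- function(M, epsilon = 1e-6) {
  validate_mueller3(M)
  if (M[1, 1] <= epsilon) {
    stop("m11 <= epsilon: intensity too low to normalize")
  }
  M / M[1, 1]
}

#' Ideal partial depolarizer
#'
#' Returns `diag(1, delta, delta)` in transmission convention, or
#' `diag(1, delta, -delta)` in backscattering convention, where the
#' mirror-like reflection flips the sign of the 45-degree linear channel.
#' The backscatter form reproduces the negative m33 observed in
#' backscattering tissue measurements.
#'
#' @param delta Depolarization coefficient in `[0, 1]` (1 = none, 0 = full).
#' @param backscatter Use the backscattering sign convention.
#' @return 3x3 Mueller matrix.
#' @export
make_depolarizer <- function(delta, backscatter = FALSE) {
  if (!is.finite(delta) || delta < 0 || delta > 1) {
    stop("delta must lie in [0, 1]")
  }
  diag(c(1, delta, if (backscatter) -delta else delta))
}

#' Linear retarder (3x3 sub-block)
#'
#' @param delta Retardance in radians.
#' @param theta Fast-axis orientation in radians (counter-clockwise from
#'   horizontal).
#' @return 3x3 Mueller matrix of an ideal linear retarder restricted to the
#'   linear Stokes channels.
#' @export
make_linear_retarder <- function(delta, theta = 0) {
  c2 <- cos(2 * theta)
  s2 <- sin(2 * theta)
  cd <- cos(delta)
  matrix(c(
    1, 0, 0,
    0, c2^2 + s2^2 * cd, c2 * s2 * (1 - cd),
    0, c2 * s2 * (1 - cd), s2^2 + c2^2 * cd
  ), nrow = 3, byrow = TRUE)
}

#' Linear diattenuator from its diattenuation vector
#'
#' Builds the symmetric diattenuator sub-matrix from the two linear
#' components of the diattenuation vector `d = (d1, d2)` with magnitude
#' `D = sqrt(d1^2 + d2^2) <= 1`.
#'
#' @param d1,d2 Components of the diattenuation vector.
#' @return 3x3 Mueller matrix; the identity when `D == 0`.
#' @export
make_diattenuator <- function(d1, d2 = 0) {
  D2 <- d1^2 + d2^2
  if (D2 > 1 + 1e-12) stop("diattenuation magnitude exceeds 1")
  if (D2 == 0) return(diag(3))
  a <- sqrt(max(0, 1 - D2))
  b <- 1 - a
  matrix(c(
    1, d1, d2,
    d1, a + b * d1^2 / D2, b * d1 * d2 / D2,
    d2, b * d1 * d2 / D2, a + b * d2^2 / D2
  ), nrow = 3, byrow = TRUE)
}

#' Rotate a sample in the laboratory frame
#'
#' Conjugates `M` with the Stokes rotation acting on the (s1, s2) sub-space:
#' `R(phi) %*% M %*% R(-phi)` with the standard angle doubling, so a retarder
#' with fast axis `theta` maps to one with fast axis `theta + phi`.
#'
#' @param M 3x3 Mueller matrix.
#' @param phi Physical rotation angle in radians.
#' @return The rotated Mueller matrix.
#' @export
rotate_sample <- function(M, phi) {
  validate_mueller3(M)
  c2 <- cos(2 * phi)
  s2 <- sin(2 * phi)
  R <- matrix(c(1, 0, 0, 0, c2, -s2, 0, s2, c2), nrow = 3, byrow = TRUE)
  Rm <- matrix(c(1, 0, 0, 0, c2, s2, 0, -s2, c2), nrow = 3, byrow = TRUE)
  R %*% M %*% Rm
}

#' Per-pixel Mueller matrix image
#'
#' Container for a grid of 3x3 Mueller matrices: a `height x width x 9`
#' array in row-major element order (m11, m12, m13, m21, ..., m33) plus a
#' logical validity mask (pixels with unusably low intensity are masked).
#'
#' @param m Numeric array `c(height, width, 9)`.
#' @param valid Logical `height x width` matrix; defaults to all valid.
#' @return Object of class `mueller_image`.
#' @export
mueller_image <- function(m, valid = NULL) {
  stopifnot(is.array(m), length(dim(m)) == 3, dim(m)[3] == 9)
  h <- dim(m)[1]
  w <- dim(m)[2]
  if (is.null(valid)) valid <- matrix(TRUE, h, w)
  stopifnot(is.logical(valid), identical(dim(valid), c(h, w)))
  structure(list(m = m, valid = valid, height = h, width = w),
            class = "mueller_image")
}

#' @export
print.mueller_image <- function(x, ...) {
  cat(sprintf("<mueller_image> %d x %d pixels, %d valid (%.1f%%)\n",
              x$height, x$width, sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Extract the 3x3 matrix at one pixel
#'
#' @param img A `mueller_image`.
#' @param i,j Pixel row and column.
#' @return 3x3 matrix, or `NULL` for a masked pixel.
#' @export
pixel_matrix <- function(img, i, j) {
  stopifnot(inherits(img, "mueller_image"))
  if (!img$valid[i, j]) return(NULL)
  matrix(img$m[i, j, ], nrow = 3, byrow = TRUE)
}

#' Build a uniform Mueller image from one matrix
#'
#' @param M 3x3 Mueller matrix replicated at every pixel.
#' @param height,width Image size in pixels.
#' @return A `mueller_image`.
#' @export
uniform_mueller_image <- function(M, height, width) {
  validate_mueller3(M)
  flat <- as.vector(t(M))
  m <- array(rep(flat, each = height * width), dim = c(height, width, 9))
  mueller_image(m)
}

# Flatten image to an n_pixels x 9 matrix (row-major element order).
flatten_image <- function(img) {
  matrix(img$m, ncol = 9, dimnames = list(NULL, ELEMENT_NAMES))
}
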