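# Forward model and inversion for a rotating-polarizer PSG/PSA instrument.
#
# The polarization state generator (PSG) is an ideal linear polarizer at
# angle alpha; the analyzer (PSA) an identical polarizer at beta. Detected
# intensity for a sample M is (gain/2) * a(beta)' M s(alpha), which is
# linear in the nine Mueller elements, so a set of >= 9 independent
# (alpha, beta) pairs determines M per pixel by least squares.

#' Stokes vector behind an ideal linear polarizer
#'
#' @param angle Polarizer transmission axis, radians from horizontal.
#' @return Normalized linear Stokes vector `(1, cos 2a, sin 2a)`.
#' @export
stokes_of_polarizer <- function(angle) {
  c(1, cos(2 * angle), sin(2 * angle))
}

#' Default PSG/PSA angle design
#'
#' The minimal exactly-determined design for linear-only polarimetry: the
#' 3x3 grid of generator and analyzer angles over 0, 45 and 90 degrees
#' (9 frames).
#'
#' @return Data frame with columns `alpha` and `beta` in radians.
#' @export
default_angle_design <- function() {
  ang <- c(0, pi / 4, pi / 2)
  expand.grid(alpha = ang, beta = ang, KEEP.OUT.ATTRS = FALSE)
}

#' Instrument matrix of an angle design
#'
#' One row per frame: the outer product of the analyzer projection vector
#' and the generator Stokes vector, flattened over the nine Mueller
#' elements in row-major order, scaled by `gain/2`.
#'
#' @param alpha,beta Vectors of PSG and PSA angles in radians (same length).
#' @param gain Detector scale factor (> 0).
#' @return `length(alpha) x 9` matrix with a `"condition"` attribute giving
#'   its 2-norm condition number.
#' @export
instrument_matrix <- function(alpha, beta, gain = 1) {
  stopifnot(length(alpha) == length(beta), gain > 0)
  n <- length(alpha)
  A <- matrix(0, n, 9)
  for (k in seq_len(n)) {
    s <- stokes_of_polarizer(alpha[k])
    a <- stokes_of_polarizer(beta[k])
    A[k, ] <- (gain / 2) * as.vector(t(outer(a, s)))  # row-major a_i * s_j
  }
  sv <- svd(A, nu = 0, nv = 0)$d
  attr(A, "condition") <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  A
}

#' Predicted detected intensity for one sample matrix
#'
#' @param M 3x3 Mueller matrix.
#' @param alpha PSG polarizer angle (radians).
#' @param beta PSA polarizer angle (radians).
#' @param gain Detector scale factor.
#' @return Scalar intensity `(gain/2) * a(beta)' M s(alpha)`.
#' @export
predict_intensity <- function(M, alpha, beta, gain = 1) {
  validate_mueller3(M)
  stopifnot(gain > 0)
  s <- stokes_of_polarizer(alpha)
  a <- stokes_of_polarizer(beta)
  drop((gain / 2) * crossprod(a, M %*% s))
}

#' Intensity frame set
#'
#' @param frames Numeric array `c(height, width, n_frames)` of nonnegative
#'   intensities.
#' @param alpha,beta PSG/PSA angles in radians, one per frame.
#' @param gain Detector scale factor used in the forward model.
#' @return Object of class `frame_set`.
#' @export
frame_set <- function(frames, alpha, beta, gain = 1) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  n <- dim(frames)[3]
  if (length(alpha) != n || length(beta) != n) {
    stop("alpha/beta must have one entry per frame")
  }
  if (n < 9) stop("at least 9 frames are required to determine 9 elements")
  if (any(frames < 0)) stop("negative intensities in frame set")
  structure(list(frames = frames, alpha = alpha, beta = beta, gain = gain,
                 height = dim(frames)[1], width = dim(frames)[2]),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames of %d x %d pixels, gain %g\n",
              length(x$alpha), x$height, x$width, x$gain))
  invisible(x)
}

# Check an angle design spans all nine elements; error names the angles.
check_angle_design <- function(alpha, beta) {
  A <- instrument_matrix(alpha, beta)
  r <- qr(A)$rank
  if (r < 9) {
    stop(sprintf(
      "rank-deficient angle design (rank %d < 9): alpha = {%s}, beta = {%s} degrees",
      r,
      paste(round(alpha * 180 / pi, 2), collapse = ", "),
      paste(round(beta * 180 / pi, 2), collapse = ", ")))
  }
  invisible(A)
}

#' Simulate intensity frames from a Mueller image
#'
#' Applies the forward model at every pixel for every (alpha, beta) pair,
#' optionally adding zero-mean Gaussian detector noise.
#'
#' @param img A `mueller_image` (ground truth).
#' @param alpha,beta Angle design in radians; defaults to
#'   [default_angle_design()].
#' @param gain Detector scale factor.
#' @param noise_sd Gaussian noise standard deviation expressed as a fraction
#'   of the maximum noiseless intensity (0 = noiseless).
#' @return A `frame_set`. Noisy intensities are floored at 0.
#' @export
simulate_frames <- function(img, alpha = NULL, beta = NULL, gain = 1,
                            noise_sd = 0) {
  stopifnot(inherits(img, "mueller_image"), noise_sd >= 0)
  if (is.null(alpha) || is.null(beta)) {
    d <- default_angle_design()
    alpha <- d$alpha
    beta <- d$beta
  }
  A <- instrument_matrix(alpha, beta, gain)
  Y <- flatten_image(img) %*% t(A)            # n_pixels x n_frames
  if (noise_sd > 0) {
    Y <- Y + rnorm(length(Y), sd = noise_sd * max(abs(Y)))
    Y[Y < 0] <- 0
  }
  frames <- array(Y, dim = c(img$height, img$width, length(alpha)))
  frame_set(frames, alpha, beta, gain)
}

#' Reconstruct a Mueller image from intensity frames
#'
#' Solves, pixel by pixel, the linear system relating the nine Mueller
#' elements to the detected intensities (ordinary least squares for more
#' than nine frames), then normalizes each pixel by its m11. Pixels whose
#' recovered m11 falls at or below `epsilon` times the image maximum are
#' masked rather than normalized. Because of the normalization the result
#' is invariant to the global detector gain.
#'
#' @param fs A `frame_set`.
#' @param epsilon Relative m11 threshold below which a pixel is masked.
#' @return A `mueller_image` of m11-normalized matrices.
#' @export
reconstruct_mueller <- function(fs, epsilon = 1e-6) {
  stopifnot(inherits(fs, "frame_set"))
  check_angle_design(fs$alpha, fs$beta)
  A <- instrument_matrix(fs$alpha, fs$beta, fs$gain)
  Y <- matrix(fs$frames, ncol = length(fs$alpha))
  X <- t(qr.solve(A, t(Y)))                   # n_pixels x 9
  m11 <- X[, 1]
  valid <- m11 > epsilon * max(m11, 0)
  Xn <- X / ifelse(valid, m11, 1)
  Xn[!valid, ] <- NA_real_
  mueller_image(array(Xn, dim = c(fs$height, fs$width, 9)),
                matrix(valid, fs$height, fs$width))
}

#' Element-wise calibration error between two Mueller matrices
#'
#' The maximum over the nine elements of the absolute difference between a
#' measured and a reference matrix, the scalar conventionally quoted as the
#' element-wise accuracy of a polarimeter after calibration.
#'
#' @param M_measured,M_reference Normalized 3x3 Mueller matrices.
#' @return Scalar maximum absolute element difference.
#' @export
calibration_error <- function(M_measured, M_reference) {
  validate_mueller3(M_measured)
  validate_mueller3(M_reference)
  max(abs(M_measured - M_reference))
}
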