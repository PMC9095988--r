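# 3x3 Mueller matrix polar decomposition (MMPD) and the Mueller matrix
# transformation (MMT) anisotropy parameter.
#
# MMPD factors a normalized sample matrix as M = M_Delta %*% M_R %*% M_D
# (depolarizer . retarder . diattenuator). The diattenuation vector is read
# off the first row of M; stripping it leaves M' = M %*% solve(M_D), and the
# symmetric product M_DR = M' %*% t(M') has eigenvalues
# {1, Delta^2, Delta^2 cos^2 delta}: the unit eigenvalue belongs to the
# intensity channel, the larger remaining one gives the depolarization
# coefficient Delta and the ratio gives the linear retardance delta.

#' Diattenuation of a normalized Mueller matrix
#'
#' @param M Normalized (`m11 == 1`) 3x3 Mueller matrix.
#' @return List with `D` (magnitude, clipped to `[0, 1]`) and `d` (the
#'   vector `(m12, m13)`).
#' @export
diattenuation <- function(M) {
  validate_mueller3(M)
  d <- c(M[1, 2], M[1, 3])
  list(D = min(1, sqrt(sum(d^2))), d = d)
}

#' Remove the diattenuator factor from a Mueller matrix
#'
#' Computes `M %*% solve(M_D)` where `M_D` is the diattenuator built from
#' the first row of `M`; for zero diattenuation `M` is returned unchanged.
#'
#' @param M Normalized 3x3 Mueller matrix with diattenuation `D < 1`.
#' @param tol Singularity guard: `D >= 1 - tol` is an error.
#' @return The depolarizer-retarder product `M' = M_Delta %*% M_R`.
#' @export
strip_diattenuation <- function(M, tol = 1e-9) {
  da <- diattenuation(M)
  if (da$D == 0) return(M)
  if (da$D >= 1 - tol) stop("diattenuator is singular (D >= 1)")
  M %*% solve(make_diattenuator(da$d[1], da$d[2]))
}

#' Polar decomposition parameters of one Mueller matrix
#'
#' @param M Normalized 3x3 Mueller matrix.
#' @param eig_tol Eigenvalues in `[-eig_tol, 0)` (numerical noise) are
#'   clamped to 0; more negative ones are an error.
#' @return List of class `mmpd_result`: `D` diattenuation, `delta_dep`
#'   depolarization coefficient Delta in `[0, 1]`, `one_minus_delta` the
#'   depolarization power 1 - Delta, `delta_ret` linear retardance in
#'   radians in `[0, pi/2]`, and `eigenvalues` the two non-unit eigenvalues
#'   of `M_DR` (descending) for diagnostics.
#' @export
mmpd <- function(M, eig_tol = 1e-6) {
  validate_mueller3(M)
  da <- diattenuation(M)
  Mp <- strip_diattenuation(M)
  MDR <- Mp %*% t(Mp)
  e <- eigen(MDR, symmetric = TRUE)
  # the intensity-channel eigenvalue is the one whose eigenvector points
  # most strongly along s0; exclude it and keep the other two
  unit_idx <- which.max(abs(e$vectors[1, ]))
  lam <- sort(e$values[-unit_idx], decreasing = TRUE)
  if (any(lam < -eig_tol)) stop("M_DR has a significantly negative eigenvalue")
  lam <- pmax(lam, 0)
  delta_dep <- min(1, sqrt(lam[1]))
  delta_ret <- if (lam[1] > 0) acos(sqrt(min(1, lam[2] / lam[1]))) else 0
  structure(list(D = da$D, delta_dep = delta_dep,
                 one_minus_delta = 1 - delta_dep,
                 delta_ret = delta_ret, eigenvalues = lam),
            class = "mmpd_result")
}

#' MMT anisotropy parameter t
#'
#' `t = sqrt((m22 - m33)^2 + (m23 -+ m32)^2) / 2`. The `"minus"` variant
#' uses `(m23 - m32)`; the `"plus"` variant uses `(m23 + m32)` and is
#' invariant under sample rotation. The two coincide whenever
#' `m23 == m32 == 0`, as for essentially diagonal backscattering matrices.
#'
#' @param M Normalized 3x3 Mueller matrix.
#' @param variant `"minus"` (default) or `"plus"`.
#' @return List of class `mmt_result` with fields `t` and `variant`.
#' @export
mmt_t <- function(M, variant = c("minus", "plus")) {
  validate_mueller3(M)
  variant <- match.arg(variant)
  off <- if (variant == "minus") M[2, 3] - M[3, 2] else M[2, 3] + M[3, 2]
  structure(list(t = sqrt((M[2, 2] - M[3, 3])^2 + off^2) / 2,
                 variant = variant),
            class = "mmt_result")
}

#' Per-pixel decomposition of a Mueller image
#'
#' Applies the polar decomposition and the MMT anisotropy parameter at
#' every valid pixel (compiled kernel). Pixels where the decomposition is
#' singular (diattenuation at 1, strongly negative eigenvalues, non-finite
#' elements) are removed from the shared validity mask.
#'
#' @param img A normalized `mueller_image`.
#' @param eig_tol Negative-eigenvalue clamp tolerance (see [mmpd()]).
#' @return Object of class `parameter_maps`: matrices `D`, `delta_dep`,
#'   `one_minus_delta`, `delta_ret`, `t` (the `"minus"` variant),
#'   `t_plus`, and the logical `valid` mask.
#' @export
decompose_image <- function(img, eig_tol = 1e-6) {
  stopifnot(inherits(img, "mueller_image"))
  if (!any(img$valid)) stop("all pixels are invalid")
  mflat <- flatten_image(img)
  mflat[!as.vector(img$valid), ] <- NA_real_
  P <- decompose_pixels_cpp(mflat, eig_tol)
  h <- img$height
  w <- img$width
  shape <- function(k) matrix(P[, k], h, w)
  valid <- img$valid & matrix(P[, 7] > 0.5, h, w)
  structure(list(D = shape(1), delta_dep = shape(2),
                 one_minus_delta = shape(3), delta_ret = shape(4),
                 t = shape(5), t_plus = shape(6), valid = valid,
                 height = h, width = w),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("<parameter_maps> %d x %d pixels, %d valid\n",
              x$height, x$width, sum(x$valid)))
  for (p in c("D", "delta_dep", "one_minus_delta", "delta_ret", "t")) {
    v <- x[[p]][x$valid]
    cat(sprintf("  %-16s mean %8.4f  sd %8.4f\n", p, mean(v), sd(v)))
  }
  invisible(x)
}
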