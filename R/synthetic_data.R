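# Synthetic two-region phantoms and cohorts.
#
# A phantom is a two-region Mueller image (default: left/right split) whose
# region matrices come either from published average tissue matrices or
# from optical-element parameters (depolarizer . retarder . diattenuator in
# backscattering convention), plus the intensity frames a rotating-polarizer
# instrument would record for it, with additive Gaussian detector noise.
# A cohort repeats the phantom with per-sample Gaussian jitter on the
# diagonal elements, emulating inter-sample biological variability in a
# group of surgical specimens.

#' Reference average tissue Mueller matrices
#'
#' Published cohort-average normalized backscattering 3x3 Mueller matrices
#' of glioblastoma (GBM) tissue and of adjacent non-tumor white matter
#' (non-GBM). Both are essentially diagonal with `|m22| ~ |m33|` and a
#' negative m33 (backscattering sign convention); the GBM matrix
#' depolarizes less (larger diagonal magnitudes) than white matter.
#'
#' @param which `"gbm"` or `"non_gbm"`.
#' @return Normalized 3x3 Mueller matrix.
#' @export
tissue_preset <- function(which = c("gbm", "non_gbm")) {
  which <- match.arg(which)
  switch(which,
    gbm = matrix(c(1, -0.02, -0.01,
                   0,  0.32,  0,
                   0,  0,    -0.33), nrow = 3, byrow = TRUE),
    non_gbm = matrix(c(1, -0.02, -0.01,
                       0,  0.09,  0,
                       0,  0,    -0.09), nrow = 3, byrow = TRUE))
}

#' Region specification for a phantom
#'
#' Exactly one of `matrix` or the optical parameters must be given. With
#' optical parameters the region matrix is the product
#' depolarizer(delta_dep) . retarder(delta_ret, theta) . diattenuator(d1, d2).
#'
#' @param label Region label.
#' @param matrix Direct target 3x3 Mueller matrix (normalized).
#' @param delta_dep Depolarization coefficient in `[0, 1]`.
#' @param delta_ret,theta Retardance and fast-axis angle (radians).
#' @param d1,d2 Diattenuation vector components.
#' @param backscatter Backscattering sign convention for the depolarizer.
#' @return Object of class `region_spec` carrying the resolved matrix.
#' @export
region_spec <- function(label, matrix = NULL, delta_dep = NULL,
                        delta_ret = 0, theta = 0, d1 = 0, d2 = 0,
                        backscatter = TRUE) {
  has_mat <- !is.null(matrix)
  has_par <- !is.null(delta_dep)
  if (has_mat == has_par) {
    stop("give exactly one of 'matrix' or optical parameters ('delta_dep', ...)")
  }
  M <- if (has_mat) {
    matrix
  } else {
    make_depolarizer(delta_dep, backscatter) %*%
      make_linear_retarder(delta_ret, theta) %*%
      make_diattenuator(d1, d2)
  }
  validate_mueller3(M, normalized = TRUE)
  structure(list(label = label, M = M), class = "region_spec")
}

# Left/right split masks for a h x w image: region 1 gets the left block.
split_masks <- function(height, width, labels) {
  wl <- floor(width / 2)
  left <- matrix(FALSE, height, width)
  left[, seq_len(wl)] <- TRUE
  out <- list(left, !left)
  names(out) <- labels
  out
}

#' Build a two-region phantom and its simulated frames
#'
#' @param regions List of two `region_spec` objects; defaults to the
#'   GBM / non-GBM presets.
#' @param size Image size `c(height, width)`; regions split left/right.
#' @param masks Optional named list of two logical masks tiling the image
#'   (no overlap); overrides the default split.
#' @param noise_sd Detector noise sd as a fraction of the maximum intensity.
#' @param gain Detector gain for the simulated frames.
#' @param alpha,beta Angle design; defaults to [default_angle_design()].
#' @param seed Optional integer seed making the frames reproducible.
#' @return List of class `phantom`: `truth` (noiseless `mueller_image`),
#'   `frames` (`frame_set`), `rois` (named masks), `labels`.
#' @export
make_phantom <- function(regions = list(region_spec("GBM", tissue_preset("gbm")),
                                        region_spec("non-GBM", tissue_preset("non_gbm"))),
                         size = c(64, 64), masks = NULL, noise_sd = 0,
                         gain = 1, alpha = NULL, beta = NULL, seed = NULL) {
  stopifnot(length(regions) == 2,
            all(vapply(regions, inherits, logical(1), "region_spec")))
  labels <- vapply(regions, `[[`, character(1), "label")
  h <- size[1]
  w <- size[2]
  if (is.null(masks)) {
    masks <- split_masks(h, w, labels)
  } else {
    stopifnot(length(masks) == 2)
    names(masks) <- labels
    overlap <- masks[[1]] & masks[[2]]
    if (any(overlap)) stop("region masks overlap")
    if (!all(masks[[1]] | masks[[2]])) stop("region masks do not tile the image")
  }
  m <- array(NA_real_, dim = c(h, w, 9))
  for (r in 1:2) {
    flat <- as.vector(t(regions[[r]]$M))
    sel <- masks[[r]]
    for (k in 1:9) {
      plane <- m[, , k]
      plane[sel] <- flat[k]
      m[, , k] <- plane
    }
  }
  truth <- mueller_image(m)
  if (!is.null(seed)) set.seed(seed)
  frames <- simulate_frames(truth, alpha = alpha, beta = beta, gain = gain,
                            noise_sd = noise_sd)
  structure(list(truth = truth, frames = frames, rois = masks,
                 labels = labels), class = "phantom")
}

# Deterministic 32-bit child seed for sample i of a cohort.
child_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 16807) %% 2147483647
}

#' Generate a cohort of phantom samples
#'
#' Each sample's region matrices are the base region matrices with
#' independent Gaussian jitter (sd `jitter_sd`, truncated to the physical
#' range `[-1, 1]`) added to the diagonal elements m22 and m33, emulating
#' inter-sample variability; frames carry detector noise. Child seeds are
#' deterministic functions of `(seed, sample index)`, so the cohort is
#' reproducible sample by sample.
#'
#' @param n_samples Number of samples (specimens).
#' @param regions Two `region_spec`s, as in [make_phantom()].
#' @param size Image size per sample.
#' @param jitter_sd Inter-sample sd on the diagonal elements.
#' @param noise_sd Detector noise sd (fraction of max intensity).
#' @param seed Integer master seed.
#' @return List of class `cohort`: `samples` (list of `phantom`s with
#'   `sample_id`s), `manifest` (data frame of per-sample settings).
#' @export
make_cohort <- function(n_samples = 20,
                        regions = list(region_spec("GBM", tissue_preset("gbm")),
                                       region_spec("non-GBM", tissue_preset("non_gbm"))),
                        size = c(64, 64), jitter_sd = 0.02, noise_sd = 0.01,
                        seed = 42) {
  stopifnot(n_samples >= 1, jitter_sd >= 0, noise_sd >= 0)
  samples <- vector("list", n_samples)
  man <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    cs <- child_seed(seed, i)
    set.seed(cs)
    regs <- lapply(regions, function(rg) {
      M <- rg$M
      M[2, 2] <- min(1, max(-1, M[2, 2] + rnorm(1, sd = jitter_sd)))
      M[3, 3] <- min(1, max(-1, M[3, 3] + rnorm(1, sd = jitter_sd)))
      region_spec(rg$label, M)
    })
    ph <- make_phantom(regs, size = size, noise_sd = noise_sd)
    ph$sample_id <- sprintf("S%02d", i)
    samples[[i]] <- ph
    man[[i]] <- data.frame(sample_id = ph$sample_id, seed = cs,
                           jitter_sd = jitter_sd, noise_sd = noise_sd,
                           height = size[1], width = size[2],
                           stringsAsFactors = FALSE)
  }
  structure(list(samples = samples, manifest = do.call(rbind, man),
                 seed = seed), class = "cohort")
}

#' Run the full analysis over a cohort
#'
#' For every sample: reconstruct the Mueller image from its frames,
#' decompose it into parameter maps, and summarize both regions; then
#' compare the two region groups across samples.
#'
#' @param cohort A `cohort` from [make_cohort()].
#' @param parameters Parameters passed to [compare_groups()].
#' @param alpha Significance level.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return List: `summaries` (stacked per-sample ROI means) and
#'   `comparison` (the [compare_groups()] table).
#' @export
analyze_cohort <- function(cohort, parameters = c("m22", "m33",
                                                  "one_minus_delta", "t"),
                           alpha = 0.05, var_equal = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$samples, function(ph) {
    img <- reconstruct_mueller(ph$frames)
    maps <- decompose_image(img)
    do.call(rbind, lapply(names(ph$rois), function(lab) {
      summarize_roi(img, ph$rois[[lab]], label = lab, maps = maps,
                    sample_id = ph$sample_id)
    }))
  })
  summaries <- do.call(rbind, rows)
  list(summaries = summaries,
       comparison = compare_groups(summaries, parameters = parameters,
                                   alpha = alpha, var_equal = var_equal))
}
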