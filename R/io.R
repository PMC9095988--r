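# On-disk formats: 9-plane float TIFF for Mueller images, multi-page TIFF +
# JSON angle sidecar for frame sets, 8-bit PNG for ROI masks.

#' Write a Mueller image as a multi-plane TIFF with JSON sidecar
#'
#' Planes are written in row-major element order (m11, m12, ..., m33) as
#' 32-bit floats. TIFF float samples are stored in the [0, 1] range, so the
#' planes are affinely mapped onto it and the map (`value_lo`, `value_hi`)
#' is recorded in the sidecar (`<path>.json`) together with the plane
#' order, normalization state and mask.
#'
#' @param img A `mueller_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mueller_tiff <- function(img, path) {
  stopifnot(inherits(img, "mueller_image"))
  vals <- img$m[is.finite(img$m)]
  lo <- min(vals, 0)
  hi <- max(vals, 1)
  planes <- lapply(1:9, function(k) {
    p <- matrix(img$m[, , k], img$height, img$width)
    p[!img$valid] <- lo
    (p - lo) / (hi - lo)
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 32)
  jsonlite::write_json(
    list(planes = ELEMENT_NAMES, normalized = TRUE,
         value_lo = lo, value_hi = hi,
         valid = as.vector(img$valid), height = img$height,
         width = img$width),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Mueller image written by [write_mueller_tiff()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return A `mueller_image`.
#' @export
read_mueller_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  h <- meta$height
  w <- meta$width
  m <- array(NA_real_, c(h, w, 9))
  for (k in 1:9) {
    m[, , k] <- planes[[k]] * (meta$value_hi - meta$value_lo) + meta$value_lo
  }
  valid <- matrix(meta$valid, h, w)
  m[is.na(m)] <- 0
  img <- mueller_image(m, valid)
  img$m[array(rep(!valid, 9), c(h, w, 9))] <- NA_real_
  img
}

#' Write a frame set as multi-page TIFF plus JSON angle sidecar
#'
#' @param fs A `frame_set`.
#' @param path Output TIFF path; the sidecar `<path>.json` lists
#'   `alpha_deg`, `beta_deg` and `page` per frame plus the gain. Intensities
#'   are stored scaled to the [0, 1] float range with the scale recorded.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(fs, path) {
  stopifnot(inherits(fs, "frame_set"))
  top <- max(fs$frames, 1e-12)
  pages <- lapply(seq_along(fs$alpha), function(k) fs$frames[, , k] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(
    list(frames = data.frame(alpha_deg = fs$alpha * 180 / pi,
                             beta_deg = fs$beta * 180 / pi,
                             page = seq_along(fs$alpha)),
         gain = fs$gain, intensity_scale = top),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame set written by [write_frames_tiff()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return A `frame_set`.
#' @export
read_frames_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ord <- order(meta$frames$page)
  arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[ord[k]]] * meta$intensity_scale
  frame_set(arr, meta$frames$alpha_deg[ord] * pi / 180,
            meta$frames$beta_deg[ord] * pi / 180, gain = meta$gain)
}

#' Write / read a logical ROI mask as 8-bit PNG (nonzero = inside)
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `path` invisibly (write); logical matrix (read).
#' @export
write_roi_png <- function(mask, path) {
  stopifnot(is.logical(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_roi_png
#' @export
read_roi_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}
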