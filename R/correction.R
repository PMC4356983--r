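#' Illumination correction
#'
#' Plate-wide, per-channel estimation of the pixel-by-pixel fluorescence
#' baseline produced by uneven illumination plus background fluorescence,
#' and its subtraction from each image.  The estimator is a robust
#' reconstruction of the classic flat-background pipeline: the pixel-wise
#' median across all of a channel's images (cells occupy a minority of any
#' given pixel across the plate, so the median sees mostly baseline),
#' followed by a large-kernel 2D median filter that removes any remaining
#' cell imprint.  Correction is by subtraction, not division, and negative
#' residuals are clamped to zero so downstream integrals stay
#' non-negative.
#'
#' @param images list of numeric matrices, one channel of every field on
#'   the plate; all the same shape.
#' @param smoothing_scale half-width of the square median-filter kernel,
#'   px.
#' @param channel_role optional channel label stored in the profile.
#' @return `estimate_illumination()` returns an `illumination_profile`:
#'   list with `raster`, `n_images_used`, `smoothing_scale`,
#'   `channel_role`.
#' @examples
#' imgs <- replicate(5, matrix(100, 20, 20), simplify = FALSE)
#' prof <- estimate_illumination(imgs, smoothing_scale = 3)
#' range(prof$raster) # 100 100
#' @export
estimate_illumination <- function(images, smoothing_scale = 50,
                                  channel_role = NA_character_) {
  if (!is.list(images) || length(images) == 0)
    stop("need at least one image to estimate an illumination profile")
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all images must have the same shape")
  imgs <- lapply(images, function(m) { storage.mode(m) <- "double"; m })
  med <- cpp_pixelwise_median(imgs)
  raster <- cpp_median_filter(med, as.integer(smoothing_scale))
  structure(list(raster = raster,
                 n_images_used = length(images),
                 smoothing_scale = smoothing_scale,
                 channel_role = channel_role),
            class = "illumination_profile")
}

#' @rdname estimate_illumination
#' @param image a raw field raster (counts).
#' @param profile an `illumination_profile` for the same channel.
#' @param channel_role role of `image`; if both this and the profile carry
#'   a role they must agree.
#' @return `apply_correction()` returns the corrected raster
#'   `max(image - profile, 0)` as a double matrix.
#' @export
apply_correction <- function(image, profile, channel_role = NULL) {
  stopifnot(inherits(profile, "illumination_profile"))
  if (!all(dim(image) == dim(profile$raster)))
    stop("image and illumination profile shapes differ")
  if (!is.null(channel_role) && !is.na(profile$channel_role) &&
      channel_role != profile$channel_role)
    stop("channel-role mismatch: image is '", channel_role,
         "', profile is '", profile$channel_role, "'")
  out <- image - profile$raster # R widens integer input to double here
  out[out < 0] <- 0
  out
}

#' @rdname estimate_illumination
#' @param corrected a corrected raster.
#' @param cell_mask logical matrix, `TRUE` inside any cell.
#' @return `residual_background()` returns the mean corrected intensity
#'   over cell-free pixels — the plate's own check that background
#'   subtraction worked (should be about zero).
#' @export
residual_background <- function(corrected, cell_mask) {
  if (!all(dim(corrected) == dim(cell_mask)))
    stop("corrected image and cell mask shapes differ")
  free <- !cell_mask
  if (sum(free) < 0.01 * length(free))
    stop("fewer than 1% of pixels are cell-free; field too confluent ",
         "to judge background subtraction")
  mean(corrected[free])
}

#' Persist / load an illumination profile as float TIFF + JSON sidecar
#' @param profile an `illumination_profile`.
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   the reconstructed profile.
#' @export
write_profile <- function(profile, path) {
  write_tiff(profile$raster, path, type = "float")
  meta <- list(n_images_used = profile$n_images_used,
               smoothing_scale = profile$smoothing_scale,
               channel_role = profile$channel_role)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(raster = read_tiff(path),
                 n_images_used = meta$n_images_used,
                 smoothing_scale = meta$smoothing_scale,
                 channel_role = meta$channel_role),
            class = "illumination_profile")
}
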