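#' Cell-level quality-control thresholds
#'
#' Gates excluding cells that do not significantly express the reporter,
#' have abnormal morphology (e.g. apoptotic-like small cells) or contain
#' a significant amount of saturated pixels.  No numeric values for these
#' gates are fixed by the assay itself; the defaults here are reasoned
#' reconstructions and every one is configurable.
#'
#' @param min_total_expression minimum mean corrected total-reporter
#'   intensity per pixel (counts); the pipeline derives it per field as
#'   `expression_k` times the robust sd of cell-free residual background.
#' @param max_saturated_fraction tolerated fraction of saturated pixels in
#'   any channel over the cell mask.
#' @param area_range admissible cell area (px); apoptotic-like condensed
#'   cells fall below the lower bound.
#' @param min_form_factor minimum 4*pi*A/P^2 circularity.
#' @return a `cell_qc_thresholds` list.
#' @export
cell_qc_thresholds <- function(min_total_expression = 0,
                               max_saturated_fraction = 0.01,
                               area_range = c(200, 4000),
                               min_form_factor = 0.4) {
  stopifnot(length(area_range) == 2, area_range[1] <= area_range[2],
            max_saturated_fraction >= 0, max_saturated_fraction <= 1,
            min_total_expression >= 0)
  structure(list(min_total_expression = min_total_expression,
                 max_saturated_fraction = max_saturated_fraction,
                 area_range = area_range,
                 min_form_factor = min_form_factor),
            class = "cell_qc_thresholds")
}

#' Flag cells failing quality control
#'
#' Non-destructive: every record is kept and annotated with zero or more
#' of `low_expression`, `saturated`, `abnormal_morphology`; a cell passes
#' iff its flag set is empty.
#'
#' @param cells data frame from [measure_cells()].
#' @param thresholds a [cell_qc_thresholds()].
#' @return `cells` with `qc_flags` (comma-joined) and `qc_pass` updated.
#' @export
flag_cells <- function(cells, thresholds = cell_qc_thresholds()) {
  stopifnot(inherits(thresholds, "cell_qc_thresholds"))
  if (nrow(cells) == 0) return(cells)
  low <- cells$mean_total < thresholds$min_total_expression
  sat_frac <- pmax(cells$sat_nuclei, cells$sat_total, cells$sat_surface) /
    cells$area
  sat <- sat_frac > thresholds$max_saturated_fraction
  morph <- cells$area < thresholds$area_range[1] |
    cells$area > thresholds$area_range[2] |
    cells$form_factor < thresholds$min_form_factor
  flags <- mapply(function(a, b, c) {
    paste(c(if (a) "low_expression", if (b) "saturated",
            if (c) "abnormal_morphology"), collapse = ",")
  }, low, sat, morph)
  cells$qc_flags <- unname(flags)
  cells$qc_pass <- flags == ""
  cells
}

#' Image sharpness score
#'
#' Normalised variance of the Laplacian response on the (corrected)
#' nuclei channel — a contrast statistic that decreases monotonically
#' with defocus blur.
#'
#' @param raster nuclei-channel raster.
#' @return dimensionless focus score.
#' @export
focus_score <- function(raster) {
  storage.mode(raster) <- "double"
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- cpp_convolve3(raster, k)
  var(as.numeric(lap)) / (mean(raster) + 1)^2
}

#' Image-level quality control
#'
#' Excludes out-of-focus images, images with high residual background
#' fluorescence, and images with too few passing cells.  Focus and
#' background gates are plate-adaptive by default (`median - 3 * MAD` of
#' the focus scores, `median + 3 * MAD` of the residual backgrounds,
#' across the plate), which needs at least 4 images; with fewer, supply
#' fixed numeric gates.
#'
#' @param image_stats data frame with columns `well`, `field`,
#'   `focus_score`, `residual_background`, `n_cells_pass`.
#' @param min_cells minimum passing cells for a usable image.
#' @param focus_gate `"adaptive"` or a fixed numeric lower gate.
#' @param background_gate `"adaptive"` or a fixed numeric upper gate.
#' @return `image_stats` with a `status` column (`pass`, `out_of_focus`,
#'   `high_background`, `too_few_cells`); the gates used are attached as
#'   attributes `focus_gate` / `background_gate`.
#' @export
image_qc <- function(image_stats, min_cells = 10,
                     focus_gate = "adaptive", background_gate = "adaptive") {
  need <- c("focus_score", "residual_background", "n_cells_pass")
  if (!all(need %in% names(image_stats)))
    stop("image_stats needs columns: ", paste(need, collapse = ", "))
  adaptive <- identical(focus_gate, "adaptive") ||
    identical(background_gate, "adaptive")
  if (adaptive && nrow(image_stats) < 4)
    stop("plate-adaptive gates need at least 4 images; ",
         "supply fixed numeric focus_gate/background_gate instead")
  if (identical(focus_gate, "adaptive"))
    focus_gate <- median(image_stats$focus_score) -
      3 * mad(image_stats$focus_score)
  if (identical(background_gate, "adaptive"))
    background_gate <- median(image_stats$residual_background) +
      3 * mad(image_stats$residual_background)
  status <- rep("pass", nrow(image_stats))
  status[image_stats$n_cells_pass < min_cells] <- "too_few_cells"
  status[image_stats$residual_background > background_gate] <- "high_background"
  status[image_stats$focus_score < focus_gate] <- "out_of_focus"
  image_stats$status <- status
  attr(image_stats, "focus_gate") <- focus_gate
  attr(image_stats, "background_gate") <- background_gate
  image_stats
}

#' Plate-level transfection quality control
#'
#' A plate is analysed only if the expected knockdown phenotype is
#' visible in enough transfection-control images: rejection requires the
#' phenotype to be missing in strictly more than `max_failure_fraction`
#' (default 75\%) of control images, so a failure fraction of exactly
#' 0.75 is still accepted.  Phenotype detection itself is upstream: the
#' simulator provides per-image boolean flags, and on real data they are
#' a user-supplied annotation.
#'
#' @param control_flags logical vector, one per control image, `TRUE`
#'   when the phenotype was observed.
#' @param plate_id identifier carried into the result.
#' @param max_failure_fraction rejection threshold (strict).
#' @return a `plate_qc` list: `plate_id`, `n_control_images`,
#'   `n_phenotype_positive`, `failure_fraction`, `accepted`.
#' @export
assess_plate_transfection <- function(control_flags, plate_id = "plate",
                                      max_failure_fraction = 0.75) {
  control_flags <- control_flags[!is.na(control_flags)]
  if (length(control_flags) == 0)
    stop("no transfection-control image flags supplied")
  n <- length(control_flags)
  pos <- sum(control_flags)
  failure <- 1 - pos / n
  structure(list(plate_id = plate_id, n_control_images = n,
                 n_phenotype_positive = pos, failure_fraction = failure,
                 accepted = failure <= max_failure_fraction),
            class = "plate_qc")
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf("Plate %s: %d/%d control images phenotype-positive (failure %.1f%%) -> %s\n",
              x$plate_id, x$n_phenotype_positive, x$n_control_images,
              100 * x$failure_fraction,
              if (x$accepted) "ACCEPTED" else "REJECTED"))
  invisible(x)
}
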