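#' Otsu's automatic threshold
#'
#' Parameter-free global threshold maximising between-class variance of
#' the intensity histogram; the workhorse separating stained objects from
#' corrected background.
#'
#' @param x numeric matrix or vector.
#' @param n_bins histogram resolution.
#' @return threshold value; pixels strictly above it are foreground.  A
#'   constant image returns its single value (empty foreground).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)
  h <- tabulate(pmin(as.integer((v - lo) / (hi - lo) * n_bins) + 1L, n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + (k / n_bins) * (hi - lo)
}

.empty_label_map <- function(shape, provenance) {
  structure(list(labels = matrix(0L, shape[1], shape[2]), n = 0L,
                 provenance = provenance,
                 centroids = data.frame(label = integer(0), row = numeric(0),
                                        col = numeric(0))),
            class = "label_map")
}

.label_centroids <- function(lab, n) {
  if (n == 0)
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0)))
  pix <- which(lab > 0, arr.ind = TRUE)
  l <- factor(lab[lab > 0], levels = seq_len(n))
  data.frame(label = seq_len(n),
             row = as.numeric(tapply(pix[, 1], l, mean)) - 1,
             col = as.numeric(tapply(pix[, 2], l, mean)) - 1)
}

# fill interior holes: background components not touching the border
.fill_holes <- function(mask) {
  bg <- cpp_label_components(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  mask | (bg > 0 & !(bg %in% border))
}

# drop labels failing keep[], relabel contiguously from 1
.relabel <- function(lab, keep) {
  map <- integer(length(keep))
  map[keep] <- seq_len(sum(keep))
  out <- lab
  pos <- out > 0
  out[pos] <- map[out[pos]]
  out
}

#' Segment nuclei from the corrected DNA-stain channel
#'
#' Otsu threshold, hole filling, watershed split of touching nuclei on the
#' smoothed Euclidean distance transform, then an area gate.
#'
#' @param nuclei_corrected background-subtracted nuclei raster.
#' @param min_area,max_area retained nucleus area range, px.
#' @return a `label_map`: integer raster of labels (0 = background,
#'   contiguous from 1), label count `n`, 0-based `centroids`, and
#'   `provenance = "nuclei"`.  A blank image yields an empty map.
#' @export
segment_nuclei <- function(nuclei_corrected, min_area = 40, max_area = 2000) {
  shape <- dim(nuclei_corrected)
  thr <- otsu_threshold(nuclei_corrected)
  mask <- nuclei_corrected > thr
  if (!any(mask)) return(.empty_label_map(shape, "nuclei"))
  mask <- .fill_holes(mask)
  dist <- cpp_gaussian_blur(cpp_edt(mask), 1)
  max_rad <- max(2L, as.integer(floor(sqrt(min_area / pi))))
  peaks <- cpp_local_maxima(dist, max_rad, 0.5) & mask
  if (!any(peaks)) return(.empty_label_map(shape, "nuclei"))
  seeds <- cpp_label_components(peaks, 8L)
  lab <- cpp_watershed(-dist, seeds, mask, 8L)
  n <- max(lab)
  geom <- cpp_region_geometry(lab, n)
  keep <- geom[, 1] >= min_area & geom[, 1] <= max_area
  lab <- .relabel(lab, keep)
  n <- sum(keep)
  structure(list(labels = lab, n = as.integer(n), provenance = "nuclei",
                 centroids = .label_centroids(lab, n)),
            class = "label_map")
}

#' Grow cell bodies from nuclear seeds
#'
#' Seeded watershed over the total-reporter channel: foreground is the
#' Otsu-thresholded reporter mask (always including the nuclei), dilated
#' by `expand_px` so the plasma-membrane rim is captured; seeds flood
#' brightest-first, so touching cells split along intensity valleys.
#' Every nucleus yields exactly one cell carrying the nucleus' label;
#' cells are disjoint.  With a blank reporter channel each cell collapses
#' to its (slightly dilated) nucleus footprint.
#'
#' @param total_corrected background-subtracted total-reporter raster.
#' @param nuclei `label_map` from [segment_nuclei()] on the same field.
#' @param expand_px isotropic dilation of the foreground mask, px.
#' @return a `label_map` with `provenance = "cells"`, labels matching the
#'   seed nuclei.
#' @export
segment_cells <- function(total_corrected, nuclei, expand_px = 2) {
  stopifnot(inherits(nuclei, "label_map"))
  shape <- dim(total_corrected)
  if (nuclei$n == 0) return(.empty_label_map(shape, "cells"))
  # expression is heavily right-skewed (lognormal cell-to-cell variation),
  # so threshold the log-intensities or dim cells fall below a linear Otsu
  thr <- expm1(otsu_threshold(log1p(pmax(total_corrected, 0))))
  fg <- total_corrected > thr | nuclei$labels > 0
  if (expand_px > 0) fg <- cpp_edt(!fg) <= expand_px
  lab <- cpp_watershed(-total_corrected, nuclei$labels, fg, 8L)
  structure(list(labels = lab, n = nuclei$n, provenance = "cells",
                 centroids = nuclei$centroids),
            class = "label_map")
}

#' Integrate per-cell fluorescence and morphology
#'
#' For every cell: integrated (summed) and mean intensity in each
#' corrected channel over the cell mask, area, perimeter, form factor
#' (4*pi*A/P^2, 1 for a disk), nucleus area, and the count of saturated
#' pixels per channel measured on the *raw* rasters at the detector
#' ceiling `2^bit_depth - 1`.
#'
#' @param cells,nuclei `label_map`s from [segment_cells()] /
#'   [segment_nuclei()].
#' @param channels named list of corrected rasters
#'   (`nuclei`, `total`, `surface`).
#' @param raw_channels named list of the original uncorrected rasters,
#'   used only for saturation counting; defaults to `channels`.
#' @param bit_depth detector bit depth defining the saturation ceiling.
#' @param well,field identity stamped into the records.
#' @return data frame with one row per cell: `well, field, cell,
#'   centroid_row, centroid_col, area, perimeter, form_factor,
#'   nucleus_area, integrated_nuclei, integrated_total,
#'   integrated_surface, mean_total, sat_nuclei, sat_total, sat_surface,
#'   qc_flags, qc_pass`.
#' @export
measure_cells <- function(cells, nuclei, channels, raw_channels = channels,
                          bit_depth = 12, well = NA_character_, field = NA_integer_) {
  stopifnot(inherits(cells, "label_map"), inherits(nuclei, "label_map"))
  if (!all(dim(cells$labels) == dim(nuclei$labels)))
    stop("cell and nucleus label maps have different shapes")
  n <- cells$n
  empty <- data.frame(well = character(0), field = integer(0), cell = integer(0))
  if (n == 0) return(empty)
  geom <- cpp_region_geometry(cells$labels, n)
  area <- geom[, 1]
  # perimeter: exposed 4-edges * pi/4 is exact for digitised disks but
  # undershoots angular shapes; the boundary-pixel count provides a floor
  perim <- pmax(geom[, 2] * pi / 4, geom[, 3])
  form_factor <- 4 * pi * area / perim^2
  ngeom <- cpp_region_geometry(nuclei$labels, n)
  to_num <- function(m) { storage.mode(m) <- "double"; m }
  int_nuc <- cpp_region_sums(cells$labels, to_num(channels$nuclei), n)
  int_tot <- cpp_region_sums(cells$labels, to_num(channels$total), n)
  int_sur <- cpp_region_sums(cells$labels, to_num(channels$surface), n)
  top <- 2^bit_depth - 1
  satm <- function(raw) cpp_region_sums(cells$labels,
                                        to_num(raw == top) + 0, n)
  data.frame(
    well = rep(well, n), field = rep(as.integer(field), n), cell = seq_len(n),
    centroid_row = cells$centroids$row, centroid_col = cells$centroids$col,
    area = area, perimeter = perim, form_factor = form_factor,
    nucleus_area = ngeom[, 1],
    integrated_nuclei = int_nuc, integrated_total = int_tot,
    integrated_surface = int_sur,
    mean_total = int_tot / area,
    sat_nuclei = satm(raw_channels$nuclei),
    sat_total = satm(raw_channels$total),
    sat_surface = satm(raw_channels$surface),
    qc_flags = rep("", n), qc_pass = rep(TRUE, n),
    stringsAsFactors = FALSE)
}
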