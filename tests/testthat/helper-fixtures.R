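# shared fixture builders; everything is generated in code, nothing on disk

# small, fast simulation setup for unit tests
tiny_config <- function(conditions, seed = 42, ...) {
  simulation_config(conditions = conditions,
                    image_shape = c(140L, 180L),
                    fields_per_well = 2, replicate_wells = 2,
                    seed = seed, ...)
}

tiny_cond <- function(name = "neg", te = 0.35, n = 15,
                      control_role = "negative", ...) {
  condition_spec(name, te, n_cells_mean = n, control_role = control_role, ...)
}

# paint a hard-edged disk into a matrix (independent of the simulator)
draw_disk <- function(img, r0, c0, radius, value, add = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- pmax(1, floor(r0 - radius)):pmin(nr, ceiling(r0 + radius))
  cc <- pmax(1, floor(c0 - radius)):pmin(nc, ceiling(c0 + radius))
  d2 <- outer(rr - r0, cc - c0, function(a, b) a^2 + b^2)
  patch <- img[rr, cc]
  patch[d2 <= radius^2] <- if (add) patch[d2 <= radius^2] + value else value
  img[rr, cc] <- patch
  img
}

disk_mask <- function(nr, nc, r0, c0, radius) {
  m <- matrix(FALSE, nr, nc)
  m <- draw_disk(m, r0, c0, radius, TRUE)
  m
}

# flat illumination profile for feeding pre-corrected rasters through
# functions that expect a profile
zero_profile <- function(shape, channel_role = NA_character_) {
  structure(list(raster = matrix(0, shape[1], shape[2]),
                 n_images_used = 1L, smoothing_scale = 0,
                 channel_role = channel_role),
            class = "illumination_profile")
}

# one simulated field with its corrected channels, segmentation and
# measurements, memoised so several test files can reuse it
.fixture_env <- new.env(parent = emptyenv())
analysed_field <- function() {
  if (!is.null(.fixture_env$field)) return(.fixture_env$field)
  spec <- tiny_cond("wt", 0.4, n = 25, control_role = "none")
  cfg <- tiny_config(list(tiny_cond(), spec), seed = 7)
  sim <- simulate_field(spec, cfg, "B02", 1)
  corr <- lapply(sim$images, function(m) {
    p <- estimate_illumination(list(m), smoothing_scale = 25)
    apply_correction(m, p)
  })
  nuc <- segment_nuclei(corr$nuclei)
  cells <- segment_cells(corr$total, nuc)
  rec <- measure_cells(cells, nuc, corr, sim$images, 12, "B02", 1)
  .fixture_env$field <- list(sim = sim, corr = corr, nuclei = nuc,
                             cells = cells, records = rec)
  .fixture_env$field
}
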