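#' Synthetic screening-plate simulator
#'
#' Generates multiwell fluorescence plates with the statistical structure
#' the traffic assay assumes, together with pixel-level ground truth, so
#' the whole analysis chain can be validated without real microscope data.
#' Each field carries three channels: nuclei (DNA stain), total reporter
#' (fluorescent-protein fusion, proportional to total expressed protein)
#' and surface label (extracellular-tag immunostain, proportional to the
#' amount of reporter at the plasma membrane).  Cells are elliptical bodies
#' with a 2-pixel perimeter band standing in for the plasma membrane; the
#' integrated surface-band intensity of every cell equals its condition's
#' true traffic efficiency times the cell's total intensity, exactly,
#' before illumination, noise and clipping are applied.
#'
#' @param image_shape integer (rows, cols) of each field.
#' @param bit_depth detector bit depth; pixel values saturate at
#'   `2^bit_depth - 1` (12-bit data in 16-bit containers by default).
#' @param fields_per_well fields imaged per well.
#' @param replicate_wells wells per condition.
#' @param conditions list of [condition_spec()] objects.
#' @param illumination per-channel list with elements `shape`
#'   (`"plane"` or `"radial"`) and `amplitude` (fraction of
#'   `background_level`, in `[0, 1)`).
#' @param background_level additive background, counts.
#' @param noise_sd Gaussian detector noise, counts.
#' @param cell_radius,nucleus_radius mean radii of normal cells/nuclei, px.
#' @param nucleus_intensity mean nuclear-stain amplitude, counts.
#' @param defocus_sigma Gaussian blur sigma applied to defocused fields, px.
#' @param phenotype_positive_rate probability that a transfection-control
#'   field displays the expected knockdown phenotype.
#' @param seed integer seed controlling every random draw.
#' @return `simulation_config()` returns a validated `sim_config` object.
#' @export
simulation_config <- function(conditions,
                              image_shape = c(280L, 360L),
                              bit_depth = 12,
                              fields_per_well = 4,
                              replicate_wells = 3,
                              illumination = list(
                                nuclei = list(shape = "plane", amplitude = 0.3),
                                total = list(shape = "radial", amplitude = 0.3),
                                surface = list(shape = "plane", amplitude = 0.2)),
                              background_level = 100,
                              noise_sd = 4,
                              cell_radius = 9,
                              nucleus_radius = 4.5,
                              nucleus_intensity = 800,
                              defocus_sigma = 5,
                              phenotype_positive_rate = 0.95,
                              seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape > 0),
            bit_depth >= 8, bit_depth <= 16,
            fields_per_well >= 1, replicate_wells >= 1,
            background_level >= 0, noise_sd >= 0,
            cell_radius > nucleus_radius, defocus_sigma >= 4)
  if (!is.list(conditions) || length(conditions) == 0)
    stop("conditions must be a non-empty list of condition_spec objects")
  if (!all(vapply(conditions, inherits, TRUE, "condition_spec")))
    stop("conditions must all be condition_spec objects")
  for (ch in c("nuclei", "total", "surface")) {
    il <- illumination[[ch]]
    if (is.null(il) || !il$shape %in% c("plane", "radial") ||
        il$amplitude < 0 || il$amplitude >= 1)
      stop("illumination for channel '", ch,
           "' needs shape in {plane, radial} and amplitude in [0, 1)")
  }
  structure(list(image_shape = as.integer(image_shape),
                 bit_depth = as.integer(bit_depth),
                 channel_roles = c("nuclei", "total", "surface"),
                 conditions = conditions,
                 fields_per_well = as.integer(fields_per_well),
                 replicate_wells = as.integer(replicate_wells),
                 illumination = illumination,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 cell_radius = cell_radius,
                 nucleus_radius = nucleus_radius,
                 nucleus_intensity = nucleus_intensity,
                 defocus_sigma = defocus_sigma,
                 phenotype_positive_rate = phenotype_positive_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Treatment condition for the plate simulator
#'
#' @param name treatment label.
#' @param true_traffic_efficiency expected surface/total ratio in `[0, 1]`;
#'   near zero models the trafficking-mutant case.
#' @param n_cells_mean Poisson mean of cells per field.
#' @param expression_meanlog,expression_sdlog lognormal parameters of the
#'   per-cell total-reporter pixel amplitude (counts).
#' @param frac_apoptotic fraction of cells rendered apoptotic-like (area
#'   under 30\% of normal, bright condensed nucleus).
#' @param frac_saturating fraction of cells whose amplitude is pushed past
#'   the detector ceiling.
#' @param frac_defocused_fields fraction of this condition's fields blurred
#'   as if out of focus.
#' @param control_role `"none"`, `"negative"`, `"positive"` or
#'   `"transfection_control"`.
#' @return a `condition_spec` object.
#' @export
condition_spec <- function(name,
                           true_traffic_efficiency,
                           n_cells_mean = 80,
                           expression_meanlog = log(600),
                           expression_sdlog = 0.5,
                           frac_apoptotic = 0.02,
                           frac_saturating = 0.02,
                           frac_defocused_fields = 0,
                           control_role = c("none", "negative", "positive",
                                            "transfection_control")) {
  control_role <- match.arg(control_role)
  vals <- c(true_traffic_efficiency, n_cells_mean, expression_meanlog,
            expression_sdlog, frac_apoptotic, frac_saturating,
            frac_defocused_fields)
  if (any(!is.finite(vals)))
    stop("non-finite condition parameter for '", name, "'")
  fr <- c(frac_apoptotic, frac_saturating, frac_defocused_fields)
  stopifnot(true_traffic_efficiency >= 0, n_cells_mean >= 0,
            expression_sdlog >= 0, all(fr >= 0), all(fr <= 1))
  structure(list(name = as.character(name),
                 true_traffic_efficiency = true_traffic_efficiency,
                 n_cells_mean = n_cells_mean,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 frac_apoptotic = frac_apoptotic,
                 frac_saturating = frac_saturating,
                 frac_defocused_fields = frac_defocused_fields,
                 control_role = control_role),
            class = "condition_spec")
}

# deterministic per-field seed below 2^31
.field_seed <- function(seed, well, field) {
  h <- sum(utf8ToInt(well) * seq_along(utf8ToInt(well)))
  as.integer((as.numeric(seed) * 1000003 + h * 7919 + field * 104729) %%
               2147483647)
}

.illum_baseline <- function(shape, amplitude, background_level, nr, nc) {
  if (amplitude == 0) return(matrix(background_level, nr, nc))
  g <- if (shape == "plane") {
    outer(seq_len(nr) / nr, seq_len(nc) / nc, function(a, b) (a + b) / 2)
  } else {
    rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
    rmax2 <- rc^2 + cc^2
    outer(seq_len(nr), seq_len(nc),
          function(a, b) 1 - ((a - rc)^2 + (b - cc)^2) / rmax2)
  }
  background_level * (1 + amplitude * g)
}

#' Simulate one imaging field
#'
#' Renders the three channels of a single field for one condition and
#' returns the images with their ground-truth cell table.  Fully
#' deterministic given `(config$seed, well, field)` (or an explicit
#' `seed`): the same call yields bit-identical images.
#'
#' @param spec a [condition_spec()].
#' @param config a [simulation_config()].
#' @param well,field identity of the simulated field.
#' @param seed optional explicit seed overriding the derived one.
#' @return list with `images` (named list of integer matrices `nuclei`,
#'   `total`, `surface`), `cells` (ground-truth data frame: centroids,
#'   true integrated intensities, apoptotic/saturated flags) and
#'   `field_info` (one row: defocused / phenotype flags).
#' @export
simulate_field <- function(spec, config, well = "A01", field = 1L,
                           seed = NULL) {
  stopifnot(inherits(spec, "condition_spec"), inherits(config, "sim_config"))
  if (is.null(seed)) seed <- .field_seed(config$seed, well, field)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  ceiling_ct <- 2^config$bit_depth - 1
  defocused <- runif(1) < spec$frac_defocused_fields
  phenotype <- if (spec$control_role == "transfection_control")
    rbinom(1, 1, config$phenotype_positive_rate) == 1 else NA

  n_target <- rpois(1, spec$n_cells_mean)
  r0 <- config$cell_radius
  # dart-throwing placement: non-overlapping bodies with >= 3 px clearance
  pos_r <- numeric(0); pos_c <- numeric(0); rad <- numeric(0)
  apop <- logical(0); satur <- logical(0); nuc_rad <- numeric(0)
  for (i in seq_len(n_target)) {
    is_apop <- runif(1) < spec$frac_apoptotic
    is_sat <- runif(1) < spec$frac_saturating
    r_i <- if (is_apop) r0 * 0.42 * runif(1, 0.95, 1.05) else
      pmin(pmax(rnorm(1, r0, 0.08 * r0), 0.85 * r0), 1.15 * r0)
    rn_i <- if (is_apop) r_i else
      config$nucleus_radius * runif(1, 0.95, 1.05)
    placed <- FALSE
    for (try in 1:80) {
      rr <- runif(1, r_i + 3, nr - r_i - 3)
      cc <- runif(1, r_i + 3, nc - r_i - 3)
      if (length(pos_r) == 0 ||
          all(sqrt((pos_r - rr)^2 + (pos_c - cc)^2) > rad + r_i + 3)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) next
    pos_r <- c(pos_r, rr); pos_c <- c(pos_c, cc); rad <- c(rad, r_i)
    nuc_rad <- c(nuc_rad, rn_i); apop <- c(apop, is_apop)
    satur <- c(satur, is_sat)
  }
  n_cells <- length(pos_r)
  amp <- rlnorm(n_cells, spec$expression_meanlog, spec$expression_sdlog)
  amp[satur] <- 1.2 * ceiling_ct

  ideal <- list(nuclei = matrix(0, nr, nc), total = matrix(0, nr, nc),
                surface = matrix(0, nr, nc))
  true_total <- true_surface <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    R <- rad[i]; Rn <- nuc_rad[i]
    rr0 <- max(1L, floor(pos_r[i] - R - 1)); rr1 <- min(nr, ceiling(pos_r[i] + R + 1))
    cc0 <- max(1L, floor(pos_c[i] - R - 1)); cc1 <- min(nc, ceiling(pos_c[i] + R + 1))
    d2 <- outer((rr0:rr1) - pos_r[i], (cc0:cc1) - pos_c[i],
                function(a, b) a^2 + b^2)
    disk <- d2 <= R^2
    ring <- disk & d2 > (R - 2)^2
    nucd <- d2 <= Rn^2
    n_disk <- sum(disk); n_ring <- sum(ring)
    true_total[i] <- amp[i] * n_disk
    true_surface[i] <- spec$true_traffic_efficiency * true_total[i]
    s_amp <- if (n_ring > 0) true_surface[i] / n_ring else 0
    p <- ideal$total[rr0:rr1, cc0:cc1]; p[disk] <- p[disk] + amp[i]
    ideal$total[rr0:rr1, cc0:cc1] <- p
    p <- ideal$surface[rr0:rr1, cc0:cc1]; p[ring] <- p[ring] + s_amp
    ideal$surface[rr0:rr1, cc0:cc1] <- p
    namp <- config$nucleus_intensity * (if (apop[i]) 2.5 else 1)
    p <- ideal$nuclei[rr0:rr1, cc0:cc1]; p[nucd] <- p[nucd] + namp
    ideal$nuclei[rr0:rr1, cc0:cc1] <- p
  }

  imgs <- list()
  for (ch in config$channel_roles) {
    sig <- cpp_gaussian_blur(ideal[[ch]], 0.8)
    if (defocused) sig <- cpp_gaussian_blur(sig, config$defocus_sigma)
    il <- config$illumination[[ch]]
    base <- .illum_baseline(il$shape, il$amplitude, config$background_level,
                            nr, nc)
    img <- sig + base + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    img <- round(pmin(pmax(img, 0), ceiling_ct))
    storage.mode(img) <- "integer"
    imgs[[ch]] <- img
  }

  # the saturated flag reflects the rendered image, not just the intent
  sat_obs <- logical(n_cells)
  if (n_cells > 0) {
    for (i in seq_len(n_cells)) {
      R <- rad[i]
      rr0 <- max(1L, floor(pos_r[i] - R)); rr1 <- min(nr, ceiling(pos_r[i] + R))
      cc0 <- max(1L, floor(pos_c[i] - R)); cc1 <- min(nc, ceiling(pos_c[i] + R))
      sat_obs[i] <- any(imgs$total[rr0:rr1, cc0:cc1] == ceiling_ct) ||
        any(imgs$surface[rr0:rr1, cc0:cc1] == ceiling_ct)
    }
  }

  cells <- data.frame(
    well = rep(well, n_cells), field = rep(as.integer(field), n_cells),
    cell = seq_len(n_cells),
    row = pos_r - 1, col = pos_c - 1, # 0-based centroids
    radius = rad, nucleus_radius = nuc_rad,
    true_total = true_total, true_surface = true_surface,
    true_traffic_efficiency = rep(spec$true_traffic_efficiency, n_cells),
    apoptotic = apop, saturated = sat_obs,
    stringsAsFactors = FALSE)
  field_info <- data.frame(
    well = well, field = as.integer(field), condition = spec$name,
    defocused = defocused, phenotype_positive = phenotype,
    stringsAsFactors = FALSE)
  list(images = imgs, cells = cells, field_info = field_info)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a whole screening plate
#'
#' Lays conditions onto wells (row-major, `replicate_wells` wells each),
#' simulates every field and optionally writes the plate to disk as
#' 16-bit TIFFs plus ground-truth CSV tables, a layout CSV and the
#' simulation config.
#'
#' @param config a [simulation_config()]; must contain at least one
#'   condition with `control_role = "negative"`.
#' @param out_dir if non-`NULL`, directory to write the plate into.
#' @param keep_images keep the rasters in the returned object (default;
#'   set `FALSE` with `out_dir` to save memory).
#' @return a `sim_plate` list: `fields` (per-field list with `images` and
#'   identity), `ground_truth` (`cells`, `fields`, `conditions` tables),
#'   `layout` data frame and the `config`.
#' @export
simulate_plate <- function(config, out_dir = NULL, keep_images = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  roles <- vapply(config$conditions, `[[`, "", "control_role")
  if (!any(roles == "negative"))
    stop("plate layout must include at least one negative-control condition")

  n_cond <- length(config$conditions)
  wells_needed <- n_cond * config$replicate_wells
  well_ids <- as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0)))
  if (wells_needed > length(well_ids)) stop("more wells than a 384-well plate")
  layout <- data.frame(
    well = well_ids[seq_len(wells_needed)],
    condition = rep(vapply(config$conditions, `[[`, "", "name"),
                    each = config$replicate_wells),
    class = rep(ifelse(roles == "none", "siRNA", "control"),
                each = config$replicate_wells),
    control_role = rep(roles, each = config$replicate_wells),
    stringsAsFactors = FALSE)

  schema <- filename_schema()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fields <- list()
  gt_cells <- list(); gt_fields <- list()
  k <- 0L
  for (ci in seq_len(n_cond)) {
    spec <- config$conditions[[ci]]
    cond_wells <- layout$well[layout$condition == spec$name]
    for (w in cond_wells) {
      for (f in seq_len(config$fields_per_well)) {
        sim <- simulate_field(spec, config, well = w, field = f)
        k <- k + 1L
        gt_cells[[k]] <- sim$cells
        gt_fields[[k]] <- sim$field_info
        if (!is.null(out_dir)) {
          for (ch in config$channel_roles) {
            fn <- format_filename(schema, w, f, ch)
            write_tiff(sim$images[[ch]], file.path(out_dir, fn), "uint16")
          }
        }
        fields[[k]] <- list(well = w, field = f, condition = spec$name,
                            images = if (keep_images) sim$images else NULL)
      }
    }
  }
  gt <- list(
    cells = do.call(rbind, gt_cells),
    fields = do.call(rbind, gt_fields),
    conditions = data.frame(
      condition = vapply(config$conditions, `[[`, "", "name"),
      true_traffic_efficiency =
        vapply(config$conditions, `[[`, 0, "true_traffic_efficiency"),
      control_role = roles, stringsAsFactors = FALSE))
  if (!is.null(out_dir)) {
    write.csv(gt$cells, file.path(out_dir, "ground_truth_cells.csv"),
              row.names = FALSE)
    write.csv(gt$fields, file.path(out_dir, "ground_truth_fields.csv"),
              row.names = FALSE)
    write.csv(gt$conditions, file.path(out_dir, "ground_truth_conditions.csv"),
              row.names = FALSE)
    write.csv(layout, file.path(out_dir, "layout.csv"), row.names = FALSE)
    write_config(.sim_config_as_list(config), file.path(out_dir, "sim_config.yaml"))
    ph <- gt$fields[!is.na(gt$fields$phenotype_positive),
                    c("well", "field", "phenotype_positive")]
    if (nrow(ph) > 0)
      write.csv(ph, file.path(out_dir, "phenotype_flags.csv"), row.names = FALSE)
  }
  structure(list(fields = fields, ground_truth = gt, layout = layout,
                 config = config), class = "sim_plate")
}

.sim_config_as_list <- function(config) {
  conds <- lapply(config$conditions, function(s) unclass(s))
  out <- unclass(config)
  out$conditions <- conds
  out
}

#' Rebuild a simulation config from its YAML-style file
#' @param path config file written by [simulate_plate()] or by hand.
#' @return a [simulation_config()] object.
#' @export
load_sim_config <- function(path) {
  x <- read_config(path)
  conds <- lapply(x$conditions, function(cc) {
    do.call(condition_spec, cc[intersect(names(cc), names(formals(condition_spec)))])
  })
  args <- x[intersect(names(x), names(formals(simulation_config)))]
  args$conditions <- conds
  do.call(simulation_config, args)
}
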