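#' Filename schema for plate images
#'
#' Configurable template mapping `(well, field, channel role)` to a file
#' name and back; `parse_filename(format_filename(x)) == x` for every
#' valid identity.  The `{field}` token accepts an optional zero-padding
#' width as `{field:02d}`.
#'
#' @param template filename template containing `{well}`, `{field}` (or
#'   `{field:0Nd}`) and `{channel}`.
#' @param channels named character vector mapping the channel roles
#'   `nuclei`, `total`, `surface` to their filename tokens.
#' @return a `filename_schema` object.
#' @examples
#' s <- filename_schema()
#' format_filename(s, "A01", 3, "total")   # "A01_f03_ch2.tif"
#' parse_filename("A01_f03_ch2.tif", s)
#' @export
filename_schema <- function(template = "{well}_f{field:02d}_ch{channel}.tif",
                            channels = c(nuclei = "1", total = "2",
                                         surface = "3")) {
  stopifnot(all(c("nuclei", "total", "surface") %in% names(channels)))
  pad <- 0L
  m <- regmatches(template, regexec("\\{field(:0(\\d+)d)?\\}", template))[[1]]
  if (length(m) == 0) stop("template must contain a {field} token")
  if (m[3] != "") pad <- as.integer(m[3])
  # build the matching regex: escape literal stretches, translate tokens
  tok_rx <- "\\{(well|channel|field(:0\\d+d)?)\\}"
  starts <- gregexpr(tok_rx, template)[[1]]
  lens <- attr(starts, "match.length")
  esc <- function(x) gsub("([^A-Za-z0-9_])", "\\\\\\1", x)
  rx <- ""
  pos <- 1L
  order <- character(0)
  for (i in seq_along(starts)) {
    rx <- paste0(rx, esc(substr(template, pos, starts[i] - 1L)))
    tok <- substr(template, starts[i], starts[i] + lens[i] - 1L)
    if (startsWith(tok, "{well")) {
      rx <- paste0(rx, "([A-Z][0-9]{2})"); order <- c(order, "well")
    } else if (startsWith(tok, "{field")) {
      rx <- paste0(rx, "([0-9]+)"); order <- c(order, "field")
    } else {
      rx <- paste0(rx, "(", paste(esc(unique(channels)), collapse = "|"), ")")
      order <- c(order, "channel")
    }
    pos <- starts[i] + lens[i]
  }
  rx <- paste0(rx, esc(substr(template, pos, nchar(template))))
  if (!setequal(order, c("well", "field", "channel")))
    stop("template must contain each of {well}, {field}, {channel} once")
  structure(list(template = template, channels = channels, pad = pad,
                 order = order, regex = paste0("^", rx, "$")),
            class = "filename_schema")
}

#' @rdname filename_schema
#' @param schema a `filename_schema`.
#' @param well,field,channel_role identity to format.
#' @export
format_filename <- function(schema, well, field, channel_role) {
  stopifnot(inherits(schema, "filename_schema"))
  tok <- schema$channels[[channel_role]]
  if (is.null(tok)) stop("unknown channel role: ", channel_role)
  fld <- if (schema$pad > 0) sprintf(paste0("%0", schema$pad, "d"),
                                     as.integer(field))
         else as.character(as.integer(field))
  out <- sub("\\{well\\}", well, schema$template)
  out <- sub("\\{field(:0\\d+d)?\\}", fld, out)
  sub("\\{channel\\}", tok, out)
}

#' @rdname filename_schema
#' @param name a file name (no directory part).
#' @return `parse_filename()` returns a list `(well, field,
#'   channel_role)`, or `NULL` if the name does not match the schema.
#' @export
parse_filename <- function(name, schema = filename_schema()) {
  m <- regmatches(name, regexec(schema$regex, name))[[1]]
  if (length(m) != 4) return(NULL)
  g <- setNames(m[-1], schema$order)
  role <- names(schema$channels)[match(g[["channel"]], schema$channels)]
  list(well = unname(g[["well"]]), field = as.integer(g[["field"]]),
       channel_role = role)
}

#' Load and validate a plate layout
#'
#' @param path CSV path (or a data frame) with columns `well`,
#'   `condition`, `class`, `control_role`.  Wells must be unique and at
#'   least one well must carry `control_role = "negative"` — without it
#'   deviation scores are impossible.
#' @return validated layout data frame.
#' @export
load_layout <- function(path) {
  layout <- if (is.data.frame(path)) path else
    read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "condition", "class", "control_role")
  missing <- setdiff(need, names(layout))
  if (length(missing) > 0)
    stop("layout is missing column(s) ", paste(missing, collapse = ", "),
         "; expected schema: well, condition, class, control_role")
  dup <- layout$well[duplicated(layout$well)]
  if (length(dup) > 0)
    stop("duplicate well id(s) in layout: ", paste(unique(dup), collapse = ", "))
  bad <- !layout$control_role %in% c("none", "negative", "positive",
                                     "transfection_control")
  if (any(bad))
    stop("invalid control_role value(s): ",
         paste(unique(layout$control_role[bad]), collapse = ", "))
  if (!any(layout$control_role == "negative"))
    stop("layout has no negative-control well; deviation scores are impossible")
  layout
}

# collect per-field channel rasters from a directory or a sim_plate
.collect_fields <- function(images, schema) {
  skipped <- data.frame(file = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (inherits(images, "sim_plate")) {
    fields <- lapply(images$fields, function(f) {
      if (is.null(f$images)) stop("sim_plate was built with keep_images = FALSE; ",
                                  "write it to disk and pass the directory")
      list(well = f$well, field = f$field, channels = f$images)
    })
    return(list(fields = fields, skipped = skipped))
  }
  files <- list.files(images)
  entries <- list()
  for (fn in files) {
    if (!grepl("\\.tiff?$", fn, ignore.case = TRUE)) {
      skipped <- rbind(skipped, data.frame(file = fn,
                                           reason = "not a TIFF file"))
      next
    }
    id <- parse_filename(fn, schema)
    if (is.null(id)) {
      skipped <- rbind(skipped, data.frame(file = fn,
                                           reason = "does not match filename schema"))
      next
    }
    key <- paste(id$well, id$field, sep = "_")
    if (is.null(entries[[key]]))
      entries[[key]] <- list(well = id$well, field = id$field,
                             channels = list())
    entries[[key]]$channels[[id$channel_role]] <-
      read_tiff(file.path(images, fn))
  }
  fields <- Filter(function(e) {
    all(c("nuclei", "total", "surface") %in% names(e$channels))
  }, entries)
  incomplete <- setdiff(names(entries), names(fields))
  for (key in incomplete)
    skipped <- rbind(skipped, data.frame(
      file = key, reason = "incomplete channel set for field"))
  list(fields = unname(fields), skipped = skipped)
}

#' Run the full quantification pipeline
#'
#' End-to-end execution of the two-pass design: (1) estimate per-channel
#' illumination correction functions across the whole plate; (2) per
#' field, subtract them, segment nuclei and cells, integrate
#' fluorescence, and apply cell-level QC; then image-level QC
#' (focus/background/cell count), plate-level transfection QC, and
#' deviation-score hit calling for the three readouts.  Fully
#' deterministic: no random numbers are drawn during analysis.
#'
#' @param images a directory of TIFFs named per the filename schema, or a
#'   `sim_plate` from [simulate_plate()].
#' @param layout plate layout (path or data frame, see [load_layout()]).
#' @param config nested configuration list; missing entries fall back to
#'   [default_config()].
#' @param out_dir optional output directory for the CSV/report bundle.
#' @param phenotype_flags optional data frame `well, field,
#'   phenotype_positive` for plate transfection QC; when `images` is a
#'   directory, a `phenotype_flags.csv` therein is picked up
#'   automatically, and a `sim_plate` supplies its own ground-truth
#'   flags.
#' @return (invisibly) a result bundle: `cells`, `images` (per-field
#'   stats + status), `image_summaries`, `condition_summaries`, `hits`,
#'   `plate_qc`, `profiles`, `skipped`, `rejected`.
#' @export
run_pipeline <- function(images, layout, config = list(), out_dir = NULL,
                         phenotype_flags = NULL) {
  cfg <- .merge_config(default_config(), config)
  layout <- load_layout(layout)
  schema <- filename_schema(cfg$io$filename_template,
                            unlist(cfg$io$channel_tokens))
  bit_depth <- if (inherits(images, "sim_plate"))
    images$config$bit_depth else if (!is.null(cfg$io$bit_depth))
      cfg$io$bit_depth else 12

  if (is.null(phenotype_flags)) {
    if (inherits(images, "sim_plate")) {
      gtf <- images$ground_truth$fields
      phenotype_flags <- gtf[!is.na(gtf$phenotype_positive),
                             c("well", "field", "phenotype_positive")]
    } else if (file.exists(file.path(images, "phenotype_flags.csv"))) {
      phenotype_flags <- read.csv(file.path(images, "phenotype_flags.csv"))
    }
  }

  col <- .collect_fields(images, schema)
  fields <- col$fields
  if (length(fields) == 0) stop("no complete fields found in input")

  # plate-level transfection QC first: a failing plate is not analysed
  plate_qc <- NULL
  tc_wells <- layout$well[layout$control_role == "transfection_control"]
  if (length(tc_wells) > 0 && !is.null(phenotype_flags) &&
      nrow(phenotype_flags) > 0) {
    fl <- phenotype_flags[phenotype_flags$well %in% tc_wells, ]
    if (nrow(fl) > 0)
      plate_qc <- assess_plate_transfection(
        as.logical(fl$phenotype_positive),
        max_failure_fraction = cfg$plate_qc$max_failure_fraction)
  }
  if (!is.null(plate_qc) && !plate_qc$accepted) {
    bundle <- list(plate_qc = plate_qc, rejected = TRUE,
                   skipped = col$skipped, cells = NULL, images = NULL,
                   image_summaries = NULL, condition_summaries = NULL,
                   hits = NULL, profiles = NULL)
    if (!is.null(out_dir)) .write_bundle(bundle, out_dir, cfg)
    return(invisible(bundle))
  }

  # pass 1: illumination correction functions, one per channel, per plate
  profiles <- list()
  for (ch in c("nuclei", "total", "surface")) {
    profiles[[ch]] <- estimate_illumination(
      lapply(fields, function(f) f$channels[[ch]]),
      smoothing_scale = cfg$correction$smoothing_scale, channel_role = ch)
  }

  # pass 2: per-field correction, segmentation, integration, cell QC
  all_cells <- list(); img_stats <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    corr <- lapply(c(nuclei = "nuclei", total = "total", surface = "surface"),
                   function(ch) apply_correction(f$channels[[ch]],
                                                 profiles[[ch]], ch))
    nuc <- segment_nuclei(corr$nuclei,
                          min_area = cfg$segmentation$nucleus_min_area,
                          max_area = cfg$segmentation$nucleus_max_area)
    cells <- segment_cells(corr$total, nuc,
                           expand_px = cfg$segmentation$cell_expand_px)
    rec <- measure_cells(cells, nuc, corr, f$channels, bit_depth,
                         well = f$well, field = f$field)
    cell_mask <- cells$labels > 0
    rb <- residual_background(corr$total, cell_mask)
    free <- as.numeric(corr$total[!cell_mask])
    noise_sd_hat <- mad(free)
    thr <- cell_qc_thresholds(
      min_total_expression = cfg$cell_qc$expression_k * noise_sd_hat,
      max_saturated_fraction = cfg$cell_qc$max_saturated_fraction,
      area_range = c(cfg$cell_qc$cell_area_min, cfg$cell_qc$cell_area_max),
      min_form_factor = cfg$cell_qc$min_form_factor)
    rec <- flag_cells(rec, thr)
    all_cells[[i]] <- rec
    img_stats[[i]] <- data.frame(
      well = f$well, field = f$field,
      focus_score = focus_score(corr$nuclei),
      residual_background = rb,
      n_cells = nrow(rec), n_cells_pass = sum(rec$qc_pass),
      stringsAsFactors = FALSE)
  }
  cells_tab <- do.call(rbind, all_cells)
  img_tab <- do.call(rbind, img_stats)
  img_tab <- image_qc(img_tab, min_cells = cfg$image_qc$min_cells,
                      focus_gate = cfg$image_qc$focus_gate,
                      background_gate = cfg$image_qc$background_gate)

  # summaries over passing images only
  im_sum <- image_summary(cells_tab)
  im_sum <- merge(im_sum, img_tab[, c("well", "field", "status")],
                  by = c("well", "field"))
  im_sum <- merge(im_sum, layout[, c("well", "condition")], by = "well")
  im_sum <- im_sum[order(im_sum$well, im_sum$field), ]
  passing <- im_sum[im_sum$status == "pass", ]
  neg_cond <- unique(layout$condition[layout$control_role == "negative"])[1]
  cond_sum <- condition_summary(passing, aggregate = cfg$scoring$aggregate)
  hits <- score_screen(passing, neg_cond, k = cfg$scoring$sem_multiplier,
                       aggregate = cfg$scoring$aggregate,
                       welch = identical(cfg$scoring$t_test, "welch"))

  bundle <- list(cells = cells_tab, images = img_tab,
                 image_summaries = im_sum, condition_summaries = cond_sum,
                 hits = hits, plate_qc = plate_qc, profiles = profiles,
                 skipped = col$skipped, rejected = FALSE)
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir, cfg)
  invisible(bundle)
}

.write_bundle <- function(bundle, out_dir, cfg) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) if (!is.null(x))
    write.csv(x, file.path(out_dir, name), row.names = FALSE)
  wcsv(bundle$cells, "cells.csv")
  wcsv(bundle$images, "images.csv")
  wcsv(bundle$image_summaries, "image_summaries.csv")
  wcsv(bundle$condition_summaries, "conditions.csv")
  wcsv(bundle$hits, "hits.csv")
  wcsv(bundle$skipped, "skipped_files.csv")
  if (!is.null(bundle$profiles))
    for (ch in names(bundle$profiles))
      write_profile(bundle$profiles[[ch]],
                    file.path(out_dir, paste0("illumination_", ch, ".tif")))
  cfg_path <- file.path(out_dir, "config_used.yaml")
  write_config(cfg, cfg_path)
  manifest <- list(
    package = "hcstraffic",
    version = as.character(utils::packageVersion("hcstraffic")),
    r_version = R.version.string,
    config_md5 = unname(tools::md5sum(cfg_path)),
    rejected = bundle$rejected)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(screen_report(bundle), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Plain-text screen report
#' @param bundle result of [run_pipeline()].
#' @return character vector of report lines.
#' @export
screen_report <- function(bundle) {
  lines <- c("Plasma-membrane traffic screen report",
             strrep("=", 38))
  if (!is.null(bundle$plate_qc)) {
    pq <- bundle$plate_qc
    lines <- c(lines, sprintf(
      "Plate transfection QC: %d/%d control images phenotype-positive (failure %.1f%%) -> %s",
      pq$n_phenotype_positive, pq$n_control_images,
      100 * pq$failure_fraction, if (pq$accepted) "accepted" else "REJECTED"))
  }
  if (isTRUE(bundle$rejected)) {
    return(c(lines, "Plate rejected by transfection QC: no hit calling performed."))
  }
  lines <- c(lines,
             sprintf("Fields analysed: %d (%d passing image QC)",
                     nrow(bundle$images),
                     sum(bundle$images$status == "pass")),
             sprintf("Cells measured: %d (%d passing cell QC)",
                     nrow(bundle$cells), sum(bundle$cells$qc_pass)),
             "")
  h <- bundle$hits[bundle$hits$readout == "traffic_efficiency", ]
  lines <- c(lines, "Traffic-efficiency deviation scores vs negative control:",
             sprintf("  %-20s score %+7.3f  %-9s p=%.4g",
                     h$condition, h$deviation_score, h$classification,
                     h$p_value))
  lines
}
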