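#' Per-cell traffic efficiency
#'
#' The core ratiometric readout: integrated surface-label fluorescence
#' over integrated total-reporter fluorescence for each cell.  Because
#' both integrals scale with expression level, the ratio is robust to the
#' strong cell-to-cell expression heterogeneity typical of inducible
#' reporters.  Cells with zero total signal cannot be scored — they must
#' already carry the `low_expression` flag upstream, so reaching one here
#' is a contract violation.
#'
#' @param cells data frame of QC-passing cells with `integrated_surface`
#'   and `integrated_total` columns.
#' @return numeric vector of per-cell ratios.
#' @export
cell_traffic_efficiency <- function(cells) {
  if (any(cells$integrated_total <= 0))
    stop("cell with integrated_total <= 0 reached traffic-efficiency ",
         "computation; such cells must be excluded by the low_expression flag")
  cells$integrated_surface / cells$integrated_total
}

#' Per-image summaries of the three readouts
#'
#' One traffic-efficiency value per image: the median over the image's
#' QC-passing cells (likewise for total and surface expression); even
#' cell counts use the mean of the two middle values.  Images with zero
#' passing cells emit no summary.
#'
#' @param cells QC-annotated cell table for a whole plate.
#' @param passing_only drop cells with `qc_pass == FALSE` first.
#' @return data frame with one row per (well, field) that has at least
#'   one passing cell: `median_traffic_efficiency`, `median_total`,
#'   `median_surface`, `n_cells`.
#' @export
image_summary <- function(cells, passing_only = TRUE) {
  if (passing_only && "qc_pass" %in% names(cells))
    cells <- cells[cells$qc_pass, , drop = FALSE]
  if (nrow(cells) == 0)
    return(data.frame(well = character(0), field = integer(0),
                      median_traffic_efficiency = numeric(0),
                      median_total = numeric(0), median_surface = numeric(0),
                      n_cells = integer(0)))
  te <- cell_traffic_efficiency(cells)
  key <- interaction(cells$well, cells$field, drop = TRUE)
  agg <- function(v) as.numeric(tapply(v, key, median))
  first <- function(v) tapply(v, key, `[`, 1)
  data.frame(well = as.character(first(cells$well)),
             field = as.integer(first(cells$field)),
             median_traffic_efficiency = agg(te),
             median_total = agg(cells$integrated_total),
             median_surface = agg(cells$integrated_surface),
             n_cells = as.integer(tapply(te, key, length)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-condition aggregation of image summaries
#'
#' Averages the per-image medians of every readout across all QC-passing
#' images of a treatment, with the standard error of that mean.  A
#' condition with a single passing image gets a mean but an undefined
#' SEM and is excluded from deviation scoring.
#'
#' @param image_summaries output of [image_summary()], restricted to
#'   QC-passing images, with a `condition` column (or supplied via
#'   `conditions`).
#' @param conditions optional vector assigning a condition to each row.
#' @param aggregate `"mean"` (default) or `"median"` across images.
#' @return data frame, one row per condition: for each readout `r` in
#'   traffic_efficiency/total/surface, `mean_r` and `sem_r`, plus
#'   `n_images`.
#' @export
condition_summary <- function(image_summaries, conditions = NULL,
                              aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (is.null(conditions)) conditions <- image_summaries$condition
  if (is.null(conditions)) stop("no condition assignment supplied")
  if (nrow(image_summaries) == 0) stop("no passing images to aggregate")
  f <- factor(conditions)
  ctr <- if (aggregate == "mean") mean else median
  one <- function(v, fun) as.numeric(tapply(v, f, fun))
  sem <- function(v) as.numeric(tapply(v, f, function(x)
    if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_))
  out <- data.frame(
    condition = levels(f),
    mean_traffic_efficiency = one(image_summaries$median_traffic_efficiency, ctr),
    sem_traffic_efficiency = sem(image_summaries$median_traffic_efficiency),
    mean_total = one(image_summaries$median_total, ctr),
    sem_total = sem(image_summaries$median_total),
    mean_surface = one(image_summaries$median_surface, ctr),
    sem_surface = sem(image_summaries$median_surface),
    n_images = as.integer(tapply(seq_along(f), f, length)),
    stringsAsFactors = FALSE)
  out
}

#' Deviation score of a treatment versus the negative control
#'
#' `(mean_test - mean_neg) / (k * sem_neg)` for the chosen readout.  With
#' the default `k = 2`, an absolute score above 1 means the effect
#' magnitude exceeds twice the negative control's SEM — the screen's
#' significance criterion — so enhancers sit above +1 and inhibitors
#' below -1.
#'
#' @param test,neg single rows of [condition_summary()] output.
#' @param readout `"traffic_efficiency"`, `"total"` or `"surface"`.
#' @param k SEM multiplier in the denominator.
#' @return dimensionless score.
#' @export
deviation_score <- function(test, neg,
                            readout = c("traffic_efficiency", "total", "surface"),
                            k = 2) {
  readout <- match.arg(readout)
  m <- paste0("mean_", readout); s <- paste0("sem_", readout)
  sem_neg <- neg[[s]]
  if (is.na(sem_neg))
    stop("negative control SEM undefined (single image?); cannot score")
  if (sem_neg == 0)
    stop("degenerate negative control: SEM is exactly zero")
  (test[[m]] - neg[[m]]) / (k * sem_neg)
}

#' Classify a deviation score
#'
#' Strict thresholds: enhancer above +1, inhibitor below -1, neutral
#' otherwise (scores of exactly +/-1 are neutral).
#'
#' @param score finite deviation score (vectorised).
#' @return character vector in `{enhancer, inhibitor, neutral}`.
#' @export
classify_condition <- function(score) {
  if (any(!is.finite(score))) stop("non-finite deviation score")
  ifelse(score > 1, "enhancer", ifelse(score < -1, "inhibitor", "neutral"))
}

#' Two-tailed t-test of a treatment against the negative control
#'
#' Student's pooled-variance two-sample t-test on per-image readout
#' values (Welch's correction available via `welch = TRUE`), computed in
#' closed form.
#'
#' @param test_values,neg_values per-image values for the two groups.
#' @param welch use the Welch approximation instead of pooled variance.
#' @return list with `t`, `df`, `p_value`, and `defined` (FALSE when a
#'   group has fewer than 2 values, in which case `p_value` is `NA`).
#' @export
compare_condition <- function(test_values, neg_values, welch = FALSE) {
  nx <- length(test_values); ny <- length(neg_values)
  if (nx < 2 || ny < 2)
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                defined = FALSE))
  mx <- mean(test_values); my <- mean(neg_values)
  vx <- var(test_values); vy <- var(neg_values)
  if (welch) {
    se2 <- vx / nx + vy / ny
    tt <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tt <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  p <- if (!is.finite(tt)) 1 else 2 * pt(-abs(tt), df)
  list(t = tt, df = df, p_value = p, defined = TRUE)
}

#' Score a whole screen against its negative control
#'
#' For every condition and every readout (traffic efficiency, total and
#' surface expression) computes the deviation score, its classification
#' and the two-tailed t-test p-value versus the negative control.  Raw
#' p-values are reported; no multiple-testing correction is applied.
#'
#' @param image_summaries QC-passing [image_summary()] rows with a
#'   `condition` column.
#' @param neg_condition name of the negative-control condition.
#' @param k SEM multiplier (see [deviation_score()]).
#' @param aggregate image-to-condition aggregation, `"mean"` or
#'   `"median"`.
#' @param welch use Welch's t-test instead of Student's.
#' @return data frame of hit calls: one row per condition x readout with
#'   `mean`, `sem`, `n_images`, `deviation_score`, `classification`,
#'   `p_value`, `negative_control`.
#' @export
score_screen <- function(image_summaries, neg_condition, k = 2,
                         aggregate = "mean", welch = FALSE) {
  if (!neg_condition %in% image_summaries$condition)
    stop("negative control '", neg_condition, "' has no passing images")
  cs <- condition_summary(image_summaries, aggregate = aggregate)
  neg <- cs[cs$condition == neg_condition, ]
  readouts <- c(traffic_efficiency = "median_traffic_efficiency",
                total = "median_total", surface = "median_surface")
  rows <- list()
  for (cond in cs$condition) {
    test <- cs[cs$condition == cond, ]
    for (r in names(readouts)) {
      # a condition with a single passing image has no SEM of its own and
      # is excluded from deviation scoring (score reported as NA)
      sc <- if (is.na(test[[paste0("sem_", r)]])) NA_real_ else
        deviation_score(test, neg, r, k)
      tv <- image_summaries[image_summaries$condition == cond, readouts[r]]
      nv <- image_summaries[image_summaries$condition == neg_condition,
                            readouts[r]]
      tt <- compare_condition(tv, nv, welch = welch)
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, readout = r,
        mean = test[[paste0("mean_", r)]], sem = test[[paste0("sem_", r)]],
        n_images = test$n_images, deviation_score = sc,
        classification = if (is.na(sc)) NA_character_ else
          classify_condition(sc),
        p_value = tt$p_value,
        negative_control = neg_condition, sem_multiplier = k,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
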