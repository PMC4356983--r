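# plate simulator: determinism, ground-truth consistency, clipping,
# saturation bookkeeping, plate arithmetic

test_that("same seed gives bit-identical fields; different seed differs", {
  spec <- tiny_cond("wt", 0.4, n = 20, control_role = "none")
  cfg <- tiny_config(list(tiny_cond(), spec), seed = 5)
  f1 <- simulate_field(spec, cfg, "C03", 2)
  f2 <- simulate_field(spec, cfg, "C03", 2)
  expect_identical(f1$images, f2$images)
  expect_identical(f1$cells, f2$cells)
  cfg2 <- tiny_config(list(tiny_cond(), spec), seed = 6)
  f3 <- simulate_field(spec, cfg2, "C03", 2)
  expect_false(identical(f1$images, f3$images))
  expect_identical(names(f1$images), names(f3$images)) # schema unchanged
})

test_that("ground truth: surface/total equals the configured ratio exactly", {
  spec <- tiny_cond("wt", 0.37, n = 30, control_role = "none")
  cfg <- tiny_config(list(tiny_cond(), spec), seed = 8)
  f <- simulate_field(spec, cfg, "A01", 1)
  expect_gt(nrow(f$cells), 0)
  expect_identical(f$cells$true_surface, 0.37 * f$cells$true_total)
})

test_that("no pixel exceeds the detector ceiling, any bit depth", {
  for (bd in c(8, 12)) {
    spec <- condition_spec("sat", 0.4, n_cells_mean = 20,
                           frac_saturating = 0.5)
    cfg <- simulation_config(list(tiny_cond(), spec),
                             image_shape = c(120L, 150L), bit_depth = bd,
                             seed = 3)
    f <- simulate_field(spec, cfg, "A01", 1)
    for (ch in f$images) {
      expect_lte(max(ch), 2^bd - 1)
      expect_gte(min(ch), 0)
    }
    expect_true(any(f$images$total == 2^bd - 1)) # designed saturation present
  }
})

test_that("zero-ratio condition leaves only background in the surface channel", {
  # mutant-like case: no surface signal above baseline over cell bodies
  spec <- condition_spec("mutant", 0, n_cells_mean = 50)
  cfg <- simulation_config(list(tiny_cond(), spec),
                           image_shape = c(200L, 240L), seed = 9)
  f <- simulate_field(spec, cfg, "A01", 1)
  fp <- matrix(FALSE, 200, 240)
  for (i in seq_len(nrow(f$cells)))
    fp <- fp | disk_mask(200, 240, f$cells$row[i] + 1, f$cells$col[i] + 1,
                         f$cells$radius[i])
  in_cells <- mean(f$images$surface[fp])
  cell_free <- mean(f$images$surface[!fp])
  # same baseline+noise statistics inside and outside cells
  expect_lt(abs(in_cells - cell_free), 2)
})

test_that("saturating-cell counts match the configured fraction and the flags
           mark real ceiling pixels", {
  spec <- condition_spec("sat", 0.3, n_cells_mean = 100,
                         frac_saturating = 0.1, frac_apoptotic = 0)
  cfg <- simulation_config(list(tiny_cond(), spec),
                           image_shape = c(400L, 500L), seed = 12)
  f <- simulate_field(spec, cfg, "A01", 1)
  n <- nrow(f$cells)
  k <- sum(f$cells$saturated)
  # binomial expectation at p = 0.1, 3-sd tolerance
  expect_lt(abs(k - 0.1 * n), 3 * sqrt(n * 0.1 * 0.9) + 1e-9)
  top <- 2^cfg$bit_depth - 1
  for (i in which(f$cells$saturated)) {
    m <- disk_mask(400, 500, f$cells$row[i] + 1, f$cells$col[i] + 1,
                   f$cells$radius[i] + 1)
    expect_true(any(f$images$total[m] == top) ||
                  any(f$images$surface[m] == top))
  }
})

test_that("apoptotic cells are small with condensed bright nuclei", {
  spec <- condition_spec("ap", 0.3, n_cells_mean = 80, frac_apoptotic = 0.5)
  cfg <- simulation_config(list(tiny_cond(), spec),
                           image_shape = c(300L, 380L), seed = 4)
  f <- simulate_field(spec, cfg, "A01", 1)
  ap <- f$cells$apoptotic
  expect_gt(sum(ap), 5)
  # area below 30% of a normal cell's
  expect_lt(max(f$cells$radius[ap])^2, 0.3 * mean(f$cells$radius[!ap])^2)
})

test_that("plate assembly: field count, layout, uniqueness, controls", {
  conds <- list(tiny_cond("neg", 0.35),
                tiny_cond("a", 0.2, control_role = "none"),
                tiny_cond("b", 0.5, control_role = "none"),
                tiny_cond("tc", 0.35, control_role = "transfection_control"))
  cfg <- simulation_config(conds, image_shape = c(100L, 120L),
                           fields_per_well = 4, replicate_wells = 3,
                           seed = 2)
  plate <- simulate_plate(cfg)
  expect_equal(length(plate$fields), 4 * 3 * 4) # conditions x wells x fields
  expect_equal(nrow(plate$layout), 12)
  expect_false(any(duplicated(plate$layout$well)))
  # every simulated cell appears exactly once in the ground truth
  gt <- plate$ground_truth$cells
  expect_false(any(duplicated(gt[, c("well", "field", "cell")])))
  nf <- nrow(plate$ground_truth$fields)
  expect_equal(nf, 48)
  # transfection-control fields carry phenotype flags, others do not
  ph <- plate$ground_truth$fields
  tc_wells <- plate$layout$well[plate$layout$control_role ==
                                  "transfection_control"]
  expect_true(all(!is.na(ph$phenotype_positive[ph$well %in% tc_wells])))
  expect_true(all(is.na(ph$phenotype_positive[!ph$well %in% tc_wells])))
  # a layout without a negative control is a configuration error
  bad <- simulation_config(list(tiny_cond("x", 0.3, control_role = "none")),
                           seed = 1)
  expect_error(simulate_plate(bad), "negative")
})

test_that("plates written to disk can be read back identically", {
  conds <- list(tiny_cond("neg", 0.35), tiny_cond("t", 0.5, control_role = "none"))
  cfg <- simulation_config(conds, image_shape = c(100L, 120L),
                           fields_per_well = 1, replicate_wells = 1,
                           seed = 20)
  d <- withr::local_tempdir()
  plate <- simulate_plate(cfg, out_dir = d)
  schema <- filename_schema()
  for (f in plate$fields) {
    for (ch in c("nuclei", "total", "surface")) {
      back <- read_tiff(file.path(d, format_filename(schema, f$well,
                                                     f$field, ch)))
      expect_identical(back, f$images[[ch]] + 0)
    }
  }
  expect_true(file.exists(file.path(d, "layout.csv")))
  expect_true(file.exists(file.path(d, "ground_truth_cells.csv")))
})

test_that("invalid condition parameters are rejected", {
  expect_error(condition_spec("x", NaN), "non-finite")
  expect_error(condition_spec("x", -0.1))
  expect_error(condition_spec("x", 0.5, frac_apoptotic = 1.5))
  expect_error(simulation_config(list(), seed = 1), "non-empty")
  expect_error(simulation_config(list(tiny_cond()), bit_depth = 20))
})
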