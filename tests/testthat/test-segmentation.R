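# nuclei detection, seeded cell growing, fluorescence integration

test_that("blank images yield empty label maps, not errors", {
  nuc <- segment_nuclei(matrix(0, 50, 60))
  expect_equal(nuc$n, 0)
  expect_true(all(nuc$labels == 0))
  cells <- segment_cells(matrix(0, 50, 60), nuc)
  expect_equal(cells$n, 0)
})

test_that("well-separated nuclei are each found within 2 px of truth", {
  set.seed(21)
  nr <- 200; nc <- 240
  img <- matrix(0, nr, nc)
  centers <- expand.grid(r = c(30, 90, 150), c = c(30, 90, 150, 210))
  for (i in 1:12) img <- draw_disk(img, centers$r[i], centers$c[i], 5, 800)
  img <- img + matrix(rnorm(nr * nc, 0, 4), nr, nc)
  nuc <- segment_nuclei(img)
  expect_equal(nuc$n, 12)
  for (i in 1:12) {
    d <- sqrt((nuc$centroids$row + 1 - centers$r[i])^2 +
                (nuc$centroids$col + 1 - centers$c[i])^2)
    expect_lt(min(d), 2)
  }
})

test_that("touching equal nuclei are split by the watershed", {
  img <- matrix(0, 60, 60)
  img <- draw_disk(img, 30, 25, 6, 800)
  img <- draw_disk(img, 30, 36, 6, 800) # centres 11 px apart, radius 6
  nuc <- segment_nuclei(img)
  expect_equal(nuc$n, 2)
  # split roughly down the middle
  areas <- tabulate(nuc$labels[nuc$labels > 0], 2)
  expect_lt(abs(areas[1] - areas[2]) / sum(areas), 0.25)
})

test_that("the nucleus area gate removes too-small and too-large objects", {
  img <- matrix(0, 100, 100)
  img <- draw_disk(img, 20, 20, 2, 800)   # ~13 px, below gate
  img <- draw_disk(img, 50, 50, 5, 800)   # ~80 px, inside gate
  img <- draw_disk(img, 80, 70, 18, 800)  # ~1000 px, inside default gate
  nuc <- segment_nuclei(img, min_area = 40, max_area = 500)
  expect_equal(nuc$n, 1)
})

test_that("one nucleus in one bright disk recovers the disk (Jaccard >= 0.8)", {
  nr <- 100; nc <- 100
  nuclei_img <- draw_disk(matrix(0, nr, nc), 50, 50, 5, 800)
  total_img <- draw_disk(matrix(0, nr, nc), 50, 50, 18, 500)
  nuc <- segment_nuclei(nuclei_img)
  expect_equal(nuc$n, 1)
  cells <- segment_cells(total_img, nuc)
  truth <- disk_mask(nr, nc, 50, 50, 18)
  got <- cells$labels == 1
  jac <- sum(truth & got) / sum(truth | got)
  expect_gte(jac, 0.8)
  expect_true(all(got[nuclei_img > 0])) # cell mask contains its nucleus
})

test_that("two nuclei in one connected region give exactly two cells", {
  nr <- 80; nc <- 120
  nuclei_img <- draw_disk(matrix(0, nr, nc), 40, 45, 5, 800)
  nuclei_img <- draw_disk(nuclei_img, 40, 75, 5, 800)
  total_img <- matrix(0, nr, nc)
  total_img[25:55, 30:90] <- 400 # one connected bright slab
  nuc <- segment_nuclei(nuclei_img)
  expect_equal(nuc$n, 2)
  cells <- segment_cells(total_img, nuc)
  labs <- unique(cells$labels[cells$labels > 0])
  expect_setequal(labs, 1:2)
  # cells are disjoint by construction of the label raster; check both
  # nuclei kept their own labels
  expect_equal(unique(cells$labels[nuclei_img > 0 &
                                     disk_mask(nr, nc, 40, 45, 5)]), 1)
})

test_that("with a blank reporter channel cells collapse onto their nuclei", {
  nuclei_img <- draw_disk(matrix(0, 60, 60), 30, 30, 5, 800)
  nuc <- segment_nuclei(nuclei_img)
  cells <- segment_cells(matrix(0, 60, 60), nuc, expand_px = 2)
  inside <- cells$labels == 1
  expect_true(all(inside[nuc$labels == 1]))
  # bounded by the nucleus dilated by expand_px
  dil <- disk_mask(60, 60, 30, 30, 5 + 3.5)
  expect_true(all(dil[inside]))
})

test_that("fluorescence integration matches a brute-force pixel loop exactly", {
  fx <- analysed_field()
  rec <- fx$records
  lab <- fx$cells$labels
  for (ch in c("nuclei", "total", "surface")) {
    vals <- fx$corr[[ch]]
    brute <- numeric(fx$cells$n)
    for (p in which(lab > 0)) brute[lab[p]] <- brute[lab[p]] + vals[p]
    expect_identical(rec[[paste0("integrated_", ch)]], brute)
  }
  # area via the same loop
  brute_area <- tabulate(lab[lab > 0], fx$cells$n)
  expect_equal(rec$area, brute_area)
  expect_equal(rec$mean_total, rec$integrated_total / rec$area)
})

test_that("simple integration identities hold", {
  lab <- matrix(0L, 10, 10); lab[2:6, 3] <- 1L; lab[8, 1:5] <- 2L
  labmap <- structure(list(labels = lab, n = 2L, provenance = "cells",
                           centroids = data.frame(label = 1:2, row = c(3, 7),
                                                  col = c(2, 2))),
                      class = "label_map")
  ch <- matrix(7, 10, 10)
  zero <- matrix(0, 10, 10)
  rec <- measure_cells(labmap, labmap,
                       list(nuclei = zero, total = ch, surface = zero),
                       bit_depth = 12)
  expect_equal(rec$integrated_total, c(35, 35)) # 5 px x 7 counts
  expect_equal(rec$mean_total, c(7, 7))
  expect_equal(rec$integrated_surface, c(0, 0))
})

test_that("saturation is counted on the raw rasters at the bit-depth ceiling", {
  lab <- matrix(0L, 8, 8); lab[3:5, 3:5] <- 1L
  labmap <- structure(list(labels = lab, n = 1L, provenance = "cells",
                           centroids = data.frame(label = 1, row = 3, col = 3)),
                      class = "label_map")
  raw <- matrix(0, 8, 8); raw[4, 4] <- 4095; raw[4, 5] <- 4095
  raw[1, 1] <- 4095 # outside the cell: not counted
  corr <- list(nuclei = raw * 0, total = raw * 0, surface = raw * 0)
  rec <- measure_cells(labmap, labmap, corr,
                       raw_channels = list(nuclei = raw * 0, total = raw,
                                           surface = raw * 0),
                       bit_depth = 12)
  expect_equal(rec$sat_total, 2)
  expect_equal(rec$sat_nuclei, 0)
})

test_that("label bookkeeping: bijection and signal conservation", {
  fx <- analysed_field()
  expect_equal(nrow(fx$records), fx$cells$n)
  expect_equal(fx$cells$n, fx$nuclei$n)
  expect_lte(sum(fx$records$integrated_total), sum(fx$corr$total))
  expect_true(all(fx$records$area > 0))
  expect_true(all(fx$records$form_factor > 0 &
                    fx$records$form_factor <= 1.05))
})

test_that("simulated fields are recovered nearly one-to-one", {
  fx <- analysed_field()
  gt <- fx$sim$cells
  ok <- 0
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((fx$nuclei$centroids$row - gt$row[i])^2 +
                (fx$nuclei$centroids$col - gt$col[i])^2)
    if (min(d) <= gt$nucleus_radius[i]) ok <- ok + 1
  }
  expect_gte(ok / nrow(gt), 0.95)
  expect_lte(abs(fx$nuclei$n - nrow(gt)), ceiling(0.05 * nrow(gt)))
})
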