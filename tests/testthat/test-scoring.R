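# ratiometric readout, aggregation, deviation scores, t-tests

test_that("traffic efficiency is the surface/total ratio and is
           scale-invariant", {
  cells <- data.frame(integrated_surface = c(50, 0, 30),
                      integrated_total = c(100, 80, 300))
  expect_equal(cell_traffic_efficiency(cells), c(0.5, 0, 0.1))
  scaled <- cells; scaled$integrated_surface <- scaled$integrated_surface * 3
  scaled$integrated_total <- scaled$integrated_total * 3
  expect_equal(cell_traffic_efficiency(scaled),
               cell_traffic_efficiency(cells))
  bad <- data.frame(integrated_surface = 1, integrated_total = 0)
  expect_error(cell_traffic_efficiency(bad), "contract|low_expression")
})

test_that("image medians follow the even-count convention and a sort oracle", {
  mk <- function(te) data.frame(well = "A01", field = 1L,
                                integrated_total = 100,
                                integrated_surface = te * 100,
                                qc_pass = TRUE)
  s <- image_summary(do.call(rbind, lapply(c(0.2, 0.4, 0.9), mk)))
  expect_equal(s$median_traffic_efficiency, 0.4)
  s2 <- image_summary(do.call(rbind, lapply(c(0.2, 0.4), mk)))
  expect_equal(s2$median_traffic_efficiency, 0.3)
  # randomised check against an independent sort-and-pick oracle
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(1:15, 1)
    te <- runif(n)
    s3 <- image_summary(do.call(rbind, lapply(te, mk)))
    srt <- sort(te)
    oracle <- if (n %% 2 == 1) srt[(n + 1) / 2] else
      (srt[n / 2] + srt[n / 2 + 1]) / 2
    expect_equal(s3$median_traffic_efficiency, oracle)
    expect_equal(s3$n_cells, n)
  }
  # QC-failing cells never enter the medians
  cells <- rbind(mk(0.2), mk(0.4), mk(0.9))
  cells$qc_pass <- c(TRUE, TRUE, FALSE)
  expect_equal(image_summary(cells)$median_traffic_efficiency, 0.3)
})

test_that("condition aggregation: mean of image medians with sample SEM", {
  ims <- data.frame(condition = "t",
                    median_traffic_efficiency = c(0.40, 0.50, 0.60),
                    median_total = c(1, 2, 3), median_surface = c(4, 5, 6))
  cs <- condition_summary(ims)
  expect_equal(cs$mean_traffic_efficiency, 0.5)
  expect_equal(cs$sem_traffic_efficiency, 0.1 / sqrt(3))
  expect_equal(cs$sem_traffic_efficiency, 0.05773503, tolerance = 1e-6)
  expect_equal(cs$n_images, 3)
  two <- condition_summary(data.frame(condition = "t",
                                      median_traffic_efficiency = c(0.3, 0.5),
                                      median_total = 0, median_surface = 0))
  expect_equal(two$mean_traffic_efficiency, 0.4)
  # single image: mean reported, SEM undefined
  one <- condition_summary(data.frame(condition = "t",
                                      median_traffic_efficiency = 0.3,
                                      median_total = 0, median_surface = 0))
  expect_equal(one$mean_traffic_efficiency, 0.3)
  expect_true(is.na(one$sem_traffic_efficiency))
  # median aggregation switch
  ims2 <- data.frame(condition = "t",
                     median_traffic_efficiency = c(0.1, 0.2, 0.9),
                     median_total = 0, median_surface = 0)
  expect_equal(condition_summary(ims2, aggregate = "median")$mean_traffic_efficiency,
               0.2)
})

test_that("deviation scores: worked example, boundary, antisymmetry", {
  mk_cs <- function(vals) condition_summary(
    data.frame(condition = "x", median_traffic_efficiency = vals,
               median_total = vals, median_surface = vals))
  neg <- mk_cs(c(0.40, 0.50, 0.60)) # sem = 0.0577350
  test <- mk_cs(c(0.65, 0.70, 0.75))
  sc <- deviation_score(test, neg, "traffic_efficiency", k = 2)
  # oracle: hand evaluation (0.70 - 0.50) / (2 * 0.1/sqrt(3))
  expect_equal(sc, 0.2 / (2 * 0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(sc, sqrt(3), tolerance = 1e-12)
  # identical means -> 0
  expect_equal(deviation_score(neg, neg, "traffic_efficiency"), 0)
  # effect of exactly k x SEM -> score exactly 1, the significance boundary
  sem <- neg$sem_traffic_efficiency
  boundary <- neg; boundary$mean_traffic_efficiency <-
    neg$mean_traffic_efficiency + 2 * sem
  expect_equal(deviation_score(boundary, neg, "traffic_efficiency", k = 2), 1)
  # swapping test and control negates the score (for equal-SEM groups,
  # the only case where the denominator is unchanged)
  shifted <- mk_cs(c(0.60, 0.70, 0.80))
  expect_equal(deviation_score(neg, shifted, "traffic_efficiency"),
               -deviation_score(shifted, neg, "traffic_efficiency"))
  # degenerate control
  degen <- mk_cs(c(0.5, 0.5, 0.5))
  expect_error(deviation_score(test, degen, "traffic_efficiency"),
               "degenerate")
  one_img <- condition_summary(data.frame(
    condition = "x", median_traffic_efficiency = 0.5,
    median_total = 0.5, median_surface = 0.5))
  expect_error(deviation_score(test, one_img, "traffic_efficiency"),
               "undefined")
})

test_that("classification uses strict +/-1 thresholds", {
  expect_equal(classify_condition(1.5), "enhancer")
  expect_equal(classify_condition(-1.2), "inhibitor")
  expect_equal(classify_condition(c(1, -1, 0, 0.999, -0.999)),
               rep("neutral", 5))
  expect_equal(classify_condition(1 + 1e-9), "enhancer")
  expect_error(classify_condition(NaN), "non-finite")
  expect_error(classify_condition(Inf), "non-finite")
})

test_that("pooled t-test matches stats::t.test and the closed form", {
  # identical groups: t = 0, p = 1
  r0 <- compare_condition(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6))
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  # worked example {1,2,3} vs {4,5,6}
  r <- compare_condition(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(r$t), 3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-sqrt(13.5), 4), tolerance = 1e-12)
  expect_equal(r$p_value, 0.02131164, tolerance = 1e-6)
  # randomised agreement with the reference implementation
  set.seed(61)
  for (i in 1:25) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1), mean = runif(1))
    ours <- compare_condition(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    oursw <- compare_condition(x, y, welch = TRUE)
    refw <- t.test(x, y)
    expect_equal(oursw$p_value, refw$p.value, tolerance = 1e-10)
  }
  # under-sized groups are flagged undefined
  u <- compare_condition(1, c(1, 2))
  expect_false(u$defined)
  expect_true(is.na(u$p_value))
})

test_that("t-test p-values sit inside the exhaustive-permutation neighbourhood", {
  # oracle: exact permutation distribution of the mean difference at n=4+4
  set.seed(71)
  for (rep in 1:5) {
    x <- rnorm(4, 0, 1); y <- rnorm(4, 0.8, 1)
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    idx <- utils::combn(8, 4)
    diffs <- apply(idx, 2, function(i) abs(mean(pool[i]) - mean(pool[-i])))
    p_perm <- mean(diffs >= obs - 1e-12)
    p_t <- compare_condition(x, y)$p_value
    expect_lt(abs(p_t - p_perm), 0.12) # resolution of 70 permutations
  }
})

test_that("score_screen assembles hit calls for all three readouts", {
  set.seed(81)
  mk <- function(cond, te, n = 5) data.frame(
    condition = cond, well = "A01", field = seq_len(n),
    median_traffic_efficiency = te + rnorm(n, 0, 0.01),
    median_total = 1000 + rnorm(n, 0, 30),
    median_surface = te * 1000 + rnorm(n, 0, 20))
  ims <- rbind(mk("neg", 0.35), mk("up", 0.50), mk("down", 0.20),
               mk("same", 0.35))
  hits <- score_screen(ims, "neg")
  expect_equal(nrow(hits), 4 * 3)
  te <- hits[hits$readout == "traffic_efficiency", ]
  expect_equal(te$classification[te$condition == "up"], "enhancer")
  expect_equal(te$classification[te$condition == "down"], "inhibitor")
  expect_equal(te$deviation_score[te$condition == "neg"], 0)
  expect_equal(te$p_value[te$condition == "neg"], 1)
  expect_lt(te$p_value[te$condition == "up"], 0.01)
  expect_error(score_screen(ims, "absent"), "no passing images")
})
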