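test_that("roi_average is the mean of valid ROI voxels", {
  map <- array(0.3, c(4, 4, 1))
  expect_equal(roi_average(map, array(TRUE, c(4, 4, 1))), 0.3)
  map2 <- array(c(0.1, 0.3, 99, 99), c(4, 1, 1))
  roi <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  expect_equal(roi_average(map2, roi), 0.2)
  map2[1, 1, 1] <- NA  # invalid voxels are ignored
  expect_equal(roi_average(map2, roi), 0.3)
  expect_error(roi_average(map2, array(FALSE, c(4, 1, 1))), "no valid")
})

test_that("histograms conserve voxels and localize constant values", {
  map <- array(0.05, c(5, 5, 2))  # the midpoint of [0, 0.1]
  h <- roi_histogram(map, array(TRUE, c(5, 5, 2)), range = c(0, 0.1))
  expect_equal(sum(h$counts), 50)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(sum(h$percent), 100)
  # values past the range edges are tracked, not dropped
  map[1, 1, 1] <- 0.5; map[2, 1, 1] <- -0.2
  h2 <- roi_histogram(map, array(TRUE, c(5, 5, 2)), range = c(0, 0.1))
  expect_equal(h2$out_of_range_high, 1L)
  expect_equal(h2$out_of_range_low, 1L)
  expect_equal(sum(h2$counts) + h2$out_of_range_low + h2$out_of_range_high,
               h2$n_total)
  # a value exactly at range max lands in the last (right-closed) bin
  h3 <- roi_histogram(array(0.1, c(2, 2, 1)), array(TRUE, c(2, 2, 1)),
                      range = c(0, 0.1))
  expect_equal(h3$counts[50], 4)
  expect_equal(h3$out_of_range_high, 0L)
})

test_that("uniform draws fill histogram bins binomially", {
  set.seed(101)
  n <- 10000
  vals <- array(runif(n, 0, 0.02), c(100, 100, 1))
  h <- roi_histogram(vals, array(TRUE, c(100, 100, 1)), range = c(0, 0.02))
  # each bin is Binomial(n, 1/50): mean 200, sd ~ 14
  sd_bin <- sqrt(n * (1 / 50) * (49 / 50))
  expect_true(all(abs(h$counts - 200) < 3 * sd_bin))
  expect_equal(sum(h$counts), n)
})

test_that("per-bin comparison matches the textbook t statistic", {
  mk <- function(percents) {
    h <- roi_histogram(array(0.01, c(2, 2, 1)), array(TRUE, c(2, 2, 1)),
                       range = c(0, 0.02), n_bins = 4)
    h$percent <- percents
    h
  }
  a <- list(mk(c(30, 30, 20, 20)), mk(c(32, 28, 22, 18)), mk(c(28, 32, 18, 22)))
  b <- list(mk(c(10, 50, 20, 20)), mk(c(12, 48, 22, 18)), mk(c(8, 52, 18, 22)))
  res <- compare_histograms(a, b)
  # hand-computed pooled-variance two-sample t for bin 1:
  # means 30 vs 10, each group sd = 2, n = 3 -> t = 20 / (2 sqrt(2/3))
  t_expected <- 20 / (2 * sqrt(2 / 3))
  expect_equal(res$statistic[1], t_expected, tolerance = 1e-9)
  expect_equal(res$p_value[1],
               2 * pt(-abs(t_expected), df = 4), tolerance = 1e-9)
  expect_lt(res$p_value[1], 0.05)
  expect_lt(res$p_value[2], 0.05)
  # bins 3 and 4 are identical across groups
  expect_true(all(res$p_value[3:4] > 0.99))
  # identical groups: every defined p-value is 1 or degenerate-flagged
  res_id <- compare_histograms(a, a)
  expect_true(all(res_id$p_value >= 0.999 | res_id$degenerate))
  # paired mode with B = A flags zero-variance bins instead of crashing
  res_p <- compare_histograms(a, a, paired = TRUE)
  expect_true(all(res_p$degenerate))
  expect_true(all(res_p$p_value == 1))
  # binning mismatch is an error
  bad <- list(mk(c(1, 2, 3, 4)), mk(c(1, 2, 3, 4)))
  bad[[1]]$bin_edges <- bad[[1]]$bin_edges * 2
  expect_error(compare_histograms(bad, b), "binning")
})

test_that("per-animal aggregation averages paired ovaries", {
  expect_equal(unname(aggregate_subject(c(0.02, 0.04), c("m1", "m1"))), 0.03)
  expect_equal(unname(aggregate_subject(0.05, "m2")), 0.05)
  # 12 ovaries across 8 animals reduce to 8 per-animal values
  animal <- c("a", "a", "b", "c", "c", "d", "e", "e", "f", "g", "h", "h")
  vals <- seq(0.01, 0.12, by = 0.01)
  out <- aggregate_subject(vals, animal)
  expect_length(out, 8L)
  expect_equal(unname(out["a"]), mean(vals[1:2]))
  expect_equal(unname(out["b"]), vals[3])
})

test_that("paired group comparison reproduces the hand-computed t-test", {
  a <- c(0.020, 0.025, 0.018, 0.030, 0.022)
  b <- c(0.010, 0.012, 0.011, 0.015, 0.013)
  res <- compare_roi_groups_paired(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic, t_manual, tolerance = 1e-9)
  expect_equal(res$p_value, 2 * pt(-abs(t_manual), df = 4), tolerance = 1e-9)
  # antisymmetry under group swap
  res_swap <- compare_roi_groups_paired(b, a)
  expect_equal(res_swap$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(res_swap$p_value, res$p_value, tolerance = 1e-12)
  # degenerate identical groups
  res_id <- compare_roi_groups_paired(a, a)
  expect_true(res_id$degenerate)
  expect_equal(res_id$p_value, 1)
  expect_error(compare_roi_groups_paired(a, b[1:3]), "equal-length")
})

test_that("seeded power study: paired test separates DF from SF permeability", {
  # five animals with paired DF/SF ROI-mean PS, DF 40% below SF, 10% noise
  set.seed(2024)
  n_rep <- 200
  ps_sf <- 0.010
  ps_df <- 0.006
  rejections <- vapply(seq_len(n_rep), function(i) {
    sf <- ps_sf * (1 + rnorm(5, 0, 0.10))
    df <- ps_df * (1 + rnorm(5, 0, 0.10))
    compare_roi_groups_paired(df, sf)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("the DF/SF rule classifies quadrants and ignores voxel order", {
  dims <- c(4, 4, 1)
  mk_vm <- function(ps, late) {
    structure(list(fbv = array(0.03, dims), ps = array(ps, dims),
                   late_rate = array(late, dims),
                   valid_mask = array(TRUE, dims),
                   qc_negative = array(FALSE, dims), cb0 = 1,
                   windows = kinetic_windows()), class = "vascular_maps")
  }
  roi <- array(TRUE, dims)
  expect_equal(classify_follicle(mk_vm(0.002, 0.01), roi, 0.005)$call, "DF")
  expect_equal(classify_follicle(mk_vm(0.010, -0.004), roi, 0.005)$call, "SF")
  expect_equal(classify_follicle(mk_vm(0.002, -0.004), roi, 0.005)$call,
               "indeterminate")
  expect_equal(classify_follicle(mk_vm(0.010, 0.01), roi, 0.005)$call,
               "indeterminate")
  # adding invalid-masked voxels to the ROI does not change the call
  vm <- mk_vm(0.002, 0.01)
  vm$ps[1, 1, 1] <- NA; vm$late_rate[1, 1, 1] <- NA
  expect_equal(classify_follicle(vm, roi, 0.005)$call, "DF")
})

test_that("noiseless phantom classification is perfect with the median rule", {
  tr <- build_phantom(small_spec(seed = 31))
  chain <- run_chain(tr)
  rois <- list(f1 = tr$follicle_id == 1L, f2 = tr$follicle_id == 2L)
  calls <- classify_follicles(chain$vmaps, rois)
  expect_equal(vapply(calls, `[[`, "", "call"),
               c(f1 = "DF", f2 = "SF"))
  # thresholds are echoed so the call is reproducible
  expect_equal(calls$f1$ps_threshold, calls$f2$ps_threshold)
  expect_equal(calls$f1$late_threshold, 0)
})
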