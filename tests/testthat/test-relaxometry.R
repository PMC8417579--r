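test_that("spgr_signal matches the closed form and its limits", {
  # frozen high-precision evaluation of the SPGR equation
  expect_equal(spgr_signal(1000, 1, 15, 0.01), 58.9510143602, tolerance = 1e-9)
  # vanishing flip angle kills the signal; saturation limit returns M0
  expect_lt(spgr_signal(1000, 1, 1e-6, 0.01), 1e-4)
  expect_equal(spgr_signal(500, 5000, 90, 0.01), 500, tolerance = 1e-9)
  expect_error(spgr_signal(1000, -1, 15, 0.01), "r1")
  expect_error(spgr_signal(1000, 1, 15, 0), "tr")
})

test_that("spgr_signal is monotone in M0 and in R1 below the Ernst angle", {
  r1 <- seq(0.2, 5, length.out = 30)
  s <- spgr_signal(1000, r1, 5, 0.01)  # 5 deg is below the Ernst angle here
  expect_true(all(diff(s) > 0))
  m0 <- seq(100, 2000, length.out = 20)
  expect_true(all(diff(spgr_signal(m0, 1, 15, 0.01)) > 0))
  # linearity in M0
  expect_equal(spgr_signal(2000, 1.3, 30, 0.01),
               2 * spgr_signal(1000, 1.3, 30, 0.01))
})

test_that("noiseless VFA signals invert to (M0, R1) essentially exactly", {
  acq <- std_acq()
  r1_grid <- c(0.2, 0.5, 1, 2, 3.5, 5)
  m0_grid <- c(400, 800, 1500)
  cases <- expand.grid(r1 = r1_grid, m0 = m0_grid)
  nv <- nrow(cases)
  vfa <- array(NA_real_, c(nv, 1, 1, 5))
  for (j in 1:5)
    vfa[, 1, 1, j] <- spgr_signal(cases$m0, cases$r1, acq$flip_angles[j],
                                  acq$tr)
  maps <- fit_r1_vfa(vfa, acq)
  expect_true(all(maps$valid_mask))
  expect_lt(max(abs(maps$r1pre[, 1, 1] - cases$r1) / cases$r1), 1e-6)
  expect_lt(max(abs(maps$m0[, 1, 1] - cases$m0) / cases$m0), 1e-6)
})

test_that("single-voxel VFA fit agrees with stats::nls on noisy data", {
  acq <- std_acq()
  set.seed(42)
  s_true <- spgr_signal(900, 1.4, acq$flip_angles, acq$tr)
  s_obs <- s_true + rnorm(5, 0, 0.01 * max(s_true))
  vfa <- array(s_obs, c(1, 1, 1, 5))
  maps <- fit_r1_vfa(vfa, acq)
  ref <- stats::nls(s ~ m0 * sin(a) * (1 - exp(-0.01 * r1)) /
                      (1 - cos(a) * exp(-0.01 * r1)),
                    data = list(s = s_obs, a = acq$flip_angles * pi / 180),
                    start = list(m0 = 900, r1 = 1.4), algorithm = "port",
                    lower = c(1, 0.05), upper = c(1e6, 20))
  est <- coef(ref)
  expect_equal(maps$r1pre[1, 1, 1], unname(est["r1"]), tolerance = 1e-6)
  expect_equal(maps$m0[1, 1, 1], unname(est["m0"]), tolerance = 1e-6)
})

test_that("invalid voxels are masked, not errors", {
  acq <- std_acq()
  vfa <- array(0, c(2, 1, 1, 5))
  vfa[2, 1, 1, ] <- spgr_signal(800, 1, acq$flip_angles, acq$tr)
  maps <- fit_r1_vfa(vfa, acq)
  expect_false(maps$valid_mask[1, 1, 1])
  expect_true(is.na(maps$r1pre[1, 1, 1]))
  expect_true(maps$valid_mask[2, 1, 1])
  expect_error(fit_r1_vfa(vfa[, , , 1:2, drop = FALSE],
                          acq_params(c(5, 15), tr_ms = 10)),
               "3 flip angles")
})

test_that("Monte-Carlo VFA recovery at 1% noise is accurate in the median", {
  acq <- std_acq()
  set.seed(11)
  n <- 500
  s_true <- spgr_signal(1000, 1, acq$flip_angles, acq$tr)
  vfa <- array(rep(s_true, each = n) + rnorm(n * 5, 0, 0.01 * max(s_true)),
               c(n, 1, 1, 5))
  maps <- fit_r1_vfa(vfa, acq)
  expect_gt(mean(maps$valid_mask), 0.99)
  med <- median(maps$r1pre[, 1, 1], na.rm = TRUE)
  expect_lt(abs(med - 1) / 1, 0.05)
})

test_that("post-contrast R1 inversion is exact on identity and roundtrip", {
  # identical signals: R1post equals R1pre
  ipre <- spgr_signal(1000, 0.8, 15, 0.01)
  expect_equal(invert_r1_post(ipre, ipre, 0.8, 15, 0.01), 0.8,
               tolerance = 1e-9)
  # forward-generate at a known R1post and invert
  ipost <- spgr_signal(1000, 2, 15, 0.01)
  expect_equal(invert_r1_post(ipre, ipost, 0.8, 15, 0.01), 2,
               tolerance = 1e-9)
})

test_that("closed-form R1 inversion matches a bracketed numerical root-finder", {
  # independent oracle: solve the pre/post signal-ratio equation for R1post
  # by uniroot on the forward model, over a seeded grid of conditions
  set.seed(3)
  tr <- 0.01
  cases <- expand.grid(r1pre = c(0.3, 0.7, 1.5), r1post = c(0.5, 2, 6, 12),
                       alpha = c(10, 15, 40))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    ipre <- spgr_signal(1000, cs$r1pre, cs$alpha, tr)
    ipost <- spgr_signal(1000, cs$r1post, cs$alpha, tr)
    got <- invert_r1_post(ipre, ipost, cs$r1pre, cs$alpha, tr)
    oracle <- uniroot(function(r1) {
      spgr_signal(1000, r1, cs$alpha, tr) - ipost
    }, interval = c(1e-4, 200), tol = 1e-13)$root
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("non-physical enhancement ratios yield NA, never an error", {
  ipre <- spgr_signal(1000, 0.8, 15, 0.01)
  # ratio pushing the signal past the saturation ceiling
  expect_true(is.na(invert_r1_post(ipre, ipre * 50, 0.8, 15, 0.01)))
  expect_true(is.na(invert_r1_post(0, 10, 0.8, 15, 0.01)))
})

test_that("concentration conversion is the relaxation enhancement over r1", {
  acq <- std_acq(frame_times = c(1, 3))
  # single voxel, forward signals at known R1post
  r1pre <- 0.7
  relax <- structure(list(r1pre = array(r1pre, c(1, 1, 1)),
                          m0 = array(1000, c(1, 1, 1)),
                          fit_rss = array(0, c(1, 1, 1)),
                          valid_mask = array(TRUE, c(1, 1, 1))),
                     class = "relaxometry_maps")
  pre <- array(spgr_signal(1000, r1pre, 15, acq$tr), c(1, 1, 1))
  # frame 1: no enhancement; frame 2: R1post - R1pre = 3.3 -> 1 mM at r1 = 3.3
  post <- array(c(pre, spgr_signal(1000, r1pre + 3.3, 15, acq$tr)),
                c(1, 1, 1, 2))
  conc <- concentration_series(dce_series(post, acq$frame_times), pre,
                               relax, acq)
  expect_equal(conc$data[1, 1, 1, 1], 0, tolerance = 1e-9)
  expect_equal(conc$data[1, 1, 1, 2], 1, tolerance = 1e-9)
  # concentration increases monotonically with R1post
  r1post <- seq(0.7, 4, length.out = 10)
  sig <- spgr_signal(1000, r1post, 15, acq$tr)
  cc <- vapply(sig, function(s)
    (invert_r1_post(pre[1], s, r1pre, 15, acq$tr) - r1pre) / 3.3, numeric(1))
  expect_true(all(diff(cc) > 0))
})

test_that("invalid relaxometry voxels propagate NA concentrations", {
  acq <- std_acq(frame_times = c(1, 3))
  relax <- structure(list(r1pre = array(c(0.7, NA), c(2, 1, 1)),
                          m0 = array(1000, c(2, 1, 1)),
                          fit_rss = array(0, c(2, 1, 1)),
                          valid_mask = array(c(TRUE, FALSE), c(2, 1, 1))),
                     class = "relaxometry_maps")
  pre <- array(spgr_signal(1000, 0.7, 15, acq$tr), c(2, 1, 1))
  post <- array(rep(pre, 2), c(2, 1, 1, 2))
  conc <- concentration_series(dce_series(post, acq$frame_times), pre,
                               relax, acq)
  expect_true(all(is.na(conc$data[2, 1, 1, ])))
  expect_true(all(!is.na(conc$data[1, 1, 1, ])))
})
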