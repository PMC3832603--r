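test_that("sample_coefficients honours the CI-to-SD convention", {
  p <- red_params()
  s <- sample_coefficients(p, 1000, seed = 5)
  expect_equal(dim(s$draws), c(1000L, 4L))
  # column SDs within 10% of half-width / 1.96 (law of large numbers)
  for (k in c("b", "c", "d", "g")) {
    target <- p$ci_halfwidth[[k]] / 1.96
    expect_equal(sd(s$draws[, k]), target, tolerance = 0.1)
  }
  expect_true(all(s$draws > 0))

  # determinism: same seed gives identical matrices
  s2 <- sample_coefficients(p, 1000, seed = 5)
  expect_identical(s$draws, s2$draws)

  # zero-width CIs collapse every draw onto the fitted values
  p0 <- biexp_params(100, 3000, 150, 900)
  s0 <- sample_coefficients(p0, 50, seed = 1)
  expect_true(all(s0$draws[, "b"] == 100))
  expect_true(all(s0$draws[, "g"] == 900))

  # bezier draws cover all eight coordinates
  fx <- oecf_fixture("canon40d_red")
  sb <- sample_coefficients(fx$bezier, 200, seed = 2)
  expect_equal(ncol(sb$draws), 8L)
  expect_equal(colnames(sb$draws), c(paste0("x", 0:3), paste0("y", 0:3)))
})

test_that("mc_linear_bounds propagates uncertainty with the right shape", {
  p <- red_params()
  s <- sample_coefficients(p, 400, seed = 11)
  b <- suppressWarnings(mc_linear_bounds(s, levels = 64))
  expect_length(b$levels, 64L)
  expect_length(b$sd_exposure, 64L)
  expect_true(all(b$sd_exposure >= 0))
  expect_true(all(diff(b$levels) > 0))
  # f(0) = 0 is CI-independent under a = b + d: zero SD at zero response
  expect_equal(b$sd_exposure[1], 0)

  # zero-width CIs give exactly zero SD everywhere
  p0 <- biexp_params(103, 3640, 157, 981, g_max = 250)
  b0 <- mc_linear_bounds(sample_coefficients(p0, 100, seed = 1),
                         levels = 32)
  expect_true(all(b0$sd_exposure == 0))
  expect_equal(b0$n_dropped, 0L)

  # halving CI half-widths approximately halves mid-range SDs
  ph <- p
  ph$ci_halfwidth <- p$ci_halfwidth / 2
  bh <- suppressWarnings(
    mc_linear_bounds(sample_coefficients(ph, 400, seed = 11), levels = 64))
  mid <- 20:40
  ratio <- median(bh$sd_exposure[mid] / b$sd_exposure[mid])
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
})

test_that("mc_linear_bounds is seed-deterministic and converges", {
  p <- red_params()
  b1 <- suppressWarnings(
    mc_linear_bounds(sample_coefficients(p, 500, seed = 3), levels = 32))
  b2 <- suppressWarnings(
    mc_linear_bounds(sample_coefficients(p, 500, seed = 3), levels = 32))
  expect_identical(b1$sd_exposure, b2$sd_exposure)

  # doubling draws moves mid-range SDs by < 5%
  b4 <- suppressWarnings(
    mc_linear_bounds(sample_coefficients(p, 1000, seed = 3), levels = 32))
  mid <- 10:25
  expect_lt(max(abs(b4$sd_exposure[mid] - b1$sd_exposure[mid]) /
                  b1$sd_exposure[mid]), 0.05)
})

test_that("bezier-route bounds separate the two uncertainty axes", {
  fx <- oecf_fixture("canon40d_red")
  s <- sample_coefficients(fx$bezier, 300, seed = 7)
  b <- suppressWarnings(mc_linear_bounds(s, levels = 64))
  expect_equal(b$method, "bezier_lut")
  expect_s3_class(b$response_sd, "data.frame")
  expect_equal(nrow(b$response_sd), 64L)
  tab <- sd_curve(b)
  expect_named(tab, c("level", "sd_exposure", "sd_response"))
  expect_equal(nrow(tab), 64L)
})

test_that("sd_curve emits one row per level and flags the saturation peak", {
  p <- red_params()
  b <- suppressWarnings(
    mc_linear_bounds(sample_coefficients(p, 500, seed = 13), levels = 128))
  tab <- sd_curve(b)
  expect_equal(nrow(tab), 128L)
  expect_equal(tab$level[128], 1)
  expect_equal(which.max(tab$sd_exposure), 128L)
})

test_that("bootstrap_bezier produces CIs with the expected limits", {
  # noiseless data on an exact curve: CI half-widths collapse
  cv <- known_curve()
  dn <- curve_dataset(cv, 40)
  bb <- bootstrap_bezier(dn, n_boot = 60, subset_size = 20, seed = 9)
  expect_lt(max(bb$ci_x, bb$ci_y), 1e-6)

  # subset_size = dataset size: all replicates identical, CIs zero
  bb2 <- bootstrap_bezier(dn, n_boot = 20, subset_size = 40, seed = 9)
  expect_equal(max(bb2$ci_x, bb2$ci_y), 0)

  # reproducibility under a fixed seed
  p <- red_params()
  truth <- synthetic_truth(p, noise_sd = 2, seed = 3)
  ds <- simulate_oecf(truth)
  ds$e_max <- invert_biexp(p, p$g_max)
  dsn <- filter_p_min(normalise_dataset(ds), 31 / 255)
  b1 <- bootstrap_bezier(dsn, n_boot = 40, subset_size = 32, seed = 17)
  b2 <- bootstrap_bezier(dsn, n_boot = 40, subset_size = 32, seed = 17)
  expect_identical(b1$ci_x, b2$ci_x)
  # interior control points scatter under noise (endpoints stay anchored)
  expect_true(all(b1$ci_y[2:3] > 0))

  # oversized subsets refuse
  expect_error(bootstrap_bezier(dn, 10, subset_size = 41, seed = 1),
               "exceeds")
})

test_that("bootstrap CI widths shrink as subsets approach the dataset", {
  p <- red_params()
  truth <- synthetic_truth(p, noise_sd = 2, seed = 8)
  ds <- simulate_oecf(truth)
  ds$e_max <- invert_biexp(p, p$g_max)
  dsn <- filter_p_min(normalise_dataset(ds), 31 / 255)
  n <- nrow(dsn$points)
  w16 <- bootstrap_bezier(dsn, n_boot = 80, subset_size = 16, seed = 2)
  w_all <- bootstrap_bezier(dsn, n_boot = 80, subset_size = n, seed = 2)
  expect_lt(mean(c(w_all$ci_x, w_all$ci_y)),
            mean(c(w16$ci_x, w16$ci_y)))
})
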