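test_that("eval_bezier interpolates endpoints and matches de Casteljau", {
  cv <- known_curve()
  expect_equal(eval_bezier(cv, 0), cbind(x = 0, y = 0))
  expect_equal(eval_bezier(cv, 1), cbind(x = 1, y = 1))

  # midpoint against a de Casteljau subdivision oracle
  decasteljau <- function(px, py, t) {
    for (k in 1:3) {
      px <- (1 - t) * head(px, -1) + t * tail(px, -1)
      py <- (1 - t) * head(py, -1) + t * tail(py, -1)
    }
    c(px, py)
  }
  set.seed(31)
  for (i in 1:10) {
    px <- sort(runif(4)); py <- sort(runif(4))
    cv2 <- bezier_curve(px, py)
    t <- runif(1)
    expect_equal(as.numeric(eval_bezier(cv2, t)),
                 decasteljau(px, py, t), tolerance = 1e-12)
    # closed form at t = 0.5: (P0 + 3P1 + 3P2 + P3)/8
    expect_equal(as.numeric(eval_bezier(cv2, 0.5)),
                 c((px[1] + 3 * px[2] + 3 * px[3] + px[4]) / 8,
                   (py[1] + 3 * py[2] + 3 * py[3] + py[4]) / 8))
  }
  expect_error(eval_bezier(cv, 1.2), "\\[0, 1\\]")
})

test_that("evaluated points stay inside the control-point convex hull", {
  set.seed(32)
  for (i in 1:10) {
    px <- runif(4); py <- runif(4)
    cv <- bezier_curve(px, py)
    xy <- eval_bezier(cv, runif(100))
    # axis-aligned bounding box of the hull suffices as a necessary check
    expect_true(all(xy[, 1] >= min(px) - 1e-12 & xy[, 1] <= max(px) + 1e-12))
    expect_true(all(xy[, 2] >= min(py) - 1e-12 & xy[, 2] <= max(py) + 1e-12))
  }
})

test_that("fit_bezier recovers a known generator and pins endpoints", {
  cv <- known_curve()
  dn <- curve_dataset(cv, 20)
  fit <- fit_bezier(dn)  # default: one parameter-correction pass
  expect_lt(max(abs(fit$px - cv$px), abs(fit$py - cv$py)), 1e-6)
  # endpoints pinned to extreme data points
  pts <- dn$points[order(dn$points$exposure), ]
  expect_equal(fit$px[1], pts$exposure[1])
  expect_equal(fit$py[4], pts$response[nrow(pts)])
  # the correction pass improves on the plain chord-length fit
  fit0 <- fit_bezier(dn, correction_passes = 0)
  expect_lt(attr(fit, "sse"), attr(fit0, "sse") + 1e-15)
})

test_that("collinear data fit to the straight chord", {
  x <- seq(0, 1, length.out = 12)
  dn <- oecf_dataset(x, x, normalised = TRUE, g_max = 0.98)
  fit <- fit_bezier(dn)
  xy <- eval_bezier(fit, seq(0, 1, 0.01))
  expect_lt(max(abs(xy[, 2] - xy[, 1])), 1e-9)
})

test_that("fit_bezier enforces its preconditions", {
  raw <- oecf_dataset(c(1, 2, 3, 4, 5) / 100, c(10, 60, 120, 180, 240))
  expect_error(fit_bezier(raw), "normalised")
  small <- oecf_dataset(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3),
                        normalised = TRUE)
  expect_error(fit_bezier(small), "at least 4")
})

test_that("fit_bezier_segments partitions with shared anchors", {
  cv <- known_curve()
  dn <- curve_dataset(cv, 30)
  one <- fit_bezier_segments(dn, 1)
  expect_length(one, 1L)
  expect_equal(one[[1]]$px, fit_bezier(dn)$px)

  segs <- fit_bezier_segments(dn, 3)
  expect_length(segs, 3L)
  # C0 continuity: each segment starts where the previous one ends
  for (k in 2:3) {
    expect_equal(segs[[k]]$px[1], segs[[k - 1]]$px[4])
    expect_equal(segs[[k]]$py[1], segs[[k - 1]]$py[4])
  }
  expect_error(fit_bezier_segments(dn, 20), "too few points")
})

test_that("piecewise data from two generators is recovered segment-wise", {
  c1 <- bezier_curve(c(0, 0.05, 0.15, 0.3), c(0, 0.2, 0.5, 0.6))
  c2 <- bezier_curve(c(0.3, 0.5, 0.8, 1), c(0.6, 0.7, 0.9, 1))
  xy1 <- eval_bezier(c1, seq(0, 1, length.out = 10))
  xy2 <- eval_bezier(c2, seq(0, 1, length.out = 10)[-1])
  dn <- oecf_dataset(c(xy1[, 1], xy2[, 1]), c(xy1[, 2], xy2[, 2]),
                     normalised = TRUE, g_max = 0.98)
  segs <- fit_bezier_segments(dn, 2, correction_passes = 3)
  expect_lt(max(abs(segs[[1]]$px - c1$px), abs(segs[[1]]$py - c1$py)), 1e-5)
  expect_lt(max(abs(segs[[2]]$px - c2$px), abs(segs[[2]]$py - c2$py)), 1e-5)
})

test_that("build_lut swaps axes and honours its contracts", {
  cv <- known_curve()
  lut <- build_lut(cv)
  expect_equal(nrow(lut), 256L)
  expect_equal(lut$response[1], cv$py[1])
  expect_equal(lut$exposure[1], cv$px[1])
  expect_equal(lut$response[256], cv$py[4])
  expect_true(all(diff(lut$response) > 0))

  # a straight-line curve gives the identity map
  line <- bezier_curve(c(0, 1, 2, 3) / 3, c(0, 1, 2, 3) / 3)
  li <- build_lut(line)
  expect_lt(max(abs(li$response - li$exposure)), 1e-12)

  # non-monotone y refuses
  wiggle <- bezier_curve(c(0, 0.3, 0.7, 1), c(0, 1.8, -0.8, 1))
  expect_error(build_lut(wiggle), "monotone")
})

test_that("lut_lookup interpolates linearly and flags saturation", {
  cv <- known_curve()
  lut <- build_lut(cv)
  # stored node returns exactly
  expect_equal(as.numeric(lut_lookup(lut, lut$response[100])),
               lut$exposure[100])
  # midpoint between adjacent nodes returns the mean of their exposures
  mid <- (lut$response[10] + lut$response[11]) / 2
  expect_equal(as.numeric(lut_lookup(lut, mid)),
               (lut$exposure[10] + lut$exposure[11]) / 2)
  # below range errors, above range clamps with a saturation flag
  expect_error(lut_lookup(lut, -0.01), "not linearisable")
  top <- lut_lookup(lut, 1.5)
  expect_equal(as.numeric(top), lut$exposure[256])
  expect_true(attr(top, "saturated"))
})

test_that("LUT inversion is consistent with direct root-finding inversion", {
  cv <- known_curve()
  lut <- build_lut(cv, 256)
  p_grid <- seq(cv$py[1] + 1e-6, cv$py[4] - 1e-6, length.out = 200)
  # oracle: solve y(t) = p by bisection, then read x(t)
  oracle <- vapply(p_grid, function(p) {
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (eval_bezier(cv, mid)[, 2] < p) lo <- mid else hi <- mid
    }
    eval_bezier(cv, (lo + hi) / 2)[, 1]
  }, numeric(1))
  got <- lut_lookup(lut, p_grid)
  expect_lt(max(abs(got - oracle)), 1 / (2 * 256))

  # denser LUTs reduce the round-trip error
  err_for <- function(n) {
    lutn <- build_lut(cv, n)
    tt <- seq(0.01, 0.99, length.out = 500)
    xy <- eval_bezier(cv, tt)
    max(abs(lut_lookup(lutn, xy[, 2]) - xy[, 1]))
  }
  expect_lt(err_for(4096), err_for(256))
})

test_that("bezier JSON and LUT CSV round trip", {
  fx <- oecf_fixture("canon40d_green")
  tf <- tempfile(fileext = ".json")
  write_bezier_json(fx$bezier, tf)
  back <- read_bezier_json(tf)
  expect_equal(back$px, fx$bezier$px)
  expect_equal(back$ci_y, fx$bezier$ci_y)

  # the published green-channel P1 x sits below P0 x, so x(t) is
  # (verbatim-fixture) non-monotone and build_lut warns
  lut <- suppressWarnings(build_lut(fx$bezier))
  tc <- tempfile(fileext = ".csv")
  write_lut_csv(lut, tc)
  back2 <- read_lut_csv(tc)
  expect_equal(back2$exposure, lut$exposure, tolerance = 1e-12)
})
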