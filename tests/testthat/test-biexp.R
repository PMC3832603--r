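test_that("eval_biexp satisfies the constrained-model identities", {
  p <- red_params()
  # f(0) = 0 exactly under a = b + d
  expect_identical(eval_biexp(p, 0), 0)
  # asymptote a at very large exposure
  expect_equal(eval_biexp(p, 100), p$a, tolerance = 1e-12)
  # term-by-term oracle at a fixed exposure (published red coefficients)
  E <- 0.001
  expect_equal(eval_biexp(p, E),
               260 - 103 * exp(-3640 * E) - 157 * exp(-981 * E))
  expect_error(eval_biexp(p, -1), ">= 0")
})

test_that("biexp derivative is strictly positive for random positive draws", {
  set.seed(21)
  for (i in 1:20) {
    p <- biexp_params(b = runif(1, 1, 200), c = runif(1, 100, 8000),
                      d = runif(1, 1, 200), g = runif(1, 50, 2000))
    E <- sort(runif(50, 0, 0.02))
    d1 <- p$b * p$c * exp(-p$c * E) + p$d * p$g * exp(-p$g * E)
    expect_true(all(d1 > 0))
    # strictly increasing mathematically; allow exact ties where the
    # curve has numerically saturated
    expect_true(all(diff(eval_biexp(p, E)) >= 0))
  }
})

test_that("invert_biexp is the functional inverse", {
  p <- red_params()
  expect_equal(invert_biexp(p, 0), 0)
  e_max <- invert_biexp(p, p$g_max)
  E <- seq(0, e_max, length.out = 100)
  back <- invert_biexp(p, eval_biexp(p, E))
  expect_true(all(abs(back - E) <= 1e-8 * e_max))
  # p = g_max coincides with the e_max estimate from the fit route
  # (same root by construction, on continuous noiseless data)
  Eg <- make_ladder(e_max, "nd", ods = seq(0, 1.6, by = 0.1))$exposure
  ds <- oecf_dataset(Eg, eval_biexp(p, Eg))
  expect_equal(invert_biexp(p, 250), estimate_e_max(ds, "biexp_fit"),
               tolerance = 1e-6)
  # responses at or above the asymptote have no solution
  expect_error(invert_biexp(p, p$a), "asymptote")
  expect_error(invert_biexp(p, -2), ">= 0")
})

test_that("fit_biexp recovers noiseless truth and reports CIs", {
  p <- red_params()
  ladder <- make_ladder(invert_biexp(p, 250), "nd",
                        ods = seq(0, 1.6, by = 0.1))
  E <- ladder$exposure
  ds <- oecf_dataset(E, eval_biexp(p, E))
  fit <- fit_biexp(ds)
  expect_equal(fit$b, p$b, tolerance = 1e-4)
  expect_equal(fit$c, p$c, tolerance = 1e-4)
  expect_equal(fit$d, p$d, tolerance = 1e-4)
  expect_equal(fit$g, p$g, tolerance = 1e-4)
  expect_equal(fit$a, fit$b + fit$d)
  expect_true(all(fit$ci_halfwidth >= 0))
  expect_true(fit$c >= fit$g)  # identifiability tie-break
  expect_lt(attr(fit, "sse"), 1e-12)
})

test_that("fit_biexp handles the single-exponential degenerate case", {
  # c = g: the model collapses to (b + d) * (1 - exp(-rate E))
  amp <- 240; rate <- 900
  E <- seq(0, 1.6, by = 0.1) / 400
  resp <- amp * (1 - exp(-rate * E))
  fit <- fit_biexp(oecf_dataset(E, resp))
  # closed-form oracle: total amplitude and common rate
  expect_equal(fit$b + fit$d, amp, tolerance = 1e-3)
  pred <- eval_biexp(fit, E)
  expect_equal(pred, resp, tolerance = 1e-6)
})

test_that("fit_biexp refuses underdetermined input", {
  expect_error(fit_biexp(oecf_dataset(1:5 / 100, c(10, 50, 90, 120, 150))),
               "at least 6")
})

test_that("fit_biexp works on the normalised scale too", {
  p <- red_params()
  ds <- noiseless_ladder(p)
  ds$e_max <- invert_biexp(p, 250)
  dn <- normalise_dataset(ds)
  fit_n <- fit_biexp(dn)
  expect_equal(fit_n$scale, "normalised")
  # normalised asymptote should approximate a / 255
  expect_equal(fit_n$a, p$a / 255, tolerance = 0.05)
})

test_that("linearise_response maps the boundary contract", {
  p <- red_params()
  e_max <- invert_biexp(p, p$g_max)
  p$e_max <- e_max
  r0 <- linearise_response(p, 0)
  expect_equal(r0$exposure, 0)
  expect_false(r0$saturated)
  rtop <- linearise_response(p, 250)
  expect_equal(rtop$exposure, e_max)
  expect_true(rtop$saturated)
  r255 <- linearise_response(p, 255)
  expect_equal(r255$exposure, e_max)
  expect_true(r255$saturated)
  # mid-range raw level recovers its generating exposure within half a level
  E_true <- e_max / 3
  praw <- round(eval_biexp(p, E_true))
  rmid <- linearise_response(p, praw)
  slope <- p$b * p$c * exp(-p$c * E_true) + p$d * p$g * exp(-p$g * E_true)
  expect_lt(abs(rmid$exposure - E_true), 0.6 / slope)
})

test_that("biexp parameter JSON round trips", {
  p <- red_params()
  p$e_max <- 0.0122
  tf <- tempfile(fileext = ".json")
  write_biexp_json(p, tf)
  back <- read_biexp_json(tf)
  expect_equal(back$b, p$b)
  expect_equal(back$c, p$c)
  expect_equal(back$ci_halfwidth, p$ci_halfwidth)
  expect_equal(back$e_max, p$e_max)
  expect_equal(back$scale, p$scale)
})

test_that("all four published fixtures satisfy a > g_max", {
  for (nm in oecf_fixtures()) {
    fx <- oecf_fixture(nm)
    expect_gt(fx$biexp$a, fx$g_max)
  }
})
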