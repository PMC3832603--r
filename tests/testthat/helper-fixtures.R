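# Shared helpers: small constructors used across test files.

# the published red-channel gain, the default ground truth for simulations
red_params <- function() oecf_fixture("canon40d_red")$biexp

# a well-behaved monotone Bezier curve used as a generator in fit tests
known_curve <- function() {
  bezier_curve(c(0, 0.1, 0.5, 1), c(0, 0.4, 0.8, 1))
}

# exact samples from a curve wrapped as a normalised dataset
curve_dataset <- function(curve, n = 20) {
  xy <- eval_bezier(curve, seq(0, 1, length.out = n))
  oecf_dataset(xy[, 1], xy[, 2], normalised = TRUE, g_max = 0.98)
}

# noiseless synthetic ladder dataset from a known biexponential gain
noiseless_ladder <- function(params = red_params(), n_points = 96) {
  simulate_oecf(synthetic_truth(params, noise_sd = 0, seed = 1),
                n_points = n_points)
}

# brute-force Wilcoxon signed-rank oracle: enumerate all sign assignments
wsr_enumerate <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.numeric(signs %*% r)
  w_min <- pmin(w_plus, sum(r) - w_plus)
  list(W = w_obs, p = mean(w_min <= w_obs + 1e-9))
}
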