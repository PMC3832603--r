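# Monte-Carlo propagation of fitted-parameter uncertainty to recovered
# linear responses, and bootstrap confidence intervals for Bezier control
# points.

# evaluate expr with a temporarily seeded RNG, restoring global state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw coefficient samples from fitted-parameter uncertainty
#'
#' Draws each coefficient independently from a Gaussian centred on its
#' fitted value with standard deviation `CI half-width / 1.96` (the normal
#' 95% quantile).  For the biexponential model, draws violating positivity
#' are redrawn (the redraw count is recorded) and the asymptote `a` is
#' recomputed per draw as `b + d` so the `f(0) = 0` constraint holds for
#' every draw.
#'
#' @param params A fitted `biexp_params` or `bezier_curve` carrying 95% CI
#'   half-widths.
#' @param n_draws Number of draws; default 1000.
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `param_samples`: a list with `draws` (matrix
#'   `n_draws x k`, labelled columns), `method`, `source`, `seed` and
#'   `n_redrawn`.
#' @export
sample_coefficients <- function(params, n_draws = 1000L, seed = 1L) {
  n_draws <- as.integer(n_draws)
  if (inherits(params, "biexp_params")) {
    sds <- params$ci_halfwidth / 1.96
    mu <- c(b = params$b, c = params$c, d = params$d, g = params$g)
    n_redrawn <- 0L
    draws <- .with_seed(seed, {
      m <- sapply(names(mu), function(k) {
        stats::rnorm(n_draws, mu[k], sds[k])
      })
      bad <- which(rowSums(m <= 0) > 0)
      while (length(bad) > 0) {
        n_redrawn <<- n_redrawn + length(bad)
        m[bad, ] <- sapply(names(mu), function(k) {
          stats::rnorm(length(bad), mu[k], sds[k])
        })
        bad <- which(rowSums(m <= 0) > 0)
      }
      m
    })
    colnames(draws) <- names(mu)
    structure(list(draws = draws, method = "biexp", source = params,
                   seed = seed, n_redrawn = n_redrawn),
              class = "param_samples")
  } else if (inherits(params, "bezier_curve")) {
    mu <- c(params$px, params$py)
    sds <- c(params$ci_x, params$ci_y) / 1.96
    draws <- .with_seed(seed, {
      sapply(seq_along(mu), function(k) {
        stats::rnorm(n_draws, mu[k], sds[k])
      })
    })
    colnames(draws) <- c(paste0("x", 0:3), paste0("y", 0:3))
    structure(list(draws = draws, method = "bezier_lut", source = params,
                   seed = seed, n_redrawn = 0L),
              class = "param_samples")
  } else {
    stop("`params` must be a biexp_params or bezier_curve", call. = FALSE)
  }
}

# vectorised inversion of one biexponential draw at many levels:
# monotone-grid interpolation start + Newton refinement
.invert_draw <- function(b, cc, d, g, levels, e_top) {
  grid <- seq(0, e_top, length.out = 512)
  fg <- b * (1 - exp(-cc * grid)) + d * (1 - exp(-g * grid))
  E <- stats::approx(fg, grid, xout = levels, ties = "ordered", rule = 2)$y
  for (k in 1:4) {
    fE <- b * (1 - exp(-cc * E)) + d * (1 - exp(-g * E))
    d1 <- b * cc * exp(-cc * E) + d * g * exp(-g * E)
    E <- pmax(E - (fE - levels) / d1, 0)
  }
  E
}

#' Monte-Carlo confidence bounds for recovered linear responses
#'
#' For each of `levels` response levels spanning the valid range, inverts
#' every coefficient draw and records the mean and standard deviation of
#' the recovered (normalised) exposure.  Biexponential levels span
#' `[0, g_max]`; Bezier levels span the curve's response range
#' (`p_min`-equivalent up to the maximum).  Draws that do not define an
#' invertible curve over the requested range (biexponential asymptote
#' below the top level; non-monotone Bezier response) are dropped and
#' counted; a warning is raised when more than 5% are dropped.  For the
#' Bezier route, per-parameter-value spread of the curve itself is also
#' recorded (`response_sd`), separating response-axis from exposure-axis
#' uncertainty.
#'
#' @param samples A `param_samples` from [sample_coefficients()].
#' @param levels Number of response levels; default 256.
#' @return An object of class `mc_bounds`: `levels` (response values),
#'   `mean_exposure`, `sd_exposure`, `n_draws`, `n_dropped`, `seed`,
#'   `method`, `g_max`, and for the Bezier route a `response_sd` data
#'   frame (columns `t`, `mean_x`, `sd_x`, `mean_y`, `sd_y`).
#' @export
mc_linear_bounds <- function(samples, levels = 256L) {
  stopifnot(inherits(samples, "param_samples"))
  n_levels <- as.integer(levels)
  draws <- samples$draws
  n <- nrow(draws)
  if (samples$method == "biexp") {
    src <- samples$source
    lev <- seq(0, src$g_max, length.out = n_levels)
    top <- max(lev)
    a_dr <- draws[, "b"] + draws[, "d"]
    ok <- a_dr > top * (1 + 1e-9)
    n_drop <- sum(!ok)
    if (n_drop == n) {
      stop("no Monte-Carlo draw defines an invertible curve up to g_max",
           call. = FALSE)
    }
    if (n_drop > 0.05 * n) {
      warning(sprintf(
        "%d of %d draws (%.1f%%) have asymptote below g_max and were dropped",
        n_drop, n, 100 * n_drop / n))
    }
    kept <- which(ok)
    mat <- matrix(NA_real_, length(kept), n_levels)
    for (i in seq_along(kept)) {
      r <- draws[kept[i], ]
      # per-draw top exposure from bracketed root finding
      p <- biexp_params(r["b"], r["c"], r["d"], r["g"], g_max = src$g_max)
      e_top <- .invert_biexp_one(p, top)
      mat[i, ] <- .invert_draw(r["b"], r["c"], r["d"], r["g"], lev, e_top)
    }
    # normalise exposures by the fitted curve's e_max so bounds are on the
    # same [0, 1] exposure scale the curves are compared on
    e_ref <- .invert_biexp_one(src, top)
    mat <- mat / e_ref
    structure(list(levels = lev,
                   mean_exposure = colMeans(mat),
                   sd_exposure = apply(mat, 2, stats::sd),
                   n_draws = n, n_dropped = n_drop, seed = samples$seed,
                   method = "biexp", g_max = src$g_max),
              class = "mc_bounds")
  } else {
    src <- samples$source
    lev <- seq(src$py[1], src$py[4], length.out = n_levels)
    tt <- seq(0, 1, length.out = n_levels)
    B <- .bernstein3(tt)
    xs <- matrix(NA_real_, n, n_levels)
    ys <- matrix(NA_real_, n, n_levels)
    expo <- matrix(NA_real_, n, n_levels)
    ok <- logical(n)
    for (i in seq_len(n)) {
      px <- draws[i, 1:4]; py <- draws[i, 5:8]
      x <- as.numeric(B %*% px); y <- as.numeric(B %*% py)
      if (any(diff(y) <= 0)) next
      ok[i] <- TRUE
      xs[i, ] <- x; ys[i, ] <- y
      expo[i, ] <- stats::approx(y, x, xout = lev, rule = 2,
                                 ties = "ordered")$y
    }
    n_drop <- sum(!ok)
    if (n_drop == n) {
      stop("no Monte-Carlo draw defines a monotone Bezier response",
           call. = FALSE)
    }
    if (n_drop > 0.05 * n) {
      warning(sprintf(
        "%d of %d draws (%.1f%%) gave non-monotone curves and were dropped",
        n_drop, n, 100 * n_drop / n))
    }
    expo <- expo[ok, , drop = FALSE]
    structure(list(levels = lev,
                   mean_exposure = colMeans(expo),
                   sd_exposure = apply(expo, 2, stats::sd),
                   n_draws = n, n_dropped = n_drop, seed = samples$seed,
                   method = "bezier_lut", g_max = NULL,
                   response_sd = data.frame(
                     t = tt,
                     mean_x = colMeans(xs[ok, , drop = FALSE]),
                     sd_x = apply(xs[ok, , drop = FALSE], 2, stats::sd),
                     mean_y = colMeans(ys[ok, , drop = FALSE]),
                     sd_y = apply(ys[ok, , drop = FALSE], 2, stats::sd))),
              class = "mc_bounds")
  }
}

#' @export
print.mc_bounds <- function(x, ...) {
  cat(sprintf(
    "<mc_bounds> method=%s, %d levels, %d draws (%d dropped), seed=%d\n",
    x$method, length(x$levels), x$n_draws, x$n_dropped, x$seed))
  invisible(x)
}

#' Standard deviation of recovered responses versus level
#'
#' Tabulates the Monte-Carlo standard deviation of the recovered
#' (normalised) exposure as a function of the relative response level
#' `p / g_max`, the usual diagnostic for choosing a working `g_max`: the
#' SD grows with level and peaks at the top of the range, where the OECF
#' saturates.  For the Bezier route the response-axis SD is included as a
#' second column.
#'
#' @param bounds An `mc_bounds` object.
#' @return A data frame with columns `level` (relative response),
#'   `sd_exposure`, and for the Bezier route `sd_response`.
#' @export
sd_curve <- function(bounds) {
  stopifnot(inherits(bounds, "mc_bounds"))
  if (bounds$method == "biexp") {
    data.frame(level = bounds$levels / bounds$g_max,
               sd_exposure = bounds$sd_exposure)
  } else {
    top <- bounds$levels[length(bounds$levels)]
    sd_resp <- stats::approx(bounds$response_sd$mean_y,
                             bounds$response_sd$sd_y,
                             xout = bounds$levels, rule = 2,
                             ties = "ordered")$y
    data.frame(level = bounds$levels / top,
               sd_exposure = bounds$sd_exposure,
               sd_response = sd_resp)
  }
}

#' Bootstrap confidence intervals for Bezier control points
#'
#' Refits the cubic Bezier curve on `n_boot` random subsets of
#' `subset_size` points (drawn without replacement by default) and attaches
#' 95% CI half-widths (`1.96 * SD` across replicates) for every
#' control-point coordinate to the full-data fit.
#'
#' With `anchor = "global"` (the default) every subset includes the two
#' extreme data points of the full OECF, so all replicate fits share the
#' pinned endpoints and the CIs measure the sampling spread of the curve
#' itself; on noiseless data exactly on a cubic Bezier the CIs collapse to
#' zero.  `anchor = "subset"` draws fully random subsets, whose own
#' extremes pin each replicate's endpoints; this also propagates the
#' spread of the endpoint points into the `P0`/`P3` intervals.
#'
#' @param oecf_norm A normalised, `p_min`-filtered `oecf_dataset`.
#' @param n_boot Number of bootstrap replicates; default 1000.
#' @param subset_size Points per replicate; default 32.
#' @param seed Integer seed.
#' @param replace Draw subsets with replacement instead (default `FALSE`).
#' @param anchor `"global"` or `"subset"`; see Details.
#' @return The full-data `bezier_curve` with `ci_x` / `ci_y` filled in and
#'   attributes `boot_mean_px`, `boot_mean_py`, `n_boot_ok`.
#' @export
bootstrap_bezier <- function(oecf_norm, n_boot = 1000L, subset_size = 32L,
                             seed = 1L, replace = FALSE,
                             anchor = c("global", "subset")) {
  stopifnot(inherits(oecf_norm, "oecf_dataset"))
  anchor <- match.arg(anchor)
  n <- nrow(oecf_norm$points)
  if (subset_size > n && !replace) {
    stop("`subset_size` (", subset_size, ") exceeds the dataset size (",
         n, ")", call. = FALSE)
  }
  base <- suppressWarnings(fit_bezier(oecf_norm))
  px <- matrix(NA_real_, n_boot, 4)
  py <- matrix(NA_real_, n_boot, 4)
  ends <- c(which.min(oecf_norm$points$exposure),
            which.max(oecf_norm$points$exposure))
  idx_all <- .with_seed(seed, {
    lapply(seq_len(n_boot), function(i) {
      if (anchor == "global" && subset_size > 2L) {
        pool <- setdiff(seq_len(n), ends)
        c(ends, sample(pool, min(subset_size - 2L, length(pool)),
                       replace = replace))
      } else {
        sample.int(n, subset_size, replace = replace)
      }
    })
  })
  for (i in seq_len(n_boot)) {
    ds <- oecf_norm
    ds$points <- oecf_norm$points[idx_all[[i]], , drop = FALSE]
    fit <- tryCatch(suppressWarnings(fit_bezier(ds)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    px[i, ] <- fit$px; py[i, ] <- fit$py
  }
  ok <- stats::complete.cases(px)
  if (sum(ok) < 2L) {
    stop("bootstrap produced fewer than 2 successful fits", call. = FALSE)
  }
  out <- base
  out$ci_x <- 1.96 * apply(px[ok, , drop = FALSE], 2, stats::sd)
  out$ci_y <- 1.96 * apply(py[ok, , drop = FALSE], 2, stats::sd)
  attr(out, "boot_mean_px") <- colMeans(px[ok, , drop = FALSE])
  attr(out, "boot_mean_py") <- colMeans(py[ok, , drop = FALSE])
  attr(out, "n_boot_ok") <- sum(ok)
  attr(out, "seed") <- seed
  out
}
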