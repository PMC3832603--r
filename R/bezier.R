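# Cubic Bezier OECF fitting: Bernstein-basis evaluation, pinned-endpoint
# least squares with chord-length parameterisation, multi-segment variant,
# and LUT construction / lookup for inversion.

#' Cubic Bezier curve on normalised OECF axes
#'
#' Holds the four control points `P0..P3` of a cubic Bezier curve fitted to
#' a normalised OECF: `x` is normalised exposure, `y` normalised response.
#' `P0` and `P3` coincide with the minimum and maximum data points, so
#' `P0`'s y-coordinate is the (normalised) minimum linearisable response
#' `p_min`.  Monotonicity of `x(t)` and `y(t)` is validated numerically at
#' 1024 samples, not imposed: a non-monotone curve carries a warning flag.
#'
#' @param px,py Numeric vectors of length 4: control-point coordinates.
#' @param ci_x,ci_y 95% CI half-widths per coordinate (default 0).
#' @return An object of class `bezier_curve`.
#' @export
bezier_curve <- function(px, py, ci_x = rep(0, 4), ci_y = rep(0, 4)) {
  if (length(px) != 4L || length(py) != 4L) {
    stop("a cubic Bezier curve needs exactly 4 control points",
         call. = FALSE)
  }
  if (any(!is.finite(c(px, py)))) {
    stop("control-point coordinates must be finite", call. = FALSE)
  }
  if (any(c(ci_x, ci_y) < 0)) stop("CI half-widths must be >= 0",
                                   call. = FALSE)
  obj <- structure(list(px = as.numeric(px), py = as.numeric(py),
                        ci_x = as.numeric(ci_x), ci_y = as.numeric(ci_y),
                        p_min = py[1]),
                   class = "bezier_curve")
  tt <- seq(0, 1, length.out = 1024)
  xy <- eval_bezier(obj, tt)
  obj$monotone_x <- all(diff(xy[, 1]) > 0)
  obj$monotone_y <- all(diff(xy[, 2]) > 0)
  obj
}

#' @export
print.bezier_curve <- function(x, ...) {
  cat("<bezier_curve>\n")
  for (i in 1:4) {
    cat(sprintf("  P%d = (%.6g, %.6g)  CI (%.3g, %.3g)\n", i - 1,
                x$px[i], x$py[i], x$ci_x[i], x$ci_y[i]))
  }
  if (!x$monotone_x) cat("  warning: x(t) is not monotone increasing\n")
  invisible(x)
}

# Bernstein basis matrix for cubic curves: rows = t values, cols = B0..B3
.bernstein3 <- function(t) {
  cbind((1 - t)^3, 3 * (1 - t)^2 * t, 3 * (1 - t) * t^2, t^3)
}

#' Evaluate a cubic Bezier curve
#'
#' Computes `B(t) = sum_i C(3,i) (1-t)^(3-i) t^i P_i` componentwise; the
#' curve interpolates its endpoints (`B(0) = P0`, `B(1) = P3`).
#'
#' @param curve A `bezier_curve`.
#' @param t Numeric vector of parameter values in `[0, 1]`.
#' @return A two-column matrix of `(x, y)` coordinates.
#' @export
eval_bezier <- function(curve, t) {
  stopifnot(inherits(curve, "bezier_curve"))
  if (any(t < 0 | t > 1)) {
    stop("Bezier parameter t must lie in [0, 1]", call. = FALSE)
  }
  B <- .bernstein3(t)
  cbind(x = as.numeric(B %*% curve$px), y = as.numeric(B %*% curve$py))
}

# chord-length parameter values for ordered data points
.chord_param <- function(x, y) {
  d <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  if (d[length(d)] == 0) return(seq(0, 1, length.out = length(x)))
  d / d[length(d)]
}

# One parameter-correction pass: joint Gauss-Newton refinement of the
# interior control points and the per-point parameter values (endpoints
# stay pinned, t_1 = 0 and t_n = 1 stay fixed).  Simple alternation of
# foot-point projection and linear refitting stalls because the geometric
# residual barely identifies the parameterisation; the joint update
# converges quadratically on exact data.  Damped by step halving so noisy
# data cannot diverge.
.gauss_newton_pass <- function(p0, p3, x, y, t, cx, cy,
                               max_iter = 25L, tol = 1e-13) {
  n <- length(x)
  free_t <- if (n > 2L) 2:(n - 1L) else integer()
  theta <- c(cx, cy, t[free_t])
  resid <- function(theta) {
    tt <- t
    tt[free_t] <- theta[-(1:4)]
    B <- .bernstein3(tt)
    px <- c(p0[1], theta[1:2], p3[1]); py <- c(p0[2], theta[3:4], p3[2])
    c(as.numeric(B %*% px) - x, as.numeric(B %*% py) - y)
  }
  r <- resid(theta)
  rss <- sum(r^2)
  for (iter in seq_len(max_iter)) {
    tt <- t
    tt[free_t] <- theta[-(1:4)]
    B <- .bernstein3(tt)
    px <- c(p0[1], theta[1:2], p3[1]); py <- c(p0[2], theta[3:4], p3[2])
    # analytic Jacobian: control-point block is the Bernstein design,
    # parameter block is the curve tangent (diagonal across points)
    D <- cbind((1 - tt)^2, 2 * (1 - tt) * tt, tt^2)
    d1x <- as.numeric(D %*% (3 * diff(px)))
    d1y <- as.numeric(D %*% (3 * diff(py)))
    J <- matrix(0, 2 * n, length(theta))
    J[1:n, 1:2] <- B[, 2:3]
    J[(n + 1):(2 * n), 3:4] <- B[, 2:3]
    for (k in seq_along(free_t)) {
      j <- free_t[k]
      J[j, 4 + k] <- d1x[j]
      J[n + j, 4 + k] <- d1y[j]
    }
    step <- tryCatch(qr.coef(qr(J), -r), error = function(e) NULL)
    if (is.null(step)) break
    step[is.na(step)] <- 0
    lambda <- 1
    improved <- FALSE
    for (h in 1:10) {
      cand <- theta + lambda * step
      cand[-(1:4)] <- pmin(pmax(cand[-(1:4)], 0), 1)
      rc <- resid(cand)
      if (sum(rc^2) <= rss) {
        theta <- cand; r <- rc
        improved <- TRUE
        new_rss <- sum(rc^2)
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    if (rss - new_rss <= tol * max(rss, 1e-300)) { rss <- new_rss; break }
    rss <- new_rss
  }
  tt <- t
  tt[free_t] <- theta[-(1:4)]
  list(cx = theta[1:2], cy = theta[3:4], t = tt)
}

#' Fit a cubic Bezier curve to a normalised OECF
#'
#' Implements pinned-endpoint cubic Bezier least squares: `P0` and `P3`
#' are fixed at the minimum- and maximum-exposure data points, each data
#' point is assigned a chord-length parameter value, and the two interior
#' control points are solved coordinate-wise by linear least squares on
#' the Bernstein design.  By default one parameter-correction pass
#' follows: a damped Gauss-Newton refinement of the interior control
#' points and the parameter values jointly, which recovers exact
#' generating curves to machine precision and reduces the bias that
#' chord-length parameterisation leaves on unevenly spaced exposure
#' ladders.
#'
#' @param oecf_norm A normalised `oecf_dataset` (see
#'   [normalise_dataset()]), already `p_min`-filtered, with >= 4 points.
#' @param correction_passes Number of parameter-correction passes (0 fits
#'   with fixed chord-length parameters only).
#' @return A `bezier_curve` with an `sse` attribute (residual sum of
#'   squares over both coordinates).  A warning is emitted when the fitted
#'   `x(t)` is not monotone.
#' @export
fit_bezier <- function(oecf_norm, correction_passes = 1L) {
  stopifnot(inherits(oecf_norm, "oecf_dataset"))
  if (!oecf_norm$normalised) {
    stop("fit_bezier() requires a normalised dataset; ",
         "call normalise_dataset() first", call. = FALSE)
  }
  pts <- oecf_norm$points[order(oecf_norm$points$exposure), , drop = FALSE]
  x <- pts$exposure; y <- pts$response
  if (length(x) < 4L) {
    stop("at least 4 points are required for a cubic Bezier fit",
         call. = FALSE)
  }
  p0 <- c(x[1], y[1]); p3 <- c(x[length(x)], y[length(y)])
  t <- .chord_param(x, y)
  solve_inner <- function(t) {
    B <- .bernstein3(t)
    A <- B[, 2:3, drop = FALSE]
    rx <- x - B[, 1] * p0[1] - B[, 4] * p3[1]
    ry <- y - B[, 1] * p0[2] - B[, 4] * p3[2]
    qrA <- qr(A)
    list(cx = qr.coef(qrA, rx), cy = qr.coef(qrA, ry))
  }
  sol <- solve_inner(t)
  for (pass in seq_len(correction_passes)) {
    ref <- .gauss_newton_pass(p0, p3, x, y, t, sol$cx, sol$cy)
    sol <- ref
    t <- ref$t
  }
  px <- c(p0[1], sol$cx, p3[1]); py <- c(p0[2], sol$cy, p3[2])
  curve <- bezier_curve(px, py)
  B <- .bernstein3(t)
  sse <- sum((as.numeric(B %*% px) - x)^2 + (as.numeric(B %*% py) - y)^2)
  attr(curve, "sse") <- sse
  if (!curve$monotone_x) {
    warning("fitted Bezier x(t) is not monotone increasing; ",
            "LUT inversion may be undefined")
  }
  curve
}

#' Fit several Bezier segments to one OECF
#'
#' Partitions the data contiguously by exposure into `n_segments` groups of
#' (near-)equal size and fits each independently, sharing the breakpoint
#' data point between adjacent segments so that the piecewise curve is C0
#' continuous.  Segmented fits cover complex OECFs (including the
#' below-`p_min` region) at the cost of LUT values that cluster within
#' segments instead of covering the curve uniformly.
#'
#' @param oecf_norm A normalised `oecf_dataset`.
#' @param n_segments Number of segments, >= 1; each segment needs >= 4
#'   points.
#' @param correction_passes Passed on to [fit_bezier()].
#' @return A list of `bezier_curve` objects ordered by exposure.
#' @export
fit_bezier_segments <- function(oecf_norm, n_segments,
                                correction_passes = 1L) {
  stopifnot(inherits(oecf_norm, "oecf_dataset"))
  if (n_segments < 1L) stop("`n_segments` must be >= 1", call. = FALSE)
  if (n_segments == 1L) {
    return(list(fit_bezier(oecf_norm, correction_passes)))
  }
  pts <- oecf_norm$points[order(oecf_norm$points$exposure), , drop = FALSE]
  n <- nrow(pts)
  # shared breakpoints: segment k spans [cut_k, cut_{k+1}] inclusive
  cuts <- round(seq(1, n, length.out = n_segments + 1L))
  if (any(diff(cuts) + 1L < 4L)) {
    stop("too few points per segment: ", n, " points cannot support ",
         n_segments, " cubic segments (>= 4 points each)", call. = FALSE)
  }
  lapply(seq_len(n_segments), function(k) {
    seg <- pts[cuts[k]:cuts[k + 1L], , drop = FALSE]
    ds <- oecf_norm
    ds$points <- seg
    fit_bezier(ds, correction_passes)
  })
}

#' Build an inversion look-up table from a Bezier curve
#'
#' Evaluates the curve at `n_entries` uniformly spaced parameter values and
#' stores the samples with the axes swapped, i.e. as ordered
#' `(response, exposure)` pairs, so that linear responses can be recovered
#' by interpolation (see [lut_lookup()]).
#'
#' @param curve A `bezier_curve` with monotone `y(t)`.
#' @param n_entries Number of table entries; default 256.
#' @return An `oecf_lut`: a data frame with columns `response` and
#'   `exposure`, increasing in `response`.
#' @export
build_lut <- function(curve, n_entries = 256L) {
  stopifnot(inherits(curve, "bezier_curve"))
  if (n_entries < 2L) stop("`n_entries` must be >= 2", call. = FALSE)
  if (!curve$monotone_y) {
    stop("Bezier y(t) is not monotone increasing: LUT inversion undefined",
         call. = FALSE)
  }
  if (!curve$monotone_x) {
    warning("Bezier x(t) is not monotone increasing; ",
            "LUT exposures will not be ordered")
  }
  tt <- seq(0, 1, length.out = n_entries)
  xy <- eval_bezier(curve, tt)
  lut <- data.frame(response = xy[, 2], exposure = xy[, 1])
  class(lut) <- c("oecf_lut", "data.frame")
  lut
}

#' Invert a response through a Bezier look-up table
#'
#' The LUT stores the axis-swapped Bezier samples; lookup is
#' piecewise-linear interpolation between the bracketing entries.
#' Responses below the table (below the `p_min`-equivalent) are not
#' linearisable and raise an error; responses above the table are clamped
#' to the top entry and flagged via the `"saturated"` attribute.
#'
#' @param lut An `oecf_lut` from [build_lut()].
#' @param p_norm Numeric vector of normalised responses.
#' @return Normalised exposure(s), with a logical `"saturated"` attribute.
#' @export
lut_lookup <- function(lut, p_norm) {
  stopifnot(inherits(lut, "oecf_lut"))
  lo <- lut$response[1]; hi <- lut$response[nrow(lut)]
  if (any(p_norm < lo - 1e-12)) {
    stop("response below the LUT range (p_min-equivalent ", signif(lo, 6),
         "): not linearisable", call. = FALSE)
  }
  sat <- p_norm > hi
  p_clamp <- pmin(pmax(p_norm, lo), hi)
  out <- stats::approx(lut$response, lut$exposure, xout = p_clamp,
                       ties = "ordered")$y
  attr(out, "saturated") <- sat
  out
}

#' Read / write a Bezier curve as JSON
#'
#' @param curve A `bezier_curve`.
#' @param path JSON file path.
#' @export
write_bezier_json <- function(curve, path) {
  stopifnot(inherits(curve, "bezier_curve"))
  obj <- list(control_points = lapply(1:4, function(i) {
    list(x = curve$px[i], y = curve$py[i],
         ci_x = curve$ci_x[i], ci_y = curve$ci_y[i])
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bezier_json
#' @export
read_bezier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cp <- obj$control_points
  bezier_curve(px = vapply(cp, function(p) p$x, numeric(1)),
               py = vapply(cp, function(p) p$y, numeric(1)),
               ci_x = vapply(cp, function(p) p$ci_x %||% 0, numeric(1)),
               ci_y = vapply(cp, function(p) p$ci_y %||% 0, numeric(1)))
}

#' Write / read a LUT as two-column CSV
#' @param lut An `oecf_lut`.
#' @param path CSV path.
#' @export
write_lut_csv <- function(lut, path) {
  stopifnot(inherits(lut, "oecf_lut"))
  utils::write.csv(as.data.frame(lut), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_lut_csv
#' @export
read_lut_csv <- function(path) {
  tab <- utils::read.csv(path)
  lut <- data.frame(response = tab$response, exposure = tab$exposure)
  class(lut) <- c("oecf_lut", "data.frame")
  lut
}

`%||%` <- function(a, b) if (is.null(a)) b else a
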