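# Biexponential OECF model: f(E) = a - b e^{-cE} - d e^{-gE}, with the
# normalisation condition f(0) = 0 enforced as a = b + d, so only four
# coefficients (b, c, d, g) are free.  b, d are in pixel response units;
# c, g are in inverse photon-amount units.

#' Biexponential gain-model parameters
#'
#' Parameterises the saturating two-exponential camera gain
#' `f(E) = a - b exp(-c E) - d exp(-g E)` with `a = b + d` so that
#' `f(0) = 0`.  `a` is the notional limiting output approached at very
#' large exposure; the model is used for responses up to `g_max`, which
#' requires `a > g_max` for invertibility over the working range.
#'
#' @param b,d Amplitudes in pixel response units, `0 < b, d <= a`.
#' @param c,g Rates in inverse exposure units, both > 0.  By convention the
#'   faster exponential is listed first (`c >= g`); [fit_biexp()] enforces
#'   this tie-break.
#' @param ci_halfwidth Named numeric vector of 95% confidence-interval
#'   half-widths for `b`, `c`, `d`, `g` (0 when unknown).
#' @param g_max Maximum response covered by the calibration.
#' @param e_max Optional exposure with `f(e_max) = g_max`.
#' @param scale `"original"` or `"normalised"`, the response scale the
#'   parameters refer to.
#' @return An object of class `biexp_params` (the derived asymptote is
#'   stored as `$a`).
#' @export
biexp_params <- function(b, c, d, g,
                         ci_halfwidth = c(b = 0, c = 0, d = 0, g = 0),
                         g_max = 250, e_max = NULL, scale = "original") {
  b <- unname(b); c <- unname(c); d <- unname(d); g <- unname(g)
  vals <- c(b = b, c = c, d = d, g = g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("coefficients b, c, d, g must all be positive and finite",
         call. = FALSE)
  }
  ci <- c(b = 0, c = 0, d = 0, g = 0)
  ci[names(ci_halfwidth)] <- as.numeric(ci_halfwidth)
  if (any(ci < 0)) stop("CI half-widths must be >= 0", call. = FALSE)
  structure(list(a = b + d, b = b, c = c, d = d, g = g,
                 ci_halfwidth = ci, g_max = g_max, e_max = e_max,
                 scale = scale),
            class = "biexp_params")
}

#' @export
print.biexp_params <- function(x, ...) {
  cat(sprintf(
    "<biexp_params> a=%.6g (=b+d)  b=%.6g  c=%.6g  d=%.6g  g=%.6g\n",
    x$a, x$b, x$c, x$d, x$g))
  cat(sprintf("  95%% CI half-widths: b=%.3g c=%.3g d=%.3g g=%.3g\n",
              x$ci_halfwidth["b"], x$ci_halfwidth["c"],
              x$ci_halfwidth["d"], x$ci_halfwidth["g"]))
  cat(sprintf("  g_max=%g%s, scale=%s\n", x$g_max,
              if (!is.null(x$e_max)) sprintf(", e_max=%g", x$e_max) else "",
              x$scale))
  invisible(x)
}

#' Evaluate the biexponential gain curve
#'
#' @param params A `biexp_params` object.
#' @param E Numeric vector of exposures, all >= 0.  Values above `e_max`
#'   (when set) are permitted but lie outside the calibrated range.
#' @return `f(E)` in response units; `f(0) = 0` exactly and
#'   `f(E) -> a` as `E` grows.
#' @export
eval_biexp <- function(params, E) {
  stopifnot(inherits(params, "biexp_params"))
  if (any(E < 0)) stop("exposure must be >= 0", call. = FALSE)
  params$a - params$b * exp(-params$c * E) - params$d * exp(-params$g * E)
}

# sum of squared residuals of the constrained model at theta = (b,c,d,g)
.biexp_ssr <- function(theta, E, p) {
  f <- theta[1] * (1 - exp(-theta[2] * E)) +
    theta[3] * (1 - exp(-theta[4] * E))
  sum((p - f)^2)
}

# Jacobian of model predictions wrt (b, c, d, g)
.biexp_jacobian <- function(theta, E) {
  b <- theta[1]; cc <- theta[2]; d <- theta[3]; g <- theta[4]
  cbind(b = 1 - exp(-cc * E), c = b * E * exp(-cc * E),
        d = 1 - exp(-g * E), g = d * E * exp(-g * E))
}

#' Fit the biexponential gain model to an OECF dataset
#'
#' Least-squares estimation of (b, c, d, g) under the `f(0) = 0` constraint
#' (`a := b + d`), using bounded Gauss-Newton (`nls` with the port
#' algorithm) from a multi-start grid: rate starts are log-spaced over two
#' decades from `1 / E_span` with the faster rate assigned to `c`, and
#' amplitude starts split the maximum response evenly between `b` and `d`.
#' The best converged start (lowest SSE) wins; exchangeable exponentials
#' are reported with `c >= g`.  95% CI half-widths are `1.96 * SE` from
#' the fit covariance (a Moore-Penrose pseudoinverse of the Gauss-Newton
#' normal matrix covers rate-degenerate fits).  `e_max` is derived from
#' the fit by solving `f(E) = g_max` when the asymptote allows it.
#'
#' @param oecf An `oecf_dataset` (original or normalised scale) with at
#'   least 6 points.
#' @return A `biexp_params` object with an `sse` attribute.
#' @export
fit_biexp <- function(oecf) {
  stopifnot(inherits(oecf, "oecf_dataset"))
  E <- oecf$points$exposure
  p <- oecf$points$response
  if (length(E) < 6L) {
    stop("at least 6 points are required to fit the biexponential model",
         call. = FALSE)
  }
  e_span <- max(E) - min(E[E > 0], max(E) / 100)
  if (e_span <= 0) e_span <- max(E)
  rates <- 10^seq(0, 2, length.out = 5) / e_span
  b0 <- max(p) / 2
  upper_amp <- 2^oecf$bit_depth
  if (oecf$normalised) upper_amp <- 2
  starts <- list()
  for (i in seq_along(rates)) for (j in seq_along(rates)) {
    if (rates[i] > rates[j]) starts[[length(starts) + 1L]] <-
        c(b = b0, c = rates[i], d = b0, g = rates[j])
  }
  dat <- data.frame(E = E, p = p)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::nls(p ~ b * (1 - exp(-c * E)) + d * (1 - exp(-g * E)),
                 data = dat, start = as.list(st), algorithm = "port",
                 lower = c(b = 1e-12, c = 1e-12, d = 1e-12, g = 1e-12),
                 upper = c(b = upper_amp, c = Inf, d = upper_amp, g = Inf),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) {
    # fall back to direct bounded minimisation of the SSE
    ssr_of <- function(th) .biexp_ssr(th, E, p)
    opt <- NULL
    for (st in starts) {
      o <- tryCatch(stats::optim(st, ssr_of, method = "L-BFGS-B",
                                 lower = rep(1e-12, 4),
                                 upper = c(upper_amp, Inf, upper_amp, Inf),
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(opt) || o$value < opt$value)) opt <- o
    }
    if (is.null(opt)) {
      stop("biexponential fit failed to converge from any start",
           call. = FALSE)
    }
    theta <- opt$par
    ssr <- opt$value
  } else {
    theta <- stats::coef(best$fit)
    ssr <- best$ssr
  }
  names(theta) <- c("b", "c", "d", "g")
  # tie-break: report the faster exponential as (b, c)
  if (theta["c"] < theta["g"]) {
    theta <- c(b = unname(theta["d"]), c = unname(theta["g"]),
               d = unname(theta["b"]), g = unname(theta["c"]))
  }
  # covariance via pseudoinverse of J'J (robust to c ~ g degeneracy)
  J <- .biexp_jacobian(theta, E)
  dof <- max(length(E) - 4L, 1L)
  sigma2 <- ssr / dof
  sv <- svd(crossprod(J))
  pos <- sv$d > max(sv$d) * 1e-12
  cov <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  se <- sqrt(pmax(diag(sigma2 * cov), 0))
  ci <- 1.96 * se
  names(ci) <- names(theta)
  out <- biexp_params(b = theta["b"], c = theta["c"], d = theta["d"],
                      g = theta["g"], ci_halfwidth = ci,
                      g_max = oecf$g_max,
                      scale = if (oecf$normalised) "normalised"
                              else "original")
  if (out$a > oecf$g_max) out$e_max <- invert_biexp(out, oecf$g_max)
  attr(out, "sse") <- ssr
  out
}

#' Invert the biexponential gain curve
#'
#' Finds the unique exposure `E >= 0` with `f(E) = p` by bracketed root
#' finding (the upper bracket is grown geometrically until it encloses the
#' root) followed by Newton polishing, so that
#' `|f(invert_biexp(p)) - p| <= 1e-9 * a`.
#'
#' @param params A `biexp_params` object.
#' @param p Numeric vector of responses with `0 <= p < a`.
#' @return Exposure(s) in the units the parameters were fitted on.
#' @export
invert_biexp <- function(params, p) {
  stopifnot(inherits(params, "biexp_params"))
  if (any(p < 0)) stop("response must be >= 0", call. = FALSE)
  if (any(p >= params$a)) {
    stop("response >= asymptote a = ", signif(params$a, 6),
         ": no finite exposure attains it", call. = FALSE)
  }
  vapply(p, function(pi) .invert_biexp_one(params, pi), numeric(1))
}

.invert_biexp_one <- function(params, p) {
  if (p == 0) return(0)
  hi <- 1 / min(params$c, params$g)
  for (k in 1:200) {
    if (eval_biexp(params, hi) > p) break
    hi <- hi * 2
  }
  if (eval_biexp(params, hi) <= p) {
    stop("failed to bracket the root during inversion", call. = FALSE)
  }
  E <- stats::uniroot(function(E) eval_biexp(params, E) - p,
                      lower = 0, upper = hi, tol = 1e-12 * hi)$root
  # Newton polish to drive the residual to ~machine precision
  for (k in 1:5) {
    fE <- eval_biexp(params, E)
    d1 <- params$b * params$c * exp(-params$c * E) +
      params$d * params$g * exp(-params$g * E)
    if (d1 <= 0) break
    step <- (fE - p) / d1
    E <- max(E - step, 0)
    if (abs(step) <= 1e-15 * max(E, 1e-300)) break
  }
  E
}

#' Linearise a raw pixel response through the biexponential model
#'
#' Normalises the raw level onto the fitted scale, inverts the gain curve
#' and rescales the result by `e_max`, so the output is proportional to
#' the photon amount incident during the exposure.  Saturated inputs
#' (`p_raw >= g_max`) map to `e_max` and are flagged.
#'
#' @param params A fitted `biexp_params` with `e_max` available (or an
#'   explicit `e_max` argument).
#' @param p_raw Integer pixel level(s) in `[0, 2^bit_depth - 1]`.
#' @param bit_depth Bit depth of `p_raw`; default 8.
#' @param e_max Exposure anchor; defaults to `params$e_max`.
#' @return A list with `exposure` (numeric vector) and `saturated`
#'   (logical vector).
#' @export
linearise_response <- function(params, p_raw, bit_depth = 8L,
                               e_max = params$e_max) {
  stopifnot(inherits(params, "biexp_params"))
  if (is.null(e_max)) {
    stop("`e_max` is required to rescale linearised responses",
         call. = FALSE)
  }
  if (any(p_raw < 0) || any(p_raw > 2^bit_depth - 1)) {
    stop("`p_raw` outside the representable range", call. = FALSE)
  }
  # express g_max and the raw level on the fitted response scale
  scale_div <- if (params$scale == "normalised") 2^bit_depth - 1 else 1
  p_fit <- p_raw / scale_div
  g_max_fit <- params$g_max
  sat <- p_fit >= g_max_fit
  p_fit[sat] <- g_max_fit
  e_top <- invert_biexp(params, g_max_fit)
  expo <- invert_biexp(params, p_fit) / e_top * e_max
  list(exposure = expo, saturated = sat)
}

#' Read / write biexponential parameters as JSON
#'
#' @param params A `biexp_params` object.
#' @param path JSON file path.
#' @return `write_biexp_json()` returns `path` invisibly;
#'   `read_biexp_json()` returns a `biexp_params`.
#' @export
write_biexp_json <- function(params, path) {
  stopifnot(inherits(params, "biexp_params"))
  obj <- list(a = params$a, b = params$b, c = params$c, d = params$d,
              g = params$g, ci_halfwidths = as.list(params$ci_halfwidth),
              g_max = params$g_max, E_max = params$e_max,
              scale = params$scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_biexp_json
#' @export
read_biexp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  biexp_params(b = obj$b, c = obj$c, d = obj$d, g = obj$g,
               ci_halfwidth = unlist(obj$ci_halfwidths),
               g_max = obj$g_max, e_max = obj$E_max, scale = obj$scale)
}
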