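# OECF data model: measured (exposure, response) pairs with the
# g_max / p_min / E_max normalisation protocol.

#' Create an OECF dataset
#'
#' An OECF (opto-electronic conversion function) dataset holds measured
#' pairs of input exposure (photon amount, umol-equivalent units) and mean
#' camera response (pixel intensity levels), for one colour channel.  The
#' normalisation anchors are `g_max`, the maximum pixel response included in
#' characterisation (chosen below full saturation, about 250 of 255, to
#' avoid clipping artefacts), and `e_max`, the exposure producing `g_max`.
#' `p_min` is the minimum response the Bezier route can linearise.
#'
#' @param exposure Numeric vector of exposures, all >= 0.
#' @param response Numeric vector of camera responses in
#'   `[0, 2^bit_depth - 1]`, same length.
#' @param channel Channel label (e.g. `"red"`, `"uv"`).
#' @param bit_depth Integer encoding depth; default 8.
#' @param g_max Maximum response used for characterisation; default 250.
#' @param p_min Optional minimum linearisable response.
#' @param e_max Optional exposure producing `g_max`
#'   (see [estimate_e_max()]).
#' @param normalised Logical; `TRUE` when both axes are on `[0, 1]` scales.
#' @return An object of class `oecf_dataset`.
#' @export
oecf_dataset <- function(exposure, response, channel = "grey",
                         bit_depth = 8L, g_max = 250, p_min = NULL,
                         e_max = NULL, normalised = FALSE) {
  exposure <- as.numeric(exposure)
  response <- as.numeric(response)
  if (length(exposure) != length(response)) {
    stop("`exposure` and `response` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(exposure)) || any(!is.finite(response))) {
    stop("exposures and responses must be finite", call. = FALSE)
  }
  if (any(exposure < 0)) stop("exposures must be >= 0", call. = FALSE)
  pmax_allowed <- if (normalised) 1.05 else 2^bit_depth - 1
  if (any(response < 0) || any(response > pmax_allowed)) {
    stop("responses outside the representable range", call. = FALSE)
  }
  if (normalised && any(exposure > 1.05)) {
    stop("normalised exposures must lie within [0, 1.05]", call. = FALSE)
  }
  structure(list(
    points = data.frame(exposure = exposure, response = response),
    channel = channel, bit_depth = as.integer(bit_depth),
    g_max = g_max, p_min = p_min, e_max = e_max,
    normalised = isTRUE(normalised)
  ), class = "oecf_dataset")
}

#' @export
print.oecf_dataset <- function(x, ...) {
  cat(sprintf(
    "<oecf_dataset> channel=%s, %d points, %d-bit, g_max=%g%s%s%s\n",
    x$channel, nrow(x$points), x$bit_depth, x$g_max,
    if (!is.null(x$e_max)) sprintf(", e_max=%g", x$e_max) else "",
    if (!is.null(x$p_min)) sprintf(", p_min=%g", x$p_min) else "",
    if (x$normalised) " (normalised)" else ""))
  invisible(x)
}

#' Normalise an OECF dataset to unit axes
#'
#' Divides the response axis by `2^bit_depth - 1` (255 for 8-bit data) and
#' the exposure axis by `e_max`, the exposure producing the response
#' `g_max`.  Note the two axes use different anchors: normalised responses
#' therefore top out near `g_max / 255` (about 0.96), not at 1.
#'
#' @param oecf An `oecf_dataset` with `e_max` set.
#' @return The normalised `oecf_dataset` (`normalised = TRUE`); `g_max` and
#'   `p_min` are rescaled onto the response axis, and the original anchors
#'   are retained so [denormalise_dataset()] can round-trip.
#' @export
normalise_dataset <- function(oecf) {
  stopifnot(inherits(oecf, "oecf_dataset"))
  if (oecf$normalised) return(oecf)
  if (is.null(oecf$e_max)) {
    stop("`e_max` is not set; estimate it first with estimate_e_max()",
         call. = FALSE)
  }
  pmax <- 2^oecf$bit_depth - 1
  out <- oecf
  out$points$exposure <- oecf$points$exposure / oecf$e_max
  out$points$response <- oecf$points$response / pmax
  out$g_max <- oecf$g_max / pmax
  if (!is.null(oecf$p_min)) out$p_min <- oecf$p_min / pmax
  out$normalised <- TRUE
  attr(out, "orig_e_max") <- oecf$e_max
  attr(out, "orig_bit_depth") <- oecf$bit_depth
  out
}

#' Undo [normalise_dataset()]
#'
#' @param oecf A normalised `oecf_dataset` produced by
#'   [normalise_dataset()].
#' @return The dataset on its original scales.
#' @export
denormalise_dataset <- function(oecf) {
  stopifnot(inherits(oecf, "oecf_dataset"))
  if (!oecf$normalised) return(oecf)
  pmax <- 2^oecf$bit_depth - 1
  out <- oecf
  out$points$exposure <- oecf$points$exposure * oecf$e_max
  out$points$response <- oecf$points$response * pmax
  out$g_max <- oecf$g_max * pmax
  if (!is.null(oecf$p_min)) out$p_min <- oecf$p_min * pmax
  out$normalised <- FALSE
  out
}

#' Estimate the exposure that produces the response g_max
#'
#' `e_max` anchors the exposure-axis normalisation.  Two estimators are
#' offered: `"biexp_fit"` fits the biexponential gain model on the original
#' scale and solves `f(E) = g_max` by root finding; `"interpolation"`
#' inverts the piecewise-linear interpolant of the measured points at
#' `g_max`, which requires data bracketing `g_max` at the upper end.
#'
#' @param oecf An `oecf_dataset` on the original (not normalised) scale.
#' @param method `"biexp_fit"` (default) or `"interpolation"`.
#' @return Scalar exposure estimate in the dataset's exposure units.
#' @export
estimate_e_max <- function(oecf, method = c("biexp_fit", "interpolation")) {
  stopifnot(inherits(oecf, "oecf_dataset"))
  method <- match.arg(method)
  if (oecf$normalised) {
    stop("estimate_e_max() expects data on the original scale", call. = FALSE)
  }
  if (method == "biexp_fit") {
    params <- fit_biexp(oecf)
    if (params$a <= oecf$g_max) {
      stop("fitted asymptote a = ", signif(params$a, 6),
           " does not exceed g_max = ", oecf$g_max,
           "; e_max is undefined on this fit", call. = FALSE)
    }
    return(invert_biexp(params, oecf$g_max))
  }
  pts <- average_replicates(oecf)$points
  pts <- pts[order(pts$exposure), , drop = FALSE]
  above <- pts$response >= oecf$g_max
  if (!any(above) || all(above)) {
    stop("data do not bracket g_max = ", oecf$g_max,
         "; cannot interpolate e_max", call. = FALSE)
  }
  stats::approx(pts$response, pts$exposure, xout = oecf$g_max,
                ties = mean)$y
}

#' Remove responses below the minimum linearisable level
#'
#' Responses below `p_min` follow a different distribution from the rest of
#' the OECF curve and degrade a single-segment Bezier fit; they are removed
#' before fitting.  Responses exactly equal to `p_min` are retained.
#'
#' @param oecf An `oecf_dataset`.
#' @param p_min Minimum retained response, on the dataset's response scale.
#' @return The filtered dataset with `p_min` recorded.
#' @export
filter_p_min <- function(oecf, p_min) {
  stopifnot(inherits(oecf, "oecf_dataset"))
  keep <- oecf$points$response >= p_min
  if (sum(keep) < 4L) {
    stop("p_min filtering leaves ", sum(keep),
         " points; at least 4 are needed for a cubic Bezier fit",
         call. = FALSE)
  }
  out <- oecf
  out$points <- oecf$points[keep, , drop = FALSE]
  rownames(out$points) <- NULL
  out$p_min <- p_min
  out
}

#' Average repeated-exposure replicates
#'
#' Collapses points sharing an exposure value to their mean response,
#' mirroring the measurement protocol where each response is already the
#' mean over a 50 x 50 pixel region of interest.
#'
#' @param oecf An `oecf_dataset`.
#' @return The dataset with one point per distinct exposure.
#' @export
average_replicates <- function(oecf) {
  stopifnot(inherits(oecf, "oecf_dataset"))
  agg <- stats::aggregate(response ~ exposure, data = oecf$points, FUN = mean)
  out <- oecf
  out$points <- agg[order(agg$exposure), c("exposure", "response")]
  rownames(out$points) <- NULL
  out
}

#' Read an OECF table from CSV
#'
#' Expects a header `channel,exposure,response`.
#'
#' @param path CSV path.
#' @param channel Optional channel to select when the file holds several.
#' @param ... Passed on to [oecf_dataset()] (`bit_depth`, `g_max`, ...).
#' @return An `oecf_dataset`.
#' @export
read_oecf_csv <- function(path, channel = NULL, ...) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "exposure", "response")
  if (!all(need %in% names(tab))) {
    stop("OECF CSV must have columns channel, exposure, response",
         call. = FALSE)
  }
  if (is.null(channel)) {
    channel <- tab$channel[1]
    if (length(unique(tab$channel)) > 1L) {
      warning("multiple channels present; using '", channel, "'")
    }
  }
  tab <- tab[tab$channel == channel, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for channel '", channel, "'",
                            call. = FALSE)
  oecf_dataset(tab$exposure, tab$response, channel = channel, ...)
}

#' Write an OECF dataset to CSV
#'
#' @param oecf An `oecf_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_oecf_csv <- function(oecf, path) {
  stopifnot(inherits(oecf, "oecf_dataset"))
  tab <- data.frame(channel = oecf$channel, exposure = oecf$points$exposure,
                    response = oecf$points$response)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
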