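# Packaged calibration fixtures: published biexponential coefficients and
# Bezier control points for a Canon 40D (red/green/blue) and a UV-modified
# Nikon D70s ('red'-UV channel), with their 95% confidence intervals.
#
# Unit caveat, preserved verbatim from the source tables: the
# biexponential rates are printed in inverse-mol units while e_max is
# printed in umol, and plugging the printed coefficients into
# f(E) = g_max does not reproduce the printed e_max under either unit
# reading.  The fixtures store the printed values without reinterpretation;
# e_max is carried alongside as a separate anchor.

#' List the packaged camera fixtures
#'
#' @return Character vector of fixture names accepted by
#'   [oecf_fixture()].
#' @export
oecf_fixtures <- function() {
  c("canon40d_red", "canon40d_green", "canon40d_blue", "nikond70s_uv")
}

#' Load a packaged camera calibration fixture
#'
#' Returns the published characterisation of one camera channel: the
#' biexponential gain coefficients (with 95% CI half-widths) and the
#' cubic Bezier control points on normalised axes (with 95% CIs), plus
#' the normalisation anchors `g_max`, `p_min` and `e_max`.
#'
#' @param name One of [oecf_fixtures()], e.g. `"canon40d_red"`.
#' @return A list with elements `channel`, `camera`, `bit_depth`, `g_max`,
#'   `p_min`, `e_max`, `biexp` (a [biexp_params()]) and `bezier` (a
#'   [bezier_curve()]).
#' @examples
#' fx <- oecf_fixture("canon40d_red")
#' eval_bezier(fx$bezier, 1)  # the curve's top point
#' @export
oecf_fixture <- function(name) {
  name <- match.arg(name, oecf_fixtures())
  path <- system.file("extdata", paste0(name, ".json"),
                      package = "oecflin", mustWork = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  bx <- obj$biexp
  biexp <- biexp_params(b = bx$b, c = bx$c, d = bx$d, g = bx$g,
                        ci_halfwidth = unlist(bx$ci_halfwidths),
                        g_max = obj$g_max, scale = bx$scale)
  biexp$e_max <- obj$e_max_umol
  cp <- obj$bezier$control_points
  bez <- bezier_curve(px = vapply(cp, function(p) p$x, numeric(1)),
                      py = vapply(cp, function(p) p$y, numeric(1)),
                      ci_x = vapply(cp, function(p) p$ci_x, numeric(1)),
                      ci_y = vapply(cp, function(p) p$ci_y, numeric(1)))
  list(channel = obj$channel, camera = obj$camera,
       bit_depth = obj$bit_depth, g_max = obj$g_max, p_min = obj$p_min,
       e_max = obj$e_max_umol, biexp = biexp, bezier = bez)
}
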