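# Synthetic-data generator: exposure ladders, OECF measurements from a
# known biexponential gain with Gaussian read noise and quantisation, and
# patch images with ground-truth exposure maps.

# neutral-density set used to step the source: the four physical filters
# (OD 0.1, 0.2, 0.5, 1.0), the densities obtained by stacking them
# (0.3, 0.7, 1.2, 1.5) and the unfiltered beam
.DEFAULT_ODS <- c(0, 0.1, 0.2, 0.3, 0.5, 0.7, 1.0, 1.2, 1.5)
# complete/half/third stops from f/8 to f/22
.DEFAULT_FSTOPS <- c(8, 9, 10, 11, 13, 14, 16, 18, 20, 22)
# achromatic reflectance targets (barium sulphate / charcoal mixes)
.DEFAULT_REFLECTANCES <- c(0.86, 0.60, 0.51, 0.15, 0.02)

#' Build an exposure ladder
#'
#' Generates a series of known relative exposures from a base exposure:
#' by neutral-density attenuation (`base * 10^-OD`), by stopping down the
#' aperture (`base * (f_ref / f)^2`, with `f_ref` the widest aperture in
#' the list), or by diffuse targets of known reflectance (`base * R`).
#'
#' @param base_exposure Exposure of the unattenuated step, > 0.
#' @param mode `"nd"`, `"fstop"` or `"reflectance"`.
#' @param ods,f_numbers,reflectances Step definitions for the respective
#'   modes; the defaults follow common OECF measurement protocols (an OD
#'   set 0-1.5 from four stackable filters, ten f-stops from f/8 to f/22,
#'   five achromatic targets from 86% down to 2% reflectance).
#' @return An object of class `exposure_ladder`: a data frame with columns
#'   `label` and `exposure`, ordered from brightest to dimmest.
#' @export
make_ladder <- function(base_exposure,
                        mode = c("nd", "fstop", "reflectance"),
                        ods = .DEFAULT_ODS, f_numbers = .DEFAULT_FSTOPS,
                        reflectances = .DEFAULT_REFLECTANCES) {
  mode <- match.arg(mode)
  if (base_exposure <= 0) {
    stop("`base_exposure` must be positive", call. = FALSE)
  }
  steps <- switch(mode,
    nd = {
      if (length(ods) == 0) stop("empty OD list", call. = FALSE)
      data.frame(label = sprintf("OD%.1f", ods),
                 exposure = base_exposure * 10^(-ods))
    },
    fstop = {
      if (length(f_numbers) == 0) stop("empty f-number list", call. = FALSE)
      f_ref <- min(f_numbers)
      data.frame(label = sprintf("f%g", f_numbers),
                 exposure = base_exposure * (f_ref / f_numbers)^2)
    },
    reflectance = {
      if (length(reflectances) == 0) {
        stop("empty reflectance list", call. = FALSE)
      }
      data.frame(label = sprintf("R%.0f%%", 100 * reflectances),
                 exposure = base_exposure * reflectances)
    })
  if (anyDuplicated(steps$label)) {
    stop("ladder labels must be unique", call. = FALSE)
  }
  steps <- steps[order(-steps$exposure), , drop = FALSE]
  rownames(steps) <- NULL
  class(steps) <- c("exposure_ladder", "data.frame")
  steps
}

#' Ground truth for synthetic OECF data
#'
#' Pairs a known biexponential gain with a read-noise level and a seed, so
#' synthetic measurements can be generated reproducibly and compared back
#' to their generator.  Noise is additive Gaussian in intensity levels
#' (read-noise dominated), applied before quantisation.
#'
#' @param params A `biexp_params` acting as the true camera gain.
#' @param noise_sd Read-noise SD in intensity levels; default 1.
#' @param seed Integer seed.
#' @param bit_depth Quantisation depth; default 8.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(params, noise_sd = 1, seed = 1L,
                            bit_depth = 8L) {
  stopifnot(inherits(params, "biexp_params"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(params = params, noise_sd = noise_sd,
                 seed = as.integer(seed), bit_depth = as.integer(bit_depth)),
            class = "synthetic_truth")
}

#' Simulate OECF measurements from a known gain
#'
#' Applies the true gain to every ladder step, adds Gaussian read noise,
#' clamps to the representable range and rounds to integer levels.
#' Replicates are spread round-robin over the ladder steps until
#' `n_points` measurements exist (default 96, a typical measurement-set
#' size for a full characterisation).
#'
#' @param truth A `synthetic_truth`.
#' @param ladder An `exposure_ladder`; defaults to the ND ladder based at
#'   the true curve's `e_max` (so the brightest step sits at `g_max`).
#' @param n_points Total number of measurements; default 96.
#' @return An `oecf_dataset` with the per-point true exposures attached as
#'   attribute `"true_exposure"`.
#' @export
simulate_oecf <- function(truth, ladder = NULL, n_points = 96L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(ladder)) {
    base <- invert_biexp(truth$params, truth$params$g_max)
    ladder <- make_ladder(base, "nd")
  }
  stopifnot(inherits(ladder, "exposure_ladder"))
  idx <- rep(seq_len(nrow(ladder)), length.out = n_points)
  idx <- sort(idx)
  E <- ladder$exposure[idx]
  pmax_lev <- 2^truth$bit_depth - 1
  resp <- .with_seed(truth$seed, {
    clean <- eval_biexp(truth$params, E)
    noisy <- clean + stats::rnorm(length(E), 0, truth$noise_sd)
    round(pmin(pmax(noisy, 0), pmax_lev))
  })
  out <- oecf_dataset(E, resp, channel = truth$params$scale,
                      bit_depth = truth$bit_depth,
                      g_max = truth$params$g_max)
  out$channel <- "synthetic"
  attr(out, "true_exposure") <- E
  attr(out, "truth") <- truth
  out
}

#' Simulate a raw patch image and matching dark frame
#'
#' Renders each pixel of a ground-truth exposure map through the true
#' gain, adds a dark offset and Gaussian read noise, clamps and quantises.
#' The returned dark frame is generated with the same offset and noise so
#' the pair exercises the full dark-subtraction pipeline.
#'
#' @param truth A `synthetic_truth`.
#' @param exposure_map Numeric matrix of true exposures, all >= 0.
#' @param dark_level Mean dark offset in intensity levels; default 0.
#' @return A list with `image` and `dark` (`raw_image`s); the truth map is
#'   attached to `image` as attribute `"true_exposure"`.
#' @export
simulate_image <- function(truth, exposure_map, dark_level = 0) {
  stopifnot(inherits(truth, "synthetic_truth"))
  exposure_map <- as.matrix(exposure_map)
  if (any(exposure_map < 0)) {
    stop("`exposure_map` must be non-negative", call. = FALSE)
  }
  pmax_lev <- 2^truth$bit_depth - 1
  res <- .with_seed(truth$seed, {
    signal <- eval_biexp(truth$params, as.numeric(exposure_map))
    img <- round(pmin(pmax(signal + dark_level +
                             stats::rnorm(length(signal), 0,
                                          truth$noise_sd), 0), pmax_lev))
    drk <- round(pmin(pmax(dark_level +
                             stats::rnorm(length(signal), 0,
                                          truth$noise_sd), 0), pmax_lev))
    list(img = img, drk = drk)
  })
  image <- raw_image(matrix(res$img, nrow(exposure_map)),
                     truth$bit_depth, "synthetic")
  attr(image, "true_exposure") <- exposure_map
  dark <- raw_image(matrix(res$drk, nrow(exposure_map)),
                    truth$bit_depth, "synthetic")
  list(image = image, dark = dark)
}
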