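# Spectral bookkeeping: containers for radiance / sensitivity / transmittance
# spectra and the forward camera exposure model.

# physical constants (SI, CODATA 2018 exact values)
.PLANCK_H <- 6.62607015e-34   # J s
.LIGHT_C <- 2.99792458e8      # m s^-1
.AVOGADRO <- 6.02214076e23    # mol^-1

.SPECTRUM_KINDS <- c("radiance_energy", "radiance_photon", "sensitivity",
                     "transmittance")

#' Create a spectrum
#'
#' A spectrum is a per-nanometre quantity sampled on a strictly increasing
#' wavelength grid.  Four kinds are distinguished so that unit-dependent
#' operations can refuse inappropriate inputs: energy radiance
#' (W m-2 sr-1 nm-1), photon radiance (umol m-2 s-1 nm-1 sr-1),
#' dimensionless sensitivity (>= 0) and transmittance (in [0, 1]).
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector of per-nm values, same length as `wavelength`.
#' @param kind One of `"radiance_energy"`, `"radiance_photon"`,
#'   `"sensitivity"`, `"transmittance"`.
#' @return An object of class `spectrum`: a data frame with columns
#'   `wavelength` and `value` and a `kind` attribute.
#' @examples
#' spectrum(400:700, rep(1, 301), "radiance_energy")
#' @export
spectrum <- function(wavelength, value, kind = "radiance_energy") {
  kind <- match.arg(kind, .SPECTRUM_KINDS)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    stop("`wavelength` and `value` must have the same length", call. = FALSE)
  }
  if (length(wavelength) == 0L) {
    stop("spectrum must contain at least one sample", call. = FALSE)
  }
  if (any(!is.finite(wavelength)) || any(!is.finite(value))) {
    stop("spectrum values and wavelengths must be finite", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (kind == "transmittance" && (any(value < 0) || any(value > 1))) {
    stop("transmittance values must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "sensitivity" && any(value < 0)) {
    stop("sensitivity values must be non-negative", call. = FALSE)
  }
  out <- data.frame(wavelength = wavelength, value = value)
  class(out) <- c("spectrum", "data.frame")
  attr(out, "kind") <- kind
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum[%s]> %d samples, %g-%g nm\n", spectrum_kind(x),
              nrow(x), x$wavelength[1], x$wavelength[nrow(x)]))
  invisible(x)
}

#' Spectrum kind accessor
#' @param spec A `spectrum`.
#' @return Character scalar, the stored kind.
#' @export
spectrum_kind <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  attr(spec, "kind")
}

#' Convert energy radiance to photon flux
#'
#' Converts spectral radiance in energy units (W m-2 sr-1 nm-1) to photon
#' flux in umol m-2 s-1 nm-1 sr-1 using E_photon = h c / lambda, i.e.
#' value(lambda) * lambda / (h c N_A) * 1e6 with lambda in metres.
#'
#' @param spec A `spectrum` of kind `radiance_energy`.
#' @return A `spectrum` of kind `radiance_photon` on the same grid.
#' @examples
#' s <- spectrum(500, 1, "radiance_energy")
#' energy_to_photon_flux(s)$value  # ~4.18 umol
#' @export
energy_to_photon_flux <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  if (spectrum_kind(spec) != "radiance_energy") {
    stop("energy_to_photon_flux() requires a 'radiance_energy' spectrum",
         call. = FALSE)
  }
  lambda_m <- spec$wavelength * 1e-9
  v <- spec$value * lambda_m / (.PLANCK_H * .LIGHT_C * .AVOGADRO) * 1e6
  spectrum(spec$wavelength, v, "radiance_photon")
}

#' Bin a spectrum to a coarser wavelength grid
#'
#' Averages samples falling in consecutive bins of width `bin_width_nm`,
#' anchored at the first wavelength.  Binning takes the arithmetic mean so
#' per-nm units are preserved; empty bins are dropped.  Output wavelengths
#' are bin centres.
#'
#' @param spec A `spectrum`.
#' @param bin_width_nm Bin width in nm; must exceed the input sample spacing.
#' @return A `spectrum` of the same kind on the binned grid.
#' @export
bin_spectrum <- function(spec, bin_width_nm) {
  stopifnot(inherits(spec, "spectrum"))
  if (!is.numeric(bin_width_nm) || length(bin_width_nm) != 1L ||
      bin_width_nm <= 0) {
    stop("`bin_width_nm` must be a positive scalar", call. = FALSE)
  }
  w0 <- spec$wavelength[1]
  idx <- floor((spec$wavelength - w0) / bin_width_nm)
  centre <- w0 + (unique(idx) + 0.5) * bin_width_nm
  val <- as.numeric(tapply(spec$value, idx, mean))
  spectrum(centre, val, spectrum_kind(spec))
}

#' Attenuate a spectrum with a neutral density filter
#'
#' Scales all values by `10^(-optical_density)`.  Stacked filters add their
#' optical densities, so applying OD 0.5 twice equals OD 1.0 once.
#'
#' @param spec A `spectrum`.
#' @param optical_density Non-negative optical density (log10 attenuation).
#' @return The attenuated `spectrum` (same kind, same grid).
#' @export
apply_nd_filter <- function(spec, optical_density) {
  stopifnot(inherits(spec, "spectrum"))
  if (!is.numeric(optical_density) || length(optical_density) != 1L ||
      optical_density < 0) {
    stop("`optical_density` must be a non-negative scalar", call. = FALSE)
  }
  spectrum(spec$wavelength, spec$value * 10^(-optical_density),
           spectrum_kind(spec))
}

#' Camera exposure settings
#'
#' Bundles the exposure parameters entering the camera equation: relative
#' aperture (f-number), integration time (shutter speed) in seconds,
#' optical magnification, effective detector (pixel) area in m2 and the
#' informational ISO setting.
#'
#' @param f_number Lens f-number, > 0.
#' @param t_int_s Integration time in seconds, > 0.
#' @param magnification Optical magnification, >= 0 (0 for distant scenes).
#' @param detector_area_m2 Effective detector area in m2, > 0.
#' @param iso ISO speed setting (informational only).
#' @return An object of class `exposure_settings`.
#' @export
exposure_settings <- function(f_number, t_int_s, magnification = 0,
                              detector_area_m2 = 1e-10, iso = 200L) {
  if (f_number <= 0) stop("`f_number` must be positive", call. = FALSE)
  if (t_int_s <= 0) stop("`t_int_s` must be positive", call. = FALSE)
  if (magnification < 0) {
    stop("`magnification` must be non-negative", call. = FALSE)
  }
  if (detector_area_m2 <= 0) {
    stop("`detector_area_m2` must be positive", call. = FALSE)
  }
  structure(list(f_number = f_number, t_int_s = t_int_s,
                 magnification = magnification,
                 detector_area_m2 = detector_area_m2, iso = as.integer(iso)),
            class = "exposure_settings")
}

# linear interpolation of a spectrum's values onto a target grid
.interp_spectrum <- function(spec, grid) {
  stats::approx(spec$wavelength, spec$value, xout = grid, rule = 1)$y
}

#' Photoelectron-generating exposure from scene radiance
#'
#' Evaluates the standard camera equation
#' n = pi * A_d * t_int / (4 f#^2 (1 + m)^2) * integral L(l) S(l) T(l) dl,
#' giving the photon amount (umol-equivalent) that generates photoelectrons
#' at a pixel site.  Spectra are linearly interpolated onto the radiance
#' grid restricted to the common wavelength overlap, the integration range
#' is clipped to wavelengths where the sensitivity is non-zero, and the
#' integral is evaluated by the trapezoidal rule.
#'
#' @param radiance A `spectrum` of kind `radiance_photon`.
#' @param sens A `spectrum` of kind `sensitivity`.
#' @param trans A `spectrum` of kind `transmittance`.
#' @param settings An `exposure_settings` object.
#' @return Scalar photon amount (umol-equivalent units).
#' @export
exposure_integral <- function(radiance, sens, trans, settings) {
  stopifnot(inherits(radiance, "spectrum"), inherits(sens, "spectrum"),
            inherits(trans, "spectrum"),
            inherits(settings, "exposure_settings"))
  if (spectrum_kind(radiance) != "radiance_photon") {
    stop("`radiance` must be a 'radiance_photon' spectrum; ",
         "convert with energy_to_photon_flux()", call. = FALSE)
  }
  lo <- max(min(radiance$wavelength), min(sens$wavelength),
            min(trans$wavelength))
  hi <- min(max(radiance$wavelength), max(sens$wavelength),
            max(trans$wavelength))
  grid <- radiance$wavelength[radiance$wavelength >= lo &
                                radiance$wavelength <= hi]
  if (length(grid) < 2L) {
    stop("spectra have no usable common wavelength overlap", call. = FALSE)
  }
  L <- .interp_spectrum(radiance, grid)
  S <- .interp_spectrum(sens, grid)
  Tt <- .interp_spectrum(trans, grid)
  nz <- which(S > 0)
  if (length(nz) >= 2L) {
    keep <- seq(min(nz), max(nz))
    grid <- grid[keep]; L <- L[keep]; S <- S[keep]; Tt <- Tt[keep]
  }
  integrand <- L * S * Tt
  integral <- sum(diff(grid) * (utils::head(integrand, -1) +
                                  utils::tail(integrand, -1)) / 2)
  pref <- pi * settings$detector_area_m2 * settings$t_int_s /
    (4 * settings$f_number^2 * (1 + settings$magnification)^2)
  pref * integral
}

#' Read a spectrum from a delimited text file
#'
#' Accepts two-column whitespace- or comma-delimited text (wavelength nm,
#' value), with an optional header line.
#'
#' @param path File path.
#' @param kind Spectrum kind to assign (see [spectrum()]).
#' @return A `spectrum`.
#' @export
read_spectrum <- function(path, kind = "radiance_energy") {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  has_header <- !grepl("^[[:space:]]*[-+0-9.eE]+[,[:space:]]", first)
  tab <- utils::read.table(path, sep = sep, header = has_header)
  spectrum(tab[[1]], tab[[2]], kind)
}
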