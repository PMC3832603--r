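# Whole-image linearisation pipeline: dark-frame subtraction, ROI
# sampling, per-pixel inversion via a per-level table, masking.  Includes
# a minimal uncompressed greyscale TIFF reader/writer (8- and 16-bit).

#' Raw camera image
#'
#' A single-channel grid of integer pixel intensity levels.
#'
#' @param pixels Numeric/integer matrix, all values in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth Integer bit depth (8 or 16); default 8.
#' @param channel Channel label.
#' @return An object of class `raw_image`.
#' @export
raw_image <- function(pixels, bit_depth = 8L, channel = "grey") {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("image must be non-empty", call. = FALSE)
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1)) {
    stop("pixel values outside [0, 2^bit_depth - 1]", call. = FALSE)
  }
  structure(list(pixels = round(pixels), bit_depth = as.integer(bit_depth),
                 channel = channel),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image> %dx%d, %d-bit, channel=%s\n", nrow(x$pixels),
              ncol(x$pixels), x$bit_depth, x$channel))
  invisible(x)
}

#' Subtract a dark frame from an image
#'
#' Per-pixel subtraction of a lens-capped dark frame, clipped at zero
#' (pixel intensities are non-negative by construction).
#'
#' @param img,dark `raw_image`s of identical shape, bit depth and channel.
#' @return The dark-corrected `raw_image`.
#' @export
dark_subtract <- function(img, dark) {
  stopifnot(inherits(img, "raw_image"), inherits(dark, "raw_image"))
  if (!identical(dim(img$pixels), dim(dark$pixels))) {
    stop("image and dark frame differ in shape", call. = FALSE)
  }
  if (img$bit_depth != dark$bit_depth) {
    stop("image and dark frame differ in bit depth", call. = FALSE)
  }
  out <- img
  out$pixels <- pmax(img$pixels - dark$pixels, 0)
  out
}

#' Mean response over a centred square region of interest
#'
#' Averages pixel intensity over a `size x size` window whose top-left
#' corner sits at `floor(dim / 2) - size %/% 2` in each axis (0-based), the
#' deterministic "centre of the image" convention used when measuring OECF
#' responses from test-chart frames.
#'
#' @param img A `raw_image` at least `size` pixels in each dimension.
#' @param size Window side length; default 50.
#' @return Scalar mean intensity.
#' @export
roi_mean <- function(img, size = 50L) {
  stopifnot(inherits(img, "raw_image"))
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (nr < size || nc < size) {
    stop("image (", nr, "x", nc, ") smaller than the ", size, "x", size,
         " ROI", call. = FALSE)
  }
  r0 <- floor(nr / 2) - size %/% 2L  # 0-based top-left
  c0 <- floor(nc / 2) - size %/% 2L
  mean(img$pixels[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size)])
}

# mask codes for linearised images
.MASK_OK <- 0L
.MASK_SATURATED <- 1L
.MASK_BELOW_PMIN <- 2L

#' Linearise a whole image
#'
#' Runs the full pipeline: optional dark-frame subtraction, normalisation,
#' per-pixel inversion of the camera gain, and rescaling to exposure
#' units.  Inversion uses a precomputed `2^bit_depth`-entry response-to-
#' exposure table (exact at integer levels), so megapixel images cost one
#' table lookup per pixel for either method.  Pixels at or above `g_max`
#' are flagged saturated and assigned the top exposure; pixels below the
#' Bezier `p_min`-equivalent are flagged and assigned the lowest
#' linearisable exposure.
#'
#' @param img A `raw_image`.
#' @param dark Optional dark-frame `raw_image`.
#' @param method `"biexp"` or `"bezier_lut"`.
#' @param calib A `biexp_params` (biexp) or `oecf_lut` on normalised axes
#'   (bezier_lut).
#' @param e_max Exposure anchor used to rescale to photon-amount units.
#' @param units `"umol"` (multiply by `e_max`) or `"normalised"` (leave on
#'   the `[0, 1]` exposure scale).
#' @return An object of class `linear_image`: `exposures` matrix, integer
#'   `mask` matrix (0 ok, 1 saturated, 2 below p_min), `method`, `units`.
#' @export
linearize_image <- function(img, dark = NULL,
                            method = c("biexp", "bezier_lut"), calib,
                            e_max = NULL, units = c("umol", "normalised")) {
  stopifnot(inherits(img, "raw_image"))
  method <- match.arg(method)
  units <- match.arg(units)
  if (!is.null(dark)) img <- dark_subtract(img, dark)
  n_levels <- 2^img$bit_depth
  lev <- 0:(n_levels - 1L)
  mask_tab <- rep(.MASK_OK, n_levels)
  if (method == "biexp") {
    if (!inherits(calib, "biexp_params")) {
      stop("biexp linearisation needs a `biexp_params` calibration",
           call. = FALSE)
    }
    scale_div <- if (calib$scale == "normalised") n_levels - 1 else 1
    p_fit <- lev / scale_div
    sat <- p_fit >= calib$g_max
    p_fit[sat] <- calib$g_max
    e_top <- invert_biexp(calib, calib$g_max)
    expo_tab <- invert_biexp(calib, p_fit) / e_top
    mask_tab[sat] <- .MASK_SATURATED
  } else {
    if (!inherits(calib, "oecf_lut")) {
      stop("bezier_lut linearisation needs an `oecf_lut` calibration",
           call. = FALSE)
    }
    p_norm <- lev / (n_levels - 1)
    lo <- calib$response[1]; hi <- calib$response[nrow(calib)]
    below <- p_norm < lo
    sat <- p_norm > hi
    p_clamp <- pmin(pmax(p_norm, lo), hi)
    x_top <- calib$exposure[nrow(calib)]
    expo_tab <- stats::approx(calib$response, calib$exposure,
                              xout = p_clamp, ties = "ordered")$y / x_top
    mask_tab[below] <- .MASK_BELOW_PMIN
    mask_tab[sat] <- .MASK_SATURATED
  }
  if (units == "umol") {
    if (is.null(e_max)) {
      e_max <- if (method == "biexp") calib$e_max else NULL
    }
    if (is.null(e_max)) {
      stop("`e_max` is required for umol output units", call. = FALSE)
    }
    expo_tab <- expo_tab * e_max
  }
  idx <- img$pixels + 1L
  structure(list(
    exposures = matrix(expo_tab[idx], nrow(img$pixels)),
    mask = matrix(mask_tab[idx], nrow(img$pixels)),
    method = method, units = units, channel = img$channel
  ), class = "linear_image")
}

#' @export
print.linear_image <- function(x, ...) {
  cat(sprintf(
    "<linear_image> %dx%d, method=%s, units=%s, %d saturated, %d below p_min\n",
    nrow(x$exposures), ncol(x$exposures), x$method, x$units,
    sum(x$mask == .MASK_SATURATED), sum(x$mask == .MASK_BELOW_PMIN)))
  invisible(x)
}

## ---- minimal TIFF I/O (uncompressed greyscale, little-endian) ----------

#' Write a greyscale image as an uncompressed TIFF
#'
#' Minimal baseline-TIFF writer: single strip, 8- or 16-bit greyscale,
#' little-endian, no compression.  Suitable for the calibration images this
#' package produces and consumes; not a general TIFF library.
#'
#' @param img A `raw_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path) {
  stopifnot(inherits(img, "raw_image"))
  px <- img$pixels
  bits <- if (img$bit_depth <= 8) 8L else 16L
  con <- file(path, "wb")
  on.exit(close(con))
  w <- ncol(px); h <- nrow(px)
  bytes_pp <- bits / 8L
  data_len <- w * h * bytes_pp
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(8 + data_len), con, size = 4,
           endian = "little")  # IFD offset
  # pixel data, row-major
  vals <- as.integer(t(px))
  writeBin(vals, con, size = bytes_pp, endian = "little")
  tags <- list(
    c(256L, 3L, 1L, w),          # ImageWidth
    c(257L, 3L, 1L, h),          # ImageLength
    c(258L, 3L, 1L, bits),       # BitsPerSample
    c(259L, 3L, 1L, 1L),         # Compression = none
    c(262L, 3L, 1L, 1L),         # Photometric = BlackIsZero
    c(273L, 4L, 1L, 8L),         # StripOffsets
    c(277L, 3L, 1L, 1L),         # SamplesPerPixel
    c(278L, 3L, 1L, h),          # RowsPerStrip
    c(279L, 4L, 1L, data_len)    # StripByteCounts
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    tg <- as.integer(tg)
    writeBin(tg[1], con, size = 2, endian = "little")
    writeBin(tg[2], con, size = 2, endian = "little")
    writeBin(tg[3], con, size = 4, endian = "little")
    writeBin(tg[4], con, size = 4, endian = "little")
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

#' Read an uncompressed greyscale TIFF
#'
#' Counterpart of [write_tiff()]; understands little-endian baseline TIFFs
#' with 8- or 16-bit greyscale samples, no compression, one sample per
#' pixel, one or more strips.
#'
#' @param path TIFF path.
#' @param channel Channel label to attach.
#' @return A `raw_image`.
#' @export
read_tiff <- function(path, channel = "grey") {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) {
    as.integer(raw_all[off + 1]) + 256L * as.integer(raw_all[off + 2])
  }
  u32 <- function(off) {
    sum(as.numeric(raw_all[off + 1:4]) * 256^(0:3))
  }
  if (rawToChar(raw_all[1:2]) != "II" || u16(2) != 42L) {
    stop("not a little-endian TIFF file", call. = FALSE)
  }
  ifd <- u32(4)
  n_tags <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_tags)) {
    off <- ifd + 2 + (i - 1) * 12
    id <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
    val <- if (type == 3L && count == 1L) u16(off + 8) else u32(off + 8)
    tags[[as.character(id)]] <- list(type = type, count = count, val = val,
                                     off = off + 8)
  }
  need <- function(id) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) stop("TIFF missing required tag ", id, call. = FALSE)
    t
  }
  w <- need(256)$val; h <- need(257)$val
  bits <- if (is.null(tags[["258"]])) 8L else tags[["258"]]$val
  comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]$val
  if (comp != 1L) stop("only uncompressed TIFFs are supported",
                       call. = FALSE)
  if (!bits %in% c(8L, 16L)) {
    stop("only 8- or 16-bit greyscale TIFFs are supported", call. = FALSE)
  }
  read_vec <- function(tag) {
    if (tag$count == 1L) return(tag$val)
    base <- tag$val
    sz <- if (tag$type == 3L) 2 else 4
    vapply(seq_len(tag$count), function(k) {
      if (sz == 2) u16(base + (k - 1) * 2) else u32(base + (k - 1) * 4)
    }, numeric(1))
  }
  offs <- read_vec(need(273))
  counts <- read_vec(need(279))
  bytes <- unlist(lapply(seq_along(offs), function(k) {
    raw_all[(offs[k] + 1):(offs[k] + counts[k])]
  }))
  vals <- readBin(bytes, "integer", n = w * h, size = bits / 8,
                  signed = FALSE, endian = "little")
  raw_image(matrix(vals, nrow = h, byrow = TRUE), bit_depth = bits,
            channel = channel)
}

#' Write a linearised image and its mask
#'
#' The exposure plane is written as a 16-bit TIFF scaled to the full range
#' (the scale factor is returned), and the mask as an 8-bit TIFF of codes
#' 0 (ok), 1 (saturated), 2 (below p_min).
#'
#' @param limg A `linear_image`.
#' @param path Output TIFF path; the mask goes to `<path>.mask.tif`.
#' @return A list with `path`, `mask_path` and `scale` (exposure units per
#'   digital number), invisibly.
#' @export
write_linear_tiff <- function(limg, path) {
  stopifnot(inherits(limg, "linear_image"))
  top <- max(limg$exposures)
  scale <- if (top > 0) top / 65535 else 1
  q <- round(limg$exposures / scale)
  write_tiff(raw_image(q, 16L, limg$channel), path)
  mask_path <- paste0(path, ".mask.tif")
  write_tiff(raw_image(limg$mask, 8L, limg$channel), mask_path)
  invisible(list(path = path, mask_path = mask_path, scale = scale))
}
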