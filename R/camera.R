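#' Relative spectral power of a Planck blackbody illuminant
#'
#' @param wavelength Wavelengths in nm.
#' @param temperature Colour temperature in kelvin.
#' @return Relative power (scaled so the maximum over the input grid is 1).
#' @export
planck_illuminant <- function(wavelength, temperature = 3000) {
  stopifnot(temperature > 0)
  c2 <- 1.4387768775e7  # second radiation constant, nm K
  p <- wavelength^-5 / (exp(c2 / (wavelength * temperature)) - 1)
  p / max(p)
}

#' Camera rendering model
#'
#' A simple colorimeter model of a consumer camera imaging a sample under a
#' tungsten-like illuminant: three Gaussian channel sensitivities, a Planck
#' blackbody illuminant, per-channel white-balance gains, an exposure scalar
#' and gamma encoding. With `white_balance = "tungsten"` the gains are preset
#' so a flat 100% reflector renders neutral (R = G = B) under the
#' illuminant; with `"none"` all channels share a single scale, so the
#' illuminant's red-rich spectrum shows through (the yellow cast of the bare
#' silicon mirror under a 3000 K lamp).
#'
#' @param centers_nm Channel centres in nm, `(R, G, B)` order; default
#'   `c(600, 540, 465)`.
#' @param fwhm_nm Full width at half maximum of each channel in nm
#'   (default 80, recycled to length 3).
#' @param illuminant_K Blackbody colour temperature in kelvin (default 3000).
#' @param white_balance `"tungsten"` (neutralize the illuminant) or `"none"`.
#' @param exposure Linear scale applied before encoding; default 0.85 so a
#'   flat unit reflector sits just below clipping.
#' @param gamma `"srgb"` for sRGB encoding, or a numeric exponent (1 =
#'   linear).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(centers_nm = c(600, 540, 465), fwhm_nm = 80,
                         illuminant_K = 3000,
                         white_balance = c("tungsten", "none"),
                         exposure = 0.85, gamma = "srgb") {
  white_balance <- match.arg(white_balance)
  stopifnot(length(centers_nm) == 3L, all(fwhm_nm > 0), exposure > 0)
  fwhm_nm <- rep_len(fwhm_nm, 3L)
  structure(list(centers_nm = centers_nm, fwhm_nm = fwhm_nm,
                 illuminant_K = illuminant_K, white_balance = white_balance,
                 exposure = exposure, gamma = gamma),
            class = "camera_model")
}

# Channel sensitivity curves on a wavelength grid: 3 x n matrix.
camera_sensitivities <- function(camera, wavelength) {
  sigma <- camera$fwhm_nm / (2 * sqrt(2 * log(2)))
  t(vapply(1:3, function(c) {
    exp(-0.5 * ((wavelength - camera$centers_nm[c]) / sigma[c])^2)
  }, numeric(length(wavelength))))
}

srgb_encode <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Render a reflectance spectrum to a camera RGB triplet
#'
#' Each linear channel is
#' \eqn{gain_c \cdot exposure \cdot \int S_c(\lambda) I(\lambda) R(\lambda)\,
#' d\lambda} (trapezoidal rule), with gains from the camera's white-balance
#' mode, followed by gamma encoding, scaling to `[0, 255]` and clipping. By
#' default the triplet is returned as a continuous value: it models the
#' *mean* RGB over an ROI of ~1e5 pixels, which carries sub-count precision
#' even though each pixel is 8-bit. Set `quantize = TRUE` for rounded 8-bit
#' values.
#'
#' @param spec A [reflectance_spectrum()] covering the sensitivity support.
#' @param camera A [camera_model()].
#' @param quantize Round to whole 8-bit counts (default `FALSE`).
#' @return Numeric `(R, G, B)` in `[0, 255]`.
#' @export
render_rgb <- function(spec, camera = camera_model(), quantize = FALSE) {
  stopifnot(inherits(spec, "reflectance_spectrum"),
            inherits(camera, "camera_model"))
  wl <- spec$wavelengths
  S <- camera_sensitivities(camera, wl)
  I <- planck_illuminant(wl, camera$illuminant_K)
  trapz <- function(y) sum(diff(wl) * (y[-1] + y[-length(y)]) / 2)
  white <- vapply(1:3, function(c) trapz(S[c, ] * I), numeric(1))
  if (all(white == 0)) return(c(0, 0, 0))
  gains <- switch(camera$white_balance,
                  tungsten = 1 / white,
                  none = rep(1 / mean(white), 3L))
  lin <- vapply(1:3, function(c) trapz(S[c, ] * I * spec$reflectance),
                numeric(1))
  v <- pmin(1, pmax(0, gains * camera$exposure * lin))
  enc <- if (identical(camera$gamma, "srgb")) srgb_encode(v) else v^(1 / camera$gamma)
  out <- pmin(255, pmax(0, 255 * enc))
  if (quantize) out <- round(out)
  out
}

#' RGB time series container
#'
#' @param times Times in minutes (increasing).
#' @param rgb Numeric matrix `n x 3` with values in `[0, 255]`.
#' @return An object of class `rgb_series` (a data frame `time_min, R, G, B`).
#' @export
rgb_series <- function(times, rgb) {
  rgb <- as.matrix(rgb)
  stopifnot(is.numeric(times), nrow(rgb) == length(times), ncol(rgb) == 3L)
  if (any(diff(times) <= 0)) stop(input_error("times must be increasing"))
  if (any(rgb < 0 | rgb > 255)) {
    stop(input_error("RGB values must lie in [0, 255]"))
  }
  structure(data.frame(time_min = times, R = rgb[, 1], G = rgb[, 2],
                       B = rgb[, 3]),
            class = c("rgb_series", "data.frame"))
}

#' Render a spectrum series to an RGB series
#'
#' @param series A `degradation_spectra` object.
#' @param camera A [camera_model()].
#' @param quantize Passed to [render_rgb()].
#' @return An [rgb_series()].
#' @export
render_rgb_series <- function(series, camera = camera_model(),
                              quantize = FALSE) {
  rgb <- t(vapply(series$spectra, render_rgb, numeric(3), camera = camera,
                  quantize = quantize))
  rgb_series(series$times, rgb)
}

#' Write / read an RGB series as CSV
#'
#' Columns `time_min, R, G, B`.
#'
#' @param series An [rgb_series()].
#' @param path CSV file path.
#' @return `write_rgb_series()` returns `path` invisibly; `read_rgb_series()`
#'   returns an [rgb_series()].
#' @export
write_rgb_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rgb_series
#' @export
read_rgb_series <- function(path) {
  d <- utils::read.csv(path)
  rgb_series(d$time_min, as.matrix(d[, c("R", "G", "B")]))
}
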