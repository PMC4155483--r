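#' HSV hue of an RGB triplet on the 0--1 scale
#'
#' Standard hexcone hue: with `M = max(R,G,B)`, `m = min(R,G,B)` and
#' `C = M - m`,
#' `h' = (G-B)/C` if `M = R`, `(B-R)/C + 2` if `M = G`, `(R-G)/C + 4` if
#' `M = B`; the hue is `h'/6`, wrapped into `[0, 1)` by adding 1 when
#' negative (the 0--360 degree convention divided by 360). Achromatic
#' triplets (`M = m`) have no defined hue and return `NA`.
#'
#' Hue is invariant under positive scaling of the triplet, which is what
#' makes it robust to overall brightness changes.
#'
#' @param rgb Numeric `(R, G, B)` with channels in `[0, 255]`.
#' @return Hue in `[0, 1)`, or `NA` for achromatic input.
#' @examples
#' compute_hue(c(255, 0, 0))   # 0
#' compute_hue(c(0, 255, 0))   # 1/3
#' compute_hue(c(128, 128, 128))  # NA
#' @export
compute_hue <- function(rgb) {
  if (!is.numeric(rgb) || length(rgb) != 3L || any(!is.finite(rgb))) {
    stop(input_error("rgb must be a numeric triplet"))
  }
  if (any(rgb < 0 | rgb > 255)) {
    stop(input_error("rgb channels must lie in [0, 255]"))
  }
  M <- max(rgb); m <- min(rgb); C <- M - m
  if (C == 0) return(NA_real_)
  hp <- if (rgb[1] == M) {
    (rgb[2] - rgb[3]) / C
  } else if (rgb[2] == M) {
    (rgb[3] - rgb[1]) / C + 2
  } else {
    (rgb[1] - rgb[2]) / C + 4
  }
  h <- hp / 6
  if (h < 0) h <- h + 1
  h
}

#' Reference-patch colour balance
#'
#' Per-channel scaling chosen so that a reference patch (a part of the scene
#' known to be neutral, e.g. dry silicon wafer outside the flow cell) maps to
#' neutral gray at its own mean luminance: channel `c` is multiplied by
#' `mean(reference) / reference[c]`. The result is clipped to `[0, 255]`.
#' Pre-clipping, the operation is invariant to a common scaling of sample and
#' reference.
#'
#' @param rgb Sample triplet in `[0, 255]`.
#' @param reference_rgb Reference-patch triplet; all channels must be > 0.
#' @return Balanced triplet in `[0, 255]`.
#' @export
reference_balance <- function(rgb, reference_rgb) {
  if (!is.numeric(rgb) || length(rgb) != 3L ||
      !is.numeric(reference_rgb) || length(reference_rgb) != 3L) {
    stop(input_error("rgb and reference_rgb must be numeric triplets"))
  }
  if (any(reference_rgb <= 0)) {
    stop(input_error("reference channels must all be > 0"))
  }
  scale <- mean(reference_rgb) / reference_rgb
  pmin(255, pmax(0, rgb * scale))
}

#' Independent min--max normalization of each RGB channel over time
#'
#' Rescales each channel independently using its own minimum and maximum
#' over the whole degradation time course,
#' `x'(t) = (x(t) - min) / (max - min)`, then maps back to `[0, 255]` so the
#' result can be fed to [compute_hue()]. A constant channel maps to
#' mid-scale (127.5): it carries no information but must not divide by zero.
#' The operation is invariant to any per-channel affine rescaling with
#' positive slope, which is why the resulting H parameter does not depend on
#' white-balance gains or exposure.
#'
#' @param series An [rgb_series()] with at least 2 frames.
#' @return An [rgb_series()] with unit-scaled channels on `[0, 255]`.
#' @export
minmax_normalize_channels <- function(series) {
  if (!inherits(series, "rgb_series")) {
    stop(input_error("series must be an rgb_series"))
  }
  if (nrow(series) < 2L) {
    stop(input_error("min-max normalization needs at least 2 frames"))
  }
  rgb <- as.matrix(series[, c("R", "G", "B")])
  out <- apply(rgb, 2, function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(127.5, length(x))
    else (x - rng[1]) / diff(rng) * 255
  })
  rgb_series(series$time_min, out)
}

#' Hue, H parameter and normalized H for an RGB time series
#'
#' Computes, per frame: the raw hue of the as-acquired mean RGB (`hue`), the
#' *H parameter* -- the hue of the min--max-normalized channels
#' (`h_param`) -- and the series-normalized
#' `h_norm = (H - H_initial) / (H_max - H_initial)`, which is 0 at the first
#' frame and 1 at the series maximum. The raw hue responds to the dominant
#' reflected colour and is confounded at long times by the broadband lamp
#' reflection off the bare substrate; the H parameter removes per-channel
#' offset and gain and stays monotone through complete degradation.
#'
#' @param series An [rgb_series()] with at least 2 frames.
#' @return An object of class `hue_series`: data frame `time_min, hue,
#'   h_param, h_norm`.
#' @export
compute_h_parameter <- function(series) {
  if (!inherits(series, "rgb_series")) {
    stop(input_error("series must be an rgb_series"))
  }
  if (nrow(series) < 2L) stop(input_error("need at least 2 frames"))
  rgb <- as.matrix(series[, c("R", "G", "B")])
  hue <- apply(rgb, 1, compute_hue)
  norm <- minmax_normalize_channels(series)
  h_param <- apply(as.matrix(norm[, c("R", "G", "B")]), 1, compute_hue)
  if (all(is.na(h_param))) {
    warning(rugatecam_warning("all frames achromatic: H parameter undefined",
                              "rugatecam_achromatic"))
    h_norm <- rep(NA_real_, nrow(series))
  } else {
    h0 <- h_param[which(!is.na(h_param))[1]]
    hmax <- max(h_param, na.rm = TRUE)
    h_norm <- if (hmax > h0) (h_param - h0) / (hmax - h0)
      else rep(0, nrow(series))
  }
  structure(data.frame(time_min = series$time_min, hue = hue,
                       h_param = h_param, h_norm = h_norm),
            class = c("hue_series", "data.frame"))
}

#' Initial colour-based degradation rate
#'
#' OLS rate fit of the normalized H parameter over a window (see
#' [fit_rate()]); the initial `h_norm` slope ranks sample stability the same
#' way the spectrophotometric EOT and rugate-shift rates do.
#'
#' @param series A `hue_series` from [compute_h_parameter()].
#' @param window `(t_start, t_end)` in minutes; default first 25 min.
#' @return A `rate_fit`.
#' @export
color_rate <- function(series, window = NULL) {
  if (!inherits(series, "hue_series")) {
    stop(input_error("series must be a hue_series"))
  }
  fit_rate(series$time_min, series$h_norm, window)
}

#' Write / read a hue series as CSV
#'
#' Columns `time_min, hue, h_param, h_norm`.
#'
#' @param series A `hue_series`.
#' @param path CSV file path.
#' @return `write_hue_series()` returns `path` invisibly; `read_hue_series()`
#'   returns the data frame.
#' @export
write_hue_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hue_series
#' @export
read_hue_series <- function(path) {
  d <- utils::read.csv(path)
  structure(d, class = c("hue_series", "data.frame"))
}
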