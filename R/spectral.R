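# Three-point parabolic interpolation around a local maximum at index i.
# Returns fractional offset in [-0.5, 0.5] (0 when the curvature degenerates).
parabolic_offset <- function(y_lo, y_mid, y_hi) {
  den <- y_lo - 2 * y_mid + y_hi
  if (!is.finite(den) || abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (y_lo - y_hi) / den
  max(-0.5, min(0.5, off))
}

#' Locate the rugate stop-band peak in a reflectance spectrum
#'
#' Wavelength of maximum reflectance within a search band, refined to
#' sub-grid precision by three-point parabolic interpolation. If the maximum
#' sits on the band edge (as for the featureless, slowly varying spectrum of
#' the bare substrate) the result carries an `edge = TRUE` attribute and an
#' `rugatecam_edge_peak` warning is signalled; a flat spectrum raises an
#' error.
#'
#' @param spec A [reflectance_spectrum()].
#' @param search_band Numeric `(min_nm, max_nm)` within the grid.
#' @param flat_tol Relative reflectance range below which the band is
#'   declared flat (no peak).
#' @return Peak wavelength in nm (with attribute `edge` when flagged).
#' @export
find_rugate_peak <- function(spec, search_band = NULL, flat_tol = 1e-6) {
  stopifnot(inherits(spec, "reflectance_spectrum"))
  wl <- spec$wavelengths; R <- spec$reflectance
  if (is.null(search_band)) search_band <- range(wl)
  if (search_band[1] >= search_band[2] ||
      search_band[1] < min(wl) || search_band[2] > max(wl)) {
    stop(input_error("search_band must be an increasing range within the grid"))
  }
  keep <- wl >= search_band[1] & wl <= search_band[2]
  if (sum(keep) < 3L) stop(input_error("search band contains < 3 grid points"))
  wlb <- wl[keep]; Rb <- R[keep]
  if (diff(range(Rb)) <= flat_tol * max(max(Rb), .Machine$double.eps)) {
    stop(numeric_error("spectrum is flat in the search band: no peak"))
  }
  i <- which.max(Rb)
  if (i == 1L || i == length(Rb)) {
    warning(rugatecam_warning("reflectance maximum lies on the search-band edge",
                              "rugatecam_edge_peak"))
    return(structure(wlb[i], edge = TRUE))
  }
  # a saturated stop band has a flat top: take the midpoint of the contiguous
  # near-maximum run; otherwise refine the sharp maximum parabolically
  run_lo <- i; run_hi <- i
  thr <- Rb[i] * (1 - 1e-3)
  while (run_lo > 1L && Rb[run_lo - 1L] >= thr) run_lo <- run_lo - 1L
  while (run_hi < length(Rb) && Rb[run_hi + 1L] >= thr) run_hi <- run_hi + 1L
  if (run_hi - run_lo >= 2L) {
    return(structure((wlb[run_lo] + wlb[run_hi]) / 2, edge = FALSE))
  }
  off <- parabolic_offset(Rb[i - 1L], Rb[i], Rb[i + 1L])
  # local grid spacing (grid may be non-uniform)
  step <- if (off >= 0) wlb[i + 1L] - wlb[i] else wlb[i] - wlb[i - 1L]
  structure(wlb[i] + off * step, edge = FALSE)
}

#' Effective optical thickness by FFT of Fabry-Perot fringes (RIFTS)
#'
#' Implements the standard reflectometric-interference Fourier transform
#' pipeline: the reflectance is resampled by linear interpolation onto a
#' uniform wavenumber (1/wavelength) grid, a best-fit line in the wavenumber
#' domain is subtracted (mean + linear baseline, suppressing the
#' zero-frequency lobe), a Hann window is applied, the signal is zero-padded
#' to at least 2^16 points and the FFT magnitude is taken. Because a film of
#' effective optical thickness 2nL contributes a fringe term
#' \eqn{\cos(2\pi k \cdot 2nL)} in \eqn{k = 1/\lambda}, the FFT frequency
#' axis in cycles per nm^-1 *is* the EOT axis in nm; peaks are reported in
#' micrometres, largest amplitude first, refined by parabolic interpolation.
#'
#' The `resolution` field is the physical Fourier limit
#' \eqn{\lambda_{min}\lambda_{max} / (2(\lambda_{max}-\lambda_{min}))}
#' (about 0.33 um on the default 400--1000 nm grid); zero padding
#' interpolates the spectrum well below this but cannot resolve two films
#' closer than it.
#'
#' @param spec A [reflectance_spectrum()] spanning at least 100 nm.
#' @param n_peaks Number of peaks requested (>= 1). If fewer local maxima
#'   rise above the noise floor (3x the median FFT magnitude) the available
#'   ones are returned with a warning.
#' @param band Optional `(min_nm, max_nm)` sub-range to transform (the
#'   fringe-bearing portion of the spectrum); default whole grid.
#' @param min_eot_um Ignore FFT content below this EOT (residual baseline
#'   lobe), default 2 um.
#' @param min_fringe Minimum detectable fringe amplitude in reflectance
#'   units (absolute noise-floor guard), default 1e-4.
#' @param n_pad FFT length after zero padding (>= 2^16, rounded up to a power
#'   of two).
#' @return An object of class `eot_result`: list with `peak_positions`
#'   (um, by descending amplitude; ties broken towards the smaller EOT),
#'   `peak_amplitudes`, `resolution` (um) and `n_found`.
#' @export
compute_eot <- function(spec, n_peaks = 1, band = NULL, min_eot_um = 2,
                        n_pad = 2^16, min_fringe = 1e-4) {
  stopifnot(inherits(spec, "reflectance_spectrum"))
  if (!is.numeric(n_peaks) || n_peaks < 1) {
    stop(input_error("n_peaks must be >= 1"))
  }
  wl <- spec$wavelengths; R <- spec$reflectance
  if (!is.null(band)) {
    keep <- wl >= band[1] & wl <= band[2]
    wl <- wl[keep]; R <- R[keep]
  }
  if (length(wl) < 16L || diff(range(wl)) < 100) {
    stop(input_error("spectrum must span at least 100 nm"))
  }
  lmin <- min(wl); lmax <- max(wl)
  resolution_um <- lmin * lmax / (2 * (lmax - lmin)) / 1000
  # uniform wavenumber grid (nm^-1), increasing
  k <- rev(1 / wl); y <- rev(R)
  N <- length(k)
  kg <- seq(k[1], k[N], length.out = N)
  yi <- stats::approx(k, y, kg)$y
  # subtract mean + linear baseline in k
  fit <- stats::lm.fit(cbind(1, kg), yi)
  yi <- yi - fit$fitted.values
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, N - 1) / (N - 1)))
  yw <- yi * hann
  npad <- 2^max(16, ceiling(log2(N)))
  if (n_pad > npad) npad <- 2^ceiling(log2(n_pad))
  mag <- Mod(stats::fft(c(yw, rep(0, npad - N))))[1:(npad %/% 2)]
  dk <- kg[2] - kg[1]
  eot_nm <- (seq_len(npad %/% 2) - 1) / (npad * dk)
  usable <- eot_nm >= min_eot_um * 1000
  # noise floor: 3x the median magnitude, plus an absolute guard equivalent
  # to a fringe of amplitude min_fringe in reflectance units (suppresses
  # numerical dust on featureless spectra, e.g. the bare substrate)
  floor_level <- max(3 * stats::median(mag[usable]),
                     min_fringe * sum(hann) / 2)
  # local maxima above the noise floor
  idx <- which(usable)
  idx <- idx[idx > 1L & idx < length(mag)]
  is_max <- mag[idx] >= mag[idx - 1L] & mag[idx] > mag[idx + 1L] &
    mag[idx] > floor_level
  peaks_i <- idx[is_max]
  if (length(peaks_i) == 0L) {
    warning(rugatecam_warning("no FFT peaks above the noise floor",
                              "rugatecam_no_eot_peak"))
    return(structure(list(peak_positions = numeric(0),
                          peak_amplitudes = numeric(0),
                          resolution = resolution_um, n_found = 0L),
                     class = "eot_result"))
  }
  pos <- vapply(peaks_i, function(i) {
    off <- parabolic_offset(mag[i - 1L], mag[i], mag[i + 1L])
    (i - 1 + off) / (npad * dk)
  }, numeric(1))
  amp <- mag[peaks_i]
  # descending amplitude, ties towards the smaller EOT
  ord <- order(-amp, pos)
  pos <- pos[ord] / 1000; amp <- amp[ord]
  if (length(pos) < n_peaks) {
    warning(rugatecam_warning(
      sprintf("only %d of %d requested FFT peaks above the noise floor",
              length(pos), n_peaks), "rugatecam_few_eot_peaks"))
  }
  n_out <- min(n_peaks, length(pos))
  structure(list(peak_positions = pos[seq_len(n_out)],
                 peak_amplitudes = amp[seq_len(n_out)],
                 resolution = resolution_um,
                 n_found = length(pos)),
            class = "eot_result")
}

#' @export
print.eot_result <- function(x, ...) {
  cat(sprintf("<eot_result> %d peak(s), resolution %.3f um\n",
              length(x$peak_positions), x$resolution))
  if (length(x$peak_positions)) {
    cat(sprintf("  EOT = %s um (amplitude %s)\n",
                paste(formatC(x$peak_positions, digits = 4, format = "f"),
                      collapse = ", "),
                paste(formatC(x$peak_amplitudes, digits = 3, format = "g"),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Relative change in effective optical thickness
#'
#' `(EOT(t) - EOT(0)) / EOT(0) * 100`, the percentage drop in 2nL used to
#' compare degradation kinetics across samples.
#'
#' @param eot_t EOT at time t (um); vectorized.
#' @param eot_0 EOT at first exposure to the buffer (um, > 0).
#' @return Relative change in percent.
#' @export
relative_eot_change <- function(eot_t, eot_0) {
  if (!is.numeric(eot_0) || length(eot_0) != 1L || !is.finite(eot_0) ||
      eot_0 <= 0) {
    stop(input_error("eot_0 must be a positive number"))
  }
  (eot_t - eot_0) / eot_0 * 100
}

#' Assign FFT peaks to the pSi layer, the full stack and the overlayer
#'
#' For a capped porous layer the FFT of the reflectance shows two major
#' peaks: one from the porous layer itself and one from the full stack
#' (ambient/cap top interface against the substrate interface). The two
#' largest peaks are assigned by position (smaller EOT = pSi, larger = full
#' stack) and the cap overlayer follows from additivity,
#' `EOT_overlayer = EOT_full - EOT_pSi`.
#'
#' @param eot An `eot_result` from [compute_eot()] with at least 2 peaks.
#' @return Named list `pSi`, `full_stack`, `overlayer` (um).
#' @export
decompose_layers <- function(eot) {
  stopifnot(inherits(eot, "eot_result"))
  if (length(eot$peak_positions) < 2L) {
    stop(data_error("layer decomposition needs at least 2 FFT peaks"))
  }
  two <- eot$peak_positions[1:2]
  psi <- min(two); full <- max(two)
  list(pSi = psi, full_stack = full, overlayer = full - psi)
}

#' Ordinary least-squares rate fit over a time window
#'
#' Fits `value ~ time` by OLS over `[t_start, t_end]` (inclusive), ignoring
#' missing values. The slope sign is reported as-is; stability rankings use
#' its magnitude.
#'
#' @param times Times in minutes.
#' @param values Values (same length; NAs allowed and excluded).
#' @param window Numeric `(t_start, t_end)`; default the first 25 minutes of
#'   the data (the initial-rate window).
#' @return An object of class `rate_fit`: list with `slope`, `intercept`,
#'   `window`, `r_squared`, `n`.
#' @export
fit_rate <- function(times, values, window = NULL) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (is.null(window)) window <- c(min(times), min(times) + 25)
  if (length(window) != 2L || window[1] >= window[2]) {
    stop(input_error("window must be (t_start, t_end) with t_start < t_end"))
  }
  keep <- times >= window[1] & times <= window[2] & !is.na(values)
  if (sum(keep) < 3L) {
    stop(input_error("rate fit needs at least 3 non-missing points in window"))
  }
  t <- times[keep]; v <- values[keep]
  fit <- stats::lm(v ~ t)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 window = window, r_squared = r2, n = sum(keep)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> slope %.5g /min over [%g, %g] min (r2 = %.4f, n = %d)\n",
              x$slope, x$window[1], x$window[2], x$r_squared, x$n))
  invisible(x)
}

#' Analyze a degradation spectrum series
#'
#' Per time point: rugate-peak wavelength (band-limited maximum with
#' parabolic refinement), FFT-EOT with nearest-neighbour continuity tracking
#' across frames (the tracked peak is the detected FFT peak closest to the
#' previous frame's tracked EOT; the first frame takes the largest peak), and
#' the relative EOT change anchored at the first frame. Frames in which no
#' peak is detectable (e.g. the bare substrate after complete dissolution)
#' yield missing values rather than aborting the series.
#'
#' @param series A `degradation_spectra` object from
#'   [simulate_degradation_series()], or a list with `times` and `spectra`.
#' @param peak_band Search band (nm) for the rugate peak; default
#'   `(410, 850)`.
#' @param eot_band Optional fringe sub-range (nm) passed to [compute_eot()].
#' @param min_eot_um Lower EOT bound for FFT peaks (um).
#' @return A `data.frame` of class `degradation_series` with columns
#'   `time_min`, `rugate_peak_nm`, `eot_um`, `rel_eot_pct`.
#' @export
analyze_series <- function(series, peak_band = c(410, 850), eot_band = NULL,
                           min_eot_um = 2) {
  if (!is.list(series) || is.null(series$times) || is.null(series$spectra)) {
    stop(input_error("series must contain times and spectra"))
  }
  times <- series$times
  if (length(times) < 2L) stop(input_error("series needs >= 2 time points"))
  n <- length(times)
  peak <- rep(NA_real_, n); eot <- rep(NA_real_, n)
  prev_eot <- NA_real_
  for (i in seq_len(n)) {
    sp <- series$spectra[[i]]
    pk <- tryCatch(
      withCallingHandlers(
        find_rugate_peak(sp, peak_band),
        rugatecam_edge_peak = function(w) invokeRestart("muffleWarning")),
      error = function(e) NA_real_)
    if (!is.na(pk) && isTRUE(attr(pk, "edge"))) pk <- NA_real_
    peak[i] <- as.numeric(pk)
    er <- tryCatch(
      suppressWarnings(compute_eot(sp, n_peaks = 5, band = eot_band,
                                   min_eot_um = min_eot_um)),
      error = function(e) NULL)
    if (!is.null(er) && length(er$peak_positions) > 0) {
      eot[i] <- if (is.na(prev_eot)) {
        er$peak_positions[1]
      } else {
        er$peak_positions[which.min(abs(er$peak_positions - prev_eot))]
      }
      prev_eot <- eot[i]
    }
  }
  rel <- if (is.na(eot[1])) rep(NA_real_, n) else relative_eot_change(eot, eot[1])
  structure(data.frame(time_min = times, rugate_peak_nm = peak,
                       eot_um = eot, rel_eot_pct = rel),
            class = c("degradation_series", "data.frame"))
}

#' Write / read a degradation series as CSV
#'
#' Columns `time_min, rugate_peak_nm, eot_um, rel_eot_pct`.
#'
#' @param series A `degradation_series` data frame.
#' @param path CSV file path.
#' @return `write_degradation_series()` returns `path` invisibly;
#'   `read_degradation_series()` returns the data frame.
#' @export
write_degradation_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_degradation_series
#' @export
read_degradation_series <- function(path) {
  d <- utils::read.csv(path)
  structure(d, class = c("degradation_series", "data.frame"))
}
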