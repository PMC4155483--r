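#' Load a simulator/analysis configuration
#'
#' A single YAML file governs all pipeline stages (simulation, rendering,
#' fixture generation, analysis). Missing keys fall back to the documented
#' defaults; unknown top-level keys raise a config error naming the key.
#' Two ready-made configurations ship with the package:
#' `system.file("extdata", "fpsi.yaml", package = "rugatecam")` (freshly
#' etched pSi) and `"psi_ch.yaml"` (chitosan-coated).
#'
#' @param path YAML file path, or a list already parsed.
#' @return A config list with all defaults filled in.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  known <- c("sample", "seed", "wavelengths", "ambient", "substrate", "media",
             "film", "overlayer", "degradation", "time", "noise_sd",
             "camera", "images", "analysis")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop(input_error(sprintf("unknown config key(s): %s",
                             paste(bad, collapse = ", "))))
  }
  defaults <- list(
    sample = "sample", seed = 1L,
    wavelengths = list(min = 400, max = 1000, step = 0.5),
    ambient = "buffer", substrate = "si", media = list(),
    film = list(porosity = 0.534, thickness_um = 22.8,
                rugate_amplitude = 0.02, stopband_nm = 593,
                pore_fill = "buffer"),
    overlayer = NULL,
    degradation = list(dissolution_um_per_min = 0, porosity_per_min = 0,
                       oxidation_per_min = 0, shift_nm_per_min = NULL),
    time = list(start = 0, end = 300, step = 5),
    noise_sd = 0,
    camera = list(centers_nm = c(600, 540, 465), fwhm_nm = 80,
                  illuminant_K = 3000, white_balance = "none",
                  exposure = 0.85, gamma = "srgb"),
    images = list(size_px = 64, roi_radius_px = 24, noise_sd = 0),
    analysis = list(peak_band = c(410, 850), window = c(0, 25),
                    balance = TRUE)
  )
  merge_cfg <- function(def, got) {
    if (is.null(got)) return(def)
    if (!is.list(def)) return(got)
    for (k in names(got)) def[[k]] <- merge_cfg(def[[k]], got[[k]])
    def
  }
  out <- merge_cfg(defaults, cfg)
  if ("overlayer" %in% names(cfg)) out$overlayer <- cfg$overlayer
  out
}

config_media <- function(cfg) {
  media <- default_media()
  for (nm in names(cfg$media)) {
    spec <- cfg$media[[nm]]
    media[[nm]] <- optical_medium(nm, A = spec$A,
                                  B = if (is.null(spec$B)) 0 else spec$B)
  }
  media
}

#' Build the time-zero layer stack described by a configuration
#'
#' @param cfg A config list from [load_config()].
#' @return A [layer_stack()].
#' @export
config_stack <- function(cfg) {
  media <- config_media(cfg)
  get_medium <- function(name) {
    if (is.null(media[[name]])) {
      stop(input_error(sprintf("config names unknown medium '%s'", name)))
    }
    media[[name]]
  }
  f <- cfg$film
  period <- rugate_period_for(f$stopband_nm, f$porosity,
                              get_medium(cfg$substrate),
                              get_medium(f$pore_fill))
  film <- porous_layer(porosity = f$porosity, thickness = f$thickness_um,
                       skeleton = get_medium(cfg$substrate),
                       pore_fill = get_medium(f$pore_fill),
                       rugate_amplitude = f$rugate_amplitude,
                       rugate_period = period)
  layers <- list(film)
  if (!is.null(cfg$overlayer)) {
    layers <- c(list(uniform_layer(get_medium(cfg$overlayer$medium),
                                   cfg$overlayer$thickness_um)), layers)
  }
  layer_stack(layers, substrate = get_medium(cfg$substrate),
              ambient = get_medium(cfg$ambient))
}

#' Build the degradation trajectory described by a configuration
#'
#' If `degradation$shift_nm_per_min` is set, the porosity rate is solved with
#' [porosity_rate_for_shift()] so the stop band blue-shifts at that rate over
#' the initial-rate window; otherwise `porosity_per_min` is used directly.
#'
#' @param cfg A config list from [load_config()].
#' @param stack The matching [config_stack()] (rebuilt if omitted).
#' @return A [degradation_trajectory()].
#' @export
config_trajectory <- function(cfg, stack = config_stack(cfg)) {
  d <- cfg$degradation
  film <- Filter(function(l) inherits(l, "porous_layer"), stack$layers)[[1]]
  kp <- d$porosity_per_min
  if (!is.null(d$shift_nm_per_min)) {
    kp <- porosity_rate_for_shift(film, d$shift_nm_per_min,
                                  window = diff(range(cfg$analysis$window)),
                                  oxidation_rate = d$oxidation_per_min)
  }
  degradation_trajectory(
    dissolution_rate = d$dissolution_um_per_min,
    porosity_rate = kp,
    oxidation_rate = d$oxidation_per_min,
    t_grid = seq(cfg$time$start, cfg$time$end, by = cfg$time$step))
}

#' Build the camera model described by a configuration
#'
#' @param cfg A config list from [load_config()].
#' @return A [camera_model()].
#' @export
config_camera <- function(cfg) {
  camera_model(centers_nm = unlist(cfg$camera$centers_nm),
               fwhm_nm = unlist(cfg$camera$fwhm_nm),
               illuminant_K = cfg$camera$illuminant_K,
               white_balance = cfg$camera$white_balance,
               exposure = cfg$camera$exposure,
               gamma = cfg$camera$gamma)
}

#' Wavelength grid described by a configuration
#'
#' @param cfg A config list from [load_config()].
#' @return Numeric vector of wavelengths in nm.
#' @export
config_wavelengths <- function(cfg) {
  default_wavelengths(cfg$wavelengths$min, cfg$wavelengths$max,
                      cfg$wavelengths$step)
}

#' Simulate a degradation experiment: spectra files and an image stack
#'
#' Runs the optical forward model over the configured time grid, writes one
#' two-column spectrum file per time point (plus a `manifest.csv`), renders
#' each spectrum through the camera model and writes the synthetic image
#' stack. Deterministic for a given config and seed.
#'
#' @param config Config path or list (see [load_config()]).
#' @param out_dir Output directory; `spectra/` and `images/` are created
#'   inside.
#' @param seed Optional seed overriding the config's.
#' @return Invisibly, a list with `spectra_dir`, `images_dir`, the simulated
#'   `series` and the rendered `rgb`.
#' @export
cmd_simulate <- function(config, out_dir, seed = NULL) {
  cfg <- load_config(config)
  if (is.null(seed)) seed <- cfg$seed
  stack <- config_stack(cfg)
  traj <- config_trajectory(cfg, stack)
  wl <- config_wavelengths(cfg)
  series <- simulate_degradation_series(stack, traj, wl,
                                        noise_sd = cfg$noise_sd, seed = seed)
  spectra_dir <- file.path(out_dir, "spectra")
  dir.create(spectra_dir, recursive = TRUE, showWarnings = FALSE)
  fn <- sprintf("spectrum_%04d.txt", seq_along(series$times))
  for (i in seq_along(series$times)) {
    write_spectrum(series$spectra[[i]], file.path(spectra_dir, fn[i]))
  }
  utils::write.csv(data.frame(filename = fn, time_min = series$times),
                   file.path(spectra_dir, "manifest.csv"), row.names = FALSE)
  camera <- config_camera(cfg)
  rgb <- render_rgb_series(series, camera)
  images_dir <- file.path(out_dir, "images")
  generate_fixture_stack(rgb, images_dir,
                         noise_sd = cfg$images$noise_sd, seed = seed + 1L,
                         size_px = cfg$images$size_px,
                         roi_radius_px = cfg$images$roi_radius_px)
  invisible(list(spectra_dir = spectra_dir, images_dir = images_dir,
                 series = series, rgb = rgb))
}

#' Read a directory of spectrum files back into a series
#'
#' @param spectra_dir Directory written by [cmd_simulate()] (spectrum files
#'   plus `manifest.csv`).
#' @return A `degradation_spectra` object.
#' @export
read_spectra_dir <- function(spectra_dir) {
  manifest <- file.path(spectra_dir, "manifest.csv")
  if (!file.exists(manifest)) {
    stop(data_error(sprintf("no manifest.csv in '%s'", spectra_dir)))
  }
  man <- utils::read.csv(manifest)
  spectra <- lapply(file.path(spectra_dir, man$filename), read_spectrum)
  structure(list(times = man$time_min, spectra = spectra),
            class = "degradation_spectra")
}

#' Analyze simulated or measured data: degradation and hue series CSVs
#'
#' Runs the spectral analysis ([analyze_series()]) on the spectrum files and,
#' when an image directory is given, the colour analysis
#' ([extract_rgb_series()] + [compute_h_parameter()]) on the image stack.
#' Works in spectra-only mode when `images_dir` is `NULL`.
#'
#' @param spectra_dir Directory of spectrum files (see [read_spectra_dir()]).
#' @param images_dir Optional image-stack directory (see
#'   [read_masked_stack()]).
#' @param config Config path or list.
#' @param out_dir Output directory for `degradation.csv`, `rgb.csv`,
#'   `hue.csv`.
#' @param balance Apply the reference-patch balance when extracting RGB
#'   (default from config).
#' @return Invisibly, a list with `degradation` (data frame) and, with
#'   images, `rgb` and `hue`.
#' @export
cmd_analyze <- function(spectra_dir, images_dir = NULL, config = list(),
                        out_dir, balance = NULL) {
  cfg <- load_config(config)
  if (is.null(balance)) balance <- isTRUE(cfg$analysis$balance)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  series <- read_spectra_dir(spectra_dir)
  deg <- analyze_series(series, peak_band = unlist(cfg$analysis$peak_band))
  write_degradation_series(deg, file.path(out_dir, "degradation.csv"))
  out <- list(degradation = deg)
  if (!is.null(images_dir)) {
    stack <- read_masked_stack(images_dir)
    rgb <- extract_rgb_series(stack, balance = balance)
    hue <- compute_h_parameter(rgb)
    write_rgb_series(rgb, file.path(out_dir, "rgb.csv"))
    write_hue_series(hue, file.path(out_dir, "hue.csv"))
    out$rgb <- rgb
    out$hue <- hue
  }
  invisible(out)
}

#' Stability report across samples
#'
#' For each sample, fits the three initial degradation rates -- relative EOT
#' change (%/min), rugate-peak shift (nm/min) and normalized H parameter
#' (/min) -- over a common window, ranks the samples from most to least
#' stable per metric (smaller rate magnitude = more stable), and flags
#' whether all available metrics agree on the order.
#'
#' @param samples Named list; each element a list with `degradation` (a
#'   `degradation_series`) and optionally `hue` (a `hue_series`), as returned
#'   by [cmd_analyze()].
#' @param window `(t_start, t_end)` in minutes (default first 25 min).
#' @return An object of class `stability_report`: list with `rates` (data
#'   frame sample x metric), `ranking` (list per metric), `agreement`
#'   (logical) and `window`.
#' @export
stability_report <- function(samples, window = c(0, 25)) {
  if (!is.list(samples) || length(samples) < 1L || is.null(names(samples))) {
    stop(input_error("samples must be a named list"))
  }
  metrics <- c(rel_eot_pct_per_min = "rel_eot_pct",
               rugate_nm_per_min = "rugate_peak_nm",
               h_norm_per_min = "h_norm")
  rate_of <- function(sample, metric) {
    src <- if (metric == "h_norm") sample$hue else sample$degradation
    if (is.null(src) || !metric %in% names(src)) return(NA_real_)
    tryCatch(fit_rate(src$time_min, src[[metric]], window)$slope,
             error = function(e) NA_real_)
  }
  rates <- sapply(names(metrics), function(m) {
    vapply(samples, rate_of, numeric(1), metric = metrics[[m]])
  })
  rates <- matrix(rates, nrow = length(samples),
                  dimnames = list(names(samples), names(metrics)))
  ranking <- lapply(names(metrics), function(m) {
    r <- abs(rates[, m])
    if (all(is.na(r))) return(NULL)
    names(sort(r))  # most stable (smallest |rate|) first
  })
  names(ranking) <- names(metrics)
  avail <- Filter(Negate(is.null), ranking)
  agreement <- length(avail) <= 1L ||
    all(vapply(avail[-1], identical, logical(1), y = avail[[1]]))
  ties <- any(vapply(names(metrics), function(m) {
    r <- abs(rates[, m])
    anyDuplicated(r[!is.na(r)]) > 0
  }, logical(1)))
  structure(list(rates = as.data.frame(rates), ranking = ranking,
                 agreement = agreement, tied = ties, window = window),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> window [%g, %g] min\n",
              x$window[1], x$window[2]))
  print(round(x$rates, 6))
  for (m in names(x$ranking)) {
    if (!is.null(x$ranking[[m]]) && nrow(x$rates) > 1L) {
      cat(sprintf("  %s: %s (most to least stable)\n", m,
                  paste(x$ranking[[m]], collapse = " > ")))
    }
  }
  if (nrow(x$rates) > 1L) {
    cat(sprintf("  metric agreement: %s%s\n", x$agreement,
                if (x$tied) " (ties present)" else ""))
  }
  invisible(x)
}

#' End-to-end comparison report from analyzed sample directories
#'
#' Reads each sample's `degradation.csv` (and `hue.csv` when present) from
#' the directories written by [cmd_analyze()], builds the
#' [stability_report()], prints it, and writes `report.csv` (the rate table)
#' and `report.txt` (the printed report).
#'
#' @param sample_dirs Named character vector of analyzed-sample directories.
#' @param out_dir Output directory for the report files.
#' @param window Rate-fit window in minutes.
#' @return The `stability_report`, invisibly.
#' @export
cmd_report <- function(sample_dirs, out_dir, window = c(0, 25)) {
  if (is.null(names(sample_dirs)) || any(names(sample_dirs) == "")) {
    names(sample_dirs) <- basename(sample_dirs)
  }
  samples <- lapply(sample_dirs, function(d) {
    degf <- file.path(d, "degradation.csv")
    if (!file.exists(degf)) {
      stop(data_error(sprintf("no degradation.csv in '%s'", d)))
    }
    s <- list(degradation = read_degradation_series(degf))
    huef <- file.path(d, "hue.csv")
    if (file.exists(huef)) s$hue <- read_hue_series(huef)
    s
  })
  rep <- stability_report(samples, window)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cbind(sample = rownames(rep$rates), rep$rates),
                   file.path(out_dir, "report.csv"), row.names = FALSE)
  txt <- utils::capture.output(print(rep))
  writeLines(txt, file.path(out_dir, "report.txt"))
  print(rep)
  invisible(rep)
}
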