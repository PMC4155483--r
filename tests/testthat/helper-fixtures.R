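# Shared fixtures: media shortcuts, standard stacks, and a lazy cache for the
# expensive full-length simulations used by the acceptance tests.

med <- default_media()

# The characterized freshly etched film: p = 0.534, L = 22.8 um, stop band
# designed at 593 nm, pores filled by the degradation buffer.
make_fpsi_film <- function(porosity = 0.534, amplitude = 0.02,
                           stopband = 593, thickness = 22.8,
                           fill = med$buffer) {
  porous_layer(porosity, thickness, med$si, fill,
               rugate_amplitude = amplitude,
               rugate_period = rugate_period_for(stopband, porosity,
                                                 med$si, fill))
}

make_fpsi_stack <- function(...) {
  layer_stack(list(make_fpsi_film(...)), substrate = med$si,
              ambient = med$buffer)
}

# A small, fast film for unit tests (few periods, coarse grid).
make_small_stack <- function(porosity = 0.55, thickness = 5,
                             fill = med$buffer) {
  layer_stack(list(porous_layer(porosity, thickness, med$si, fill,
                                rugate_amplitude = 0.02,
                                rugate_period = rugate_period_for(
                                  593, porosity, med$si, fill))),
              substrate = med$si, ambient = med$buffer)
}

coarse_grid <- function(step = 2) default_wavelengths(step = step)

# Lazy cache shared across test files (the 61-frame simulations take tens of
# seconds each; several acceptance blocks reuse them).
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

run_config_pipeline <- function(config_name) {
  cfg_path <- system.file("extdata", config_name, package = "rugatecam")
  cfg <- load_config(cfg_path)
  stack <- config_stack(cfg)
  traj <- config_trajectory(cfg, stack)
  series <- simulate_degradation_series(stack, traj, config_wavelengths(cfg))
  deg <- analyze_series(series, peak_band = unlist(cfg$analysis$peak_band))
  rgb <- render_rgb_series(series, config_camera(cfg))
  hue <- compute_h_parameter(rgb)
  list(cfg = cfg, series = series, degradation = deg, rgb = rgb, hue = hue)
}

fulldeg_run <- function() cached("fulldeg", run_config_pipeline("fulldeg.yaml"))
fpsi_run <- function() cached("fpsi", run_config_pipeline("fpsi.yaml"))
psich_run <- function() cached("psich", run_config_pipeline("psi_ch.yaml"))

# Circular unwrap for hue trajectories that cross the red/magenta boundary:
# values above 0.5 are read as negative (hue is periodic with period 1).
unwrap_hue <- function(h) ifelse(!is.na(h) & h > 0.5, h - 1, h)
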