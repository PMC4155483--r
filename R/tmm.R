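#' Reflectance spectrum container
#'
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param reflectance Reflectance values in `[0, 1]` (a numerical slack of
#'   1e-9 is tolerated and clamped).
#' @return An object of class `reflectance_spectrum` (a list with
#'   `wavelengths` and `reflectance`).
#' @export
reflectance_spectrum <- function(wavelengths, reflectance) {
  stopifnot(is.numeric(wavelengths), is.numeric(reflectance))
  if (length(wavelengths) != length(reflectance)) {
    stop(input_error("wavelengths and reflectance must have equal length"))
  }
  if (length(wavelengths) < 2L || any(diff(wavelengths) <= 0)) {
    stop(input_error("wavelengths must be strictly increasing"))
  }
  if (any(reflectance < -1e-9 | reflectance > 1 + 1e-9)) {
    stop(input_error("reflectance must lie in [0, 1] (1e-9 slack)"))
  }
  structure(list(wavelengths = wavelengths,
                 reflectance = pmin(1, pmax(0, reflectance))),
            class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> %d points, %.4g-%.4g nm, R in [%.4g, %.4g]\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

#' Default wavelength grid
#'
#' 400--1000 nm at 0.5 nm, matching the working range of the reflectance
#' spectrometer setup the package models.
#'
#' @param min,max,step Grid limits and spacing in nm.
#' @return Numeric vector of wavelengths.
#' @export
default_wavelengths <- function(min = 400, max = 1000, step = 0.5) {
  seq(min, max, by = step)
}

# Flatten a stack into slabs: list(n = matrix [n_lambda x n_slab], d_nm =
# vector). Rugate layers are discretized at >= `sub_per_period` sublayers per
# period with the porosity profile anchored at the layer bottom (so top-down
# dissolution removes profile from the top). Sublayer porosities are clipped
# to [0, 1].
stack_slabs <- function(stack, wavelengths, sub_per_period = 20) {
  ns <- list(); ds <- numeric(0)
  for (l in stack$layers) {
    if (inherits(l, "uniform_layer")) {
      ns <- c(ns, list(medium_index(l$medium, wavelengths) + 0 * wavelengths))
      ds <- c(ds, l$thickness * 1000)
    } else if (l$rugate_amplitude == 0 || is.null(l$rugate_period)) {
      ns <- c(ns, list(bruggeman_index(min(1, max(0, l$porosity)),
                                       l$skeleton, l$pore_fill, wavelengths) +
                         0 * wavelengths))
      ds <- c(ds, l$thickness * 1000)
    } else {
      d_sub <- l$rugate_period / sub_per_period
      n_sub <- max(1L, as.integer(ceiling(l$thickness / d_sub)))
      d_sub <- l$thickness / n_sub
      # midpoint depth measured from the bottom of the layer
      z_mid <- l$thickness - (seq_len(n_sub) - 0.5) * d_sub
      p <- pmin(1, pmax(0, l$porosity +
                          l$rugate_amplitude * sin(2 * pi * z_mid / l$rugate_period)))
      eps_sk <- medium_index(l$skeleton, wavelengths)^2
      eps_f <- medium_index(l$pore_fill, wavelengths)^2
      for (j in seq_len(n_sub)) {
        ns <- c(ns, list(bruggeman_eps(p[j], eps_sk, eps_f)))
        ds <- c(ds, d_sub * 1000)
      }
    }
  }
  list(n = ns, d_nm = ds)
}

#' Simulate normal-incidence reflectance of a layer stack
#'
#' Characteristic-matrix (transfer-matrix) reflectance of the stack at normal
#' incidence with real (lossless) indices. Rugate layers are discretized into
#' at least `sub_per_period` sublayers per porosity period, each sublayer's
#' index coming from [bruggeman_index()]. For lossless films the
#' characteristic matrix has real diagonal and purely imaginary off-diagonal
#' entries, which the implementation exploits to run in real arithmetic,
#' vectorized over the wavelength grid.
#'
#' The output shows the expected physics: a stop band near
#' \eqn{2 n_{eff}(\bar p) \Lambda} for rugate layers and Fabry-Perot fringes
#' with wavenumber spacing \eqn{1/(2nL)}.
#'
#' @param stack A [layer_stack()].
#' @param wavelengths Strictly increasing grid in nm
#'   (default [default_wavelengths()]).
#' @param sub_per_period Sublayers per rugate period (default 20;
#'   convergence-tested against 40).
#' @return A [reflectance_spectrum()].
#' @examples
#' si <- default_media("si"); air <- default_media("air")
#' bare <- layer_stack(list(), substrate = si, ambient = air)
#' simulate_reflectance(bare, seq(400, 1000, by = 10))
#' @export
simulate_reflectance <- function(stack, wavelengths = default_wavelengths(),
                                 sub_per_period = 20) {
  stopifnot(inherits(stack, "layer_stack"))
  if (!is.numeric(wavelengths) || length(wavelengths) < 2L ||
      any(diff(wavelengths) <= 0)) {
    stop(input_error("wavelengths must be strictly increasing"))
  }
  slabs <- stack_slabs(stack, wavelengths, sub_per_period)
  n0 <- medium_index(stack$ambient, wavelengths)
  ns <- medium_index(stack$substrate, wavelengths)
  # M = [[a, i b], [i c, d]] with a, b, c, d real
  a <- rep(1, length(wavelengths)); b <- numeric(length(wavelengths))
  cc <- numeric(length(wavelengths)); d <- rep(1, length(wavelengths))
  two_pi <- 2 * pi
  for (j in seq_along(slabs$d_nm)) {
    n <- slabs$n[[j]]
    delta <- two_pi * n * slabs$d_nm[j] / wavelengths
    Cd <- cos(delta); Sd <- sin(delta)
    a2 <- a * Cd - b * n * Sd
    b2 <- a * Sd / n + b * Cd
    c2 <- cc * Cd + d * n * Sd
    d2 <- d * Cd - cc * Sd / n
    a <- a2; b <- b2; cc <- c2; d <- d2
  }
  num_re <- n0 * a - ns * d
  num_im <- n0 * ns * b - cc
  den_re <- n0 * a + ns * d
  den_im <- n0 * ns * b + cc
  R <- (num_re^2 + num_im^2) / (den_re^2 + den_im^2)
  reflectance_spectrum(wavelengths, pmin(1, pmax(0, R)))
}

#' Simulate a time series of degrading reflectance spectra
#'
#' Applies [evolve_stack()] at every time in the trajectory's grid and runs
#' [simulate_reflectance()], optionally adding seeded Gaussian reflectance
#' noise (clamped to `[0, 1]`). Deterministic given inputs and seed.
#'
#' @param stack Time-zero [layer_stack()].
#' @param traj A [degradation_trajectory()] (its `t_grid` sets the cadence,
#'   e.g. every 5 min to 300 min).
#' @param wavelengths Wavelength grid in nm.
#' @param noise_sd Additive Gaussian reflectance noise SD (default 0).
#' @param seed Optional RNG seed for the noise; the caller's RNG state is
#'   restored afterwards.
#' @param sub_per_period Rugate discretization (see [simulate_reflectance()]).
#' @return An object of class `degradation_spectra`: a list with `times`
#'   (minutes) and `spectra` (list of [reflectance_spectrum()]).
#' @export
simulate_degradation_series <- function(stack, traj,
                                        wavelengths = default_wavelengths(),
                                        noise_sd = 0, seed = NULL,
                                        sub_per_period = 20) {
  stopifnot(inherits(traj, "degradation_trajectory"))
  if (length(traj$t_grid) < 1L) stop(input_error("empty t_grid"))
  spectra <- lapply(traj$t_grid, function(t) {
    simulate_reflectance(evolve_stack(stack, traj, t), wavelengths,
                         sub_per_period)
  })
  if (noise_sd > 0) {
    spectra <- with_seed(seed, lapply(spectra, function(s) {
      reflectance_spectrum(s$wavelengths,
                           pmin(1, pmax(0, s$reflectance +
                                          stats::rnorm(length(s$reflectance),
                                                       sd = noise_sd))))
    }))
  }
  structure(list(times = traj$t_grid, spectra = spectra),
            class = "degradation_spectra")
}

#' Write / read a reflectance spectrum as two-column text
#'
#' Plain delimited text with a `wavelength_nm reflectance` header and
#' deterministic 6-significant-digit values.
#'
#' @param spec A [reflectance_spectrum()].
#' @param path Output file path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns a [reflectance_spectrum()].
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "reflectance_spectrum"))
  lines <- c("wavelength_nm\treflectance",
             sprintf("%s\t%s",
                     formatC(spec$wavelengths, digits = 6, format = "g"),
                     formatC(spec$reflectance, digits = 6, format = "g")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[0-9.+-]", first)
  d <- utils::read.table(path, header = has_header)
  reflectance_spectrum(d[[1]], d[[2]])
}
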