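#' Porous silicon layer (optionally with a sinusoidal rugate profile)
#'
#' Describes a porous layer by its mean porosity, thickness, skeleton medium,
#' pore-filling medium and, when `rugate_amplitude > 0`, a sinusoidal porosity
#' depth profile \eqn{p(z) = \bar p + a\,\sin(2\pi z/\Lambda)} (z measured from
#' the layer bottom) which produces the narrow photonic stop band of a rugate
#' filter at \eqn{\lambda \approx 2\,n_{eff}(\bar p)\,\Lambda}.
#'
#' @param porosity Mean pore volume fraction in `[0, 1]`.
#' @param thickness Layer thickness in micrometres (> 0). May be omitted when
#'   `n_periods` and `rugate_period` are given (then
#'   `thickness = n_periods * rugate_period`).
#' @param skeleton,pore_fill [optical_medium()] for the solid skeleton (Si or
#'   a Si/SiO2 blend) and the pore content (air, ethanol, buffer, ...).
#' @param rugate_amplitude Porosity-modulation amplitude `a >= 0`
#'   (dimensionless); `porosity +/- a` must stay within `[0, 1]`.
#' @param rugate_period Spatial period of the porosity modulation in
#'   micrometres (required when `rugate_amplitude > 0`).
#' @param n_periods Optional integer number of modulation periods.
#' @return An object of class `porous_layer`.
#' @seealso [rugate_period_for()] to place the stop band at a target
#'   wavelength, [layer_stack()].
#' @export
porous_layer <- function(porosity, thickness = NULL, skeleton, pore_fill,
                         rugate_amplitude = 0, rugate_period = NULL,
                         n_periods = NULL) {
  stopifnot(is.numeric(porosity), length(porosity) == 1L,
            inherits(skeleton, "optical_medium"),
            inherits(pore_fill, "optical_medium"),
            is.numeric(rugate_amplitude), rugate_amplitude >= 0)
  if (porosity < 0 || porosity > 1) stop(input_error("porosity must lie in [0, 1]"))
  if (porosity - rugate_amplitude < 0 || porosity + rugate_amplitude > 1) {
    stop(input_error("porosity +/- rugate_amplitude must stay within [0, 1]"))
  }
  if (rugate_amplitude > 0 && is.null(rugate_period)) {
    stop(input_error("rugate_amplitude > 0 requires a rugate_period"))
  }
  if (is.null(thickness)) {
    if (is.null(n_periods) || is.null(rugate_period)) {
      stop(input_error("either thickness or (n_periods, rugate_period) required"))
    }
    thickness <- n_periods * rugate_period
  }
  if (thickness <= 0) stop(input_error("thickness must be > 0"))
  structure(list(porosity = porosity, thickness = thickness,
                 skeleton = skeleton, pore_fill = pore_fill,
                 rugate_amplitude = rugate_amplitude,
                 rugate_period = rugate_period,
                 n_periods = n_periods),
            class = c("porous_layer", "rugatecam_layer"))
}

#' Uniform (non-porous) overlayer
#'
#' A homogeneous film, e.g. the spin-coated chitosan cap on top of the porous
#' silicon.
#'
#' @param medium [optical_medium()] of the film.
#' @param thickness Thickness in micrometres (> 0).
#' @return An object of class `uniform_layer`.
#' @export
uniform_layer <- function(medium, thickness) {
  stopifnot(inherits(medium, "optical_medium"),
            is.numeric(thickness), length(thickness) == 1L)
  if (thickness <= 0) stop(input_error("thickness must be > 0"))
  structure(list(medium = medium, thickness = thickness),
            class = c("uniform_layer", "rugatecam_layer"))
}

#' Layer stack: ambient / films / substrate
#'
#' @param layers List of [porous_layer()] / [uniform_layer()] objects ordered
#'   from the ambient side (top) to the substrate (bottom). May be empty (bare
#'   substrate).
#' @param substrate [optical_medium()] of the bulk substrate (crystalline Si).
#' @param ambient [optical_medium()] of the ambient (air, or the buffer in a
#'   flow cell).
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(layers, substrate, ambient) {
  stopifnot(is.list(layers),
            inherits(substrate, "optical_medium"),
            inherits(ambient, "optical_medium"))
  for (l in layers) {
    if (!inherits(l, "rugatecam_layer")) {
      stop(input_error("all layers must be porous_layer or uniform_layer"))
    }
  }
  structure(list(layers = layers, substrate = substrate, ambient = ambient),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> ambient=%s, substrate=%s, %d layer(s)\n",
              x$ambient$name, x$substrate$name, length(x$layers)))
  for (l in x$layers) {
    if (inherits(l, "porous_layer")) {
      cat(sprintf("  porous: p=%.3f L=%.3g um a=%.3g Lambda=%s um (%s in %s)\n",
                  l$porosity, l$thickness, l$rugate_amplitude,
                  if (is.null(l$rugate_period)) "-" else format(l$rugate_period, digits = 4),
                  l$skeleton$name, l$pore_fill$name))
    } else {
      cat(sprintf("  uniform: %s L=%.3g um\n", l$medium$name, l$thickness))
    }
  }
  invisible(x)
}

#' Linear-in-time degradation trajectory
#'
#' Parametrizes the two degradation mechanisms of hydride-terminated pSi in
#' aqueous media -- oxidation of the Si matrix and hydrolysis to soluble
#' silicates -- as three linear rates with clipping: top-down thickness loss
#' (`dissolution_rate`), pore-wall thinning seen as a porosity increase
#' (`porosity_rate`), and progressive Si-to-SiO2 conversion of the skeleton
#' (`oxidation_rate`).
#'
#' @param dissolution_rate Thickness loss in um/min (>= 0).
#' @param porosity_rate Porosity increase in fraction/min (>= 0).
#' @param oxidation_rate Skeleton oxidized-fraction increase in 1/min (>= 0).
#' @param t_grid Time grid in minutes, strictly increasing from 0.
#' @param oxide [optical_medium()] the skeleton oxidizes towards (silica).
#' @return An object of class `degradation_trajectory`.
#' @export
degradation_trajectory <- function(dissolution_rate = 0, porosity_rate = 0,
                                   oxidation_rate = 0,
                                   t_grid = seq(0, 300, by = 5),
                                   oxide = default_media("sio2")) {
  stopifnot(is.numeric(t_grid), length(t_grid) >= 1L)
  if (dissolution_rate < 0 || porosity_rate < 0 || oxidation_rate < 0) {
    stop(input_error("degradation rates must be >= 0"))
  }
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    stop(input_error("t_grid must be strictly increasing from 0"))
  }
  structure(list(dissolution_rate = dissolution_rate,
                 porosity_rate = porosity_rate,
                 oxidation_rate = oxidation_rate,
                 t_grid = t_grid, oxide = oxide),
            class = "degradation_trajectory")
}

#' Evolve a layer stack to time t under a degradation trajectory
#'
#' Porous layers lose thickness (`L(t) = max(0, L0 - k_L t)`, floored at 0),
#' gain porosity (`p(t) = min(1, p0 + k_p t)`, clipped), and their skeleton
#' index is blended linearly from the original skeleton towards the oxide by
#' the oxidized fraction `min(1, k_ox t)`. Uniform overlayers are untouched.
#' Fully dissolved layers (zero thickness) are removed, so after complete
#' dissolution the spectrum is that of the bare substrate.
#'
#' @param stack The time-zero [layer_stack()].
#' @param traj A [degradation_trajectory()].
#' @param t Time in minutes (>= 0).
#' @return The evolved `layer_stack`.
#' @export
evolve_stack <- function(stack, traj, t) {
  stopifnot(inherits(stack, "layer_stack"),
            inherits(traj, "degradation_trajectory"))
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop(input_error("t must be a single time >= 0"))
  }
  f_ox <- min(1, traj$oxidation_rate * t)
  layers <- list()
  for (l in stack$layers) {
    if (!inherits(l, "porous_layer")) { layers <- c(layers, list(l)); next }
    L <- max(0, l$thickness - traj$dissolution_rate * t)
    if (L <= 0) next
    p <- min(1, l$porosity + traj$porosity_rate * t)
    sk <- if (f_ox > 0) blend_media(l$skeleton, traj$oxide, f_ox) else l$skeleton
    # keep the modulation amplitude; sublayer porosities are clipped to [0,1]
    # when the profile is discretized, so the stop band fades as p -> 1
    a <- l$rugate_amplitude
    nl <- l
    nl$thickness <- L
    nl$porosity <- p
    nl$skeleton <- sk
    nl$rugate_amplitude <- a
    layers <- c(layers, list(nl))
  }
  layer_stack(layers, stack$substrate, stack$ambient)
}

#' Rugate period that places the stop band at a target wavelength
#'
#' Solves \eqn{\lambda_0 = 2 n_{eff}(\bar p; \lambda_0) \Lambda} for
#' \eqn{\Lambda} with the effective index evaluated at the target wavelength
#' itself, so the designed stack's stop band sits at `stopband_nm`.
#'
#' @param stopband_nm Target stop-band centre in nm.
#' @param porosity Mean porosity of the layer.
#' @param skeleton,pore_fill [optical_medium()] components.
#' @return Rugate period in micrometres.
#' @export
rugate_period_for <- function(stopband_nm, porosity, skeleton, pore_fill) {
  n <- bruggeman_index(porosity, skeleton, pore_fill, stopband_nm)
  (stopband_nm / (2 * n)) / 1000
}

#' Predicted stop-band centre wavelength of a rugate layer
#'
#' Fixed-point solution of \eqn{\lambda = 2 n_{eff}(\bar p; \lambda) \Lambda}
#' (a handful of iterations suffice for the mild Cauchy dispersion used here).
#'
#' @param layer A [porous_layer()] with `rugate_period` set.
#' @return Stop-band wavelength in nm.
#' @export
stopband_wavelength <- function(layer) {
  stopifnot(inherits(layer, "porous_layer"))
  if (is.null(layer$rugate_period)) {
    stop(input_error("layer has no rugate_period"))
  }
  lambda <- 600
  for (i in 1:30) {
    n <- bruggeman_index(layer$porosity, layer$skeleton, layer$pore_fill, lambda)
    lambda_new <- 2 * n * layer$rugate_period * 1000
    if (abs(lambda_new - lambda) < 1e-9) break
    lambda <- lambda_new
  }
  lambda
}

#' Porosity rate producing a target initial rugate blue-shift
#'
#' Finds the porosity increase rate `k_p` such that the stop-band wavelength
#' of `layer` shifts by `rate_nm_per_min` per minute on average over the first
#' `window` minutes (the initial-rate window used for stability ranking),
#' accounting for skeleton oxidation if `oxidation_rate > 0`.
#'
#' @param layer A rugate [porous_layer()] at time zero.
#' @param rate_nm_per_min Target blue-shift magnitude in nm/min (> 0).
#' @param window Averaging window in minutes (default 25).
#' @param oxidation_rate Skeleton oxidation rate also acting (1/min).
#' @param oxide Oxide medium (silica).
#' @return Porosity rate in fraction/min.
#' @export
porosity_rate_for_shift <- function(layer, rate_nm_per_min, window = 25,
                                    oxidation_rate = 0,
                                    oxide = default_media("sio2")) {
  stopifnot(inherits(layer, "porous_layer"), rate_nm_per_min > 0)
  lambda0 <- stopband_wavelength(layer)
  shift_at <- function(kp) {
    l <- layer
    l$porosity <- min(1, layer$porosity + kp * window)
    f_ox <- min(1, oxidation_rate * window)
    if (f_ox > 0) l$skeleton <- blend_media(layer$skeleton, oxide, f_ox)
    (lambda0 - stopband_wavelength(l)) / window
  }
  kp_max <- (1 - layer$porosity) / window
  if (shift_at(kp_max) < rate_nm_per_min) {
    stop(numeric_error("target shift rate not reachable before full porosity"))
  }
  stats::uniroot(function(kp) shift_at(kp) - rate_nm_per_min,
                 c(0, kp_max), tol = 1e-12)$root
}
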