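#' Effective optical thickness (2nL) of a porous layer
#'
#' Convenience forward model for SLIM: `2 * n_eff(p; fill) * L` at a reference
#' wavelength, in micrometres.
#'
#' @param porosity Pore fraction in `[0, 1]`.
#' @param thickness Thickness in micrometres.
#' @param skeleton,fill [optical_medium()] components.
#' @param wavelength_ref Reference wavelength in nm.
#' @return EOT in micrometres.
#' @export
eot_2nl <- function(porosity, thickness, skeleton, fill, wavelength_ref = 593) {
  2 * bruggeman_index(porosity, skeleton, fill, wavelength_ref) * thickness
}

#' SLIM inversion: porosity and thickness from two EOT measurements
#'
#' The spectroscopic liquid infiltration method measures the effective optical
#' thickness of the same porous layer with two pore fillings (air, then a
#' liquid of known index). Writing `EOT_air = 2 n_eff(p; air) L` and
#' `EOT_fill = 2 n_eff(p; fill) L` with the two-component Bruggeman mixing
#' rule leaves a 2x2 system whose porosity enters only through the index
#' ratio; it is solved by a bracketed one-dimensional root search in
#' `p` over (0, 1), after which `L` follows directly.
#'
#' @param eot_air EOT measured with air-filled pores, in micrometres (> 0).
#' @param eot_fill EOT measured with liquid-filled pores, in micrometres
#'   (> `eot_air` when the liquid index exceeds 1: infiltration raises EOT).
#' @param skeleton [optical_medium()] of the skeleton (Si).
#' @param fill [optical_medium()] of the infiltration liquid (e.g. ethanol).
#' @param wavelength_ref Reference wavelength in nm for the index evaluation.
#' @return A list with elements `porosity` and `thickness` (micrometres).
#' @examples
#' si <- default_media("si"); eth <- default_media("ethanol")
#' air <- default_media("air")
#' ea <- eot_2nl(0.534, 22.8, si, air)
#' ef <- eot_2nl(0.534, 22.8, si, eth)
#' slim_invert(ea, ef, si, eth)
#' @export
slim_invert <- function(eot_air, eot_fill, skeleton, fill,
                        wavelength_ref = 593) {
  stopifnot(inherits(skeleton, "optical_medium"),
            inherits(fill, "optical_medium"))
  if (!is.numeric(eot_air) || !is.numeric(eot_fill) || eot_air <= 0) {
    stop(input_error("EOTs must be positive numbers"))
  }
  n_fill_ref <- medium_index(fill, wavelength_ref)
  if (abs(n_fill_ref - 1) < 1e-9) {
    stop(inconsistent_error(
      "fill medium is optically identical to air: SLIM system is degenerate"))
  }
  if (n_fill_ref > 1 && eot_fill <= eot_air) {
    stop(inconsistent_error(
      "infiltration by a liquid with n > 1 must raise the EOT"))
  }
  ratio <- eot_fill / eot_air
  g <- function(p) {
    bruggeman_index(p, skeleton, fill, wavelength_ref) /
      bruggeman_index(p, skeleton, default_media("air"), wavelength_ref) - ratio
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0) {
    stop(inconsistent_error(
      "no porosity in (0, 1) is consistent with the EOT pair"))
  }
  p <- stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
  n_air <- bruggeman_index(p, skeleton, default_media("air"), wavelength_ref)
  list(porosity = p, thickness = eot_air / (2 * n_air))
}
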