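#' Optical medium with a Cauchy dispersion model
#'
#' A lossless (real-index) medium whose refractive index follows the two-term
#' Cauchy form \eqn{n(\lambda) = A + B/\lambda^2} with \eqn{\lambda} in nm.
#' Absorption is neglected throughout the package: on the 400--1000 nm working
#' range the films of interest are thin enough that a real index reproduces
#' the interference structure (stop band and Fabry-Perot fringes) that the
#' analysis relies on.
#'
#' @param name Character label (e.g. `"si"`, `"air"`).
#' @param A Cauchy constant term (index at infinite wavelength); must give
#'   `n >= 1` on 400--1000 nm.
#' @param B Cauchy dispersion term in nm^2 (0 for a non-dispersive medium).
#' @return An object of class `optical_medium`.
#' @examples
#' si <- optical_medium("si", A = 3.42, B = 1e4)
#' medium_index(si, c(400, 593, 1000))
#' @export
optical_medium <- function(name, A, B = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(B), length(B) == 1L, is.finite(B))
  m <- structure(list(name = name, A = A, B = B), class = "optical_medium")
  n <- medium_index(m, c(400, 1000))
  if (any(n < 1)) {
    stop(input_error(sprintf(
      "medium '%s' has refractive index < 1 on 400-1000 nm", name)))
  }
  m
}

#' @export
print.optical_medium <- function(x, ...) {
  cat(sprintf("<optical_medium> %s: n(lambda) = %g + %g/lambda^2  (n@593nm = %.4f)\n",
              x$name, x$A, x$B, medium_index(x, 593)))
  invisible(x)
}

#' Evaluate the refractive index of a medium
#'
#' @param medium An [optical_medium()].
#' @param wavelength Wavelengths in nm (vectorized).
#' @return Numeric vector of (real) refractive indices.
#' @export
medium_index <- function(medium, wavelength) {
  stopifnot(inherits(medium, "optical_medium"), is.numeric(wavelength))
  medium$A + medium$B / wavelength^2
}

#' Linearly blend two media
#'
#' Returns a medium whose index is `(1 - frac) * n_a + frac * n_b` at every
#' wavelength (exact for Cauchy media, since the index is linear in the
#' coefficients). Used to model progressive oxidation of the silicon skeleton
#' towards silica.
#'
#' @param a,b [optical_medium()] objects.
#' @param frac Blend fraction in `[0, 1]` (0 = pure `a`, 1 = pure `b`).
#' @return An `optical_medium`.
#' @export
blend_media <- function(a, b, frac) {
  stopifnot(inherits(a, "optical_medium"), inherits(b, "optical_medium"),
            is.numeric(frac), length(frac) == 1L, frac >= 0, frac <= 1)
  optical_medium(sprintf("%s+%s(%.3f)", a$name, b$name, frac),
                 A = (1 - frac) * a$A + frac * b$A,
                 B = (1 - frac) * a$B + frac * b$B)
}

#' Built-in optical media
#'
#' The default constants used across the package: silicon as a two-term Cauchy
#' fit (A = 3.42 with mild visible dispersion), silica n = 1.46, ethanol
#' n = 1.36, the 1:1 ethanol/aqueous buffer n = 1.35, chitosan n = 1.54 and
#' air n = 1. These are configuration values, overridable in the simulator
#' config file.
#'
#' @param name Optional single medium to retrieve (e.g. `"si"`); with no
#'   argument the full named list is returned.
#' @return A named list of `optical_medium` objects, or a single one.
#' @export
default_media <- function(name = NULL) {
  media <- list(
    si       = optical_medium("si",       A = 3.42, B = 1e4),
    sio2     = optical_medium("sio2",     A = 1.46),
    ethanol  = optical_medium("ethanol",  A = 1.36),
    buffer   = optical_medium("buffer",   A = 1.35),
    chitosan = optical_medium("chitosan", A = 1.54),
    air      = optical_medium("air",      A = 1.0)
  )
  if (is.null(name)) return(media)
  if (!name %in% names(media)) {
    stop(input_error(sprintf("unknown built-in medium '%s'", name)))
  }
  media[[name]]
}

#' Bruggeman effective-medium index of a two-component composite
#'
#' Solves the symmetric two-component Bruggeman condition
#' \deqn{(1-p)\frac{\epsilon_{sk}-\epsilon}{\epsilon_{sk}+2\epsilon} +
#'       p\frac{\epsilon_f-\epsilon}{\epsilon_f+2\epsilon} = 0}
#' for the effective permittivity \eqn{\epsilon = n_{eff}^2} of a porous
#' skeleton (volume fraction `1 - porosity`) whose pores are filled by a
#' second medium (volume fraction `porosity`), and returns
#' \eqn{n_{eff} = \sqrt{\epsilon}}. The physical root (the positive root of
#' the underlying quadratic, which always lies between the two component
#' permittivities) is taken in closed form.
#'
#' @param porosity Pore volume fraction in `[0, 1]` (vectorized).
#' @param skeleton,fill [optical_medium()] objects for the solid skeleton and
#'   the pore-filling medium.
#' @param wavelength Wavelength(s) in nm (vectorized; recycled against
#'   `porosity`).
#' @return Effective refractive index (numeric, between the two component
#'   indices).
#' @examples
#' si <- default_media("si"); air <- default_media("air")
#' bruggeman_index(0.534, si, air, 593)
#' @export
bruggeman_index <- function(porosity, skeleton, fill, wavelength) {
  if (any(!is.finite(porosity)) || any(porosity < 0) || any(porosity > 1)) {
    stop(input_error("porosity must lie in [0, 1]"))
  }
  eps_sk <- medium_index(skeleton, wavelength)^2
  eps_f  <- medium_index(fill, wavelength)^2
  bruggeman_eps(porosity, eps_sk, eps_f)
}

# Closed-form positive root of 2*eps^2 - b*eps - eps_sk*eps_f/2 = 0 where
# b = (2-3p)*eps_sk + (3p-1)*eps_f; returns n_eff = sqrt(eps). Vectorized.
bruggeman_eps <- function(p, eps_sk, eps_f) {
  b <- (2 - 3 * p) * eps_sk + (3 * p - 1) * eps_f
  disc <- b^2 + 8 * eps_sk * eps_f
  if (any(disc < 0)) {
    stop(numeric_error("Bruggeman discriminant negative; no physical root"))
  }
  eps <- (b + sqrt(disc)) / 4
  lo <- pmin(eps_sk, eps_f) * (1 - 1e-12)
  hi <- pmax(eps_sk, eps_f) * (1 + 1e-12)
  if (any(eps < lo | eps > hi)) {
    stop(numeric_error("Bruggeman root outside the admissible bracket"))
  }
  sqrt(eps)
}
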