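---
title: "Models and methods behind rugatecam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rugatecam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rugatecam` follows the degradation of porous silicon (pSi) rugate photonic
crystals two ways: through their reflectance spectra (peak position and
effective optical thickness) and through the colour recorded by an ordinary
camera (hue and the normalized *H parameter*). This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not capture.

## Optical model

**Media.** Every medium is lossless with a two-term Cauchy index
$n(\lambda) = A + B/\lambda^2$ ($\lambda$ in nm). Defaults: silicon
$A = 3.42$, $B = 10^4\,\mathrm{nm}^2$ (mild visible dispersion); silica
$n = 1.46$; ethanol $n = 1.36$; the 1:1 ethanol/pH-10 buffer $n = 1.35$;
chitosan $n = 1.54$; air $n = 1$. These are configuration values, not code.
Neglecting absorption is the significant simplification: real silicon
absorbs strongly below ~500 nm, which damps the blue end of measured
spectra. The interference structure the analysis relies on — the stop band
and the Fabry–Pérot fringes — survives the simplification; absolute
reflectance levels in the blue do not.

**Effective medium.** A porous layer of porosity $p$ is homogenized with the
symmetric two-component Bruggeman condition
$(1-p)\frac{\varepsilon_{sk}-\varepsilon}{\varepsilon_{sk}+2\varepsilon} +
p\frac{\varepsilon_f-\varepsilon}{\varepsilon_f+2\varepsilon} = 0$, solved
in closed form (positive root of the underlying quadratic, which always lies
between the component permittivities). The tests cross-check this root
against a brute-force sign-change scan of the residual at $10^{-6}$
resolution.

**Reflectance.** Normal-incidence characteristic (transfer) matrices. For
lossless films the matrix has real diagonal and purely imaginary
off-diagonal entries, so the whole recursion runs in real arithmetic,
vectorized over the wavelength grid; this is fast enough that no compiled
code is needed (a 3 400-sublayer film on the 1 201-point grid takes well
under a second). A rugate layer with porosity profile
$p(z) = \bar p + a\sin(2\pi z/\Lambda)$ (anchored at the layer bottom, so
top-down dissolution removes profile from the top) is discretized at 20
sublayers per period, each homogenized independently. Convergence against 40
sublayers: stop-band position moves by at most one grid step (0.5 nm), the
FFT-extracted EOT by ~0.003 µm, and off-band reflectance by <0.2%;
pointwise differences at the steep stop-band *edges* can reach a few
percent, which no quantity in the pipeline depends on.

**Film geometry.** The characterized film is $p = 0.534$, $L = 22.8$ µm.
The modulation amplitude and period are not published, so they are set by
two observable constraints: the period places the stop band at 593 nm
through $\lambda_0 = 2 n_\mathrm{eff}(\bar p;\lambda_0)\Lambda$ (solved
self-consistently in the dispersion), and the amplitude $a = 0.02$ gives a
band ~18 nm wide at half maximum, inside the 10–30 nm range typical of
these filters. Larger amplitudes produce a saturated band >50 nm wide,
visibly unlike the narrow-band samples. The chitosan cap is modelled as a
uniform overlayer; its bundled thickness (5.58 µm) is chosen so its optical
thickness $2nL$ equals the 17.2 µm that the layer-decomposition worked
example uses.

## Degradation model

Three mechanisms, each linear in time with clipping, acting on porous layers
only:

| parameter | units | meaning | bundled values |
|---|---|---|---|
| `dissolution_um_per_min` | µm/min | top-down thickness loss, floored at 0 | 0 |
| `porosity_per_min` | 1/min | pore-wall thinning, $p$ clipped to [0, 1] | solved (below) or 0.00466 |
| `oxidation_per_min` | 1/min | Si→SiO₂ skeleton conversion (index blended linearly) | 0.002 |

Linear-with-clipping is the simplest parametrization that reproduces the
observed monotone blue shift and EOT loss; it makes the evolved film's EOT
non-increasing in time by construction. The bundled configurations put the
degradation in the *porosity* channel rather than the thickness channel
because the validated experiments conclude the films degrade by dissolution
of the pore walls rather than from the top down, and because it keeps the
fringe spacing (~6 nm in wavelength) dense throughout the run, so the
camera-channel integrals stay smooth. When $p$ reaches 1 the film is
optically the buffer and the spectrum is continuously the bare-substrate
Fresnel one.

Rather than prescribing a porosity rate directly, a configuration can state
the observable it should produce: `shift_nm_per_min` makes
`porosity_rate_for_shift()` solve for the rate at which the stop band
blue-shifts by that amount per minute averaged over the initial-rate window.
The bundled samples use the two measured shift rates, 1.33 nm/min (fpSi) and
1.99 nm/min (chitosan-coated); with these the fpSi film completes
degradation near the end of the 300-min run. A third configuration
(`fulldeg.yaml`) instead empties the pores at exactly 100 min
($k_p = (1-0.534)/100$) to exercise the bare-silicon tail that confounds the
raw hue.

## Spectral analysis (RIFTS, SLIM)

`compute_eot()` resamples the reflectance by linear interpolation onto a
uniform $k = 1/\lambda$ grid, removes the best-fit line in $k$ (mean plus
linear baseline, suppressing the zero-frequency lobe), applies a Hann
window, zero-pads to $2^{16}$ points and takes the FFT magnitude. A film of
optical thickness $2nL$ contributes $\cos(2\pi k \cdot 2nL)$, so the
frequency axis *is* the EOT axis. Peaks are local maxima above a noise
floor, refined parabolically, sorted by amplitude (ties towards the smaller
EOT). The floor is 3× the median magnitude *and* at least the response of a
fringe of amplitude $10^{-4}$ in reflectance units — the absolute guard is
what keeps a featureless bare-substrate spectrum from yielding
numerical-dust peaks. Content below 2 µm EOT is ignored as residual
baseline. The reported `resolution`,
$\lambda_{\min}\lambda_{\max}/(2(\lambda_{\max}-\lambda_{\min}))$ (0.33 µm
on the default 400–1000 nm grid), is the physical two-film resolution
limit; a *single* clean fringe frequency is located far more precisely
(the oracle tests recover constructed frequencies to ~0.0003 µm).

Because silicon's index is dispersive, the fringe frequency of a real pSi
layer drifts across the spectrum (a chirp): the FFT peak measures the
*group* optical thickness, sits a few percent above the mid-band phase
$2nL$, and can carry substructure. The time-series tracker
(`analyze_series()`) therefore follows the peak nearest to the previous
frame's value (largest peak in the first frame) instead of re-ranking by
amplitude each frame; frames with no detectable peak (bare substrate)
become missing values and are excluded from rate fits.

`find_rugate_peak()` returns the in-band maximum refined by three-point
parabolic interpolation; when the stop band is saturated ($R \approx 1$
plateau) it returns the plateau midpoint instead, since a parabola fitted to
a flat top is biased to the first grid point. An extremum on the band edge
is flagged (`edge` attribute, warning) and treated as missing by the series
analyzer. `slim_invert()` reduces the two-filling system to one equation in
$p$ (the EOT ratio equals the index ratio), solved by bracketed root search
on (0, 1); round trips recover $(p, L)$ to $10^{-14}$ relative on noiseless
input, and physically impossible pairs (infiltration lowering the EOT, or
identical media) raise classed errors instead of spurious answers.

Rate fits are ordinary least squares over a window, defaulting to the first
25 min — the "initial rate" window, chosen because the validated
experiments report distinct early and late kinetics with a change around
25 min. Whether the original rates were least-squares or endpoint slopes is
not stated; OLS is used because it degrades gracefully with missing frames.

## Camera model and the H parameter

Channel $c$ integrates $gain_c \cdot exposure \cdot \int S_c(\lambda)
I(\lambda) R(\lambda)\,d\lambda$ (trapezoid rule) with Gaussian
sensitivities (centres 600/540/465 nm, FWHM 80 nm — plausible consumer-CFA
curves, configurable since the actual camera's are unpublished) and a
Planck 3000 K illuminant. `white_balance = "tungsten"` presets the gains so
a flat reflector renders neutral; `"none"` applies a single common scale,
letting the red-rich tungsten spectrum show through — that mode reproduces
the yellow cast of the bare silicon mirror that makes the raw hue
non-monotonic at long times. The result is sRGB-encoded and scaled to
[0, 255] but *not* rounded by default: the quantity modelled is the mean
over ~10³–10⁵ ROI pixels, which carries sub-count precision (per-pixel
8-bit quantization happens in the image writer, and averaging recovers the
mean). Hue is computed on the encoded values, matching the use of
as-acquired camera files.

The *H parameter* is the hue of the min–max-normalized channels, each
channel scaled by its own extrema over the whole run (a retrospective,
whole-series operation; streaming use is out of scope). Normalization makes
the result invariant to any positive per-channel affine map — white-balance
gains, exposure, the reference-patch balance — which is why the colour
route needs no radiometric calibration. A constant channel maps to
mid-scale 127.5 (non-informative, but no division by zero); an achromatic
frame has no hue and is reported missing rather than 0. The normalized
$h_{norm} = (H - H_{initial})/(H_{max} - H_{initial})$ is anchored at 0 on
the first frame and 1 at the series maximum.

On the bundled full-dissolution run the H parameter rises monotonically
(within $10^{-6}$ numerical noise) through the entire 300-min series,
including the constant bare-silicon tail, while the raw hue rises and then
falls — the behaviour that motivates the parameter. The property is *not*
unconditional: once the stop band leaves the blue edge of the visible
range, the normalized hue can wrap across the red/magenta boundary (hue is
circular), and simulations confirm wrap-around for some geometries.
Property tests therefore assert strict monotonicity while the band remains
in the visible (≥450 nm) — verified across randomized configurations — and
full-series monotonicity for the study configuration specifically.

## Synthetic data: what it does and does not emulate

The generator reproduces the *structure* of the experiment: 5-min cadence
over 300 min, 400–1000 nm spectra at 0.5 nm, a narrow stop band on a
fringed background, monotone blue shift and EOT loss, complete dissolution
to a bare mirror, tungsten-lit 8-bit frames with a masked disc ROI and a
neutral reference patch, optional seeded Gaussian noise on reflectance and
pixels. It does not emulate: absorption and the resulting blue-end damping,
scattering or pore-size effects, illumination drift, bubbles or motion in
the flow cell, JPEG artefacts (fixtures are lossless PNG; a JPEG-robustness
mode would add compression, not determinism), or the gradual dissolution of
oxide residues that keeps real channels evolving after the film proper is
gone. Passing tests therefore demonstrate the *pipeline's* correctness and
the qualitative phenomenology, not instrument-level radiometric accuracy;
the measured rate *values* of any real sample depend on chemistry the
simulator only parametrizes.

## Numerical choices and degenerate inputs

* Wavelength grid strictly increasing, reflectance clamped to [0, 1] with
  $10^{-9}$ slack; simulated reflectance is clipped against rounding.
* Stop-band placement and the shift-rate solver evaluate the Bruggeman index
  self-consistently at the band wavelength (fixed-point iteration; the
  dispersion is mild so a handful of iterations converge to $10^{-9}$).
* FFT peak ties (equal amplitude) break towards the smaller EOT;
  nearest-neighbour EOT tracking seeds from the largest first-frame peak.
* Rate fits need ≥3 non-missing points in the window; missing values are
  gaps, never interpolated.
* Error taxonomy: `rugatecam_input_error` (caller mistakes),
  `rugatecam_numeric_error` (no peak / no root),
  `rugatecam_data_error` (unreadable or inconsistent files),
  `rugatecam_inconsistent_error` (physically impossible measurement pairs);
  the CLI maps these to exit codes 2/3.
* All stochastic paths (reflectance noise, pixel noise) are seeded and
  restore the caller's RNG state; identical configuration and seed give
  byte-identical output files.

## Problem sizes

The default simulations used by the tests and the acceptance script are the
full experimental geometry: 61 frames at 5-min cadence, 1 201-wavelength
spectra, ~3 400 transfer-matrix sublayers per frame (about 35 s per
61-frame series in plain R). Unit tests exercise the same code paths on
thinner films and coarser grids where full scale adds nothing.

## Known limitations

* Real (lossless) indices only; oblique incidence and polarization are out
  of scope.
* The EOT reported for dispersive films is the group optical thickness; no
  dispersion correction to phase $2nL$ is applied.
* decompose_layers assigns the two largest FFT peaks to film and full
  stack, which presumes the cap/film interface term is not dominant — true
  for the wet measurement geometry it models; a dry high-contrast stack can
  rank the cap's own peak among the top two.
* The H parameter is retrospective (needs the whole series for its
  extrema) and its monotonicity is guaranteed only while the stop band
  stays within the camera's visible range.
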