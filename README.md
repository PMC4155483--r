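# rugatecam

Monitoring the degradation of porous silicon (pSi) photonic crystals with a
consumer colour camera.

Porous silicon etched with a sinusoidal porosity depth profile is a
one-dimensional photonic crystal (a *rugate filter*): it reflects a narrow
band of light whose centre wavelength is set by the optical period of the
profile, `lambda = 2 n_eff(p) Lambda`. When such a film degrades in aqueous
media — the silicon skeleton oxidizes and hydrolyses to soluble silicates —
its effective refractive index and thickness drop, the stop band shifts to
the blue (a hypsochromic shift), and the film's colour visibly changes from
red towards green. `rugatecam` implements the complete analysis chain for
following that process two ways at once:

* **Spectrophotometric route.** Rugate-peak tracking; effective optical
  thickness (EOT = 2nL) extracted as the frequency of the Fabry–Pérot
  interference fringes via an FFT of the reflectance spectrum in wavenumber
  space (the RIFTS procedure); the relative change
  `ΔEOT/EOT₀ (%) = (EOT − EOT₀)/EOT₀ × 100`; decomposition of a two-layer
  (chitosan-capped) film through the additivity `EOT₁ + EOT₂ = EOT₃`; and
  the SLIM inversion (spectroscopic liquid infiltration method), which
  solves the two-component Bruggeman effective-medium relation
  `(1−p)(ε_sk−ε)/(ε_sk+2ε) + p(ε_f−ε)/(ε_f+2ε) = 0` for porosity and
  thickness from EOTs measured with two pore fillings.

* **Colour route.** Mean RGB over a masked region of interest in time-lapse
  photographs; HSV hue on the 0–1 scale, `H = h'/6` with the standard
  hexcone `h'` (plus 1 when negative); and the *H parameter* — the hue
  recomputed after each channel has been independently min–max normalized
  over the whole time course, which removes per-channel offset and gain and
  stays monotone through complete degradation even when the raw hue is
  confounded by the broadband lamp reflection off the exposed silicon
  mirror.

Because no public datasets of such experiments exist, the package includes a
first-class forward simulator: a normal-incidence transfer-matrix solver over
Bruggeman effective-medium sublayers (rugate profiles, uniform caps, linear
degradation mechanisms with clipping), a camera model (Planck illuminant,
Gaussian channel sensitivities, white balance, sRGB encoding), and a
synthetic image-stack writer, so the whole pipeline is testable end to end.

Intended users: researchers in photonic biosensing and degradable drug-delivery
carriers who want low-cost colorimetric monitoring validated against
spectrophotometry, and anyone needing a reference implementation of RIFTS/SLIM
analysis for porous silicon.

## Worked example

Simulate the freshly etched sample (stop band at 593 nm, blue-shifting at
1.33 nm/min) and its chitosan-capped counterpart (1.99 nm/min), analyze both
routes, and rank their stability:

```r
library(rugatecam)

for (s in c("fpsi", "psi_ch")) {
  cfg <- system.file("extdata", paste0(s, ".yaml"), package = "rugatecam")
  res <- cmd_simulate(cfg, file.path("runs", s), seed = 1)
  cmd_analyze(res$spectra_dir, res$images_dir, cfg,
              file.path("runs", s, "analysis"))
}
cmd_report(c(fpSi = "runs/fpsi/analysis", `pSi-ch` = "runs/psi_ch/analysis"),
           "runs/report")
```

which prints:

```
<stability_report> window [0, 25] min
       rel_eot_pct_per_min rugate_nm_per_min h_norm_per_min
fpSi             -0.224850         -1.327143       0.010210
pSi-ch           -0.339984         -1.992857       0.015603
  rel_eot_pct_per_min: fpSi > pSi-ch (most to least stable)
  rugate_nm_per_min: fpSi > pSi-ch (most to least stable)
  h_norm_per_min: fpSi > pSi-ch (most to least stable)
  metric agreement: TRUE
```

Reading the table: the fpSi film loses relative optical thickness at
0.22 %/min and its rugate peak moves at −1.33 nm/min over the first 25
minutes; the chitosan-coated film degrades faster on every metric (its cap
admits the buffer and its amines accelerate hydrolysis), so the ranking
fpSi > pSi-ch is the same whether measured with a spectrometer (EOT or peak
shift) or with nothing but a camera (the normalized H-parameter rate) —
which is the point of the method.

A command-line driver with the same stages lives at
`inst/cli/rugatecam.R` (`simulate` / `analyze` / `report` subcommands; exit
codes 0/2/3 for ok / configuration error / data error).

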