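Package: rugatecam
Title: Camera-Based Monitoring of Porous Silicon Photonic Crystal Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to monitor the degradation of porous silicon (pSi) rugate
    photonic crystals with a consumer colour camera, together with the
    spectrophotometric analysis that validates it. Includes a normal-incidence
    transfer-matrix forward simulator for intact, chitosan-coated, degrading
    and fully dissolved pSi films (Bruggeman effective-medium mixing, sinusoidal
    rugate porosity profiles, linear-in-time degradation mechanisms), rugate
    peak tracking, effective optical thickness (EOT = 2nL) extraction by FFT of
    Fabry-Perot interference fringes (RIFTS), SLIM porosity/thickness inversion,
    a spectral camera-rendering model (Planck illuminant, Gaussian channel
    sensitivities), HSV hue and the min-max-normalized H parameter for
    time-lapse image stacks, degradation-rate fitting, and a stability-ranking
    report across samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
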