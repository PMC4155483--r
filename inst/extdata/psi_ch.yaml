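# Chitosan-coated porous silicon (pSi-ch): the fpSi film capped by a
# spin-coated chitosan overlayer (2nL = 17.2 um). Degrades faster than
# fpSi (initial blue-shift rate 1.99 nm/min), reproducing the observed
# stability order fpSi > pSi-ch.
sample: pSi-ch
seed: 1
wavelengths: {min: 400.0, max: 1000.0, step: 0.5}
ambient: buffer
substrate: si
film:
  porosity: 0.534
  thickness_um: 22.8
  rugate_amplitude: 0.02
  stopband_nm: 593.0
  pore_fill: buffer
overlayer: {medium: chitosan, thickness_um: 5.584416}
degradation:
  dissolution_um_per_min: 0.0
  oxidation_per_min: 0.002
  shift_nm_per_min: 1.99
time: {start: 0, end: 300, step: 5}
noise_sd: 0.0
camera:
  centers_nm: [600.0, 540.0, 465.0]
  fwhm_nm: 80.0
  illuminant_K: 3000.0
  white_balance: none
  exposure: 0.85
  gamma: srgb
images: {size_px: 64, roi_radius_px: 24, noise_sd: 0.0}
analysis:
  peak_band: [410.0, 850.0]
  window: [0.0, 25.0]
  balance: true
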