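make_gaussian_band <- function(center, sigma = 15, base = 0.2, amp = 0.6,
                               wl = default_wavelengths(step = 0.5)) {
  reflectance_spectrum(wl, base + amp * exp(-0.5 * ((wl - center) / sigma)^2))
}

make_cosine_spectrum <- function(eot_um, wl = default_wavelengths(step = 0.5),
                                 base = 0.3, amp = 0.1) {
  reflectance_spectrum(wl, base + amp * cos(2 * pi * eot_um * 1000 / wl))
}

test_that("rugate peak localization reaches sub-grid precision", {
  sp <- make_gaussian_band(593)
  expect_lt(abs(find_rugate_peak(sp, c(500, 700)) - 593), 0.25)
  # off-grid centre
  sp2 <- make_gaussian_band(593.17)
  expect_lt(abs(find_rugate_peak(sp2, c(500, 700)) - 593.17), 0.25)
  flat <- reflectance_spectrum(seq(400, 700, 1), rep(0.4, 301))
  expect_error(find_rugate_peak(flat), class = "rugatecam_numeric_error")
  ramp <- reflectance_spectrum(seq(400, 700, 1),
                               seq(0.2, 0.6, length.out = 301))
  expect_warning(pk <- find_rugate_peak(ramp), class = "rugatecam_edge_peak")
  expect_true(attr(pk, "edge"))
})

test_that("FFT EOT recovers constructed fringe frequencies within resolution", {
  e <- compute_eot(make_cosine_spectrum(59.28), 1)
  expect_equal(e$resolution, 400 * 1000 / (2 * 600) / 1000)
  expect_lt(abs(e$peak_positions[1] - 59.28), e$resolution)
  set.seed(3)
  for (eot in runif(15, 10, 100)) {
    got <- compute_eot(make_cosine_spectrum(eot), 1)
    expect_lt(abs(got$peak_positions[1] - eot), got$resolution)
  }
  flat <- reflectance_spectrum(default_wavelengths(step = 1),
                               rep(0.3, 601))
  expect_warning(e0 <- compute_eot(flat, 1), class = "rugatecam_no_eot_peak")
  expect_length(e0$peak_positions, 0)
  expect_error(compute_eot(make_cosine_spectrum(50), 0),
               class = "rugatecam_input_error")
})

test_that("two superposed fringe systems resolve into separate EOT peaks", {
  wl <- default_wavelengths(step = 0.5)
  R <- 0.3 + 0.08 * cos(2 * pi * 45000 / wl) + 0.05 * cos(2 * pi * 62000 / wl)
  e <- compute_eot(reflectance_spectrum(wl, R), 2)
  expect_equal(sort(e$peak_positions), c(45, 62), tolerance = 0.01)
  # amplitude ordering: the stronger fringe comes first
  expect_equal(e$peak_positions[1], 45, tolerance = 0.01)
})

test_that("relative EOT change follows the percentage definition", {
  expect_equal(relative_eot_change(60, 60), 0)
  expect_equal(relative_eot_change(30, 60), -50)
  expect_equal(relative_eot_change(60.2, 59.7), 0.5 / 59.7 * 100)
  expect_equal(relative_eot_change(60.2, 59.7), 0.8375, tolerance = 1e-4)
  expect_error(relative_eot_change(60, 0), class = "rugatecam_input_error")
})

test_that("layer decomposition assigns pSi, full stack and overlayer", {
  e <- structure(list(peak_positions = c(60.2, 77.4),
                      peak_amplitudes = c(2, 1), resolution = 1 / 3,
                      n_found = 2L), class = "eot_result")
  d <- decompose_layers(e)
  expect_equal(d$pSi, 60.2)
  expect_equal(d$full_stack, 77.4)
  expect_equal(d$overlayer, 17.2)
  same <- structure(list(peak_positions = c(50, 50),
                         peak_amplitudes = c(1, 1), resolution = 1 / 3,
                         n_found = 2L), class = "eot_result")
  expect_equal(decompose_layers(same)$overlayer, 0)
  one <- structure(list(peak_positions = 50, peak_amplitudes = 1,
                        resolution = 1 / 3, n_found = 1L),
                   class = "eot_result")
  expect_error(decompose_layers(one), class = "rugatecam_data_error")
})

test_that("a capped porous film shows additive EOT peaks (overlayer = 2nL)", {
  # higher-porosity film so the pSi and full-stack components dominate the
  # weak buffer/chitosan interface term, as in the wet measurement geometry
  film <- make_fpsi_film(porosity = 0.7)
  cap_2nl <- 17.2
  cap <- uniform_layer(med$chitosan, cap_2nl / (2 * 1.54))
  sp <- simulate_reflectance(layer_stack(list(cap, film), med$si, med$buffer))
  e <- compute_eot(sp, 2)
  d <- decompose_layers(e)
  expect_equal(d$overlayer, cap_2nl, tolerance = e$resolution)
  # additivity against the film alone
  alone <- compute_eot(simulate_reflectance(layer_stack(list(film), med$si,
                                                        med$buffer)), 1)
  expect_equal(d$pSi, alone$peak_positions[1], tolerance = e$resolution)
  expect_equal(d$full_stack - d$pSi - cap_2nl, 0, tolerance = e$resolution)
})

test_that("rate fitting is exact on lines and rejects degenerate input", {
  t <- 0:10
  f <- fit_rate(t, 2 * t, c(0, 10))
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)
  expect_equal(fit_rate(t, rep(5, 11), c(0, 10))$slope, 0)
  expect_error(fit_rate(c(0, 1), c(1, 2), c(0, 1)),
               class = "rugatecam_input_error")
  expect_error(fit_rate(t, 2 * t, c(10, 0)), class = "rugatecam_input_error")
  # NAs are excluded, not propagated
  v <- 2 * t; v[c(3, 7)] <- NA
  expect_equal(fit_rate(t, v, c(0, 10))$slope, 2)
})

test_that("analyze_series handles flat series, monotone dissolution and gaps", {
  wl <- coarse_grid()
  sp <- simulate_reflectance(make_small_stack(), wl)
  same <- structure(list(times = c(0, 5, 10), spectra = list(sp, sp, sp)),
                    class = "degradation_spectra")
  d <- analyze_series(same, peak_band = c(450, 750))
  expect_equal(d$rel_eot_pct, c(0, 0, 0))
  expect_equal(diff(d$rugate_peak_nm), c(0, 0))
  # dissolution by thickness loss: bare-substrate frames become missing
  stack <- make_small_stack()
  traj <- degradation_trajectory(dissolution_rate = 0.25,
                                 t_grid = seq(0, 30, 10))
  ser <- simulate_degradation_series(stack, traj, wl)
  d2 <- analyze_series(ser, peak_band = c(450, 750))
  expect_true(is.na(d2$rugate_peak_nm[4]))  # t = 30 > 5 um / 0.25
  expect_true(is.na(d2$eot_um[4]))
  expect_error(analyze_series(list(times = 0, spectra = list(sp))),
               class = "rugatecam_input_error")
})

test_that("tracked EOT stays continuous on a slow noiseless degradation", {
  stack <- make_fpsi_stack()
  kp <- porosity_rate_for_shift(stack$layers[[1]], 0.5, window = 25,
                                oxidation_rate = 0)
  traj <- degradation_trajectory(porosity_rate = kp,
                                 t_grid = seq(0, 30, 5))
  ser <- simulate_degradation_series(stack, traj, default_wavelengths(step = 1))
  d <- analyze_series(ser, peak_band = c(450, 750))
  res <- compute_eot(ser$spectra[[1]], 1)$resolution
  expect_true(all(abs(diff(d$eot_um)) <= 3 * res))
  expect_true(all(diff(d$rel_eot_pct) <= 0))
})

test_that("degradation series round-trip through CSV", {
  d <- structure(data.frame(time_min = c(0, 5), rugate_peak_nm = c(593, 590),
                            eot_um = c(100, 99), rel_eot_pct = c(0, -1)),
                 class = c("degradation_series", "data.frame"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_degradation_series(d, path)
  expect_equal(as.data.frame(read_degradation_series(path)),
               as.data.frame(d))
})
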