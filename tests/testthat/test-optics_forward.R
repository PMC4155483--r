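# Brute-force oracle: scan the Bruggeman residual over a permittivity grid
# and locate the sign change.
bruggeman_root_scan <- function(p, eps_sk, eps_f, step = 1e-6) {
  eps <- seq(min(eps_sk, eps_f), max(eps_sk, eps_f), by = step)
  f <- (1 - p) * (eps_sk - eps) / (eps_sk + 2 * eps) +
    p * (eps_f - eps) / (eps_f + 2 * eps)
  i <- which(diff(sign(f)) != 0)[1]
  sqrt((eps[i] + eps[i + 1]) / 2)
}

test_that("Bruggeman mixing honours limits and matches the root-scan oracle", {
  si <- med$si; air <- med$air
  expect_equal(bruggeman_index(0, si, air, 593), medium_index(si, 593))
  expect_equal(bruggeman_index(1, si, air, 593), medium_index(air, 593))
  # eps_sk = 4, eps_f = 1 at p = 0.5 against the independent scan
  m2 <- optical_medium("m2", 2); m1 <- optical_medium("m1", 1)
  expect_equal(bruggeman_index(0.5, m2, m1, 600),
               bruggeman_root_scan(0.5, 4, 1), tolerance = 1e-6)
  expect_error(bruggeman_index(1.2, si, air, 593),
               class = "rugatecam_input_error")
})

test_that("effective index decreases strictly with porosity for a low-index fill", {
  p <- seq(0, 1, by = 0.05)
  n <- bruggeman_index(p, med$si, med$buffer, 593)
  expect_true(all(diff(n) < 0))
  expect_true(all(n >= medium_index(med$buffer, 593) - 1e-12))
  expect_true(all(n <= medium_index(med$si, 593) + 1e-12))
})

test_that("transfer matrix reproduces the Fresnel and quarter-wave closed forms", {
  sub <- optical_medium("sub", 3.5)
  amb <- optical_medium("amb", 1.0)
  bare <- simulate_reflectance(layer_stack(list(), sub, amb),
                               seq(400, 1000, by = 50))
  expect_equal(bare$reflectance,
               rep(((3.5 - 1) / (3.5 + 1))^2, length(bare$wavelengths)),
               tolerance = 1e-12)
  # quarter-wave film: extremum at the design wavelength, two-beam closed form
  n_f <- 1.3; lambda0 <- 600
  film <- uniform_layer(optical_medium("f", n_f), lambda0 / (4 * n_f) / 1000)
  sp <- simulate_reflectance(layer_stack(list(film), sub, amb),
                             seq(400, 1000, by = 0.5))
  R0 <- sp$reflectance[sp$wavelengths == lambda0]
  expect_equal(R0, ((3.5 - n_f^2) / (3.5 + n_f^2))^2, tolerance = 1e-9)
  # n_f < sqrt(n_sub): antireflection minimum at lambda0
  expect_lt(R0, sp$reflectance[sp$wavelengths == 550])
  expect_lt(R0, sp$reflectance[sp$wavelengths == 650])
  expect_error(simulate_reflectance(layer_stack(list(), sub, amb),
                                    c(500, 450)),
               class = "rugatecam_input_error")
})

test_that("uniform-layer fringes carry EOT = 2nL through the FFT pipeline", {
  sub <- optical_medium("sub", 3.5)
  film <- uniform_layer(optical_medium("f", 1.3), 22.8)
  sp <- simulate_reflectance(layer_stack(list(film), sub, med$air))
  e <- compute_eot(sp, 1)
  expect_equal(e$peak_positions[1], 2 * 1.3 * 22.8, tolerance = e$resolution)
})

test_that("rugate stop band sits at 2 n_eff(p) Lambda and energy is bounded", {
  stack <- make_fpsi_stack()
  sp <- simulate_reflectance(stack, default_wavelengths(step = 0.5))
  expect_true(all(sp$reflectance >= 0 & sp$reflectance <= 1))
  predicted <- stopband_wavelength(stack$layers[[1]])
  peak <- find_rugate_peak(sp, c(500, 700))
  expect_lt(abs(peak - predicted), 2 * 0.5)
})

test_that("evolve_stack is the identity at t = 0 and dissolves to bare substrate", {
  stack <- make_small_stack()
  traj <- degradation_trajectory(dissolution_rate = 0.5, porosity_rate = 0,
                                 oxidation_rate = 0, t_grid = c(0, 5, 10))
  e0 <- evolve_stack(stack, traj, 0)
  expect_equal(e0$layers[[1]]$thickness, stack$layers[[1]]$thickness)
  expect_equal(e0$layers[[1]]$porosity, stack$layers[[1]]$porosity)
  # t >= L0 / k_L: layer gone, spectrum equals the bare-substrate Fresnel
  gone <- evolve_stack(stack, traj, 10 + 1)
  expect_length(gone$layers, 0)
  wl <- coarse_grid()
  expect_equal(simulate_reflectance(gone, wl)$reflectance,
               simulate_reflectance(layer_stack(list(), med$si, med$buffer),
                                    wl)$reflectance)
  expect_error(evolve_stack(stack, traj, -1), class = "rugatecam_input_error")
})

test_that("degradation blue-shifts the stop band and never raises the EOT", {
  stack <- make_fpsi_stack()
  traj <- degradation_trajectory(porosity_rate = 3e-3, oxidation_rate = 1e-3,
                                 t_grid = c(0, 20, 40))
  wl <- default_wavelengths(step = 1)
  peaks <- vapply(c(0, 20, 40), function(t) {
    as.numeric(find_rugate_peak(simulate_reflectance(evolve_stack(stack, traj, t), wl),
                                c(450, 750)))
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
  eots <- vapply(c(0, 20, 40), function(t) {
    l <- evolve_stack(stack, traj, t)$layers[[1]]
    eot_2nl(l$porosity, l$thickness, l$skeleton, l$pore_fill)
  }, numeric(1))
  expect_true(all(diff(eots) < 0))
})

test_that("degradation series are deterministic and seeded noise reproduces", {
  stack <- make_small_stack()
  wl <- coarse_grid()
  traj1 <- degradation_trajectory(porosity_rate = 1e-3, t_grid = 0)
  single <- simulate_degradation_series(stack, traj1, wl)
  expect_length(single$spectra, 1L)
  expect_equal(single$spectra[[1]]$reflectance,
               simulate_reflectance(stack, wl)$reflectance)
  traj <- degradation_trajectory(porosity_rate = 1e-3, t_grid = c(0, 10, 20))
  a <- simulate_degradation_series(stack, traj, wl, noise_sd = 0.01, seed = 7)
  b <- simulate_degradation_series(stack, traj, wl, noise_sd = 0.01, seed = 7)
  d <- simulate_degradation_series(stack, traj, wl, noise_sd = 0.01, seed = 8)
  expect_identical(a$spectra, b$spectra)
  expect_false(identical(a$spectra, d$spectra))
  clean <- simulate_degradation_series(stack, traj, wl)
  expect_true(all(clean$spectra[[2]]$reflectance >= 0))
  expect_error(degradation_trajectory(t_grid = c(5, 10)),
               class = "rugatecam_input_error")
})

test_that("SLIM inversion recovers porosity and thickness to 1e-6 relative", {
  si <- med$si; eth <- med$ethanol; air <- med$air
  # the characterized film values
  ea <- eot_2nl(0.534, 22.8, si, air)
  ef <- eot_2nl(0.534, 22.8, si, eth)
  got <- slim_invert(ea, ef, si, eth)
  expect_equal(got$porosity, 0.534, tolerance = 1e-6)
  expect_equal(got$thickness, 22.8, tolerance = 1e-6)
  # random round trips
  set.seed(11)
  for (i in 1:20) {
    p <- runif(1, 0.2, 0.85); L <- runif(1, 5, 40)
    got <- slim_invert(eot_2nl(p, L, si, air), eot_2nl(p, L, si, eth),
                       si, eth)
    expect_equal(got$porosity, p, tolerance = 1e-6)
    expect_equal(got$thickness, L, tolerance = 1e-6)
  }
})

test_that("SLIM flags degenerate and inconsistent measurements", {
  si <- med$si
  expect_error(slim_invert(50, 50, si, med$air),
               class = "rugatecam_inconsistent_error")
  expect_error(slim_invert(60, 55, si, med$ethanol),
               class = "rugatecam_inconsistent_error")
  # p -> 0 limit: nearly equal EOTs recover a near-zero porosity
  ea <- eot_2nl(0.005, 22.8, si, med$air)
  ef <- eot_2nl(0.005, 22.8, si, med$ethanol)
  expect_lt(slim_invert(ea, ef, si, med$ethanol)$porosity, 0.01)
})

test_that("spectrum files round-trip through the two-column text format", {
  sp <- simulate_reflectance(make_small_stack(), coarse_grid(5))
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$wavelengths, sp$wavelengths, tolerance = 1e-5)
  expect_equal(back$reflectance, sp$reflectance, tolerance = 1e-5)
  # headerless files are accepted too
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%g %g", sp$wavelengths, sp$reflectance), p2)
  expect_equal(read_spectrum(p2)$reflectance, back$reflectance,
               tolerance = 1e-5)
})
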