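test_that("the free-Ca2+ solver honors conservation against the bisection oracle", {
  expect_equal(solve_free_ca(5, list()), 5)     # no buffers
  expect_equal(solve_free_ca(0, list(buffer_species("b", 10, 1))), 0)
  # frozen oracle value: one buffer (10 uM, kd 1 uM), total 5 uM
  expect_equal(solve_free_ca(5, buffer_species("b", 10, 1)), 0.7416574,
               tolerance = 1e-6)
  bufs <- list(buffer_species("BAPTA", 200, 0.16),
               buffer_species("indicator", 2, 1.6),
               buffer_species("CaM", 40, 2, n_sites = 4))
  totals <- c(0.01, 0.5, 5, 50, 500, 5000, 1e4)
  x <- solve_free_ca(totals, bufs)
  expect_equal(x, oracle_free_ca(totals, bufs), tolerance = 1e-6)
  # conservation residual < 1e-9 relative
  resid <- abs(total_ca_for_free(x, bufs) - totals)
  expect_lt(max(resid / pmax(totals, 1)), 1e-9)
})

test_that("free Ca2+ is monotone in total Ca2+ and in buffer load", {
  bufs <- list(buffer_species("chel", 100, 1))
  totals <- seq(0, 500, length.out = 40)
  expect_true(all(diff(solve_free_ca(totals, bufs)) >= 0))
  by_load <- vapply(c(10, 50, 100, 200), function(tt)
    solve_free_ca(120, buffer_species("chel", tt, 1)), numeric(1))
  expect_true(all(diff(by_load) < 0))
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- kd_roundtrip_config(1.4, noise_sigma = 0.02, seed = 11)
  s1 <- simulate_cam_titration(cfg)
  s2 <- simulate_cam_titration(cfg)
  expect_identical(s1$points, s2$points)
  cfg3 <- kd_roundtrip_config(1.4, noise_sigma = 0.02, seed = 12)
  expect_false(identical(simulate_cam_titration(cfg3)$points, s1$points))
})

test_that("a zero-amplitude construct produces a flat, non-responding series", {
  cfg <- kd_roundtrip_config(700, dynamic_range = 1,
                             binding_model = "hyperbolic")
  s <- simulate_cam_titration(cfg)
  r <- s$points$f_donor / s$points$f_acceptor
  expect_lt(diff(range(r)), 1e-12)
})

test_that("a schedule exceeding the cuvette capacity is rejected", {
  sch <- data.frame(added_volume = rep(300, 5), stock_conc = 100)
  cfg <- generator_config(true_kd = 1, schedule = sch,
                          initial_volume = 2000, max_volume = 3000)
  expect_error(simulate_cam_titration(cfg),
               class = "fretbind_schedule_error")
})

test_that("synthesized spectra interpolate the endpoint spectra", {
  cfg <- generator_config(true_kd = 1, r_min = 1, r_max = 2.5)
  s0 <- synthesize_spectrum(0, cfg)
  s1 <- synthesize_spectrum(1, cfg)
  s37 <- synthesize_spectrum(0.37, cfg)
  expect_equal(s37$intensity_au,
               0.63 * s0$intensity_au + 0.37 * s1$intensity_au,
               tolerance = 1e-12)
  expect_error(synthesize_spectrum(1.2, cfg),
               class = "fretbind_parameter_error")
  # band integrals reproduce the configured channel intensities to < 0.5%
  band <- function(sp, lo, hi)
    sum(sp$intensity_au[sp$wavelength_nm >= lo & sp$wavelength_nm <= hi])
  expect_equal(band(s0, 470, 480), 1000 * 1, tolerance = 0.005 * 1000)
  expect_equal(band(s0, 530, 540), 1000, tolerance = 0.005 * 1000)
  expect_equal(band(s1, 470, 480), 1000 * 2.5, tolerance = 0.005 * 2500)
  # the 475/535 peak ratio rises strictly with the bound fraction
  peak_ratio <- vapply(seq(0, 1, by = 0.1), function(f) {
    sp <- synthesize_spectrum(f, cfg)
    sp$intensity_au[sp$wavelength_nm == 475] /
      sp$intensity_au[sp$wavelength_nm == 535]
  }, numeric(1))
  expect_true(all(diff(peak_ratio) > 0))
  expect_equal(peak_ratio[1], 1, tolerance = 1e-6)
  expect_equal(peak_ratio[11], 2.5, tolerance = 1e-6)
})

test_that("the Ca2+ assay generator reduces to plain dilution without buffers", {
  sch <- titration_schedule(c(1, 2, 5, 10, 20), 2000, 1000)
  cfg <- generator_config(true_hill = data.frame(ec50 = 1, n = 1, weight = 1),
                          schedule = sch)
  assay <- simulate_ca_assay(cfg, buffers = list(),
                             indicator = list(kd = 1.6, total = 0,
                                              f_min = 100, f_max = 1100))
  # with no chelation, free Ca2+ read back from the indicator equals the
  # dilution-corrected total
  free <- free_calcium(assay$points$f_indicator[-1], 100, 1100)
  expect_equal(free, c(1, 2, 5, 10, 20), tolerance = 1e-9)
})

test_that("construct enumeration reproduces the published biosensor families", {
  smd4 <- biosensor_construct(330, 375, smd = 4)
  fam <- enumerate_constructs(smd4, c(345, 351, 361, 375))
  expect_length(fam, 4)
  expect_identical(vapply(fam, `[[`, character(1), "name"),
                   c("BSGPER_330-345", "BSGPER_330-351", "BSGPER_330-361",
                     "BSGPER_330-375"))
  smd1 <- biosensor_construct(83, 93, smd = 1)
  gly <- enumerate_constructs(smd1, 93, gly_flank_options = 3L)
  expect_identical(gly[[1]]$name, "BSGPER_GGG83-93GGG")
  expect_identical(enumerate_constructs(smd1), list(smd1))
  expect_error(enumerate_constructs(smd1, 120),
               class = "fretbind_range_error")
})
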