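test_that("fractional response from the emission ratio is the affine map", {
  expect_equal(fractional_from_ratio(1.0, 1.0, 2.0), 0.0)
  expect_equal(fractional_from_ratio(2.0, 1.0, 2.0), 1.0)
  expect_equal(fractional_from_ratio(1.5, 1.0, 2.0), 0.5)
  # strictly increasing in r over (r_min, r_max)
  r <- seq(1.001, 1.999, length.out = 50)
  expect_true(all(diff(fractional_from_ratio(r, 1, 2)) > 0))
  expect_error(fractional_from_ratio(1.5, 2.0, 2.0),
               class = "fretbind_degenerate_endpoints")
})

test_that("clamp policy tolerates small excursions and rejects large ones", {
  expect_warning(f <- fractional_from_ratio(0.97, 1.0, 2.0),
                 class = "fretbind_clamp")
  expect_equal(f, 0)
  expect_warning(f <- fractional_from_ratio(2.04, 1.0, 2.0),
                 class = "fretbind_clamp")
  expect_equal(f, 1)
  expect_error(fractional_from_ratio(2.2, 1.0, 2.0),
               class = "fretbind_range_error")
})

test_that("single-channel fractional responses respect channel direction", {
  expect_equal(fractional_from_intensity(100, 100, 200, "donor"), 0.0)
  expect_equal(fractional_from_intensity(150, 100, 200, "donor"), 0.5)
  # acceptor intensity falls on binding: unbound maximum maps to 0
  expect_equal(fractional_from_intensity(200, 100, 200, "acceptor"), 0.0)
  expect_equal(fractional_from_intensity(100, 100, 200, "acceptor"), 1.0)
  expect_error(fractional_from_intensity(150, 200, 100, "donor"),
               class = "fretbind_degenerate_endpoints")
})

test_that("dynamic range is the fold difference of the endpoint ratios", {
  expect_equal(dynamic_range(1.0, 2.0), 2.0)
  expect_equal(dynamic_range(1.0, 1.0), 1.0)
  expect_error(dynamic_range(0, 2), class = "fretbind_invalid_endpoint")
})

test_that("dilution correction follows conservation of mass", {
  pts <- data.frame(step = 0:1, added_volume = c(0, 10),
                    stock_conc = c(0, 100), f_donor = c(100, 110),
                    f_acceptor = c(100, 95))
  s <- titration_series(pts, initial_volume = 990, biosensor_total = 0.5)
  resp <- apply_dilution_correction(s)
  # 10 uL of 100 uM into 990 uL -> 1.0 uM total; intensity factor 1000/990
  expect_equal(resp$titrant_total, c(0, 1.0))
  expect_equal(resp$dilution_factor, c(1, 1000 / 990))
  expect_equal(resp$f_donor_corr[2], 110 * 1000 / 990)
  # no additions -> factor 1, concentration 0
  s0 <- titration_series(pts[1, ], initial_volume = 990,
                         biosensor_total = 0.5)
  resp0 <- apply_dilution_correction(s0)
  expect_equal(resp0$titrant_total, 0)
  expect_equal(resp0$dilution_factor, 1)
})

test_that("dilution correction conserves titrant moles on random schedules", {
  set.seed(41)
  for (i in 1:5) {
    n <- 12
    pts <- data.frame(step = 0:n,
                      added_volume = c(0, runif(n, 1, 30)),
                      stock_conc = c(0, runif(n, 10, 500)),
                      f_donor = runif(n + 1, 50, 200),
                      f_acceptor = runif(n + 1, 50, 200))
    v0 <- runif(1, 500, 3000)
    resp <- apply_dilution_correction(
      titration_series(pts, v0, biosensor_total = 0.5))
    moles_in <- cumsum(pts$added_volume * pts$stock_conc)
    vol <- v0 + cumsum(pts$added_volume)
    expect_equal(resp$titrant_total * vol, moles_in, tolerance = 1e-12)
  }
})

test_that("the emission ratio is invariant under dilution", {
  cfg <- kd_roundtrip_config(1.4, dynamic_range = 2.5)
  s <- simulate_cam_titration(cfg)
  resp <- apply_dilution_correction(s)
  expect_equal(resp$ratio, resp$f_donor_corr / resp$f_acceptor_corr,
               tolerance = 1e-12)
  expect_equal(resp$ratio, s$points$f_donor / s$points$f_acceptor,
               tolerance = 1e-12)
})

test_that("ratio and donor-intensity fractional responses agree on ideal-ratio data", {
  cfg <- kd_roundtrip_config(0.44)
  resp <- apply_dilution_correction(simulate_cam_titration(cfg))
  f_ratio <- fractional_from_ratio(resp$ratio, min(resp$ratio),
                                   max(resp$ratio))
  f_donor <- fractional_from_intensity(resp$f_donor_corr,
                                       min(resp$f_donor_corr),
                                       max(resp$f_donor_corr), "donor")
  expect_lt(max(abs(f_ratio - f_donor)), 1e-12)
})

test_that("an ideal-ratio point generated at a known bound fraction round-trips", {
  cfg <- generator_config(true_kd = 1, r_min = 1.2, r_max = 2.9)
  r_at <- function(f) 1.2 + (2.9 - 1.2) * f
  expect_equal(fractional_from_ratio(r_at(0.37), 1.2, 2.9), 0.37)
})

test_that("dynamic range of a noiseless synthetic series matches the generator", {
  for (dr in c(1.31, 2.65)) {
    cfg <- kd_roundtrip_config(8.01, dynamic_range = dr)
    resp <- apply_dilution_correction(simulate_cam_titration(cfg))
    # endpoints from the fit, since the last point is near but not at saturation
    fit <- fit_binding(resp, model = "quadratic")
    expect_equal(fit$dynamic_range, dr, tolerance = 1e-9)
  }
})

test_that("series validation catches malformed inputs", {
  pts <- data.frame(step = 0:1, added_volume = c(5, 10),
                    stock_conc = c(0, 10), f_donor = c(1, 1),
                    f_acceptor = c(1, 1))
  expect_error(titration_series(pts, 1000, 0.5),
               class = "fretbind_schedule_error")  # baseline volume != 0
  pts$added_volume <- c(0, -1)
  expect_error(titration_series(pts, 1000, 0.5),
               class = "fretbind_schedule_error")
})
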