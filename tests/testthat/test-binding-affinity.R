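test_that("hyperbolic isotherm has the textbook landmarks", {
  expect_equal(predict_hyperbolic(2, 2), 0.5)
  expect_equal(predict_hyperbolic(0, 2), 0)
  expect_equal(predict_hyperbolic(19 * 2, 2), 0.95)
  expect_error(predict_hyperbolic(1, 0), class = "fretbind_parameter_error")
})

test_that("quadratic isotherm matches the mass-action bisection oracle", {
  expect_equal(predict_quadratic(0, 0.5, 0.5), 0)
  # frozen oracle value for (cam 1.0, bs 0.5, kd 0.5)
  expect_equal(predict_quadratic(1.0, 0.5, 0.5), 0.5857864, tolerance = 1e-6)
  set.seed(7)
  for (i in 1:20) {
    cam <- runif(1, 0.01, 50); bs <- runif(1, 0.05, 5)
    kd <- 10^runif(1, -2, 2)
    f <- predict_quadratic(cam, bs, kd)
    expect_equal(f, oracle_quadratic_fraction(cam, bs, kd),
                 tolerance = 1e-9)
    # mass action identity: f/(1-f) * kd == free CaM
    free_cam <- cam - f * bs
    expect_equal(f / (1 - f) * kd, free_cam, tolerance = 1e-9 * free_cam)
  }
})

test_that("quadratic isotherm reduces to the hyperbola without depletion", {
  kd <- 3
  cam <- 10^seq(-2, 2, length.out = 50)
  delta <- abs(predict_quadratic(cam, kd / 1000, kd) -
               predict_hyperbolic(cam, kd))
  expect_lt(max(delta), 0.002)
})

test_that("noiseless round-trips recover every published Kd to < 0.1%", {
  tab <- gper_binding_params()
  for (i in seq_len(nrow(tab))) {
    kd <- tab$kd_um[i]
    model <- if (kd > 50) "hyperbolic" else "quadratic"
    cfg <- kd_roundtrip_config(kd, dynamic_range = tab$dynamic_range[i],
                               binding_model = model)
    fit <- fit_binding(apply_dilution_correction(simulate_cam_titration(cfg)),
                       model = model)
    expect_lt(abs(fit$kd_app - kd) / kd, 1e-3)
    expect_equal(fit$dynamic_range, tab$dynamic_range[i], tolerance = 1e-6)
  }
})

test_that("a flat response yields a no-binding result", {
  cfg <- kd_roundtrip_config(1, dynamic_range = 1)  # r_max == r_min
  resp <- apply_dilution_correction(simulate_cam_titration(cfg))
  expect_warning(fit <- fit_binding(resp, model = "quadratic"),
                 class = "fretbind_no_binding")
  expect_false(fit$binding_detected)
  expect_true(is.na(fit$kd_app))
})

test_that("auto model selection uses the depletion isotherm when kd <= bs_total", {
  for (kd in c(0.05, 0.2, 0.5)) {  # kd <= bs_total = 0.5
    cfg <- kd_roundtrip_config(kd)
    fit <- fit_binding(apply_dilution_correction(simulate_cam_titration(cfg)),
                       model = "auto")
    expect_identical(fit$model, "quadratic")
  }
  # far above the depletion regime the hyperbola is selected
  cfg <- kd_roundtrip_config(136.62, binding_model = "hyperbolic")
  fit <- fit_binding(apply_dilution_correction(simulate_cam_titration(cfg)),
                     model = "auto")
  expect_identical(fit$model, "hyperbolic")
})

test_that("saturating concentration has the hyperbolic closed form and a depletion offset", {
  expect_equal(saturating_concentration(2, coverage = 0.95), 19 * 2)
  expect_equal(saturating_concentration(2, coverage = 0.5), 2)
  expect_error(saturating_concentration(2, coverage = 1),
               class = "fretbind_parameter_error")
  # quadratic model: verify against the bisection oracle, and check the
  # depletion bound relative to the hyperbolic value
  kd <- 0.44; bs <- 0.5; cov <- 0.95
  c_quad <- saturating_concentration(kd, bs, cov, model = "quadratic")
  expect_equal(oracle_quadratic_fraction(c_quad, bs, kd), cov,
               tolerance = 1e-9)
  c_hyp <- saturating_concentration(kd, coverage = cov)
  expect_gte(c_quad, c_hyp - bs)
})

test_that("fold difference reports the ratio and its nearest integer", {
  fd <- fold_difference(3.41, 0.44)
  expect_equal(fd$fold, 3.41 / 0.44)
  expect_equal(fd$nearest, 8)
  expect_equal(fold_difference(1, 1)$nearest, 1)
  expect_equal(fold_difference(2, 1)$nearest, 2)
})

test_that("spectral-ratio fitting is exact on spectral data while the affine model is biased", {
  kd <- 1.4
  cfg <- kd_roundtrip_config(kd, dynamic_range = 2.5, mode = "spectral")
  resp <- apply_dilution_correction(simulate_cam_titration(cfg))
  fit_spec <- fit_binding(resp, model = "quadratic",
                          response_model = "spectral_ratio")
  fit_aff <- fit_binding(resp, model = "quadratic",
                         response_model = "affine_ratio")
  err_spec <- abs(fit_spec$kd_app - kd) / kd
  err_aff <- abs(fit_aff$kd_app - kd) / kd
  expect_lt(err_spec, 1e-3)
  # the affine approximation leaves a finite, visible bias and misfit
  expect_gt(err_aff, err_spec)
  expect_gt(fit_aff$rss, fit_spec$rss)
})

test_that("fraction-space fitting works on pre-normalized responses", {
  kd <- 8.01
  cfg <- kd_roundtrip_config(kd, dynamic_range = 2.65)
  resp <- apply_dilution_correction(simulate_cam_titration(cfg))
  # normalize with the true endpoints so the fraction is exact
  resp$bs_fract <- fractional_from_ratio(resp$ratio, 1, 2.65)
  fit <- fit_binding(resp, model = "quadratic", response_model = "fraction")
  expect_lt(abs(fit$kd_app - kd) / kd, 1e-6)
})
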