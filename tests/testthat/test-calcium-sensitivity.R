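test_that("indicator calibration maps fluorescence to free Ca2+", {
  expect_equal(free_calcium(200, 100, 300), 1.6)  # half-saturation = Kd
  expect_equal(free_calcium(100, 100, 300), 0)
  expect_error(free_calcium(300, 100, 300),
               class = "fretbind_saturation_error")
  expect_error(free_calcium(90, 100, 300), class = "fretbind_range_error")
  expect_warning(x <- free_calcium(99, 100, 300), class = "fretbind_clamp")
  expect_equal(x, 0)
  # inversion of the indicator saturation map across four decades
  ca <- 10^seq(-2, 2, length.out = 40)
  f <- 100 + (300 - 100) * ca / (1.6 + ca)
  expect_equal(free_calcium(f, 100, 300), ca, tolerance = 1e-9)
})

test_that("the Hill curve has its landmarks and reduces to the hyperbola at n = 1", {
  expect_equal(predict_hill(2.38, 2.38, 1.21), 0.5)
  expect_equal(predict_hill(2.38, 2.38, 3), 0.5)
  expect_equal(predict_hill(0, 2.38, 1.21), 0)
  ca <- 10^seq(-2, 2, length.out = 30)
  expect_equal(predict_hill(ca, 0.75, 1), predict_hyperbolic(ca, 0.75),
               tolerance = 1e-14)
  expect_error(predict_hill(1, -1, 1), class = "fretbind_parameter_error")
})

test_that("noiseless Hill fits recover all published EC50/n pairs to < 0.1%", {
  tab <- gper_ca_params()
  ca <- 10^seq(-2.5, 3, length.out = 40)
  for (i in seq_len(nrow(tab))) {
    y <- predict_hill(ca, tab$ec50_um[i], tab$hill_n[i])
    fit <- fit_hill(ca, y)
    expect_lt(abs(fit$ec50 - tab$ec50_um[i]) / tab$ec50_um[i], 1e-3)
    expect_lt(abs(fit$hill_n - tab$hill_n[i]) / tab$hill_n[i], 1e-3)
  }
})

test_that("Hill fitting fails informatively without signal and ignores point order", {
  ca <- 10^seq(-1, 1, length.out = 10)
  expect_error(fit_hill(ca, rep(0, 10)), class = "fretbind_fit_failure")
  y <- predict_hill(ca, 0.75, 1.18)
  fit1 <- fit_hill(ca, y)
  perm <- sample(seq_along(ca))
  fit2 <- fit_hill(ca[perm], y[perm])
  expect_equal(fit1$ec50, fit2$ec50, tolerance = 1e-12)
  expect_equal(fit1$hill_n, fit2$hill_n, tolerance = 1e-12)
})

test_that("a monophasic curve is not declared biphasic", {
  ca <- 10^seq(-2, 1.5, length.out = 30)
  y <- predict_hill(ca, 2.38, 1.21)
  res <- decompose_biphasic(ca, y)
  expect_false(res$biphasic)
  expect_equal(res$species2_or_global$ec50, 2.38, tolerance = 1e-3)
})

test_that("a two-species mixture is decomposed into its components", {
  ca <- 10^seq(-2, 1.8, length.out = 36)
  y <- 0.25 * predict_hill(ca, 0.13, 1.99) +
       0.75 * predict_hill(ca, 3.71, 2.53)
  res <- decompose_biphasic(ca, y)
  expect_true(res$biphasic)
  expect_lt(abs(res$species1$ec50 - 0.13) / 0.13, 0.15)
  expect_gt(res$species1$amplitude, 0.05)
  # the global fit follows the more abundant high-Ca2+ species
  expect_gt(res$species2_or_global$ec50, 1)
})

test_that("an empty low-Ca2+ segment yields a monophasic result with no species 1", {
  ca <- 10^seq(0.5, 2, length.out = 12)  # all above the 1 uM breakpoint
  y <- predict_hill(ca, 5.15, 1.43)
  res <- decompose_biphasic(ca, y)
  expect_null(res$species1)
  expect_false(res$biphasic)
})

test_that("the full assay pipeline recovers a monophasic Ca2+ sensitivity end-to-end", {
  res <- run_ca_assay(simulate_standard_ca_assay(
    data.frame(ec50 = 5.15, n = 1.43, weight = 1), dynamic_range = 2.65,
    cam_total = saturating_concentration(8.01, 0.5, model = "quadratic")))
  expect_false(res$biphasic)
  expect_lt(abs(res$species2_or_global$ec50 - 5.15) / 5.15, 0.005)
})

test_that("an assay with the indicator stuck at F_min attempts no fit", {
  pts <- data.frame(step = 0:9, added_volume = c(0, rep(1, 9)),
                    stock_conc = c(0, rep(100, 9)),
                    f_donor = rep(100, 10), f_acceptor = rep(100, 10),
                    f_indicator = rep(100, 10))
  assay <- ca_assay_series(pts, initial_volume = 2000,
                           indicator_f_min = 100, indicator_f_max = 1100)
  res <- run_ca_assay(assay)
  expect_null(res$species1)
  expect_null(res$species2_or_global)
  expect_false(res$biphasic)
  expect_true(all(res$free_ca == 0))
})

test_that("an assay lacking the indicator channel is rejected", {
  pts <- data.frame(step = 0:4, added_volume = c(0, rep(1, 4)),
                    stock_conc = c(0, rep(100, 4)),
                    f_donor = 1:5 + 100, f_acceptor = 105:101)
  expect_error(ca_assay_series(pts, 2000, 100, 1100),
               class = "fretbind_config_error")
  pts$f_indicator <- NA_real_
  expect_error(ca_assay_series(pts, 2000, 100, 1100),
               class = "fretbind_config_error")
})
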