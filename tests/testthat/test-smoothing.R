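test_that("polynomial fit recovers exactly representable signals", {
  doys <- composite_midpoint_doys()
  x <- (doys - 183) / 182
  a_true <- c(2, -1, 0.5, 3, -2, 1, 0.25)
  y <- oracle_polyval(a_true, x)
  fit <- fit_seasonal_polynomial(y, doys)
  expect_equal(unname(fit$coefficients), a_true, tolerance = 1e-8)

  fit_const <- fit_seasonal_polynomial(rep(5, 46), doys)
  expect_equal(unname(fit_const$coefficients), c(5, rep(0, 6)),
               tolerance = 1e-8)
})

test_that("polynomial fit matches the dense normal-equations oracle on a bump", {
  doys <- composite_midpoint_doys()
  comp <- aggregate_8day(seasonal_curve(100, 300, 10))
  fit <- fit_seasonal_polynomial(comp, doys)
  expect_equal(unname(fit$coefficients), oracle_polyfit(doys, comp, 6),
               tolerance = 1e-6)
  curve <- evaluate_curve(fit)
  expect_lt(abs(max(curve$values) - 10) / 10, 0.05)
  expect_lt(abs(which.max(curve$values) - 200), 8)
})

test_that("polynomial fit is linear and idempotent", {
  doys <- composite_midpoint_doys()
  comp <- aggregate_8day(seasonal_curve(120, 280, 9))
  f1 <- fit_seasonal_polynomial(comp, doys)
  f3 <- fit_seasonal_polynomial(3 * comp, doys)
  expect_equal(unname(f3$coefficients), 3 * unname(f1$coefficients),
               tolerance = 1e-8)
  # re-smoothing its own fitted curve reproduces the coefficients
  resampled <- evaluate_curve(f1, doys = doys)$values
  f_again <- fit_seasonal_polynomial(resampled, doys)
  expect_equal(f_again$coefficients, f1$coefficients, tolerance = 1e-8)
})

test_that("polynomial fit handles missing composites and degenerate input", {
  doys <- composite_midpoint_doys()
  comp <- aggregate_8day(seasonal_curve(120, 280, 9))
  comp_missing <- comp
  comp_missing[c(3, 17, 30, 44)] <- NA  # 8.7% missing, tolerated
  fit <- fit_seasonal_polynomial(comp_missing, doys)
  expect_equal(unname(fit$coefficients),
               oracle_polyfit(doys[-c(3, 17, 30, 44)],
                              comp[-c(3, 17, 30, 44)], 6),
               tolerance = 1e-6)
  comp_gone <- comp
  comp_gone[1:20] <- NA  # 43% missing: year unusable
  expect_error(fit_seasonal_polynomial(comp_gone, doys),
               class = "smipp_insufficient_data")
  expect_error(fit_seasonal_polynomial(comp[1:5], doys[1:5]),
               class = "smipp_insufficient_data")
})

test_that("evaluated curves match an independent evaluation oracle", {
  # scaled-basis conventions: a = (2, 0, ...) is constant 2; a = (0, 1, 0, ...)
  # evaluates to the scaled abscissa (doy - 183) / 182
  f <- structure(list(coefficients = c(a0 = 2, a1 = 0, a2 = 0, a3 = 0,
                                       a4 = 0, a5 = 0, a6 = 0),
                      center = 183, scale = 182, degree = 6L, year = 2000L),
                 class = "seasonal_poly")
  expect_equal(evaluate_curve(f)$values, rep(2, 365))
  f$coefficients <- c(a0 = 0, a1 = 1, a2 = 0, a3 = 0, a4 = 0, a5 = 0, a6 = 0)
  expect_equal(evaluate_curve(f)$values[100], (100 - 183) / 182)

  set.seed(4)
  for (i in 1:20) {
    f$coefficients[] <- rnorm(7)
    expect_equal(evaluate_curve(f)$values,
                 oracle_polyval(unname(f$coefficients), ((1:365) - 183) / 182),
                 tolerance = 1e-10)
  }
})

test_that("SSA reproduces low-rank signals to numerical tolerance", {
  rec <- ssa_smooth(rep(3, 365), embed_window = 120, n_components = 4)
  expect_equal(rec$values, rep(3, 365), tolerance = 1e-9)

  sinus <- 5 + 2 * sin(2 * pi * (1:365) / 365)
  rec2 <- ssa_smooth(sinus, embed_window = 120, n_components = 4)
  expect_lt(sqrt(mean((rec2$values - sinus)^2)), 1e-6)

  # Hankel rank 4: constant + one harmonic + linear trend
  sig <- 1 + 0.01 * (1:365) + sin(2 * pi * (1:365) / 180)
  rec3 <- ssa_smooth(sig, embed_window = 100, n_components = 4)
  expect_lt(sqrt(mean((rec3$values - sig)^2)), 1e-8)
})

test_that("SSA denoises a seasonal signal in nearly all seeded trials", {
  clean <- 4 + 3 * sin(2 * pi * ((1:365) - 80) / 365)
  set.seed(12)
  improved <- vapply(1:200, function(i) {
    noisy <- clean + rnorm(365, 0, 0.5)
    rec <- ssa_smooth(noisy)$values
    sqrt(mean((rec - clean)^2)) < sqrt(mean((noisy - clean)^2))
  }, logical(1))
  expect_gte(mean(improved), 0.95)
})

test_that("SSA validates its inputs and gap-fills small holes", {
  expect_error(ssa_smooth(rep(NA_real_, 365)), class = "smipp_insufficient_data")
  expect_error(ssa_smooth(1:10, embed_window = 50),
               class = "smipp_invalid_parameters")
  expect_error(ssa_smooth(1:365, embed_window = 120, n_components = 200),
               class = "smipp_invalid_parameters")
  sinus <- 5 + 2 * sin(2 * pi * (1:365) / 365)
  holey <- sinus
  holey[sample(365, 40)] <- NA  # 11% missing, interpolated
  rec <- ssa_smooth(holey)
  expect_lt(sqrt(mean((rec$values - sinus)^2)), 0.05)
  holey[1:120] <- NA  # 33%: unusable
  expect_error(ssa_smooth(holey), class = "smipp_insufficient_data")
})
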