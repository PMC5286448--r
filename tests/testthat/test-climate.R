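make_climate <- function(years, fun) {
  do.call(rbind, lapply(years, function(yr)
    data.frame(year = yr, doy = 1:365, temperature = fun(yr, 1:365))))
}

test_that("preseason aggregate averages the stated window", {
  clim <- make_climate(2000:2004, function(yr, d) rep(10, 365))
  pre <- preseason_aggregate(clim, "temperature", 120, 30)
  expect_equal(pre$value, rep(10, 5))

  # linear ramp: the 30-day mean before DOY 120 is the ramp at DOY 104.5
  ramp <- make_climate(2000:2001, function(yr, d) 0.2 * d)
  pre2 <- preseason_aggregate(ramp, "temperature", 120, 30)
  expect_equal(pre2$value, rep(0.2 * 104.5, 2))

  set.seed(3)
  rnd <- make_climate(2000:2002, function(yr, d) rnorm(365))
  pre3 <- preseason_aggregate(rnd, "temperature", 120, 30)
  for (i in 1:3) {
    v <- rnd$temperature[rnd$year == 1999 + i]
    expect_equal(pre3$value[i], sum(v[90:119]) / 30)  # summation oracle
  }
})

test_that("preseason windows borrow days from the previous year when needed", {
  clim <- make_climate(2000:2002, function(yr, d) yr - 2000 + d / 1000)
  pre <- preseason_aggregate(clim, "temperature", 20, 30)
  expect_true(is.na(pre$value[1]))  # first year has no previous December
  # window for 2001: DOY 355..365 of 2000 and DOY 1..19 of 2001
  expected <- mean(c(0 + (355:365) / 1000, 1 + (1:19) / 1000))
  expect_equal(pre$value[2], expected)
  expect_error(preseason_aggregate(clim, "temperature", 120, 0),
               class = "smipp_invalid_parameters")
})

test_that("summer aggregate covers JJA with the documented modes", {
  clim <- make_climate(2000:2002, function(yr, d) rep(200, 365))
  expect_equal(summer_aggregate(clim, "temperature")$value, rep(200, 3))

  # sinusoid peaking at DOY 197: JJA mean from the exact discrete sum
  sin_fun <- function(yr, d) 20 + 8 * cos(2 * pi * (d - 197) / 365)
  clim2 <- make_climate(2000, sin_fun)
  expected <- mean(sin_fun(2000, 152:243))
  expect_equal(summer_aggregate(clim2, "temperature")$value, expected)

  clim3 <- make_climate(2000:2001, function(yr, d) rep(0, 365))
  names(clim3)[3] <- "precipitation"
  expect_equal(summer_aggregate(clim3, "precipitation")$value, c(0, 0))
  clim4 <- make_climate(2000, function(yr, d) rep(3, 365))
  names(clim4)[3] <- "precipitation"
  # mean monthly precipitation: 92-day total over three months
  expect_equal(summer_aggregate(clim4, "precipitation",
                                mode = "monthly_total")$value, 3 * 92 / 3)
})

test_that("sensitivity returns exact values on exact linear couplings", {
  temp <- c(8.2, 9.1, 7.5, 10.3, 8.8, 9.6, 7.9)
  gs <- -1.9 * temp + 130
  s <- sensitivity(gs, temp)
  expect_equal(s$r, -1.0, tolerance = 1e-12)
  expect_equal(s$slope, -1.9, tolerance = 1e-12)
  set.seed(15)
  s2 <- sensitivity(rnorm(500), rnorm(500))
  expect_lt(abs(s2$r), 0.1)
  expect_false(sensitivity(gs, rep(5, 7))$defined)
  expect_error(sensitivity(gs[1:4], temp[1:4]), class = "smipp_insufficient_data")
})

test_that("sensitivity transforms correctly under affine climate rescaling", {
  set.seed(16)
  temp <- rnorm(20, 10, 2)
  gs <- 120 - 1.9 * temp + rnorm(20, 0, 2)
  s1 <- sensitivity(gs, temp)
  s2 <- sensitivity(gs, 1.8 * temp + 32)  # e.g. Fahrenheit
  expect_equal(s2$r, s1$r, tolerance = 1e-12)
  expect_equal(s2$slope, s1$slope / 1.8, tolerance = 1e-12)
})

test_that("partial correlation equals the residual-regression oracle", {
  set.seed(27)
  for (i in 1:100) {
    n <- 20
    c1 <- rnorm(n); c2 <- rnorm(n)
    x <- 0.5 * c1 + rnorm(n)
    y <- -0.3 * c2 + 0.4 * x + rnorm(n)
    pc <- partial_correlation(y, x, cbind(c1, c2))
    expect_equal(pc$r, oracle_partial_r(y, x, c1, c2), tolerance = 1e-10)
  }
  # an indicator that is an exact function of a control partials out to ~0
  set.seed(28)
  c1 <- rnorm(50); c2 <- rnorm(50)
  pc0 <- partial_correlation(2 * c1 - 1, rnorm(50), cbind(c1, c2))
  expect_lt(abs(pc0$r), 1e-8)
  # with independent controls, partial r tracks the plain r at large n
  n <- 2000
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  pc1 <- partial_correlation(y, x, cbind(rnorm(n), rnorm(n)))
  expect_lt(abs(pc1$r - cor(x, y)), 0.05)
  # singular control design is flagged, not raised
  expect_false(partial_correlation(y[1:20], x[1:20],
                                   cbind(rep(1, 20), rep(2, 20)))$defined)
})

test_that("recovered sensitivities are unbiased across ensembles", {
  est <- t(sapply(1:8, function(s)
    recover_climate_sensitivity(n_sites = 6, seed = 1000 + s)$mean_abs))
  se <- c(sd(est[, "start"]), sd(est[, "end"])) / sqrt(8)
  expect_lt(abs(mean(est[, "start"]) - 1.9), 3 * se[1])
  expect_lt(abs(mean(est[, "end"]) - 1.7), 3 * se[2])
})
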