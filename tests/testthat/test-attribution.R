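test_that("trend estimates match the closed-form OLS oracle", {
  years <- 2000:2014
  tr <- ols_trend(years, 2 * (years - 2000) + 7)
  expect_equal(tr$slope, 2.0, tolerance = 1e-10)
  expect_lt(tr$p_value, 1e-12)
  expect_equal(ols_trend(years, rep(3.5, 15))$slope, 0, tolerance = 1e-12)
  set.seed(6)
  for (i in 1:100) {
    y <- rnorm(15)
    expect_equal(ols_trend(years, y)$slope, oracle_slope(years, y),
                 tolerance = 1e-10)
  }
  expect_error(ols_trend(1:2, 1:2), class = "smipp_insufficient_data")
})

test_that("trend contributions follow the signed absolute-share formula", {
  c1 <- trend_contributions(1, 2, 1, gpp_trend = 5)
  expect_equal(c(c1$c_start, c1$c_max, c1$c_end), c(25, 50, 25))
  c2 <- trend_contributions(-1, 3, 0, gpp_trend = 5)
  expect_equal(c(c2$c_start, c2$c_max, c2$c_end), c(-25, 75, 0))
  # a shrinking GPP trend flips all the signs
  c3 <- trend_contributions(-1, 3, 0, gpp_trend = -5)
  expect_equal(c(c3$c_start, c3$c_max, c3$c_end), c(25, -75, 0))

  set.seed(23)
  for (i in 1:100) {
    s <- rnorm(3); g <- rnorm(1)
    cc <- trend_contributions(s[1], s[2], s[3], g)
    expect_equal(c(cc$c_start, cc$c_max, cc$c_end),
                 unname(oracle_trend_shares(s, g)), tolerance = 1e-10)
    expect_equal(abs(cc$c_start) + abs(cc$c_max) + abs(cc$c_end), 100,
                 tolerance = 1e-9)
  }
  expect_false(trend_contributions(0, 0, 0, 1)$defined)
})

test_that("IAV shares are consistency-weighted and close to 100 exactly", {
  one <- data.frame(comp_start = c(0, 0, 0), comp_max = c(3, -2, 1),
                    comp_end = c(0, 0, 0), year = 1:3)
  s1 <- iav_contributions(one)
  expect_equal(c(s1$c_start, s1$c_max, s1$c_end), c(0, 100, 0))

  two <- data.frame(comp_start = c(2, -2, 0), comp_max = c(1, -1, 0),
                    comp_end = c(0, 0, 0))
  s2 <- iav_contributions(two)
  expect_equal(c(s2$c_start, s2$c_max, s2$c_end), c(200 / 3, 100 / 3, 0),
               tolerance = 1e-10)

  set.seed(41)
  for (i in 1:100) {
    cm <- matrix(rnorm(45), 15, 3,
                 dimnames = list(NULL, c("comp_start", "comp_max", "comp_end")))
    sh <- iav_contributions(as.data.frame(cm))
    expect_equal(c(sh$c_start, sh$c_max, sh$c_end),
                 unname(oracle_iav_shares(cm, rowSums(cm))), tolerance = 1e-9)
    expect_equal(sh$c_start + sh$c_max + sh$c_end, 100, tolerance = 1e-9)
    # invariant under a common positive rescaling
    sh2 <- iav_contributions(as.data.frame(cm * 3.7))
    expect_equal(c(sh2$c_start, sh2$c_max, sh2$c_end),
                 c(sh$c_start, sh$c_max, sh$c_end), tolerance = 1e-9)
    # against the observed anomaly the oracle still agrees (no exact closure)
    obs <- rowSums(cm) + rnorm(15, 0, 0.1)
    sho <- iav_contributions(as.data.frame(cm), reference = "observed",
                             observed = obs)
    expect_equal(c(sho$c_start, sho$c_max, sho$c_end),
                 unname(oracle_iav_shares(cm, obs)), tolerance = 1e-9)
  }
  zero <- data.frame(comp_start = numeric(3), comp_max = numeric(3),
                     comp_end = numeric(3))
  expect_false(iav_contributions(zero)$defined)
})

test_that("IAV shares are a smaller case of iav_contributions for two years", {
  # single nonzero component with mixed signs stays at 100%
  cm <- data.frame(comp_start = c(5, -3, 1), comp_max = c(0, 0, 0),
                   comp_end = c(0, 0, 0))
  sh <- iav_contributions(cm)
  expect_equal(sh$c_start, 100)
})

test_that("component trends add up to the trend of the fitted anomaly", {
  set.seed(52)
  tab <- make_exact_table(15, c(3, 96, 2.5), 77)
  tab$d_gpp <- tab$d_gpp + rnorm(15, 0, 25)
  fit <- fit_smipp(tab)
  d <- decompose_anomalies(fit)
  lhs <- ols_trend(d$year, d$comp_start)$slope +
    ols_trend(d$year, d$comp_max)$slope +
    ols_trend(d$year, d$comp_end)$slope +
    ols_trend(d$year, d$residual)$slope
  expect_equal(lhs, ols_trend(d$year, d$d_gpp)$slope, tolerance = 1e-9)
})

test_that("spatial correlation treats pixels as observations", {
  set.seed(61)
  a <- rnorm(500)
  expect_equal(spatial_correlation(a, 2 * a)$r2, 1.0, tolerance = 1e-12)
  b <- rnorm(10000)
  a2 <- rnorm(10000)
  expect_lt(spatial_correlation(a2, b)$r2, 0.01)
  noisy <- -a + rnorm(500, 0, 0.5)
  sc <- spatial_correlation(a, noisy)
  expect_equal(sc$r, cor(a, noisy), tolerance = 1e-12)
  expect_equal(sc$r2, cor(a, noisy)^2, tolerance = 1e-12)
  expect_lt(sc$r, 0)
  expect_error(spatial_correlation(1:5, 1:5), class = "smipp_insufficient_data")
  m <- matrix(rnorm(20), 4, 5)
  m2 <- m + rnorm(20, 0, 0.1)
  m2[2, 3] <- NA
  expect_equal(spatial_correlation(m, m2)$n, 19)
})
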