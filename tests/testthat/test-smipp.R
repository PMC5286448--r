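test_that("anomaly table applies the advance/delay sign convention", {
  rec <- data.frame(year = 1:3, gs_start = c(100, 110, 120),
                    gpp_max = c(8, 10, 12), gs_end = c(285, 295, 290),
                    annual_gpp = c(900, 1000, 1100))
  an <- build_anomalies(rec, min_years = 3)
  expect_equal(an$d_gs_start, c(10, 0, -10))  # earlier start counts positive
  expect_equal(an$d_gpp_max, c(-2, 0, 2))
  expect_equal(an$d_gs_end, c(-5, 5, 0))      # later end counts positive
  expect_equal(an$d_gpp, c(-100, 0, 100))
  for (cl in c("d_gpp", "d_gs_start", "d_gpp_max", "d_gs_end"))
    expect_equal(sum(an[[cl]]), 0, tolerance = 1e-12)
})

test_that("anomaly table excludes invalid years listwise and enforces minimum", {
  rec <- data.frame(year = 1:6, gs_start = c(100, 110, 120, 105, 115, 90),
                    gpp_max = c(8, 10, 12, 9, 11, 20),
                    gs_end = c(285, 295, 290, 280, 300, 350),
                    annual_gpp = c(900, 1000, 1100, 950, 1050, 2000),
                    valid = c(rep(TRUE, 5), FALSE))
  an <- build_anomalies(rec)
  expect_equal(nrow(an), 5)
  expect_false(6 %in% an$year)
  expect_error(build_anomalies(rec[1:4, ]), class = "smipp_insufficient_data")
})

test_that("predictor interrelationships are reported, not enforced", {
  an <- data.frame(d_gs_start = c(1, -1, 2, -2, 0),
                   d_gpp_max = c(1, -1, 2, -2, 0),
                   d_gs_end = c(1, 1, -1, -1, 0))
  ci <- check_independence(an)
  expect_equal(ci$r2[ci$pair == "d_gs_start ~ d_gpp_max"], 1.0)
  # orthogonal columns
  an2 <- data.frame(d_gs_start = c(1, 1, -1, -1), d_gpp_max = c(1, -1, 1, -1),
                    d_gs_end = c(1, -1, -1, 1))
  expect_equal(check_independence(an2)$r2, rep(0, 3), tolerance = 1e-12)
  # independent Gaussians are near-orthogonal at n = 1000
  set.seed(31)
  an3 <- data.frame(d_gs_start = rnorm(1000), d_gpp_max = rnorm(1000),
                    d_gs_end = rnorm(1000))
  expect_lt(mean(check_independence(an3)$r2), 0.01)
})

test_that("noise-free tables are recovered exactly with unit R-squared", {
  for (seed in 1:5) {
    tab <- make_exact_table(15, c(3.0, 96.0, 2.5), seed)
    fit <- fit_smipp(tab)
    expect_equal(unname(fit$eta), c(3.0, 96.0, 2.5), tolerance = 1e-8)
    expect_equal(fit$r2, 1.0, tolerance = 1e-10)
    expect_equal(fit$intercept, 0, tolerance = 1e-8)
    d <- decompose_anomalies(fit)
    expect_equal(d$residual, rep(0, 15), tolerance = 1e-8)
  }
})

test_that("degenerate designs fail loudly, naming the offender", {
  tab <- make_exact_table(10, c(3, 96, 2.5), 2)
  tab$d_gpp_max <- 0
  err <- tryCatch(fit_smipp(tab), condition = identity)
  expect_s3_class(err, "smipp_degenerate_design")
  expect_match(conditionMessage(err), "d_gpp_max")
  tab2 <- make_exact_table(10, c(3, 96, 2.5), 3)
  tab2$d_gs_end <- 2 * tab2$d_gs_start  # collinear
  err2 <- tryCatch(fit_smipp(tab2), condition = identity)
  expect_s3_class(err2, "smipp_degenerate_design")
  expect_error(fit_smipp(make_exact_table(4, c(1, 1, 1), 4)),
               class = "smipp_insufficient_data")
})

test_that("decomposition reconstructs every year exactly", {
  set.seed(14)
  for (i in 1:10) {
    tab <- make_exact_table(12, c(3, 96, 2.5), 100 + i)
    tab$d_gpp <- tab$d_gpp + rnorm(12, 0, 20)
    fit <- fit_smipp(tab)
    d <- decompose_anomalies(fit)
    recon <- fit$intercept + d$comp_start + d$comp_max + d$comp_end + d$residual
    expect_equal(recon, tab$d_gpp,
                 tolerance = 1e-9 * max(1, sd(tab$d_gpp)))
    expect_equal(sum(d$residual), 0, tolerance = 1e-8)  # OLS with intercept
  }
  # a zero coefficient zeroes its component
  tab0 <- make_exact_table(12, c(0, 96, 2.5), 55)
  expect_equal(decompose_anomalies(fit_smipp(tab0))$comp_start, rep(0, 12))
})

test_that("fits are equivariant under rescaling of the response", {
  tab <- make_exact_table(15, c(3, 96, 2.5), 9)
  tab$d_gpp <- tab$d_gpp + rnorm(15, 0, 15)
  f1 <- fit_smipp(tab)
  tab2 <- tab
  tab2$d_gpp <- 7 * tab$d_gpp
  f2 <- fit_smipp(tab2)
  expect_equal(f2$eta, 7 * f1$eta, tolerance = 1e-10)
  expect_equal(f2$components, 7 * f1$components, tolerance = 1e-10)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
})

test_that("coefficient t-tests are calibrated under the null", {
  # response independent of the predictors: p-values should be uniform
  set.seed(88)
  pvals <- replicate(300, {
    tab <- make_exact_table(15, c(0, 0, 0), sample.int(1e6, 1))
    tab$d_gpp <- rnorm(15)
    fit_smipp(tab)$p_values[["max"]]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})
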