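# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementation paths.

# Polynomial evaluation by explicit powers (no Horner).
oracle_polyval <- function(coefs, x) {
  as.numeric(outer(x, seq_along(coefs) - 1, `^`) %*% coefs)
}

# OLS slope by the closed-form moment ratio.
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Normal-equations polynomial fit on a scaled abscissa.
oracle_polyfit <- function(doys, values, degree, center = 183, scl = 182) {
  X <- outer((doys - center) / scl, 0:degree, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% values))
}

# Trend-contribution formula evaluated literally.
oracle_trend_shares <- function(s, g) {
  100 * sign(s * g) * abs(s) / sum(abs(s))
}

# Consistency-weighted IAV shares evaluated literally, year by year.
oracle_iav_shares <- function(cm, g) {
  num <- c(0, 0, 0)
  for (i in seq_len(nrow(cm))) num <- num + cm[i, ] * sign(g[i])
  100 * num / sum(abs(g))
}

# Partial correlation via explicit residual regressions.
oracle_partial_r <- function(y, x, c1, c2) {
  ry <- residuals(lm(y ~ c1 + c2))
  rx <- residuals(lm(x ~ c1 + c2))
  cor(ry, rx)
}

# 8-day aggregation by direct slicing.
oracle_8day <- function(daily) {
  out <- numeric(46)
  for (k in 1:45) out[k] <- mean(daily[(8 * k - 7):(8 * k)])
  out[46] <- mean(daily[361:365])
  out
}

# A quick anomaly table with exact linear structure.
make_exact_table <- function(n_years, eta, seed) {
  set.seed(seed)
  ds <- scale(rnorm(n_years, 0, 5), scale = FALSE)[, 1]
  dm <- scale(rnorm(n_years, 0, 1), scale = FALSE)[, 1]
  de <- scale(rnorm(n_years, 0, 5), scale = FALSE)[, 1]
  data.frame(year = seq_len(n_years),
             d_gpp = eta[1] * ds + eta[2] * dm + eta[3] * de,
             d_gs_start = ds, d_gpp_max = dm, d_gs_end = de)
}
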