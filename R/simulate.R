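#' Ground-truth parameters for the synthetic GPP generator
#'
#' Bundles the mean state, long-term trends, inter-annual variability (IAV),
#' temperature couplings and noise level of one synthetic pixel or site.
#' Defaults reflect a mid-latitude temperate site: season from DOY 120 to
#' 280, peak daily GPP 10 g C m-2 d-1, spring phenology advancing 1.9 days
#' per degree of preseason warming and autumn phenology delayed 1.7 days per
#' degree, with moderate residual IAV and observation noise.
#'
#' @param mean_gs_start,mean_gs_end Long-term mean growing-season start/end
#'   (DOY); must satisfy `mean_gs_start < mean_gs_end`.
#' @param mean_gpp_max Long-term mean peak daily GPP (g C m-2 d-1), > 0.
#' @param trend_gs_start,trend_gs_end Linear trends (days yr-1).
#' @param trend_gpp_max Linear trend of the peak (g C m-2 d-1 yr-1).
#' @param iav_sd_gs_start,iav_sd_gs_end SD of climate-independent
#'   year-to-year variability (days).
#' @param iav_sd_gpp_max SD of climate-independent peak variability
#'   (g C m-2 d-1).
#' @param temp_sens_gs_start Coupling to preseason temperature
#'   (days per degree C; negative = earlier start when warmer).
#' @param temp_sens_gs_end Coupling to preseason temperature
#'   (days per degree C; positive = later end when warmer).
#' @param temp_sens_gpp_max Coupling of the peak to summer (JJA) temperature
#'   (g C m-2 d-1 per degree C).
#' @param obs_noise_sd SD of additive Gaussian observation noise on daily
#'   GPP (g C m-2 d-1); series are clipped at 0.
#' @param climate_anom_sd SD of the year-specific seasonal temperature
#'   anomalies (degrees C) that drive the couplings.
#' @param temp_noise_sd SD of day-to-day temperature noise (degrees C).
#' @param n_years Number of years (>= 3).
#' @param start_year First calendar year label.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   seed and parameters.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(mean_gs_start = 120, mean_gs_end = 280,
                         mean_gpp_max = 10,
                         trend_gs_start = 0, trend_gs_end = 0,
                         trend_gpp_max = 0,
                         iav_sd_gs_start = 2.5, iav_sd_gs_end = 2.5,
                         iav_sd_gpp_max = 0.5,
                         temp_sens_gs_start = -1.9, temp_sens_gs_end = 1.7,
                         temp_sens_gpp_max = 0.2,
                         obs_noise_sd = 0.5,
                         climate_anom_sd = 2.0, temp_noise_sd = 1.5,
                         n_years = 15L, start_year = 2000L, seed = 1L) {
  p <- list(mean_gs_start = mean_gs_start, mean_gs_end = mean_gs_end,
            mean_gpp_max = mean_gpp_max,
            trend_gs_start = trend_gs_start, trend_gs_end = trend_gs_end,
            trend_gpp_max = trend_gpp_max,
            iav_sd_gs_start = iav_sd_gs_start, iav_sd_gs_end = iav_sd_gs_end,
            iav_sd_gpp_max = iav_sd_gpp_max,
            temp_sens_gs_start = temp_sens_gs_start,
            temp_sens_gs_end = temp_sens_gs_end,
            temp_sens_gpp_max = temp_sens_gpp_max,
            obs_noise_sd = obs_noise_sd,
            climate_anom_sd = climate_anom_sd, temp_noise_sd = temp_noise_sd,
            n_years = as.integer(n_years), start_year = as.integer(start_year),
            seed = as.integer(seed))
  if (!is.finite(p$mean_gs_start) || !is.finite(p$mean_gs_end) ||
      p$mean_gs_start >= p$mean_gs_end)
    stop_invalid_parameters("truth_params: mean_gs_start must be < mean_gs_end")
  if (p$mean_gpp_max <= 0)
    stop_invalid_parameters("truth_params: mean_gpp_max must be > 0")
  if (p$n_years < 3L)
    stop_invalid_parameters("truth_params: n_years must be >= 3")
  sds <- c(p$iav_sd_gs_start, p$iav_sd_gs_end, p$iav_sd_gpp_max,
           p$obs_noise_sd, p$climate_anom_sd, p$temp_noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop_invalid_parameters("truth_params: all SDs must be finite and >= 0")
  structure(p, class = "truth_params")
}

# Deterministic seasonal (climatological) components of the daily climate.
seasonal_temperature <- function(doys) {
  8 - 15 * cos(2 * pi * (doys - 17.5) / 365)
}
seasonal_radiation <- function(doys) {
  200 - 150 * cos(2 * pi * (doys - 10) / 365)
}

# Seasonal block of each DOY: 1 = spring (1-151), 2 = summer/JJA (152-243),
# 3 = autumn (244-365). Year-specific temperature anomalies are constant
# within a block and independent across blocks, so the three indicator
# couplings are driven by mutually independent climate anomalies.
season_block <- function(doys) {
  ifelse(doys < min(JJA_DOYS), 1L, ifelse(doys <= max(JJA_DOYS), 2L, 3L))
}

# Mean over the 30-day (or `window`) preseason DOY range, clamped to the
# current year. Used internally to read the realized driver anomaly.
window_doys <- function(mean_date, window) {
  d <- (ceiling(mean_date) - window):(ceiling(mean_date) - 1)
  d[d >= 1 & d <= DAYS_PER_YEAR]
}

#' Simulate one site: daily GPP, daily climate and the ground-truth table
#'
#' Generates `n_years` of daily GPP and climate for a single site/pixel.
#' Per year, the indicator truths are
#' `mean + trend * (year index) + coupling * (realized seasonal temperature
#' anomaly) + independent Gaussian IAV`; the daily GPP is the exact
#' [seasonal_curve()] through those truths plus additive Gaussian
#' observation noise clipped at 0. Daily temperature is a seasonal sinusoid
#' plus a year- and season-specific anomaly (constant over spring, summer
#' and autumn blocks) plus day-to-day noise; the couplings are driven by the
#' *realized* mean temperature anomaly of each indicator's own window (the
#' 30 days preceding the long-term mean start/end date; JJA for the peak),
#' so regressing the truths on the aggregated climate recovers the
#' prescribed sensitivities without attenuation.
#'
#' @param params A [truth_params()] object.
#' @param preseason_window Length of the preseason driver window in days
#'   (default 30).
#' @return A list of class `smipp_site` with elements
#'   * `gpp`: data.frame (year, doy, date, gpp) — daily GPP, g C m-2 d-1;
#'   * `climate`: data.frame (year, doy, date, temperature, precipitation,
#'     radiation) — daily climate;
#'   * `truth`: data.frame (year, gs_start, gpp_max, gs_end, annual_gpp,
#'     preseason_temp_start, jja_temp, preseason_temp_end) — exact per-year
#'     truths; `annual_gpp` is the sum of the noise-free daily curve;
#'   * `params`: the input parameters.
#' @export
simulate_site <- function(params, preseason_window = 30L) {
  stopifnot(inherits(params, "truth_params"))
  p <- params
  set.seed(p$seed)
  doys <- seq_len(DAYS_PER_YEAR)
  blocks <- season_block(doys)
  t_clim <- seasonal_temperature(doys)

  w_start <- window_doys(p$mean_gs_start, preseason_window)
  w_end <- window_doys(p$mean_gs_end, preseason_window)
  exp_start <- mean(t_clim[w_start])
  exp_jja <- mean(t_clim[JJA_DOYS])
  exp_end <- mean(t_clim[w_end])

  years <- p$start_year + seq_len(p$n_years) - 1L
  gpp_rows <- vector("list", p$n_years)
  clim_rows <- vector("list", p$n_years)
  truth_rows <- vector("list", p$n_years)

  for (i in seq_len(p$n_years)) {
    block_anom <- stats::rnorm(3L, 0, p$climate_anom_sd)
    temp <- t_clim + block_anom[blocks] + stats::rnorm(DAYS_PER_YEAR, 0, p$temp_noise_sd)
    precip <- stats::rgamma(DAYS_PER_YEAR, shape = 0.5, scale = 5)
    rad <- pmax(seasonal_radiation(doys) + stats::rnorm(DAYS_PER_YEAR, 0, 20), 0)

    pre_start <- mean(temp[w_start])
    jja <- mean(temp[JJA_DOYS])
    pre_end <- mean(temp[w_end])

    iav <- stats::rnorm(3L)
    gs_start <- p$mean_gs_start + p$trend_gs_start * (i - 1) +
      p$temp_sens_gs_start * (pre_start - exp_start) + p$iav_sd_gs_start * iav[1]
    gs_end <- p$mean_gs_end + p$trend_gs_end * (i - 1) +
      p$temp_sens_gs_end * (pre_end - exp_end) + p$iav_sd_gs_end * iav[2]
    gpp_max <- p$mean_gpp_max + p$trend_gpp_max * (i - 1) +
      p$temp_sens_gpp_max * (jja - exp_jja) + p$iav_sd_gpp_max * iav[3]
    if (gs_start >= gs_end || gpp_max <= 0)
      stop_invalid_parameters(sprintf(
        "simulate_site: degenerate year %d (gs_start=%.1f, gs_end=%.1f, gpp_max=%.2f); reduce trends/IAV",
        years[i], gs_start, gs_end, gpp_max))

    clean <- seasonal_curve(gs_start, gs_end, gpp_max)
    gpp <- pmax(clean + stats::rnorm(DAYS_PER_YEAR, 0, p$obs_noise_sd), 0)

    gpp_rows[[i]] <- data.frame(year = years[i], doy = doys, gpp = gpp)
    clim_rows[[i]] <- data.frame(year = years[i], doy = doys,
                                 temperature = temp, precipitation = precip,
                                 radiation = rad)
    truth_rows[[i]] <- data.frame(year = years[i], gs_start = gs_start,
                                  gpp_max = gpp_max, gs_end = gs_end,
                                  annual_gpp = sum(clean),
                                  preseason_temp_start = pre_start,
                                  jja_temp = jja,
                                  preseason_temp_end = pre_end)
  }
  gpp_df <- do.call(rbind, gpp_rows)
  clim_df <- do.call(rbind, clim_rows)
  gpp_df$date <- doy_to_date(gpp_df$year, gpp_df$doy)
  clim_df$date <- doy_to_date(clim_df$year, clim_df$doy)
  gpp_df <- gpp_df[, c("year", "doy", "date", "gpp")]
  clim_df <- clim_df[, c("year", "doy", "date", "temperature",
                         "precipitation", "radiation")]
  structure(list(gpp = gpp_df, climate = clim_df,
                 truth = do.call(rbind, truth_rows), params = p),
            class = "smipp_site")
}

#' Simulate a grid of pixels with 8-day GPP composites
#'
#' Runs [simulate_site()] independently for each pixel (with a pixel-derived
#' seed) and aggregates the daily GPP to 46 8-day composites per year
#' (composite 46 averages the final 5 days). No spatial autocorrelation is
#' imposed: pixels are independent.
#'
#' @param params Either one [truth_params()] object shared by all pixels
#'   (each still gets an independent seed) or a list of `ny * nx` objects in
#'   row-major order (x varying fastest).
#' @param ny,nx Grid dimensions.
#' @param preseason_window Passed to [simulate_site()].
#' @return A list of class `smipp_grid` with elements
#'   * `gpp`: data.frame (y, x, year, composite, gpp) — 8-day composites;
#'   * `climate`: data.frame (y, x, year, doy, temperature, precipitation,
#'     radiation) — daily climate per pixel;
#'   * `truth`: data.frame (y, x, year, ...) as in [simulate_site()];
#'   * `ny`, `nx`.
#' @export
simulate_grid <- function(params, ny, nx, preseason_window = 30L) {
  n_pix <- as.integer(ny) * as.integer(nx)
  if (inherits(params, "truth_params")) {
    params <- lapply(seq_len(n_pix), function(i) {
      q <- unclass(params)
      q$seed <- params$seed + i - 1L
      do.call(truth_params, q)
    })
  }
  if (!is.list(params) || length(params) != n_pix)
    stop_invalid_parameters(sprintf(
      "simulate_grid: need %d truth_params for a %dx%d grid, got %d",
      n_pix, ny, nx, length(params)))

  gpp_rows <- vector("list", n_pix)
  clim_rows <- vector("list", n_pix)
  truth_rows <- vector("list", n_pix)
  k <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    k <- k + 1L
    site <- simulate_site(params[[k]], preseason_window = preseason_window)
    comp <- do.call(rbind, lapply(split(site$gpp, site$gpp$year), function(d) {
      data.frame(y = iy, x = ix, year = d$year[1],
                 composite = seq_len(N_COMPOSITES),
                 gpp = aggregate_8day(d$gpp[order(d$doy)]))
    }))
    rownames(comp) <- NULL
    gpp_rows[[k]] <- comp
    clim_rows[[k]] <- cbind(y = iy, x = ix,
                            site$climate[, c("year", "doy", "temperature",
                                             "precipitation", "radiation")])
    truth_rows[[k]] <- cbind(y = iy, x = ix, site$truth)
  }
  structure(list(gpp = do.call(rbind, gpp_rows),
                 climate = do.call(rbind, clim_rows),
                 truth = do.call(rbind, truth_rows),
                 ny = as.integer(ny), nx = as.integer(nx)),
            class = "smipp_grid")
}

#' Synthetic ensemble of SMIPP anomaly tables with known coefficients
#'
#' Generates `n_cells` independent anomaly tables of `n_years` years with
#' prescribed true sensitivity coefficients. Indicator anomalies are
#' independent Gaussians (then centred); the annual-GPP anomaly is the exact
#' linear combination plus Gaussian noise whose SD is derived analytically
#' from the requested population R-squared:
#' `noise_var = signal_var * (1 - r2) / r2`.
#'
#' @param n_cells Number of cells (independent tables).
#' @param n_years Years per cell.
#' @param eta Named numeric: true coefficients `start` (g C m-2 per day of
#'   advance), `max` (g C m-2 yr-1 per g C m-2 d-1), `end` (g C m-2 per day
#'   of delay).
#' @param sd_anom Named numeric SDs of the indicator anomalies: `start`,
#'   `end` in days, `max` in g C m-2 d-1.
#' @param target_r2 Population R-squared of each cell's regression (noise
#'   calibration target), in (0, 1].
#' @param seed Integer seed.
#' @return List of `n_cells` anomaly data.frames with columns
#'   `year, d_gpp, d_gs_start, d_gpp_max, d_gs_end` (all columns centred).
#' @export
simulate_anomaly_ensemble <- function(n_cells = 500L, n_years = 15L,
                                      eta = c(start = 2.9, max = 95.9, end = 2.4),
                                      sd_anom = c(start = 4, max = 0.8, end = 4),
                                      target_r2 = 0.98, seed = 1L) {
  if (target_r2 <= 0 || target_r2 > 1)
    stop_invalid_parameters("simulate_anomaly_ensemble: target_r2 must be in (0, 1]")
  signal_var <- sum(eta[c("start", "max", "end")]^2 *
                    sd_anom[c("start", "max", "end")]^2)
  noise_sd <- sqrt(signal_var * (1 - target_r2) / target_r2)
  set.seed(seed)
  lapply(seq_len(n_cells), function(i) {
    ds <- scale(stats::rnorm(n_years, 0, sd_anom[["start"]]), scale = FALSE)[, 1]
    dm <- scale(stats::rnorm(n_years, 0, sd_anom[["max"]]), scale = FALSE)[, 1]
    de <- scale(stats::rnorm(n_years, 0, sd_anom[["end"]]), scale = FALSE)[, 1]
    dg <- eta[["start"]] * ds + eta[["max"]] * dm + eta[["end"]] * de +
      stats::rnorm(n_years, 0, noise_sd)
    data.frame(year = seq_len(n_years),
               d_gpp = scale(dg, scale = FALSE)[, 1],
               d_gs_start = ds, d_gpp_max = dm, d_gs_end = de)
  })
}
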