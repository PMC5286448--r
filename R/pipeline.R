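#' Pipeline configuration with validated defaults
#'
#' Defaults reproduce the analysis' standard choices: degree-6 polynomial
#' smoothing for 8-day data, 4-component SSA for daily data, a 10% peak
#' threshold, a 30-day preseason window, and contributions referenced to
#' the reconstructed anomaly.
#'
#' @param cadence `"8day"` (gridded pipeline) or `"daily"` (site pipeline).
#' @param fraction Threshold fraction in (0, 1).
#' @param ssa_window,ssa_components SSA settings for daily series.
#' @param degree Polynomial degree for 8-day series.
#' @param min_years Minimum usable years for the SMIPP regression.
#' @param preseason_window Preseason window length (days).
#' @param iav_reference `"reconstructed"` or `"observed"`.
#' @param seed Integer seed for synthetic inputs.
#' @param ny,nx Synthetic grid shape (8-day cadence).
#' @param n_years Years to simulate.
#' @param truth Named list of [truth_params()] overrides for the synthetic
#'   generator (e.g. `list(mean_gpp_max = 12)`).
#' @param paths Named list of input/output paths; `paths$gpp_grid` reads a
#'   grid CSV instead of simulating (climate sensitivity is then skipped).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cadence = "8day", fraction = 0.10,
                            ssa_window = 120L, ssa_components = 4L,
                            degree = 6L, min_years = 5L,
                            preseason_window = 30L,
                            iav_reference = "reconstructed",
                            seed = 1L, ny = 4L, nx = 4L, n_years = 15L,
                            truth = list(), paths = list()) {
  cfg <- list(cadence = match.arg(cadence, c("8day", "daily")),
              fraction = fraction,
              ssa_window = as.integer(ssa_window),
              ssa_components = as.integer(ssa_components),
              degree = as.integer(degree),
              min_years = as.integer(min_years),
              preseason_window = as.integer(preseason_window),
              iav_reference = match.arg(iav_reference,
                                        c("reconstructed", "observed")),
              seed = as.integer(seed), ny = as.integer(ny),
              nx = as.integer(nx), n_years = as.integer(n_years),
              truth = truth, paths = paths)
  if (!is.finite(cfg$fraction) || cfg$fraction <= 0 || cfg$fraction >= 1)
    stop_invalid_parameters("pipeline_config: fraction must be in (0, 1)")
  if (cfg$ssa_window < 2L || cfg$ssa_components < 1L ||
      cfg$ssa_components > cfg$ssa_window)
    stop_invalid_parameters("pipeline_config: invalid SSA settings")
  if (cfg$degree < 2L)
    stop_invalid_parameters("pipeline_config: degree must be >= 2")
  if (cfg$min_years < 5L)
    stop_invalid_parameters("pipeline_config: min_years must be >= 5")
  if (cfg$preseason_window < 1L)
    stop_invalid_parameters("pipeline_config: preseason_window must be >= 1")
  if (cfg$n_years < 3L || cfg$ny < 1L || cfg$nx < 1L)
    stop_invalid_parameters("pipeline_config: invalid grid/period settings")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Fields present in the file override [pipeline_config()] defaults; every
#' field is validated on load.
#'
#' @param path YAML file.
#' @param ... Further overrides applied after the file (e.g. CLI flags).
#' @return A `pipeline_config`.
#' @export
load_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  dots <- list(...)
  raw[names(dots)] <- dots
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_format_error(paste("load_config: unknown field(s)",
                            paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}

# 32-bit FNV-1a hash of a character string, as 8 hex digits. Used for the
# run manifest; implemented with split multiplication to stay exact in
# double arithmetic.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- xor_double(h, b)
    h1 <- floor(h / 65536)
    h0 <- h - h1 * 65536
    h <- ((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619
    h <- h %% 4294967296
  }
  hi <- floor(h / 65536)
  sprintf("%04x%04x", as.integer(hi), as.integer(h - hi * 65536))
}

# xor of a 32-bit value (double) with a byte.
xor_double <- function(h, b) {
  lo <- h %% 2^31
  hi <- h - lo
  hi + bitwXor(as.integer(lo), as.integer(b))
}

# Stable textual fingerprint of a results bundle: numbers rounded to 10
# significant digits so the hash is machine-independent.
fingerprint <- function(x) {
  if (is.list(x) && !is.data.frame(x))
    return(paste(vapply(x, fingerprint, character(1)), collapse = ";"))
  if (is.data.frame(x)) x <- unlist(lapply(x, function(cl) cl), use.names = FALSE)
  if (is.numeric(x)) x <- signif(x, 10)
  paste(format(x, trim = TRUE, scientific = TRUE, digits = 10),
        collapse = ",")
}

#' Run the full gridded pipeline end-to-end
#'
#' Simulates (or reads) an 8-day GPP grid with daily climate, then per
#' pixel: smooths each year, extracts the indicators, fits the SMIPP,
#' decomposes the anomalies, computes component and annual-GPP trends,
#' trend- and IAV-mode contributions, and preseason/summer temperature
#' sensitivities. Writes CSV products and a JSON run manifest (resolved
#' config, seed, package version, FNV-1a result hash) when `out_dir` is
#' given. Identical config and seed give an identical manifest hash.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional output directory (created if needed).
#' @param overwrite Refuse to clobber existing outputs unless TRUE.
#' @param quiet Suppress per-stage progress messages (stderr).
#' @return List of class `smipp_run`: `indicators`, `fits`, `contributions`,
#'   `sensitivities` (data.frames keyed by pixel), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, overwrite = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  if (!is.null(config$paths$gpp_grid)) {
    say("stage simulate: reading grid from %s", config$paths$gpp_grid)
    grid <- read_grid_csv(config$paths$gpp_grid)
    grid$climate <- NULL
  } else {
    say("stage simulate: %dx%d grid, %d years, seed %d",
        config$ny, config$nx, config$n_years, config$seed)
    tp <- do.call(truth_params,
                  c(config$truth,
                    list(n_years = config$n_years, seed = config$seed)))
    grid <- simulate_grid(tp, config$ny, config$nx,
                          preseason_window = config$preseason_window)
  }

  pix <- unique(grid$gpp[, c("y", "x")])
  ind_rows <- list(); fit_rows <- list(); con_rows <- list(); sen_rows <- list()
  for (i in seq_len(nrow(pix))) {
    iy <- pix$y[i]; ix <- pix$x[i]
    sel <- grid$gpp$y == iy & grid$gpp$x == ix
    stage <- "indicators"
    res <- tryCatch({
      ind <- extract_phenology(grid$gpp[sel, ], cadence = "8day",
                               fraction = config$fraction,
                               degree = config$degree)
      stage <- "fit"
      anoms <- build_anomalies(ind, min_years = config$min_years)
      fit <- fit_smipp(anoms, min_years = config$min_years)
      stage <- "attribute"
      comps <- decompose_anomalies(fit)
      tr <- list(start = ols_trend(comps$year, comps$comp_start),
                 max = ols_trend(comps$year, comps$comp_max),
                 end = ols_trend(comps$year, comps$comp_end),
                 gpp = ols_trend(anoms$year, anoms$d_gpp))
      tc <- trend_contributions(tr$start$slope, tr$max$slope, tr$end$slope,
                                tr$gpp$slope)
      ic <- iav_contributions(comps, reference = config$iav_reference,
                              observed = anoms$d_gpp)
      sen <- NULL
      if (!is.null(grid$climate)) {
        stage <- "sensitivity"
        clim <- grid$climate[grid$climate$y == iy & grid$climate$x == ix, ]
        v <- ind$valid
        pre_s <- preseason_aggregate(clim, "temperature",
                                     mean(ind$gs_start[v]),
                                     config$preseason_window)
        pre_e <- preseason_aggregate(clim, "temperature",
                                     mean(ind$gs_end[v]),
                                     config$preseason_window)
        jja <- summer_aggregate(clim, "temperature")
        ss <- sensitivity(ind$gs_start[match(pre_s$year, ind$year)], pre_s$value)
        se <- sensitivity(ind$gs_end[match(pre_e$year, ind$year)], pre_e$value)
        sm <- sensitivity(ind$gpp_max[match(jja$year, ind$year)], jja$value)
        sen <- data.frame(y = iy, x = ix,
                          indicator = c("gs_start", "gpp_max", "gs_end"),
                          climate = c("preseason_temp", "jja_temp",
                                      "preseason_temp"),
                          r = c(ss$r, sm$r, se$r),
                          slope = c(ss$slope, sm$slope, se$slope),
                          p_value = c(ss$p_value, sm$p_value, se$p_value))
      }
      list(ind = cbind(y = iy, x = ix, ind),
           fit = data.frame(y = iy, x = ix,
                            eta_start = fit$eta[["start"]],
                            eta_max = fit$eta[["max"]],
                            eta_end = fit$eta[["end"]],
                            r2 = fit$r2,
                            p_start = fit$p_values[["start"]],
                            p_max = fit$p_values[["max"]],
                            p_end = fit$p_values[["end"]],
                            gpp_trend = tr$gpp$slope),
           con = data.frame(y = iy, x = ix,
                            mode = c("trend", "iav"),
                            c_start = c(tc$c_start, ic$c_start),
                            c_max = c(tc$c_max, ic$c_max),
                            c_end = c(tc$c_end, ic$c_end)),
           sen = sen)
    }, smipp_error = function(e)
      stop(sprintf("pipeline halted at stage '%s', pixel (y=%d, x=%d): %s",
                   stage, iy, ix, conditionMessage(e)), call. = FALSE))
    ind_rows[[i]] <- res$ind; fit_rows[[i]] <- res$fit
    con_rows[[i]] <- res$con; sen_rows[[i]] <- res$sen
  }

  indicators <- do.call(rbind, ind_rows)
  fits <- do.call(rbind, fit_rows)
  contributions <- do.call(rbind, con_rows)
  sensitivities <- if (length(Filter(Negate(is.null), sen_rows)))
    do.call(rbind, sen_rows) else NULL
  say("stage summary: %d pixels fitted in %.1f s", nrow(fits),
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  cfg_plain <- unclass(config)
  manifest <- list(
    config = cfg_plain,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("smipp")),
    n_pixels = nrow(fits),
    result_hash = fnv1a_hash(c(fingerprint(cfg_plain[setdiff(names(cfg_plain), "paths")]),
                               fingerprint(indicators), fingerprint(fits),
                               fingerprint(contributions),
                               fingerprint(sensitivities))))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(indicators, file.path(out_dir, "indicators.csv"), overwrite)
    write_table_csv(fits, file.path(out_dir, "fits.csv"), overwrite)
    write_table_csv(contributions, file.path(out_dir, "contributions.csv"),
                    overwrite)
    if (!is.null(sensitivities))
      write_table_csv(sensitivities, file.path(out_dir, "sensitivity.csv"),
                      overwrite)
    manifest_path <- file.path(out_dir, "manifest.json")
    if (file.exists(manifest_path) && !overwrite)
      stop_invalid_parameters(sprintf(
        "run_pipeline: %s exists (set overwrite = TRUE)", manifest_path))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  structure(list(indicators = indicators, fits = fits,
                 contributions = contributions,
                 sensitivities = sensitivities, manifest = manifest),
            class = "smipp_run")
}
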