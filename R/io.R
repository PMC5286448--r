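MISSING_CODES <- c("", "NA", "-9999", "-9999.0")

#' Write a site's daily GPP and climate to CSV
#'
#' Columns `date, gpp, temperature, precipitation, radiation`, one row per
#' day on the 365-day calendar.
#'
#' @param site A `smipp_site` from [simulate_site()], or a list with `gpp`
#'   and `climate` data.frames in that layout.
#' @param path Output CSV path.
#' @param overwrite Refuse to clobber an existing file unless TRUE.
#' @return `path`, invisibly.
#' @export
write_site_csv <- function(site, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop_invalid_parameters(sprintf(
      "write_site_csv: %s exists (set overwrite = TRUE)", path))
  d <- merge(site$gpp[, c("date", "gpp")],
             site$climate[, c("date", "temperature", "precipitation",
                              "radiation")],
             by = "date", sort = TRUE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site CSV of daily GPP and climate
#'
#' Expects a header `date, gpp` and optionally `temperature,
#' precipitation, radiation`. Dates are parsed as ISO `YYYY-MM-DD`; Feb 29
#' rows are dropped and later days renumbered onto the 365-day calendar.
#' Empty fields, `NA` and `-9999` are treated as missing (never as zero).
#'
#' @param path CSV path.
#' @return List with `gpp` (data.frame `year, doy, date, gpp`) and
#'   `climate` (data.frame `year, doy, date, temperature, precipitation,
#'   radiation`; NULL when the file has no climate columns).
#' @export
read_site_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("date", "gpp") %in% names(d)))
    stop_format_error("read_site_csv: header must contain 'date' and 'gpp'")
  dates <- as.Date(d$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stop_format_error(sprintf(
      "read_site_csv: unparseable date '%s' at line %d", d$date[bad], bad + 1L))
  }
  num <- function(col) {
    if (!col %in% names(d)) return(NULL)
    v <- trimws(d[[col]])
    v[v %in% MISSING_CODES] <- NA
    suppressWarnings(as.numeric(v))
  }
  cal <- date_to_doy(dates)
  keep <- !is.na(cal$doy)  # drop Feb 29
  out_gpp <- data.frame(year = cal$year[keep], doy = cal$doy[keep],
                        date = dates[keep], gpp = num("gpp")[keep])
  clim_cols <- intersect(c("temperature", "precipitation", "radiation"),
                         names(d))
  climate <- NULL
  if (length(clim_cols)) {
    climate <- data.frame(year = cal$year[keep], doy = cal$doy[keep],
                          date = dates[keep])
    for (cl in clim_cols) climate[[cl]] <- num(cl)[keep]
  }
  list(gpp = out_gpp, climate = climate)
}

#' Write a gridded 8-day GPP cube to long-format CSV
#'
#' Long format, one row per (pixel, year, composite):
#' `y, x, year, composite, gpp`. Composites are 1-based; composite k starts
#' at DOY 8(k-1)+1; grids are y-north-up. Values are g C m-2 d-1.
#'
#' @param grid A `smipp_grid` from [simulate_grid()], or any data.frame in
#'   that layout (passed as the `gpp` element of a list).
#' @param path Output CSV path.
#' @param overwrite Refuse to clobber an existing file unless TRUE.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop_invalid_parameters(sprintf(
      "write_grid_csv: %s exists (set overwrite = TRUE)", path))
  d <- grid$gpp[, c("y", "x", "year", "composite", "gpp")]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gridded 8-day GPP cube from long-format CSV
#'
#' Validates that every (pixel, year) has all 46 composites in strictly
#' increasing order.
#'
#' @param path CSV path written by [write_grid_csv()] (or matching its
#'   layout).
#' @return List of class `smipp_grid` with elements `gpp`, `ny`, `nx`.
#' @export
read_grid_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("y", "x", "year", "composite", "gpp")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_format_error(paste("read_grid_csv: missing column(s)",
                            paste(miss, collapse = ", ")))
  split_key <- interaction(d$y, d$x, d$year, drop = TRUE)
  for (chunk in split(d$composite, split_key)) {
    if (length(chunk) != N_COMPOSITES || any(diff(chunk) <= 0) ||
        chunk[1] != 1L)
      stop_format_error(
        "read_grid_csv: each pixel-year must have composites 1..46 in increasing order")
  }
  structure(list(gpp = d, ny = max(d$y), nx = max(d$x)),
            class = "smipp_grid")
}

#' Write a per-year table (truth, indicators, fits) to CSV
#'
#' @param table A data.frame.
#' @param path Output path.
#' @param overwrite Refuse to clobber an existing file unless TRUE.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop_invalid_parameters(sprintf(
      "write_table_csv: %s exists (set overwrite = TRUE)", path))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
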