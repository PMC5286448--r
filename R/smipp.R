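#' Signed anomaly table for the SMIPP regression
#'
#' Converts a per-year indicator table into anomalies about the record
#' means (valid years only). Sign convention: growing-season-start
#' anomalies are counted positive when the start *advances* (mean minus
#' value), and end anomalies positive when the end *delays* (value minus
#' mean), so both phenology coefficients are expected positive where a
#' longer season means more carbon uptake.
#'
#' @param records data.frame from [extract_phenology()] (columns `year`,
#'   `gs_start`, `gpp_max`, `gs_end`, `annual_gpp`, optionally `valid`).
#' @param min_years Minimum number of valid years (default 5: at least one
#'   residual degree of freedom when fitting 4 parameters).
#' @return data.frame `year, d_gpp, d_gs_start, d_gpp_max, d_gs_end`; each
#'   column sums to 0 to numerical tolerance.
#' @examples
#' rec <- data.frame(year = 1:5, gs_start = c(100, 110, 120, 105, 115),
#'                   gpp_max = c(8, 12, 10, 9, 11),
#'                   gs_end = c(285, 295, 290, 288, 292),
#'                   annual_gpp = c(900, 1100, 1000, 950, 1050))
#' build_anomalies(rec)
#' @export
build_anomalies <- function(records, min_years = 5L) {
  need <- c("year", "gs_start", "gpp_max", "gs_end", "annual_gpp")
  if (!all(need %in% names(records)))
    stop_format_error(paste("build_anomalies: records need columns",
                            paste(need, collapse = ", ")))
  keep <- if ("valid" %in% names(records)) records$valid else TRUE
  keep <- keep & stats::complete.cases(records[, need])
  r <- records[keep, ]
  if (nrow(r) < min_years)
    stop_insufficient_data(sprintf(
      "build_anomalies: %d valid years < minimum %d", nrow(r), min_years))
  data.frame(year = r$year,
             d_gpp = r$annual_gpp - mean(r$annual_gpp),
             d_gs_start = mean(r$gs_start) - r$gs_start,
             d_gpp_max = r$gpp_max - mean(r$gpp_max),
             d_gs_end = r$gs_end - mean(r$gs_end))
}

#' Pairwise interrelationships of the three SMIPP predictors
#'
#' The SMIPP assumes the three indicators vary independently; this reports
#' (but does not enforce) the pairwise coefficients of determination and
#' their significance among the anomaly predictors.
#'
#' @param anomalies data.frame from [build_anomalies()].
#' @return data.frame with one row per pair: `pair, r2, p_value, n`.
#' @export
check_independence <- function(anomalies) {
  cols <- c("d_gs_start", "d_gpp_max", "d_gs_end")
  pairs <- utils::combn(cols, 2)
  rows <- apply(pairs, 2, function(pr) {
    x <- anomalies[[pr[1]]]
    y <- anomalies[[pr[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      data.frame(pair = paste(pr, collapse = " ~ "), r2 = NA_real_,
                 p_value = NA_real_, n = length(x))
    } else {
      ct <- stats::cor.test(x, y)
      data.frame(pair = paste(pr, collapse = " ~ "),
                 r2 = unname(ct$estimate)^2, p_value = ct$p.value,
                 n = length(x))
    }
  })
  do.call(rbind, rows)
}

#' Fit the SMIPP: annual-GPP anomalies on the three indicator anomalies
#'
#' Ordinary least squares of the annual-GPP anomaly on the anomalies of
#' growing-season start (advance positive), peak daily GPP, and
#' growing-season end (delay positive). The three fitted coefficients are
#' the sensitivity coefficients of annual GPP to the indicators; each
#' year's fitted anomaly splits exactly into the intercept plus the three
#' components `eta_x * anomaly_x`.
#'
#' @param anomalies data.frame from [build_anomalies()].
#' @param intercept Include an intercept (default TRUE). Mean-centred
#'   anomalies force it to ~0, but it keeps the decomposition exact when
#'   years were dropped after centring.
#' @param min_years Minimum usable years (default 5).
#' @return Object of class `smipp_fit`: `eta` (named start/max/end),
#'   `intercept`, `r2`, `p_values`, `components` (n x 3 matrix), `fitted`,
#'   `residuals`, `n_years`, `anomalies`.
#' @export
fit_smipp <- function(anomalies, intercept = TRUE, min_years = 5L) {
  cols <- c("d_gs_start", "d_gpp_max", "d_gs_end")
  if (!all(c("d_gpp", cols) %in% names(anomalies)))
    stop_format_error("fit_smipp: anomalies need columns d_gpp, d_gs_start, d_gpp_max, d_gs_end")
  n <- nrow(anomalies)
  if (n < min_years)
    stop_insufficient_data(sprintf("fit_smipp: %d years < minimum %d", n, min_years))
  for (cl in cols)
    if (stats::sd(anomalies[[cl]]) == 0)
      stop(errorCondition(
        sprintf("fit_smipp: predictor %s has zero variance", cl),
        class = c("smipp_degenerate_design", "smipp_error")))

  fml <- if (intercept) d_gpp ~ d_gs_start + d_gpp_max + d_gs_end
         else d_gpp ~ d_gs_start + d_gpp_max + d_gs_end - 1
  fit <- stats::lm(fml, data = anomalies)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(errorCondition(
      sprintf("fit_smipp: rank-deficient design (predictor %s)",
              paste(bad, collapse = ", ")),
      class = c("smipp_degenerate_design", "smipp_error")))
  }
  cf <- stats::coef(fit)
  # noise-free tables fit perfectly; summary()'s reminder about that is expected
  sm <- suppressWarnings(summary(fit))
  eta <- stats::setNames(cf[cols], c("start", "max", "end"))
  comps <- cbind(start = eta[["start"]] * anomalies$d_gs_start,
                 max = eta[["max"]] * anomalies$d_gpp_max,
                 end = eta[["end"]] * anomalies$d_gs_end)
  pv <- sm$coefficients[, "Pr(>|t|)"]
  structure(list(eta = eta,
                 intercept = if (intercept) cf[["(Intercept)"]] else 0,
                 r2 = sm$r.squared,
                 p_values = stats::setNames(pv[cols], c("start", "max", "end")),
                 components = comps,
                 fitted = as.numeric(stats::fitted(fit)),
                 residuals = as.numeric(stats::residuals(fit)),
                 n_years = n, anomalies = anomalies),
            class = "smipp_fit")
}

#' @export
print.smipp_fit <- function(x, ...) {
  cat("SMIPP fit (", x$n_years, " years)\n", sep = "")
  cat(sprintf("  eta_start: %8.3f g C m-2 per day of advance (p = %.3g)\n",
              x$eta[["start"]], x$p_values[["start"]]))
  cat(sprintf("  eta_max:   %8.3f g C m-2 yr-1 per g C m-2 d-1 (p = %.3g)\n",
              x$eta[["max"]], x$p_values[["max"]]))
  cat(sprintf("  eta_end:   %8.3f g C m-2 per day of delay (p = %.3g)\n",
              x$eta[["end"]], x$p_values[["end"]]))
  cat(sprintf("  R-squared: %.4f\n", x$r2))
  invisible(x)
}

#' Decompose annual-GPP anomalies into the three indicator components
#'
#' Splits each year's annual-GPP anomaly into the start-, peak- and
#' end-induced components plus the regression residual. The reconstruction
#' `intercept + comp_start + comp_max + comp_end + residual = d_gpp` holds
#' exactly per year.
#'
#' @param fit A `smipp_fit` from [fit_smipp()].
#' @return data.frame `year, comp_start, comp_max, comp_end, residual,
#'   d_gpp`.
#' @export
decompose_anomalies <- function(fit) {
  stopifnot(inherits(fit, "smipp_fit"))
  data.frame(year = fit$anomalies$year,
             comp_start = fit$components[, "start"],
             comp_max = fit$components[, "max"],
             comp_end = fit$components[, "end"],
             residual = fit$anomalies$d_gpp - fit$intercept -
               rowSums(fit$components),
             d_gpp = fit$anomalies$d_gpp)
}
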