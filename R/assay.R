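#' Fit an absorbance standard curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration +
#' intercept` through a serial-dilution series read at 340 nm, used to invert
#' releasate absorbances to honey concentrations.
#'
#' @param concentration Honey concentrations (% v/v); at least 3 distinct
#'   values.
#' @param absorbance Matching absorbance readings.
#' @param wavelength_nm Wavelength annotation; default 340.
#' @return Object of class `"calibration_curve"` with elements `slope`,
#'   `intercept`, `r_squared`, `wavelength_nm`, `n`, and the underlying
#'   `lm` fit.
#' @export
#' @examples
#' cal <- fit_standard_curve(c(0, 1, 2, 4), 0.1 + 2 * c(0, 1, 2, 4))
#' coef(cal)
fit_standard_curve <- function(concentration, absorbance,
                               wavelength_nm = 340) {
  if (length(concentration) != length(absorbance)) {
    stop("concentration and absorbance must have equal length", call. = FALSE)
  }
  ok <- is.finite(concentration) & is.finite(absorbance)
  concentration <- concentration[ok]; absorbance <- absorbance[ok]
  if (length(unique(concentration)) < 3L) {
    stop("a standard curve needs at least 3 distinct concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration,
                   data = data.frame(concentration = concentration,
                                     absorbance = absorbance))
  # r^2 computed directly (summary.lm warns on an exact fit)
  tss <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 wavelength_nm = wavelength_nm,
                 n = length(concentration),
                 fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve (%g nm, n = %d): A = %.6g * conc + %.6g, r^2 = %.5f\n",
    x$wavelength_nm, x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  object$intercept + object$slope * concentration
}

#' Invert a standard curve: absorbance to concentration
#'
#' `(absorbance - intercept) / slope`, clamped below at zero (with a warning)
#' because a negative honey concentration is unphysical.
#'
#' @param curve A [fit_standard_curve()] result (or any list with `slope`
#'   and `intercept`).
#' @param absorbance Numeric vector of absorbances.
#' @return Concentrations (% v/v), non-negative.
#' @export
absorbance_to_concentration <- function(curve, absorbance) {
  if (!is.finite(curve$slope) || curve$slope == 0) {
    stop("standard curve slope is zero; cannot invert", call. = FALSE)
  }
  conc <- (absorbance - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning(sum(conc < 0), " negative inverse prediction(s) clamped to 0",
            call. = FALSE)
    conc <- pmax(conc, 0)
  }
  conc
}

#' Default releasate sampling schedule
#'
#' The 14 timepoints (hours) at which the incubation medium is fully
#' replaced and saved: 15, 30, 45 min, 1, 2, 3, 6, 12 h, then 1, 2, 3, 7,
#' 14 and 21 days.
#'
#' @return Numeric vector of 14 strictly increasing hours.
#' @export
release_schedule_h <- function() {
  c(0.25, 0.5, 0.75, 1, 2, 3, 6, 12, 24, 48, 72, 168, 336, 504)
}

#' Cumulative honey release
#'
#' With full medium replacement at every sampling, the interval
#' concentrations are independent measurements and cumulative release is
#' their running sum per template.
#'
#' @param profile Data frame with columns `template_id`, `timepoint_h` and
#'   `interval_conc_pct` (negative values are clamped to 0 with a warning).
#' @return The data frame ordered by template and time with a
#'   `cumulative_pct` column appended (non-decreasing within template).
#' @export
cumulative_release <- function(profile) {
  need <- c("template_id", "timepoint_h", "interval_conc_pct")
  if (!all(need %in% names(profile))) {
    stop("profile needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  profile <- profile[order(profile$template_id, profile$timepoint_h), ,
                     drop = FALSE]
  for (tid in unique(profile$template_id)) {
    tp <- profile$timepoint_h[profile$template_id == tid]
    if (any(diff(tp) <= 0)) {
      stop("timepoints must be strictly increasing within template '",
           tid, "'", call. = FALSE)
    }
  }
  conc <- profile$interval_conc_pct
  if (any(conc < 0)) {
    warning(sum(conc < 0), " negative interval concentration(s) clamped to 0",
            call. = FALSE)
    conc <- pmax(conc, 0)
    profile$interval_conc_pct <- conc
  }
  profile$cumulative_pct <- stats::ave(conc, profile$template_id,
                                       FUN = cumsum)
  rownames(profile) <- NULL
  profile
}

#' Percent NETosis response from MPO concentrations
#'
#' Each sample's MPO concentration expressed as a percentage of the
#' tissue-culture-plastic 100 nM PMA positive control of the same
#' experiment: `100 * mpo / control`.
#'
#' @param mpo_conc Sample MPO concentrations (assay units).
#' @param positive_control_conc Positive-control MPO concentration(s);
#'   recycled; must be strictly positive.
#' @param experiment Optional label used in the error message when the
#'   control is non-positive.
#' @return Percentages, same length as `mpo_conc`.
#' @export
#' @examples
#' percent_netosis_response(50, 100)  # 50
percent_netosis_response <- function(mpo_conc, positive_control_conc,
                                     experiment = NULL) {
  if (any(!is.finite(positive_control_conc)) ||
      any(positive_control_conc <= 0)) {
    stop("positive control MPO concentration must be > 0",
         if (!is.null(experiment)) paste0(" (experiment ", experiment, ")"),
         call. = FALSE)
  }
  100 * mpo_conc / positive_control_conc
}

#' Normalize an MPO panel to its within-experiment positive controls
#'
#' Applies [percent_netosis_response()] to every heparin-treated sample row
#' of a panel, using the mean heparin-treated MPO of the rows whose
#' `condition` equals `control_condition` within the same `experiment_id`.
#'
#' @param panel Data frame with columns `experiment_id`, `sample_id`,
#'   `condition`, `heparin_flag` (logical), `mpo_conc`.
#' @param control_condition Condition label of the positive control rows;
#'   default `"positive_control"`.
#' @return The heparin-treated rows of `panel` with a `pct_netosis` column.
#' @export
netosis_response_panel <- function(panel,
                                   control_condition = "positive_control") {
  need <- c("experiment_id", "condition", "heparin_flag", "mpo_conc")
  if (!all(need %in% names(panel))) {
    stop("panel needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  hep <- panel[as.logical(panel$heparin_flag), , drop = FALSE]
  out <- NULL
  for (ex in unique(hep$experiment_id)) {
    rows <- hep[hep$experiment_id == ex, , drop = FALSE]
    ctrl <- rows$mpo_conc[rows$condition == control_condition]
    if (length(ctrl) == 0L) {
      stop("experiment '", ex, "' has no '", control_condition,
           "' rows to normalize against", call. = FALSE)
    }
    rows$pct_netosis <- percent_netosis_response(rows$mpo_conc, mean(ctrl),
                                                 experiment = ex)
    out <- rbind(out, rows)
  }
  rownames(out) <- NULL
  out
}

#' Heparin background check
#'
#' Heparin dissociates NET-bound MPO into the supernatant; replicates run
#' without heparin report only free (non-NET-associated) MPO. For each
#' condition present in both arms, the ratio of the mean MPO without heparin
#' to the mean with heparin is computed; a ratio below `cutoff` marks the
#' free-MPO background as negligible, validating MPO as a NETosis readout.
#'
#' @param panel Data frame with columns `condition`, `heparin_flag`
#'   (logical) and `mpo_conc`.
#' @param cutoff Negligibility cutoff on the ratio; default 0.2.
#' @return Data frame with one row per checked condition: `condition`,
#'   `mean_with_heparin`, `mean_without_heparin`, `ratio`, `negligible`.
#' @export
heparin_background_check <- function(panel, cutoff = 0.2) {
  need <- c("condition", "heparin_flag", "mpo_conc")
  if (!all(need %in% names(panel))) {
    stop("panel needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  flag <- as.logical(panel$heparin_flag)
  conds <- unique(panel$condition[!flag])
  conds <- conds[conds %in% panel$condition[flag]]
  if (length(conds) == 0L) {
    stop("no condition present both with and without heparin", call. = FALSE)
  }
  out <- data.frame(condition = conds, mean_with_heparin = NA_real_,
                    mean_without_heparin = NA_real_, ratio = NA_real_,
                    negligible = NA, stringsAsFactors = FALSE)
  for (i in seq_along(conds)) {
    w <- mean(panel$mpo_conc[flag & panel$condition == conds[i]])
    wo <- mean(panel$mpo_conc[!flag & panel$condition == conds[i]])
    out$mean_with_heparin[i] <- w
    out$mean_without_heparin[i] <- wo
    out$ratio[i] <- wo / w
    out$negligible[i] <- (wo / w) < cutoff
  }
  out
}
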