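# Dipole-potential ratiometry: blank-corrected 420/520 excitation ratios,
# the linear calibration psi_d = (R_ex + b)/m, and calibrated shifts
# delta_psi = k * delta_R_ex with quadrature error propagation.

#' Linear calibration of the excitation ratio against dipole potential
#'
#' Parameters of the published linear relationship
#' `psi_d (mV) = (R_ex + b) / m` with `b = 0.3 +/- 0.4` (ratio units) and
#' `m = (4.3 +/- 1.2) x 10^-3` (ratio units per mV).
#'
#' @param intercept_b,intercept_sd Intercept and its uncertainty.
#' @param slope_m_per_mV,slope_sd Slope (> 0) and its uncertainty.
#' @return An object of class `calibration_linear`.
#' @export
calibration_linear <- function(intercept_b = 0.3, intercept_sd = 0.4,
                               slope_m_per_mV = 4.3e-3, slope_sd = 1.2e-3) {
  if (slope_m_per_mV <= 0) stopf("field 'slope_m_per_mV': must be > 0")
  structure(list(intercept_b = intercept_b, intercept_sd = intercept_sd,
                 slope_m_per_mV = slope_m_per_mV, slope_sd = slope_sd),
            class = "calibration_linear")
}

#' Rescaled proportionality constant for dipole-potential changes
#'
#' The constant `k` of `delta_psi (mV) = k * delta_R_ex`, obtained by
#' rescaling the linear calibration against reference dipole-potential
#' measurements.  The default is the published `365 +/- 102` mV per ratio
#' unit.
#'
#' @param k_mV_per_ratio Proportionality constant (> 0).
#' @param k_sd Its uncertainty.
#' @param provenance `"fixed constant"` or `"fitted from anchors"`.
#' @return An object of class `rescaled_slope`.
#' @export
rescaled_slope <- function(k_mV_per_ratio = 365, k_sd = 102,
                           provenance = "fixed constant") {
  if (!is.finite(k_mV_per_ratio) || k_mV_per_ratio <= 0) {
    stopf("field 'k_mV_per_ratio': must be > 0")
  }
  if (!is.na(k_sd) && k_sd < 0) stopf("field 'k_sd': must be >= 0")
  structure(list(k_mV_per_ratio = k_mV_per_ratio, k_sd = k_sd,
                 provenance = provenance),
            class = "rescaled_slope")
}

spectrum_at <- function(sp, nm) {
  approx(sp$wavelength_nm, sp$intensity, xout = nm, rule = 1)$y
}

#' Blank-corrected excitation intensity ratio
#'
#' Computes `R_ex = (I_lab - I_blank)(num_nm) / (I_lab - I_blank)(den_nm)`
#' with intensities read off the spectra by linear interpolation, after
#' interpolating the blank onto the labelled grid.  Warns when the blank
#' peak exceeds 0.7% of the labelled peak (the acquisition protocol bound).
#'
#' @param labelled,blank [spectrum()] objects covering both wavelengths.
#' @param num_nm,den_nm Numerator and denominator wavelengths (defaults 420
#'   and 520 nm).
#' @return The ratio (positive scalar).
#' @export
compute_rex <- function(labelled, blank, num_nm = 420, den_nm = 520) {
  stopifnot(inherits(labelled, "spectrum"), inherits(blank, "spectrum"))
  for (nm in c(num_nm, den_nm)) {
    if (nm < min(labelled$wavelength_nm) || nm > max(labelled$wavelength_nm) ||
        nm < min(blank$wavelength_nm) || nm > max(blank$wavelength_nm)) {
      stopf("range does not cover ratio wavelengths: %.6g nm outside a spectrum grid", nm)
    }
  }
  blank_on_grid <- approx(blank$wavelength_nm, blank$intensity,
                          xout = labelled$wavelength_nm, rule = 1)$y
  corrected <- labelled$intensity - blank_on_grid
  frac <- max(blank_on_grid) / max(labelled$intensity)
  if (frac > 0.007) {
    warnf("blank peak is %.2f%% of the labelled peak (protocol bound 0.7%%)",
          100 * frac)
  }
  num <- approx(labelled$wavelength_nm, corrected, xout = num_nm)$y
  den <- approx(labelled$wavelength_nm, corrected, xout = den_nm)$y
  if (!is.finite(den) || den <= 0) {
    stopf("non-positive reference intensity at %.6g nm after blank correction", den_nm)
  }
  num / den
}

#' Aggregate replicate excitation ratios
#'
#' Mean and sample standard deviation (n - 1 denominator) over independent
#' replicate ratios for one condition.
#'
#' @param values Numeric vector of replicate ratios (positive, finite).
#' @param lipid_system,compound Condition labels.
#' @return An object of class `rex_result` with fields `mean_rex`,
#'   `sd_rex`, `n`, `lipid_system`, `compound`.
#' @export
aggregate_rex <- function(values, lipid_system = NA_character_,
                          compound = NA_character_) {
  values <- as.numeric(values)
  if (!length(values)) stopf("field 'values': empty input")
  if (anyNA(values) || any(!is.finite(values)) || any(values <= 0)) {
    stopf("field 'values': ratios must be finite and positive")
  }
  structure(list(mean_rex = mean(values),
                 sd_rex = if (length(values) > 1L) sd(values) else 0,
                 n = length(values),
                 lipid_system = lipid_system, compound = compound),
            class = "rex_result")
}

#' @export
print.rex_result <- function(x, ...) {
  cat(sprintf("<rex_result> %s/%s: R_ex = %.3f +/- %.3f (n = %d)\n",
              x$lipid_system, x$compound, x$mean_rex, x$sd_rex, x$n))
  invisible(x)
}

#' Absolute dipole potential from an excitation ratio
#'
#' Evaluates the linear calibration `psi_d (mV) = (R_ex + b) / m`.
#'
#' @param rex Excitation ratio.
#' @param cal A [calibration_linear()].
#' @return Dipole potential in mV.
#' @export
psi_from_rex <- function(rex, cal = calibration_linear()) {
  stopifnot(inherits(cal, "calibration_linear"))
  (rex + cal$intercept_b) / cal$slope_m_per_mV
}

#' Fit the proportionality constant from anchor points
#'
#' Ordinary least-squares slope of reference dipole potentials against
#' measured ratios over a set of anchor conditions; with exactly two anchors
#' this is the two-point slope.  The slope uncertainty comes from the
#' regression when three or more anchors are supplied and is `NA` otherwise
#' (callers may substitute the published 102 mV default).
#'
#' @param anchors Data frame (or 2-column matrix) with columns `rex` and
#'   `psi_mV`.
#' @return A [rescaled_slope()] with `provenance = "fitted from anchors"`.
#' @export
rescale_slope <- function(anchors) {
  anchors <- as.data.frame(anchors)
  if (is.null(anchors$rex) || is.null(anchors$psi_mV)) {
    names(anchors)[1:2] <- c("rex", "psi_mV")
  }
  if (nrow(anchors) < 2L) stopf("field 'anchors': need at least 2 anchor points")
  if (length(unique(anchors$rex)) < 2L) {
    stopf("field 'anchors': all rex values identical, slope undefined")
  }
  fit <- stats::lm(psi_mV ~ rex, data = anchors)
  k <- unname(stats::coef(fit)["rex"])
  if (k <= 0) stopf("field 'anchors': fitted slope is not positive")
  k_sd <- if (nrow(anchors) >= 3L) {
    unname(summary(fit)$coefficients["rex", "Std. Error"])
  } else NA_real_
  rescaled_slope(k, k_sd, provenance = "fitted from anchors")
}

#' Calibrated dipole-potential change for one condition
#'
#' `delta_psi = k (R_sample - R_control)`, with uncertainty propagated in
#' independent quadrature over the replicate dispersion of both ratios and
#' the slope uncertainty:
#' `sd = sqrt((k sd_dR)^2 + (k_sd dR)^2)` where
#' `sd_dR = sqrt(sd_sample^2 + sd_control^2)`.
#'
#' @param sample,control [aggregate_rex()] results for the compound and the
#'   matching control of the same lipid system.
#' @param slope A [rescaled_slope()].
#' @return An object of class `dipole_shift` with fields `delta_psi_mV`,
#'   `sd_mV`, `delta_rex`, `sd_delta_rex`, `lipid_system`, `compound`.
#' @export
delta_psi <- function(sample, control, slope = rescaled_slope()) {
  stopifnot(inherits(sample, "rex_result"), inherits(control, "rex_result"),
            inherits(slope, "rescaled_slope"))
  if (!is.na(sample$lipid_system) && !is.na(control$lipid_system) &&
      sample$lipid_system != control$lipid_system) {
    stopf("mismatched lipid systems: sample '%s' vs control '%s'",
          sample$lipid_system, control$lipid_system)
  }
  if (!is.na(control$compound) && control$compound != "CONTROL") {
    stopf("field 'control': compound must be CONTROL, got '%s'", control$compound)
  }
  k <- slope$k_mV_per_ratio
  k_sd <- if (is.na(slope$k_sd)) 0 else slope$k_sd
  d_rex <- sample$mean_rex - control$mean_rex
  sd_d_rex <- sqrt(sample$sd_rex^2 + control$sd_rex^2)
  structure(list(delta_psi_mV = k * d_rex,
                 sd_mV = sqrt((k * sd_d_rex)^2 + (k_sd * d_rex)^2),
                 delta_rex = d_rex, sd_delta_rex = sd_d_rex,
                 lipid_system = sample$lipid_system,
                 compound = sample$compound),
            class = "dipole_shift")
}

#' @export
print.dipole_shift <- function(x, ...) {
  cat(sprintf("<dipole_shift> %s/%s: delta_psi = %.0f +/- %.0f mV (delta R_ex = %.4f)\n",
              x$lipid_system, x$compound, x$delta_psi_mV, x$sd_mV, x$delta_rex))
  invisible(x)
}

#' Condition table of dipole-potential changes
#'
#' Builds the compound x lipid-system table of calibrated dipole shifts from
#' condition-level ratio results.  Requires one `CONTROL` entry per lipid
#' system.
#'
#' @param rex_results Data frame with columns `lipid_system`, `compound`,
#'   `mean_rex`, `sd_rex`, `n` (one row per condition), as returned by
#'   [analyze_study()].
#' @param slope A [rescaled_slope()].
#' @param wide If `TRUE`, return the report layout: one row per compound,
#'   one `"value +/- sd"` column per lipid system, rounded to integer mV.
#' @return A data frame; long format has columns `lipid_system`,
#'   `compound`, `delta_rex`, `sd_delta_rex`, `delta_psi_mV`, `sd_mV`, `n`.
#' @export
dipole_table <- function(rex_results, slope = rescaled_slope(), wide = FALSE) {
  df <- as.data.frame(rex_results)
  need <- c("lipid_system", "compound", "mean_rex", "sd_rex", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("field 'rex_results': missing column '%s'", miss[1])
  out <- list()
  for (ls in unique(df$lipid_system)) {
    sub <- df[df$lipid_system == ls, , drop = FALSE]
    ctrl_row <- sub[sub$compound == "CONTROL", , drop = FALSE]
    if (nrow(ctrl_row) != 1L) {
      stopf("missing control for lipid system '%s'", ls)
    }
    ctrl <- aggregate_rex_from_row(ctrl_row)
    for (i in which(sub$compound != "CONTROL")) {
      smp <- aggregate_rex_from_row(sub[i, , drop = FALSE])
      sh <- delta_psi(smp, ctrl, slope)
      out[[length(out) + 1L]] <- data.frame(
        lipid_system = ls, compound = sub$compound[i],
        delta_rex = sh$delta_rex, sd_delta_rex = sh$sd_delta_rex,
        delta_psi_mV = sh$delta_psi_mV, sd_mV = sh$sd_mV,
        n = sub$n[i], stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, out)
  long <- long[order(match(long$lipid_system, lipid_systems()),
                     match(long$compound, compounds())), , drop = FALSE]
  rownames(long) <- NULL
  if (!wide) return(long)
  comps <- unique(long$compound)
  systems <- unique(long$lipid_system)
  wide_df <- data.frame(compound = comps, stringsAsFactors = FALSE)
  for (ls in systems) {
    sub <- long[long$lipid_system == ls, , drop = FALSE]
    wide_df[[ls]] <- sprintf("%.0f ± %.0f",
                             round(sub$delta_psi_mV[match(comps, sub$compound)]),
                             round(sub$sd_mV[match(comps, sub$compound)]))
  }
  wide_df
}

aggregate_rex_from_row <- function(row) {
  structure(list(mean_rex = row$mean_rex, sd_rex = row$sd_rex, n = row$n,
                 lipid_system = row$lipid_system, compound = row$compound),
            class = "rex_result")
}
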