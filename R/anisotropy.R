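# Steady-state fluorescence anisotropy with G-factor correction:
# <r> = (I_VV - G I_VH) / (I_VV + 2 G I_VH),  G = I_HV / I_HH.

#' Instrumental G factor
#'
#' Correction factor for the polarization-dependent detector sensitivity,
#' obtained as the ratio of the horizontally excited intensity components
#' `I_HV / I_HH`.
#'
#' @param I_HV,I_HH Intensities (same units); `I_HH` must be > 0.
#' @return The G factor (vectorized).
#' @export
g_factor <- function(I_HV, I_HH) {
  if (any(!is.finite(I_HH)) || any(I_HH <= 0)) {
    stopf("field 'I_HH': must be > 0 to form the G factor")
  }
  I_HV / I_HH
}

#' Steady-state anisotropy
#'
#' Evaluates `<r> = (I_VV - G I_VH) / (I_VV + 2 G I_VH)` on blank-corrected
#' intensities.
#'
#' @param I_VV,I_VH Blank-corrected intensity components.
#' @param G Instrumental correction factor (> 0).
#' @return The anisotropy (vectorized); lies in (-0.5, 1] for positive
#'   intensities.
#' @export
steady_state_anisotropy <- function(I_VV, I_VH, G) {
  if (any(!is.finite(G)) || any(G <= 0)) stopf("field 'G': must be > 0")
  den <- I_VV + 2 * G * I_VH
  if (any(den == 0)) stopf("zero denominator in the anisotropy formula")
  (I_VV - G * I_VH) / den
}

#' Per-sample anisotropy from a polarized reading set
#'
#' Applies the full measurement protocol to one sample: per-repeat blank
#' subtraction (when a blank set is supplied), a per-repeat G factor from
#' that repeat's HV/HH pair, the anisotropy formula per repeat, and the mean
#' over repeats as the sample-level value.  Repeats in which any corrected
#' intensity is non-positive are excluded with a warning rather than clipped
#' (clipping would bias the anisotropy upward).
#'
#' @param set A [polarized_set()] of the labelled sample.
#' @param blank Optional matching [polarized_set()] of the blank (same
#'   number of repeats).
#' @return An object of class `anisotropy_sample` with fields `mean_r`
#'   (sample-level anisotropy), `sd_r` (SD over repeats), `G_mean`,
#'   `n_repeats_used`, `r_repeats`, `meta`.
#' @export
aggregate_anisotropy <- function(set, blank = NULL) {
  stopifnot(inherits(set, "polarized_set"))
  comp <- c("I_VV", "I_VH", "I_HV", "I_HH")
  m <- sapply(comp, function(nm) set[[nm]])
  m <- matrix(m, ncol = 4, dimnames = list(NULL, comp))
  if (!is.null(blank)) {
    stopifnot(inherits(blank, "polarized_set"))
    if (blank$n_repeats != set$n_repeats) {
      stopf("field 'blank': has %d repeats, labelled set has %d",
            blank$n_repeats, set$n_repeats)
    }
    b <- matrix(sapply(comp, function(nm) blank[[nm]]), ncol = 4)
    m <- m - b
  }
  ok <- rowSums(m <= 0) == 0L
  if (!all(ok)) {
    warnf("sample '%s': excluding %d repeat(s) with non-positive corrected intensities",
          set$meta$sample_id, sum(!ok))
  }
  if (!any(ok)) {
    stopf("sample '%s': all repeats excluded after blank correction",
          set$meta$sample_id)
  }
  m <- m[ok, , drop = FALSE]
  G <- g_factor(m[, "I_HV"], m[, "I_HH"])
  r <- steady_state_anisotropy(m[, "I_VV"], m[, "I_VH"], G)
  structure(list(mean_r = mean(r),
                 sd_r = if (length(r) > 1L) sd(r) else 0,
                 G_mean = mean(G),
                 n_repeats_used = length(r),
                 r_repeats = r,
                 meta = set$meta),
            class = "anisotropy_sample")
}

#' @export
print.anisotropy_sample <- function(x, ...) {
  cat(sprintf("<anisotropy_sample> %s: r = %.4f (SD over %d repeats %.4f, G = %.3f)\n",
              x$meta$sample_id, x$mean_r, x$n_repeats_used, x$sd_r, x$G_mean))
  invisible(x)
}

#' Condition-level anisotropy over independent samples
#'
#' Mean and sample SD of per-sample anisotropies over the independent
#' replicates of one condition (the study reports mean +/- SD over
#' triplicates).
#'
#' @param samples List of [aggregate_anisotropy()] results, or a numeric
#'   vector of per-sample anisotropies.
#' @param lipid_system,compound Condition labels.
#' @return An object of class `anisotropy_result` with fields `mean_r`,
#'   `sd_r`, `G_mean`, `n_samples`, `lipid_system`, `compound`.
#' @export
condition_anisotropy <- function(samples, lipid_system = NA_character_,
                                 compound = NA_character_) {
  if (is.numeric(samples)) {
    r <- samples
    G <- NA_real_
  } else {
    r <- vapply(samples, function(s) s$mean_r, 0)
    G <- mean(vapply(samples, function(s) s$G_mean, 0))
  }
  if (!length(r)) stopf("field 'samples': empty input")
  mean_r <- mean(r)
  if (mean_r < -0.5 || mean_r > 1) {
    stopf("field 'mean_r': %.4g outside the anisotropy range [-0.5, 1]", mean_r)
  }
  structure(list(mean_r = mean_r,
                 sd_r = if (length(r) > 1L) sd(r) else 0,
                 G_mean = G, n_samples = length(r),
                 lipid_system = lipid_system, compound = compound),
            class = "anisotropy_result")
}

#' @export
print.anisotropy_result <- function(x, ...) {
  cat(sprintf("<anisotropy_result> %s/%s: <r> = %.4f +/- %.4f (n = %d)\n",
              x$lipid_system, x$compound, x$mean_r, x$sd_r, x$n_samples))
  invisible(x)
}
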