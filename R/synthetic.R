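# Forward simulation of the three measurement arms with known ground truth.
# All randomness flows through with_seed(); the same (arguments, seed) pair
# always reproduces the same dataset.

#' Spectral shape configuration for synthetic excitation spectra
#'
#' The simulated di-8-ANEPPS excitation spectrum is modelled as two Gaussian
#' bands (one under each ratio wavelength) on a flat baseline.  The band
#' shape is a nuisance: amplitudes are solved so that the blank-subtracted
#' 420/520 intensity ratio equals the requested ground truth exactly before
#' noise.
#'
#' @param band_centers_nm Two band centers (default 420 and 520 nm, the
#'   ratio wavelengths).
#' @param band_widths_nm Two Gaussian standard deviations (> 0, nm).
#' @param baseline_frac Flat baseline as a fraction of the 520-band
#'   amplitude.
#' @param noise_cv Pointwise multiplicative noise coefficient of variation
#'   (log-normal, mean 1).  The default 0.007 reproduces replicate R_ex
#'   standard deviations of about 0.02-0.03 ratio units at control ratios.
#' @param blank_frac Blank peak intensity as a fraction of the labelled
#'   peak; must not exceed 0.007 (the blank signal stayed below 0.7% of the
#'   labelled sample in the acquisition protocol).
#' @param grid_nm Wavelength grid (default 400-625 nm in 1-nm steps, the
#'   acquisition range).
#' @return An object of class `spectrum_shape_config`.
#' @export
spectrum_shape_config <- function(band_centers_nm = c(420, 520),
                                  band_widths_nm = c(30, 40),
                                  baseline_frac = 0.02,
                                  noise_cv = 0.007,
                                  blank_frac = 0.005,
                                  grid_nm = seq(400, 625, by = 1)) {
  if (length(band_centers_nm) != 2L || length(band_widths_nm) != 2L) {
    stopf("field 'band_centers_nm'/'band_widths_nm': need exactly two bands")
  }
  if (any(band_widths_nm <= 0)) stopf("field 'band_widths_nm': widths must be > 0")
  if (baseline_frac < 0) stopf("field 'baseline_frac': must be >= 0")
  if (noise_cv < 0) stopf("field 'noise_cv': must be >= 0")
  if (blank_frac < 0 || blank_frac > 0.007) {
    stopf("field 'blank_frac': %.4g outside [0, 0.007] (blank must stay below 0.7%% of the labelled signal)",
          blank_frac)
  }
  structure(list(band_centers_nm = as.numeric(band_centers_nm),
                 band_widths_nm = as.numeric(band_widths_nm),
                 baseline_frac = baseline_frac, noise_cv = noise_cv,
                 blank_frac = blank_frac, grid_nm = as.numeric(grid_nm)),
            class = "spectrum_shape_config")
}

# log-normal multiplicative noise factors with mean exactly 1
lnorm_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

synth_truth <- function(seed, noise_model, ...) {
  structure(c(list(seed = seed, noise_model = noise_model), list(...)),
            class = "synth_truth")
}

#' Simulate a labelled/blank excitation spectrum pair
#'
#' Builds a smooth two-band spectrum whose blank-subtracted 420/520 nm
#' intensity ratio equals `truth_rex` exactly before noise, plus a blank
#' spectrum scaled to `blank_frac` of the labelled peak.  Pointwise
#' multiplicative log-normal noise with coefficient of variation
#' `shape$noise_cv` is then applied to both spectra.
#'
#' @param truth_rex Ground-truth excitation ratio (> 0).
#' @param shape A [spectrum_shape_config()].
#' @param meta A [sample_meta()] record for the labelled sample; the blank
#'   reuses it with `is_blank = TRUE` and id `<sample_id>_BLK`.
#' @param seed Integer seed.
#' @return A list with elements `labelled` and `blank` ([spectrum()]
#'   objects) and `truth` (a `synth_truth` record).
#' @export
generate_excitation_pair <- function(truth_rex,
                                     shape = spectrum_shape_config(),
                                     meta = sample_meta("synthetic", "POPC"),
                                     seed = 1L) {
  if (!is.finite(truth_rex) || truth_rex <= 0) {
    stopf("field 'truth_rex': must be a positive number")
  }
  grid <- shape$grid_nm
  c1 <- shape$band_centers_nm[1]; c2 <- shape$band_centers_nm[2]
  w1 <- shape$band_widths_nm[1]; w2 <- shape$band_widths_nm[2]
  g <- function(l, c, w) exp(-(l - c)^2 / (2 * w^2))
  # amplitudes (A2 = 1) solving I(420)/I(520) = truth_rex before noise
  e1at2 <- g(520, c1, w1)
  e2at1 <- g(420, c2, w2)
  b <- shape$baseline_frac
  den <- 1 - truth_rex * e1at2
  A1 <- (truth_rex * (1 + b) - e2at1 - b) / den
  if (!is.finite(A1) || A1 <= 0 || den <= 0) {
    stopf("field 'truth_rex': %.4g is outside the range representable by this band shape",
          truth_rex)
  }
  signal <- A1 * g(grid, c1, w1) + g(grid, c2, w2) + b
  blank0 <- shape$blank_frac * max(signal) * g(grid, 470, 80)
  labelled0 <- signal + blank0

  with_seed(seed, {
    lab <- labelled0 * lnorm_factors(length(grid), shape$noise_cv)
    blk <- blank0 * lnorm_factors(length(grid), shape$noise_cv)
    bmeta <- meta
    bmeta$sample_id <- paste0(meta$sample_id, "_BLK")
    bmeta$is_blank <- TRUE
    bmeta$blank_id <- NA_character_
    lmeta <- meta
    lmeta$blank_id <- bmeta$sample_id
    list(labelled = spectrum(grid, lab, lmeta),
         blank = spectrum(grid, blk, bmeta),
         truth = synth_truth(seed, "multiplicative log-normal",
                             truth_rex = truth_rex, shape = shape))
  })
}

#' Simulate a polarized intensity reading set
#'
#' Noiseless components satisfy `I_VV = scale (1 + 2 r)`,
#' `I_VH = scale (1 - r) / G`, `I_HV = G scale`, `I_HH = scale`, so that the
#' G-factor estimated from the HV/HH pair equals `truth_G` and the
#' G-corrected anisotropy equals `truth_r` exactly.  Each repeat draws
#' independent multiplicative log-normal noise on all four components.
#'
#' @param truth_r Ground-truth anisotropy, in (-0.5, 1).
#' @param truth_G Ground-truth G factor (> 0).
#' @param scale Overall intensity scale (arbitrary units).
#' @param n_repeats Readings per sample (study protocol: 7).
#' @param noise_cv Per-component multiplicative noise CV.
#' @param meta A [sample_meta()] record.
#' @param seed Integer seed.
#' @return A list with elements `set` (a [polarized_set()]) and `truth`.
#' @export
generate_polarized_set <- function(truth_r, truth_G = 1.2, scale = 1e5,
                                   n_repeats = 7L, noise_cv = 0,
                                   meta = sample_meta("synthetic", "POPC",
                                                      probe = "DPHPC"),
                                   seed = 1L) {
  if (!is.finite(truth_r) || truth_r <= -0.5 || truth_r >= 1) {
    stopf("field 'truth_r': must lie strictly inside (-0.5, 1)")
  }
  if (!is.finite(truth_G) || truth_G <= 0) stopf("field 'truth_G': must be > 0")
  if (scale <= 0) stopf("field 'scale': must be > 0")
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stopf("field 'n_repeats': must be >= 1")
  base <- c(I_VV = scale * (1 + 2 * truth_r),
            I_VH = scale * (1 - truth_r) / truth_G,
            I_HV = truth_G * scale,
            I_HH = scale)
  with_seed(seed, {
    comp <- lapply(base, function(v) v * lnorm_factors(n_repeats, noise_cv))
    list(set = polarized_set(comp$I_VV, comp$I_VH, comp$I_HV, comp$I_HH, meta),
         truth = synth_truth(seed, "multiplicative log-normal",
                             truth_r = truth_r, truth_G = truth_G,
                             scale = scale, noise_cv = noise_cv,
                             n_repeats = n_repeats))
  })
}

#' Noise level reproducing a target anisotropy standard deviation
#'
#' Delta-method inversion of the repeat-level anisotropy noise: with
#' independent multiplicative noise of coefficient of variation `cv` on all
#' four polarized components, one repeat's anisotropy has standard deviation
#' `2 cv (1 - r)(1 + 2 r) / 3`, and a sample mean over `n_repeats` readings
#' shrinks it by `sqrt(n_repeats)`.  Returns the `cv` for which the
#' across-sample SD equals `target_sd`.
#'
#' @param truth_r Ground-truth anisotropy.
#' @param target_sd Desired standard deviation of the per-sample anisotropy.
#' @param n_repeats Readings averaged per sample.
#' @return The per-component noise CV.
#' @export
anisotropy_noise_cv <- function(truth_r, target_sd, n_repeats = 7L) {
  if (target_sd < 0) stopf("field 'target_sd': must be >= 0")
  3 * target_sd * sqrt(n_repeats) / (2 * (1 - truth_r) * (1 + 2 * truth_r))
}

# Analytic convolution of a causal exponential decay exp(-(t-t0)/tau) with a
# unit-area Gaussian of width sigma centred at t0 (the exponentially
# modified Gaussian), computed in log space to stay finite on the rising
# edge.
exgauss_decay <- function(t, tau, t0, sigma) {
  if (sigma <= 0) return(ifelse(t >= t0, exp(-(t - t0) / tau), 0))
  a <- sigma^2 / (2 * tau^2) - (t - t0) / tau
  exp(a + pnorm((t - t0) / sigma - sigma / tau, log.p = TRUE))
}

#' Simulate a TCSPC decay histogram with its IRF
#'
#' The expected curve is the multi-exponential decay law convolved with a
#' Gaussian instrument response of the stated FWHM (computed analytically as
#' a sum of exponentially modified Gaussians), discretized on channel
#' centers and scaled so the expected peak equals `target_peak_counts`.
#' Observed counts are drawn channel-wise from a Poisson law; the IRF
#' histogram is emitted the same way from bin-integrated Gaussian
#' probabilities.
#'
#' @param truth_alphas Normalized pre-exponential amplitudes (simplex).
#' @param truth_taus_ns Component lifetimes in ns (> 0).
#' @param irf_fwhm_ns Gaussian IRF full width at half maximum (default
#'   0.05 ns, the detection resolution of the instrument).
#' @param n_channels Number of channels (default 1024).
#' @param channel_width_ns Channel width (default 0.055517 ns, the analysis
#'   time scale).
#' @param target_peak_counts Expected counts in the peak channel (the
#'   acquisition stopped at 10,000-20,000; default 15,000).
#' @param irf_center_ns Position of the IRF center on the time axis.
#' @param poisson If `FALSE`, skip the Poisson draw and round the expected
#'   curve (for deterministic fixtures).
#' @param meta A [sample_meta()] record.
#' @param seed Integer seed.
#' @return A list with `histogram` (a [decay_histogram()]) and `truth`
#'   (includes the noiseless expected curve in `expected_counts`).
#' @export
generate_decay <- function(truth_alphas = c(0.5, 0.5),
                           truth_taus_ns = c(3, 7),
                           irf_fwhm_ns = 0.05,
                           n_channels = 1024L,
                           channel_width_ns = 0.055517,
                           target_peak_counts = 15000L,
                           irf_center_ns = 1.5,
                           poisson = TRUE,
                           meta = sample_meta("synthetic", "POPC",
                                              probe = "DPHPC"),
                           seed = 1L) {
  truth_alphas <- as.numeric(truth_alphas)
  truth_taus_ns <- as.numeric(truth_taus_ns)
  if (length(truth_alphas) != length(truth_taus_ns)) {
    stopf("field 'truth_alphas': length must match 'truth_taus_ns'")
  }
  if (any(truth_alphas < 0) || abs(sum(truth_alphas) - 1) > 1e-8) {
    stopf("field 'truth_alphas': must be non-negative and sum to 1")
  }
  if (any(truth_taus_ns <= 0)) stopf("field 'truth_taus_ns': lifetimes must be > 0")
  o <- order(truth_taus_ns)
  truth_taus_ns <- truth_taus_ns[o]
  truth_alphas <- truth_alphas[o]
  if (any(diff(truth_taus_ns) == 0)) stopf("field 'truth_taus_ns': lifetimes must be distinct")
  if (irf_fwhm_ns < 0) stopf("field 'irf_fwhm_ns': must be >= 0")
  record_ns <- n_channels * channel_width_ns
  if (record_ns - irf_center_ns < 5 * max(truth_taus_ns)) {
    stopf("field 'n_channels': record length %.3g ns after the IRF is shorter than 5 x max lifetime (%.3g ns)",
          record_ns - irf_center_ns, 5 * max(truth_taus_ns))
  }
  sigma <- irf_fwhm_ns / (2 * sqrt(2 * log(2)))
  # bin-average the analytic curve (16-point midpoint rule per channel): the
  # rising edge varies strongly within one channel, so point samples at the
  # channel centers would misstate the expected counts there
  nsub <- 16L
  sub <- rep((seq_len(n_channels) - 1) * channel_width_ns, each = nsub) +
    (rep(seq_len(nsub), n_channels) - 0.5) * channel_width_ns / nsub
  fine <- rowSums(vapply(seq_along(truth_alphas), function(i) {
    truth_alphas[i] * exgauss_decay(sub, truth_taus_ns[i], irf_center_ns, sigma)
  }, numeric(length(sub))))
  shape <- colMeans(matrix(fine, nrow = nsub))
  amp <- target_peak_counts / max(shape)
  expected <- amp * shape
  # IRF: Gaussian mass per channel bin, peak scaled like the decay
  edges <- c(0, seq_len(n_channels)) * channel_width_ns
  p <- if (sigma > 0) diff(pnorm(edges, mean = irf_center_ns, sd = sigma))
       else as.numeric(findInterval(irf_center_ns, edges) == seq_len(n_channels))
  irf_expected <- p / max(p) * target_peak_counts
  with_seed(seed, {
    counts <- if (poisson) rpois(n_channels, expected) else round(expected)
    irf_counts <- if (poisson) rpois(n_channels, irf_expected) else round(irf_expected)
    list(histogram = decay_histogram(counts, channel_width_ns, irf_counts, meta),
         truth = synth_truth(seed, if (poisson) "poisson" else "none",
                             truth_alphas = truth_alphas,
                             truth_taus_ns = truth_taus_ns,
                             irf_fwhm_ns = irf_fwhm_ns,
                             irf_center_ns = irf_center_ns,
                             channel_width_ns = channel_width_ns,
                             expected_counts = expected,
                             expected_irf = irf_expected,
                             amplitude = amp))
  })
}
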