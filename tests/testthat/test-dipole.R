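test_that("compute_rex handles flat spectra, interpolation and blank warnings", {
  lab <- const_spectrum(5)
  blank <- const_spectrum(0, is_blank = TRUE)
  expect_equal(compute_rex(lab, blank), 1.0)

  # closed-form two-Gaussian oracle evaluated directly at the ratio wavelengths
  grid <- seq(400, 625, by = 0.5)
  f <- function(l) 2.4 * exp(-(l - 420)^2 / (2 * 25^2)) +
    1.1 * exp(-(l - 520)^2 / (2 * 38^2)) + 0.05
  sp <- spectrum(grid, f(grid), meta_popc())
  expect_equal(compute_rex(sp, const_spectrum(0)), f(420) / f(520),
               tolerance = 1e-9)

  # denominator driven non-positive by the blank
  big_blank <- const_spectrum(6, is_blank = TRUE)
  suppressWarnings(
    expect_error(compute_rex(lab, big_blank), "non-positive reference intensity"))

  # blank above the 0.7% protocol bound triggers a warning
  loud_blank <- const_spectrum(0.1, is_blank = TRUE)
  expect_warning(compute_rex(lab, loud_blank), "0.7")
})

test_that("replicate ratios aggregate to mean and sample SD", {
  r <- aggregate_rex(c(2.0, 2.0, 2.0), "POPC", "CONTROL")
  expect_equal(r$mean_rex, 2.0)
  expect_equal(r$sd_rex, 0)

  r <- aggregate_rex(c(2.01, 2.03, 2.05))
  expect_equal(r$mean_rex, 2.03)
  expect_equal(r$sd_rex, 0.02)

  r <- aggregate_rex(2.2)
  expect_equal(r$n, 1L)
  expect_equal(r$sd_rex, 0)

  expect_error(aggregate_rex(numeric()), "empty")
  expect_error(aggregate_rex(c(2, -1)), "positive")
})

test_that("the linear calibration maps ratios to dipole potentials", {
  expect_equal(psi_from_rex(-0.3), 0)
  expect_equal(psi_from_rex(2.03), 541.8605, tolerance = 1e-6)
  # doubling the slope halves the potential
  cal2 <- calibration_linear(slope_m_per_mV = 2 * 4.3e-3)
  for (rex in c(1, 2.03, 3)) {
    expect_equal(psi_from_rex(rex, cal2), psi_from_rex(rex) / 2)
  }
  # calibration consistency: potential differences are delta_R / slope
  for (pair in list(c(2, 2.5), c(1.8, 3.1))) {
    expect_equal(psi_from_rex(pair[2]) - psi_from_rex(pair[1]),
                 (pair[2] - pair[1]) / 4.3e-3, tolerance = 1e-9)
  }
})

test_that("slope rescaling recovers anchor slopes and regression uncertainty", {
  k <- rescale_slope(data.frame(rex = c(2, 3), psi_mV = c(300, 665)))
  expect_equal(k$k_mV_per_ratio, 365)
  expect_true(is.na(k$k_sd))
  expect_equal(k$provenance, "fitted from anchors")

  # default constant path
  k0 <- rescaled_slope()
  expect_equal(k0$k_mV_per_ratio, 365)
  expect_equal(k0$k_sd, 102)

  # collinear anchors recover the generating slope exactly
  rex <- c(1.5, 2, 2.5, 3, 3.5)
  k <- suppressWarnings(  # lm flags the exact fit
    rescale_slope(data.frame(rex = rex, psi_mV = 100 + 412.7 * rex)))
  expect_equal(k$k_mV_per_ratio, 412.7, tolerance = 1e-9)
  expect_equal(k$k_sd, 0, tolerance = 1e-6)

  expect_error(rescale_slope(data.frame(rex = 2, psi_mV = 300)), "at least 2")
  expect_error(rescale_slope(data.frame(rex = c(2, 2), psi_mV = c(1, 2))),
               "identical")
})

test_that("dipole shifts are linear with quadrature-propagated uncertainty", {
  mk <- function(mean, sd, comp = "PHLORETIN") {
    aggregate_rex_stub(mean, sd, "POPC", comp)
  }
  aggregate_rex_stub <- function(mean, sd, ls, comp) {
    structure(list(mean_rex = mean, sd_rex = sd, n = 3L,
                   lipid_system = ls, compound = comp), class = "rex_result")
  }
  ctrl <- aggregate_rex_stub(2.03, 0.02, "POPC", "CONTROL")

  # null shift: 0 mV +/- k * sd_dR
  sh <- delta_psi(mk(2.03, 0.02), ctrl)
  expect_equal(sh$delta_psi_mV, 0)
  expect_equal(sh$sd_mV, 365 * sqrt(2) * 0.02, tolerance = 1e-9)

  # pure-slope uncertainty case
  sh <- delta_psi(mk(1.83, 0), aggregate_rex_stub(2.03, 0, "POPC", "CONTROL"))
  expect_equal(sh$delta_psi_mV, -73, tolerance = 1e-9)
  expect_equal(sh$sd_mV, 20.4, tolerance = 1e-9)

  # exact linearity in delta_rex, zero at zero
  d <- vapply(c(-0.2, -0.1, 0, 0.1), function(dr) {
    delta_psi(mk(2.03 + dr, 0), aggregate_rex_stub(2.03, 0, "POPC", "CONTROL"))$delta_psi_mV
  }, 0)
  expect_equal(d, 365 * c(-0.2, -0.1, 0, 0.1), tolerance = 1e-9)

  # uncertainty floor and monotonicity
  sds <- vapply(c(0, 0.05, 0.1, 0.3), function(dr) {
    s <- delta_psi(mk(2.03 - dr, 0.01), ctrl)
    expect_gte(s$sd_mV, 102 * dr - 1e-12)
    s$sd_mV
  }, 0)
  expect_true(all(diff(sds) > 0))
  sds <- vapply(c(0, 0.01, 0.03), function(sd) delta_psi(mk(1.9, sd), ctrl)$sd_mV, 0)
  expect_true(all(diff(sds) > 0))

  ctrl_chol <- aggregate_rex_stub(3.05, 0.03, "POPC_CHOL", "CONTROL")
  expect_error(delta_psi(mk(2, 0.01), ctrl_chol), "mismatched lipid systems")
  expect_error(delta_psi(mk(2, 0.01), mk(2.03, 0.02, "PHLORETIN")), "CONTROL")
})

test_that("the condition table has the report shape and survives a round trip", {
  dir <- withr::local_tempdir()
  st <- generate_study(study_design(arms = "dipole"), dir = dir, seed = 21)
  res <- analyze_study(st$manifest)
  wide <- dipole_table(res$rex, wide = TRUE)
  expect_equal(dim(wide), c(7L, 4L))  # 7 compounds x (compound + 3 lipid systems)
  expect_equal(names(wide)[-1], lipid_systems())

  long <- res$dipole
  expect_equal(nrow(long), 21L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(long, path)
  back <- read_results_table(path)
  expect_equal(back$delta_psi_mV, long$delta_psi_mV, tolerance = 1e-12)

  # conditions generated identical to control stay at zero within noise
  null_design <- study_design(
    lipid_systems = "POPC", compounds = c("CONTROL", "GENISTEIN"),
    delta_psi_mV = within(default_delta_psi_table(), POPC <- 0))
  stn <- generate_study(null_design, dir = file.path(dir, "null"), seed = 5)
  resn <- analyze_study(stn$manifest)
  expect_lt(abs(resn$dipole$delta_psi_mV), 3 * resn$dipole$sd_mV)

  # a missing control is refused
  no_ctrl <- res$rex[res$rex$compound != "CONTROL", ]
  expect_error(dipole_table(no_ctrl), "missing control")
})

test_that("simulated triplicate studies recover shifts without bias and with calibrated errors", {
  # 200 simulated triplicate studies of one condition; slope error excluded
  # from the Monte-Carlo (it is systematic, not sampled)
  sh <- spectrum_shape_config()
  kfix <- rescaled_slope(365, 0)
  truth_d <- -103 / 365
  sims <- vapply(1:200, function(i) {
    ctrl <- vapply(1:3, function(j) {
      p <- generate_excitation_pair(2.03, sh, seed = 20000 + 10 * i + j)
      compute_rex(p$labelled, p$blank)
    }, 0)
    smp <- vapply(1:3, function(j) {
      p <- generate_excitation_pair(2.03 + truth_d, sh, seed = 50000 + 10 * i + j)
      compute_rex(p$labelled, p$blank)
    }, 0)
    s <- delta_psi(aggregate_rex(smp, "POPC", "PHLORETIN"),
                   aggregate_rex(ctrl, "POPC", "CONTROL"), kfix)
    c(s$delta_psi_mV, s$sd_mV)
  }, numeric(2))
  est <- sims[1, ]
  expect_lt(abs(mean(est) - (-103)), 3 * sd(est) / sqrt(length(est)))
  # empirical spread compatible with the propagated uncertainty (chi-square,
  # two-sided at 1%).  The propagated sd carries the replicate-scale SD (the
  # report convention); the triplicate-mean difference it describes therefore
  # has sampling variance sd^2 / 3.
  x <- sum((est - mean(est))^2) / (mean(sims[2, ]^2) / 3)
  expect_gt(x, qchisq(0.005, length(est) - 1))
  expect_lt(x, qchisq(0.995, length(est) - 1))
})
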