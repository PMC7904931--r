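test_that("zero-noise spectrum pairs reproduce the ground-truth ratio exactly", {
  sh <- spectrum_shape_config(noise_cv = 0)
  for (truth in c(0.8, 1, 2.03, 2.20, 3.05)) {
    pair <- generate_excitation_pair(truth, sh, seed = 1)
    expect_equal(compute_rex(pair$labelled, pair$blank), truth,
                 tolerance = 1e-12)
  }
  expect_error(generate_excitation_pair(-1, sh), "positive")
  expect_error(spectrum_shape_config(blank_frac = 0.02), "0.007")
})

test_that("blank spectra stay below 0.7% of the labelled peak", {
  sh <- spectrum_shape_config(noise_cv = 0.02, blank_frac = 0.007)
  for (s in 1:25) {
    pair <- generate_excitation_pair(2.5, sh, seed = s)
    # allow the multiplicative noise envelope on the bound itself
    expect_lt(max(pair$blank$intensity) / max(pair$labelled$intensity),
              0.007 * 1.15)
  }
})

test_that("noisy ratio generation is unbiased over many seeds", {
  sh <- spectrum_shape_config(noise_cv = 0.01)
  r <- vapply(1:1000, function(s) {
    pair <- generate_excitation_pair(2.5, sh, seed = s)
    compute_rex(pair$labelled, pair$blank)
  }, 0)
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 2.5), 3 * se)
})

test_that("polarized sets encode the anisotropy and G factor by construction", {
  g <- generate_polarized_set(0, truth_G = 1, scale = 500, noise_cv = 0, seed = 1)
  expect_equal(g$set$I_VV, rep(500, 7))
  expect_equal(g$set$I_VH, rep(500, 7))

  g <- generate_polarized_set(0.165, truth_G = 1.2, noise_cv = 0, seed = 1)
  expect_equal(aggregate_anisotropy(g$set)$mean_r, 0.165, tolerance = 1e-12)
  expect_equal(unique(round(g$set$I_HV / g$set$I_HH, 12)), 1.2)

  expect_error(generate_polarized_set(1.2, 1), "inside")
  expect_error(generate_polarized_set(-0.6, 1), "inside")
  expect_error(generate_polarized_set(0.2, -1), "> 0")
})

test_that("noisy anisotropy generation is unbiased and matches the tuned SD", {
  truth <- 0.3
  cv <- 0.005
  r <- vapply(1:500, function(s) {
    g <- generate_polarized_set(truth, 1.2, noise_cv = cv, seed = s)
    aggregate_anisotropy(g$set)$mean_r
  }, 0)
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - truth), 3 * se)
  # delta-method prediction for the SD of a 7-repeat sample mean
  pred <- 2 * cv * (1 - truth) * (1 + 2 * truth) / 3 / sqrt(7)
  expect_lt(abs(sd(r) / pred - 1), 0.15)
})

test_that("decay expected curve integrates to the analytic model mass", {
  d <- generate_decay(c(0.5, 0.5), c(3, 7), n_channels = 2048L, seed = 1,
                      poisson = FALSE)
  tr <- d$truth
  total <- sum(tr$expected_counts) * tr$channel_width_ns
  analytic <- tr$amplitude * sum(tr$truth_alphas * tr$truth_taus_ns)
  expect_lt(abs(total / analytic - 1), 1e-3)
  expect_equal(max(round(tr$expected_counts)), 15000)
})

test_that("near-delta IRF yields a pure exponential tail", {
  d <- generate_decay(1, 5, irf_fwhm_ns = 1e-4, seed = 1, poisson = FALSE)
  cnt <- d$truth$expected_counts
  w <- d$truth$channel_width_ns
  tail_idx <- 40:400  # well past the IRF position
  ratios <- cnt[tail_idx + 1] / cnt[tail_idx]
  expect_equal(ratios, rep(exp(-w / 5), length(tail_idx)), tolerance = 1e-9)
})

test_that("decay counts follow Poisson statistics channel-wise", {
  draws <- vapply(1:150, function(s) {
    generate_decay(c(0.5, 0.5), c(3, 7), n_channels = 768L,
                   seed = s)$histogram$counts[seq(40, 700, by = 60)]
  }, numeric(12))
  ratio <- apply(draws, 1, var) / apply(draws, 1, mean)
  # var/mean ~ 1 within Monte-Carlo error (chi-square spread at n = 150)
  expect_true(all(ratio > 0.65 & ratio < 1.45))
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("decay generation rejects invalid models and short records", {
  expect_error(generate_decay(c(0.7, 0.5), c(3, 7)), "sum to 1")
  expect_error(generate_decay(c(0.5, 0.5), c(3, -7)), "> 0")
  expect_error(generate_decay(c(0.5, 0.5), c(3, 7), n_channels = 256L),
               "shorter than 5 x max lifetime")
})

test_that("study generation is byte-identical for a fixed design and seed", {
  design <- study_design(lipid_systems = "POPC",
                         compounds = c("CONTROL", "PHLORETIN"),
                         n_replicates = 1L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(design, dir = d1, seed = 77)
  generate_study(design, dir = d2, seed = 77)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed must change the data
  d3 <- withr::local_tempdir()
  generate_study(design, dir = d3, seed = 78)
  spec <- grep("^spec_.*[^k]\\.csv$", files, value = TRUE)[1]
  expect_false(identical(readLines(file.path(d1, spec)),
                         readLines(file.path(d3, spec))))
})

test_that("generation restores the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_excitation_pair(2, spectrum_shape_config(), seed = 9))
  invisible(generate_decay(seed = 9))
  expect_identical(.Random.seed, before)
})
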