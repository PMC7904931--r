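test_that("G factor and anisotropy formula give textbook values", {
  expect_equal(g_factor(100, 100), 1.0)
  expect_equal(g_factor(120, 100), 1.2)
  expect_error(g_factor(120, 0), "> 0")

  expect_equal(steady_state_anisotropy(100, 100, 1), 0)
  expect_equal(steady_state_anisotropy(100, 0, 1.3), 1.0)
  expect_equal(steady_state_anisotropy(100, 50, 1.2), 40 / 220)
  expect_error(steady_state_anisotropy(100, -50, 1), "denominator")
})

test_that("the anisotropy is scale-invariant and G-invariant by construction", {
  set.seed(42)
  for (i in 1:20) {
    I_VV <- runif(1, 50, 200)
    I_VH <- runif(1, 50, 200)
    G <- runif(1, 0.5, 2)
    c_scale <- runif(1, 0.1, 10)
    expect_equal(steady_state_anisotropy(c_scale * I_VV, c_scale * I_VH, G),
                 steady_state_anisotropy(I_VV, I_VH, G), tolerance = 1e-12)
  }
  # any instrument G, analyzed with its own HV/HH estimate, recovers truth
  for (G in c(0.6, 1, 1.2, 1.8)) {
    g <- generate_polarized_set(0.21, G, noise_cv = 0, seed = 3)
    expect_equal(aggregate_anisotropy(g$set)$mean_r, 0.21, tolerance = 1e-12)
  }
})

test_that("zero-noise aggregation reproduces the reference anisotropies exactly", {
  for (truth in c(0.165, 0.247)) {
    g <- generate_polarized_set(truth, 1.2, noise_cv = 0, seed = 1)
    a <- aggregate_anisotropy(g$set)
    expect_equal(a$mean_r, truth, tolerance = 1e-12)
    expect_equal(a$G_mean, 1.2, tolerance = 1e-12)
    expect_equal(a$n_repeats_used, 7L)
  }
})

test_that("blank subtraction is exact and bad repeats are excluded, not clipped", {
  g <- generate_polarized_set(0.19, 1.2, scale = 1000, noise_cv = 0, seed = 2)
  b0 <- 5
  m <- g$set$meta
  lab <- polarized_set(g$set$I_VV + b0, g$set$I_VH + b0,
                       g$set$I_HV + b0, g$set$I_HH + b0, m)
  blank <- polarized_set(rep(b0, 7), rep(b0, 7), rep(b0, 7), rep(b0, 7),
                         sample_meta("B", "POPC", probe = "DPHPC",
                                     is_blank = TRUE))
  expect_equal(aggregate_anisotropy(lab, blank)$mean_r, 0.19, tolerance = 1e-12)

  # one repeat with corrupted (sub-blank) intensity is dropped
  vv <- lab$I_VV; vv[3] <- 1
  bad <- polarized_set(vv, lab$I_VH, lab$I_HV, lab$I_HH, m)
  expect_warning(a <- aggregate_anisotropy(bad, blank), "excluding 1 repeat")
  expect_equal(a$n_repeats_used, 6L)
  expect_equal(a$mean_r, 0.19, tolerance = 1e-12)

  # all repeats unusable is an error
  zero <- polarized_set(rep(1, 7), rep(1, 7), rep(1, 7), rep(1, 7), m)
  expect_warning(expect_error(aggregate_anisotropy(zero, blank),
                              "all repeats excluded"))
})

test_that("condition aggregation uses sample SD across independent samples", {
  a <- condition_anisotropy(c(0.16, 0.17, 0.18), "POPC", "CONTROL")
  expect_equal(a$mean_r, 0.17)
  expect_equal(a$sd_r, 0.01)
  expect_equal(a$n_samples, 3L)
  expect_error(condition_anisotropy(numeric()), "empty")
})

test_that("recovered anisotropies are unbiased with SDs in the reported range", {
  truth <- 0.247
  cv <- anisotropy_noise_cv(truth, 0.007, 7)
  r <- vapply(1:500, function(s) {
    aggregate_anisotropy(generate_polarized_set(truth, 1.2, noise_cv = cv,
                                                seed = s)$set)$mean_r
  }, 0)
  expect_lt(abs(mean(r) - truth), 3 * sd(r) / sqrt(length(r)))
  expect_gt(sd(r), 0.002)
  expect_lt(sd(r), 0.012)
})

test_that("the default study preserves the membrane-order ranking across systems", {
  # POPC (ld) < ternary raft mixture < POPC:Chol (lo); pooled over 5 study
  # realizations to resolve the small ternary-vs-lo gap
  root <- withr::local_tempdir()
  pooled <- NULL
  for (i in 1:5) {
    st <- generate_study(study_design(compounds = "CONTROL", arms = "anisotropy"),
                         dir = file.path(root, i), seed = 300 + i)
    res <- analyze_study(st$manifest)
    pooled <- rbind(pooled, res$anisotropy_replicates)
  }
  m <- tapply(pooled$r, pooled$lipid_system, mean)
  expect_lt(m[["POPC"]], m[["POPC_CHOL_PSM"]])
  expect_lt(m[["POPC_CHOL_PSM"]], m[["POPC_CHOL"]])
})
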