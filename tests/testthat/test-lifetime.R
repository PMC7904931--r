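test_that("the intensity-weighted mean lifetime follows its closed form", {
  expect_equal(mean_lifetime(decay_model(1, 5)), 5)
  expect_equal(mean_lifetime(decay_model(c(0.5, 0.5), c(3, 7))), 5.8)
  expect_equal(mean_lifetime(decay_model(c(1, 0), c(3, 7))), 3)

  # amplitude-weighted mean <= <tau> <= max tau for random models
  set.seed(7)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    a <- runif(k); a <- a / sum(a)
    tau <- sort(runif(k, 0.5, 10)) * (1 + 0.01 * seq_len(k))
    m <- decay_model(a, tau)
    mt <- mean_lifetime(m)
    expect_gte(mt, sum(m$alphas * m$taus_ns) - 1e-12)
    expect_lte(mt, max(tau) + 1e-12)
  }
})

test_that("decay models normalize amplitudes and reject degenerate input", {
  m <- decay_model(c(2, 2), c(7, 3))
  expect_equal(m$alphas, c(0.5, 0.5))
  expect_equal(m$taus_ns, c(3, 7))  # sorted ascending, amplitudes follow
  expect_identical(decay_model(c(1, 1), c(3, 7))$alphas,
                   decay_model(c(4, 4), c(3, 7))$alphas)
  expect_error(decay_model(c(0.5, 0.5), c(3, 3)), "distinct")
  expect_error(decay_model(c(0.5, 0.5), c(3, -1)), "positive")
})

test_that("reconvolution with a delta IRF reduces to the bare decay law", {
  n <- 300L
  w <- 0.055517
  irf <- numeric(n); irf[20] <- 1000
  m <- decay_model(1, 4)
  curve <- convolve_model(m, irf, w, n)
  tail_idx <- 25:250
  ratios <- curve[tail_idx + 1] / curve[tail_idx]
  expect_equal(ratios, rep(exp(-w / 4), length(tail_idx)), tolerance = 1e-9)
  # background enters additively
  mb <- decay_model(1, 4, background = 7)
  expect_equal(convolve_model(mb, irf, w, n), curve + 7, tolerance = 1e-9)
  expect_error(convolve_model(m, numeric(n), w, n), "all zeros")
})

test_that("the reconvolved curve is linear in the amplitude mixture", {
  n <- 400L; w <- 0.055517
  irf <- exp(-((seq_len(n) - 30) * w)^2 / (2 * 0.1^2))
  c1 <- convolve_model(decay_model(1, 3), irf, w, n, amplitude = 800)
  c2 <- convolve_model(decay_model(1, 7), irf, w, n, amplitude = 200)
  mix <- convolve_model(decay_model(c(0.8, 0.2), c(3, 7)), irf, w, n,
                        amplitude = 1000)
  expect_equal(c1 + c2, mix, tolerance = 1e-9)
})

test_that("the FFT reconvolution matches a direct quadrature oracle", {
  n <- 900L
  w <- 0.02
  center <- 0.6
  sigma <- 0.05 / (2 * sqrt(2 * log(2)))  # 50 ps FWHM
  edges <- (0:n) * w
  irf <- diff(pnorm(edges, center, sigma))
  alphas <- c(0.35, 0.65)
  taus <- c(1.1, 3.2)
  got <- convolve_model(decay_model(alphas, taus), irf, w, n, amplitude = 1e4)
  want <- oracle_reconvolution(1e4 * alphas, taus, irf, w, n)
  ref <- pmax(got, want)
  keep <- ref > 1e-6 * max(ref)
  expect_lt(max(abs(got - want)[keep] / ref[keep]), 1e-6)
})

test_that("noiseless single-exponential decays are recovered essentially exactly", {
  d <- generate_decay(1, 5, seed = 1, poisson = FALSE)
  f <- fit_reconvolution(d$histogram, 1)
  expect_lt(abs(f$model$taus_ns / 5 - 1), 1e-3)
  expect_lt(f$diagnostics$chi2_reduced, 0.05)
  expect_equal(f$mean_tau_ns, f$model$taus_ns)
})

test_that("bi-exponential fits at acquisition settings recover both lifetimes", {
  d <- generate_decay(c(0.5, 0.5), c(3, 7), seed = 2024)
  f <- fit_reconvolution(d$histogram, 2)
  expect_lt(abs(f$model$taus_ns[1] / 3 - 1), 0.05)
  expect_lt(abs(f$model$taus_ns[2] / 7 - 1), 0.05)
  expect_gt(f$diagnostics$chi2_reduced, 0.8)
  expect_lt(f$diagnostics$chi2_reduced, 1.3)
  expect_true(f$diagnostics$converged)
  p <- f$diagnostics$runs_test_p
  expect_true(is.na(p) || (p >= 0 && p <= 1))
  # Eq.-5 bound holds on the fitted model
  expect_gte(f$mean_tau_ns, sum(f$model$alphas * f$model$taus_ns))
  expect_lte(f$mean_tau_ns, max(f$model$taus_ns))
})

test_that("lifetime estimates are unbiased and chi-square is calibrated over realizations", {
  fits <- lapply(1:100, function(s) {
    fit_reconvolution(generate_decay(c(0.5, 0.5), c(3, 7), seed = 4000 + s)$histogram, 2)
  })
  t1 <- vapply(fits, function(f) f$model$taus_ns[1], 0)
  t2 <- vapply(fits, function(f) f$model$taus_ns[2], 0)
  mt <- vapply(fits, function(f) f$mean_tau_ns, 0)
  chi <- vapply(fits, function(f) f$diagnostics$chi2_reduced, 0)
  expect_lt(abs(mean(t1) / 3 - 1), 0.02)   # bias below 2%
  expect_lt(abs(mean(t2) / 7 - 1), 0.02)
  expect_gt(median(chi), 0.9)
  expect_lt(median(chi), 1.1)
  # the mean lifetime is stable even where alpha/tau trade off individually
  expect_true(all(abs(mt / 5.8 - 1) < 0.03))
})

test_that("fits refuse histograms too sparse to constrain the model", {
  d <- generate_decay(1, 5, target_peak_counts = 12000, seed = 3)
  weak <- decay_histogram(pmin(d$histogram$counts, 500), 0.055517,
                          d$histogram$irf_counts, d$histogram$meta)
  expect_error(fit_reconvolution(weak, 1), "too low")
  expect_error(fit_reconvolution(d$histogram, 4), "between 1 and 3")
})

test_that("model selection prefers the most parsimonious adequate order", {
  s1 <- select_model(generate_decay(1, 5, seed = 31)$histogram)
  expect_equal(s1$model$n_components, 1L)
  s2 <- select_model(generate_decay(c(0.5, 0.5), c(3, 7), seed = 32)$histogram)
  expect_equal(s2$model$n_components, 2L)
  expect_length(s2$candidates, 3L)
})
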