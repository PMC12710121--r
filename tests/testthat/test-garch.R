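simulate_garch11 <- function(n, omega, alpha1, beta1, seed) {
  with_seed_local(seed, {
    z <- rnorm(n + 100)
    e <- numeric(n + 100)
    s2 <- omega / (1 - alpha1 - beta1)
    for (t in seq_len(n + 100)) {
      if (t > 1) s2 <- omega + alpha1 * e[t - 1]^2 + beta1 * s2
      e[t] <- sqrt(s2) * z[t]
    }
    e[101:(n + 100)]
  })
}

test_that("AR prewhitening recovers known coefficients and orders", {
  # AR(2) with phi = (0.5, -0.3)
  x <- with_seed_local(7, as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 1500)))
  fit <- fit_ar_residuals(x)
  expect_gte(fit$order, 2)
  expect_lt(abs(fit$coefficients[1] - 0.5), 0.1)
  expect_lt(abs(fit$coefficients[2] - (-0.3)), 0.1)
  expect_lte(var(fit$residuals), var(x))
  # white noise passes through nearly unchanged
  wn <- with_seed_local(8, rnorm(1500))
  fwn <- fit_ar_residuals(wn)
  expect_gt(var(fwn$residuals) / var(wn), 0.95)
  # a deterministic sinusoid is almost fully predictable
  sn <- make_tone(5, 100, 15)
  fsn <- fit_ar_residuals(sn)
  expect_lt(var(fsn$residuals) / var(sn), 0.01)
  expect_error(fit_ar_residuals(c(rnorm(200), NA)), "non-finite")
  expect_error(fit_ar_residuals(rnorm(50)), "too short")
})

test_that("GARCH(1,1) QML recovers parameters in simulation", {
  fits <- lapply(1:40, function(r)
    fit_garch11(simulate_garch11(1500, 0.1, 0.1, 0.8, seed = 1000 + r)))
  conv <- Filter(function(f) f$converged, fits)
  expect_gt(length(conv), 35)
  expect_lt(abs(median(vapply(conv, `[[`, numeric(1), "omega")) - 0.1), 0.1)
  expect_lt(abs(median(vapply(conv, `[[`, numeric(1), "alpha1")) - 0.1), 0.1)
  expect_lt(abs(median(vapply(conv, `[[`, numeric(1), "beta1")) - 0.8), 0.1)
})

test_that("GARCH on homoskedastic noise finds little persistence", {
  e <- with_seed_local(5, rnorm(1500))
  g <- fit_garch11(e)
  expect_true(g$converged)
  expect_lt(g$alpha1, 0.15)
  # standardized residuals stay close to the raw residuals
  expect_gt(cor(g$standardized_residuals, (e - mean(e)) / sd(e)), 0.98)
  expect_error(fit_garch11(rep(1, 500)), "zero-variance")
  expect_error(fit_garch11(rnorm(100)), "at least 300")
})

test_that("KS feature sits at the null level for Gaussian input", {
  ks <- vapply(1:5, function(s)
    as.numeric(garch_ks_feature(with_seed_local(s, rnorm(1500)))),
    numeric(1))
  expect_true(all(ks < 0.05))
})

test_that("KS feature is invariant to positive amplitude rescaling", {
  s <- archetype_series("PD", seed = 12)
  f1 <- garch_ks_feature(s$samples)
  f2 <- garch_ks_feature(123.4 * s$samples)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-10)
})

test_that("asymmetric, burst-modulated oscillations raise the KS feature", {
  # paired single-regime draws differing only in waveform/burst asymmetry:
  # a skewed harmonic with unpredictable per-cycle amplitude leaves
  # non-Gaussian residuals, a plain jittered tone does not
  wins <- vapply(1:20, function(i) {
    base <- with_seed_local(3000 + i, runif(1, 4, 6))
    skewed <- oscillator_params(base, 0.35, harmonic_ratio = 0.5,
                                harmonic_phase = pi / 2,
                                amplitude_jitter_sd = 0.35)
    sym <- oscillator_params(base, 0.35)
    a <- simulate_series(skewed, state_switching_params(), 20, 500,
                         seed = 3000 + i, noise_sd = 0.12)
    b <- simulate_series(sym, state_switching_params(), 20, 500,
                         seed = 3000 + i, noise_sd = 0.12)
    fa <- garch_ks_feature(standardize_series(a$samples, 500))
    fb <- garch_ks_feature(standardize_series(b$samples, 500))
    isTRUE(as.numeric(fa) > as.numeric(fb))
  }, logical(1))
  expect_gte(mean(wins), 0.85)
})

test_that("PD-like cohorts have larger KS features than ET-like cohorts", {
  et <- vapply(1:10, function(i)
    as.numeric(garch_ks_feature(archetype_series("ET", 500 + i))),
    numeric(1))
  pd <- vapply(1:10, function(i)
    as.numeric(garch_ks_feature(archetype_series("PD", 500 + i))),
    numeric(1))
  expect_gt(median(pd), median(et))
})
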