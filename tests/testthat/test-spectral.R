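test_that("Welch PSD resolves tones and satisfies Parseval", {
  x <- make_tone(5, 100, 15)
  x <- (x - mean(x)) / sd(x)
  ps <- welch_psd(x, fs = 100)
  pk <- peak_frequency_power(ps)
  expect_lte(abs(pk$frequency - 5), ps$resolution)
  # Parseval: integrated density recovers unit variance within 5%
  expect_lt(abs(band_power_auc(ps, c(0, 50)) - 1), 0.05)
  # two tones: power ratio follows amplitude ratio squared
  x2 <- make_tone(4, 100, 15) + 0.5 * make_tone(8, 100, 15)
  ps2 <- welch_psd(x2, fs = 100)
  p4 <- band_power_auc(ps2, c(3.5, 4.5))
  p8 <- band_power_auc(ps2, c(7.5, 8.5))
  expect_lt(abs(p4 / p8 - 4), 0.4)
  expect_error(welch_psd(rnorm(100), fs = 100), "too short")
})

test_that("white-noise spectra are approximately flat", {
  worst <- vapply(1:5, function(s) {
    x <- with_seed_local(s, rnorm(1500))
    ps <- welch_psd(x, fs = 100)
    idx <- ps$frequencies > 1 & ps$frequencies < 49
    max(ps$power[idx]) / median(ps$power[idx])
  }, numeric(1))
  expect_lt(max(worst), 5)
})

test_that("peak search matches a brute-force scan with low-frequency ties", {
  with_seed_local(21, {
    for (i in 1:10) {
      ps <- structure(list(frequencies = seq(0, 50, by = 0.2),
                           power = runif(251), resolution = 0.2),
                      class = "power_spectrum")
      idx <- which(ps$frequencies >= 2 & ps$frequencies <= 30)
      brute <- idx[which.max(ps$power[idx])]
      pk <- peak_frequency_power(ps, c(2, 30))
      expect_equal(pk$frequency, ps$frequencies[brute])
      expect_equal(pk$power, ps$power[brute])
    }
  })
  # exact tie at 4 and 8 Hz resolves to the lower frequency
  f <- seq(0, 50, by = 0.2)
  p <- rep(0.1, length(f)); p[f == 4] <- 2; p[f == 8] <- 2
  tie <- structure(list(frequencies = f, power = p, resolution = 0.2),
                   class = "power_spectrum")
  expect_equal(peak_frequency_power(tie, c(2, 30))$frequency, 4)
})

test_that("band power integrates exactly and additively", {
  f <- seq(0, 50, by = 0.2)
  flat <- structure(list(frequencies = f, power = rep(1, length(f)),
                         resolution = 0.2), class = "power_spectrum")
  expect_equal(band_power_auc(flat, c(2, 30)), 28)
  with_seed_local(2, {
    ps <- structure(list(frequencies = f, power = runif(length(f)),
                         resolution = 0.2), class = "power_spectrum")
    expect_equal(band_power_auc(ps, c(2, 30)),
                 band_power_auc(ps, c(2, 10)) + band_power_auc(ps, c(10, 30)))
    # non-grid split point still additive (edge interpolation)
    expect_equal(band_power_auc(ps, c(2, 30)),
                 band_power_auc(ps, c(2, 17.13)) +
                 band_power_auc(ps, c(17.13, 30)))
  })
  expect_error(band_power_auc(flat, c(30, 2)), "inverted")
})

test_that("FWHM of an analytic Gaussian peak equals 2.3548 sigma", {
  f <- seq(0, 50, by = 0.05)
  for (sigma in c(0.5, 1, 2)) {
    p <- exp(-(f - 10)^2 / (2 * sigma^2))
    ps <- structure(list(frequencies = f, power = p, resolution = 0.05),
                    class = "power_spectrum")
    fw <- spectral_fwhm(ps, c(2, 30))
    expect_lt(abs(fw$width - 2.3548 * sigma), 0.05)
    expect_false(fw$truncated)
    # symmetric peak: crossings equidistant from the peak
    expect_lt(abs((10 - fw$lo) - (fw$hi - 10)), 0.05)
  }
  # single-bin spike degenerates to one grid step
  f2 <- seq(0, 50, by = 0.2)
  p2 <- rep(0, length(f2)); p2[f2 == 6] <- 1
  spike <- structure(list(frequencies = f2, power = p2, resolution = 0.2),
                     class = "power_spectrum")
  expect_lte(spectral_fwhm(spike, c(2, 30))$width, 2 * 0.2)
  # plateau never crossing half-maximum truncates at the band edge
  plateau <- structure(list(frequencies = f2, power = rep(1, length(f2)),
                            resolution = 0.2), class = "power_spectrum")
  expect_true(spectral_fwhm(plateau, c(2, 30))$truncated)
})

test_that("half-width power concentrates on the peak and stays below AUC", {
  x <- make_tone(5, 100, 15) + with_seed_local(6, rnorm(1500, 0, 0.05))
  ps <- welch_psd(x, fs = 100)
  hwp <- half_width_power(ps)
  auc <- band_power_auc(ps)
  expect_lte(hwp, auc)
  # a Hann window spreads even an on-grid tone over a 3-bin main lobe whose
  # half-power region carries ~3/4 of it; concentration is bounded by that
  expect_gt(hwp / auc, 0.6)
  # flat spectrum: HWP = density x width
  f <- seq(0, 50, by = 0.2)
  flat <- structure(list(frequencies = f, power = rep(2, length(f)),
                         resolution = 0.2), class = "power_spectrum")
  fwf <- spectral_fwhm(flat, c(2, 30))
  expect_equal(half_width_power(flat, c(2, 30)), 2 * fwf$width)
})

test_that("instantaneous frequency tracks constant tones and chirps", {
  x <- make_tone(5, 100, 15)
  inf <- instantaneous_frequency(x, fs = 100)
  expect_true(all(abs(inf$frequency[inf$valid] - 5) < 0.05))
  infs <- instantaneous_frequency(x, fs = 100, mode = "sample")
  expect_true(all(abs(infs$frequency[infs$valid] - 5) < 0.1))
  # linear chirp 4 -> 6 Hz: cycle frequencies increase monotonically
  t <- seq(0, 15 - 0.01, by = 0.01)
  chirp <- sin(2 * pi * (4 * t + (2 / (2 * 15)) * t^2))
  infc <- instantaneous_frequency(chirp, fs = 100)
  mid <- infc$frequency[infc$valid]
  mid <- mid[3:(length(mid) - 3)]
  expect_true(all(diff(mid) > -0.05))
  expect_gt(tail(mid, 1) - head(mid, 1), 1.5)
  # square FM +-0.5 Hz: bimodal estimates near both plateaus
  fm <- 5 + 0.5 * sign(sin(2 * pi * 0.25 * t))
  xfm <- sin(2 * pi * cumsum(fm) * 0.01)
  inff <- instantaneous_frequency(xfm, fs = 100)
  fr <- inff$frequency[inff$valid]
  expect_gt(mean(abs(fr - 4.5) < 0.15 | abs(fr - 5.5) < 0.15), 0.6)
})

test_that("TSI is near zero for stable tones and follows its IQR form", {
  x <- make_tone(5, 100, 15)
  expect_lt(tremor_stability_index(x, fs = 100), 0.1)
  # quartile stage: linear-interpolation (type 7) IQR of {-1,0,0,1} is 0.5
  expect_equal(tremorlab:::delta_f_iqr(c(-1, 0, 0, 1)), 0.5)
  # amplitude invariance
  s <- archetype_series("PD", seed = 31)
  expect_equal(tremor_stability_index(s),
               tremor_stability_index(7.3 * s$samples, fs = 100))
  expect_error(tremor_stability_index(make_tone(5, 100, 2), fs = 100),
               "cycles")
})

test_that("PD-like series have larger TSI than ET-like series", {
  tsis <- vapply(1:12, function(i) {
    c(tremor_stability_index(archetype_series("ET", 600 + i)),
      tremor_stability_index(archetype_series("PD", 600 + i)))
  }, numeric(2))
  expect_gt(median(tsis[2, ]), median(tsis[1, ]))
})

test_that("six-metric summary satisfies its internal consistency", {
  s <- archetype_series("ET", seed = 44)
  sm <- spectral_summary(s)
  expect_named(sm, c("auc", "tsi", "hwp", "peak_frequency", "fwhm",
                     "peak_power"))
  expect_true(all(unlist(sm) >= 0))
  expect_lte(sm$hwp, sm$auc)
  expect_gte(sm$peak_frequency, 2)
  expect_lte(sm$peak_frequency, 30)
  expect_lte(sm$fwhm, 28)
})

test_that("group comparison reproduces a hand-computed rank-sum", {
  # W statistic of x={1.1, 2.3, 3.5} vs y={0.2, 0.4, 4.7} by enumeration:
  # pairs with x > y: 1.1>(0.2,0.4), 2.3>(0.2,0.4), 3.5>(0.2,0.4) -> W = 6
  df <- data.frame(diagnosis = rep(c("A", "B"), each = 3),
                   m = c(1.1, 2.3, 3.5, 0.2, 0.4, 4.7))
  res <- compare_groups(df, metrics = "m")
  expect_equal(res$statistic, 6)
  expect_equal(res$p_bonferroni, pmin(1, res$p_value * 1))
  df2 <- df; df2$m2 <- df2$m
  res2 <- compare_groups(df2, metrics = c("m", "m2"))
  expect_equal(res2$p_bonferroni, pmin(1, res2$p_value * 2))
})
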