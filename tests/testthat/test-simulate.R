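test_that("degenerate oscillator reduces to a pure sinusoid", {
  osc <- oscillator_params(5, frequency_jitter_sd = 0, harmonic_ratio = 0)
  s <- simulate_series(osc, duration = 15, rate = 100, seed = 1,
                       noise_sd = 0)
  ps <- welch_psd(s$samples - mean(s$samples), fs = 100)
  expect_lt(abs(peak_frequency_power(ps)$frequency - 5), 0.21)
  sk <- mean((s$samples - mean(s$samples))^3) / sd(s$samples)^3
  expect_lt(abs(sk), 0.05)
  expect_true(all(s$state_path == 1))
})

test_that("asymmetric harmonics skew the waveform as predicted", {
  # analytic skewness of sin(p) + 0.4 sin(2p + pi/2): E[x^3] = -0.3,
  # var = 0.5 + 0.08 -> skew = -0.3 / 0.58^1.5 = -0.68
  osc <- oscillator_params(5, 0, harmonic_ratio = 0.4,
                           harmonic_phase = pi / 2)
  s <- simulate_series(osc, duration = 20, rate = 500, seed = 2,
                       noise_sd = 0)
  x <- s$samples - mean(s$samples)
  sk <- mean(x^3) / sd(x)^3
  expect_gt(abs(sk), 0.2)
  expect_lt(abs(sk - (-0.68)), 0.1)
})

test_that("state dwell times match the configured mean", {
  dwells <- unlist(lapply(1:60, function(i) {
    sw <- state_switching_params(2, c(1, 0.5), c(0, 0), mean_dwell_s = 3)
    s <- simulate_series(oscillator_params(5), sw, duration = 30,
                         rate = 100, seed = 100 + i, noise_sd = 0)
    r <- rle(s$state_path)
    # interior runs only: first/last are censored by the window
    if (length(r$lengths) > 2) r$lengths[2:(length(r$lengths) - 1)] / 100
    else numeric(0)
  }))
  expect_lt(abs(mean(dwells) - 3) / 3, 0.2)
})

test_that("PD state paths visit multiple regimes within 15 s", {
  visits <- vapply(1:40, function(i) {
    pars <- with_seed_local(900 + i, archetype_params("PD"))
    s <- simulate_series(pars$oscillator, pars$switching, 15, 100,
                         seed = 900 + i, noise_sd = pars$noise_sd)
    length(unique(s$state_path)) >= 2
  }, logical(1))
  expect_gte(mean(visits), 0.95)
})

test_that("empirical transitions are consistent with the embedded chain", {
  # 3-state uniform embedded chain: transitions from each state split
  # evenly between the two other states
  sw <- state_switching_params(3, c(1, 0.5, 0.8), c(0, 0, 0),
                               mean_dwell_s = 0.8)
  trans <- matrix(0, 3, 3)
  for (i in 1:30) {
    s <- simulate_series(oscillator_params(5), sw, 30, 100,
                         seed = 200 + i, noise_sd = 0)
    r <- rle(s$state_path)$values
    for (j in seq_len(length(r) - 1)) trans[r[j], r[j + 1]] <-
        trans[r[j], r[j + 1]] + 1
  }
  for (from in 1:3) {
    obs <- trans[from, -from]
    expect_gt(suppressWarnings(chisq.test(obs, p = c(0.5, 0.5))$p.value),
              0.01)
  }
})

test_that("patient simulation encodes the clinical phenotype conventions", {
  cfg <- default_cohort_config(seed = 1)
  et <- simulate_et_patient(cfg, seed = 5)
  pd <- simulate_pd_patient(cfg, seed = 6)
  gt_amp <- function(p, cond) {
    aff <- p$ground_truth[[1]]$affected_side
    key <- names(p$ground_truth)[grepl(paste0("/", cond, "/", aff),
                                       names(p$ground_truth))]
    p$ground_truth[[key]]$amplitude
  }
  expect_gt(gt_amp(et, "posture"), gt_amp(et, "rest"))  # ET postural
  expect_gt(gt_amp(pd, "rest"), gt_amp(pd, "posture"))  # PD rest
  expect_equal(et$ground_truth[[1]]$n_states, 1L)
  expect_gte(pd$ground_truth[[1]]$n_states, 2L)
  # affected side is 3x the other
  gt <- et$ground_truth
  rest_keys <- names(gt)[grepl("/rest/", names(gt))]
  amps <- sort(vapply(gt[rest_keys], `[[`, numeric(1), "amplitude"))
  expect_equal(unname(amps[2] / amps[1]), cfg$affected_ratio)
})

test_that("balanced hands give near-zero AUC asymmetry", {
  # matched-gain recordings (no projection geometry variance between hands)
  rels <- vapply(1:6, function(i) {
    pars <- with_seed_local(50 + i, archetype_params("ET"))
    mk <- function(hand, seed) {
      s <- simulate_series(pars$oscillator, pars$switching, 20, 200,
                           seed = seed, noise_sd = pars$noise_sd)
      raw_recording("p", list(s$samples), 200, hand = hand)
    }
    recs <- list(mk("right", 70 + 2 * i), mk("left", 71 + 2 * i))
    sel <- select_more_affected_hand(recs)
    abs(sel$auc_rel[["rest"]])
  }, numeric(1))
  expect_lt(median(rels), 0.05)
})

test_that("cohort generation is deterministic and correctly sized", {
  cfg <- default_cohort_config(n_et = 3, n_pd = 2, seed = 31)
  m1 <- simulate_cohort(cfg)
  expect_equal(length(m1), (3 + 2) * 2 * 2)  # patients x hands x conditions
  dx <- table(vapply(m1$recordings, `[[`, character(1), "diagnosis"))
  expect_equal(unname(dx[["ET"]]), 12)
  expect_equal(unname(dx[["PD"]]), 8)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  simulate_cohort(cfg, out_dir = dir1)
  simulate_cohort(cfg, out_dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(tools::md5sum(file.path(dir1, f))[[1]],
                     tools::md5sum(file.path(dir2, f))[[1]])
  }
})

test_that("paired ET/PD patients order both features in the PD direction", {
  cfg <- default_cohort_config(seed = 1)
  res <- t(vapply(1:30, function(i) {
    ctr <- cfg$centers[(i %% 4) + 1, ]
    et <- simulate_et_patient(cfg, seed = 1300 + 2 * i, center = ctr)
    pd <- simulate_pd_patient(cfg, seed = 1300 + 2 * i + 1, center = ctr)
    en <- preprocess_recording(affected_rest_recording(et))
    pn <- preprocess_recording(affected_rest_recording(pd))
    c(garch = isTRUE(as.numeric(garch_ks_feature(pn)) >
                       as.numeric(garch_ks_feature(en))),
      hmm = isTRUE(hmm_compare_nstates_feature(pn, seed = i) >
                     hmm_compare_nstates_feature(en, seed = i)))
  }, logical(2)))
  # small-sample binomial threshold for a property holding in >= 85% long-run
  expect_gte(mean(res[, "garch"]), 0.8)
  expect_gte(mean(res[, "hmm"]), 0.8)
})

test_that("monoaxial center output is accepted by the full pipeline", {
  cfg <- default_cohort_config(n_et = 6, n_pd = 6, monoaxial = TRUE,
                               seed = 13)
  m <- simulate_cohort(cfg)
  expect_true(all(vapply(m$recordings,
                         function(r) length(r$axes) == 1L, logical(1))))
  rr <- run_pipeline(run_config(cohort = m, k = 5, seed = 1))
  expect_true(is.finite(rr$report$pooled[["balanced_accuracy"]]))
})
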