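#' Oscillator parameters for synthetic tremor
#'
#' Parameters of the phase-continuous tremor oscillator: fundamental
#' frequency, per-cycle frequency jitter, amplitude, relative second
#' harmonic (whose phase controls waveform asymmetry and hence sample
#' skewness), and slow sinusoidal amplitude modulation.
#'
#' @param base_frequency Fundamental frequency in Hz (inside (2, 30)).
#' @param frequency_jitter_sd Per-cycle frequency jitter SD in Hz.
#' @param amplitude Oscillation amplitude (arbitrary acceleration units).
#' @param harmonic_ratio Second-harmonic amplitude relative to the
#'   fundamental (>= 0).
#' @param harmonic_phase Second-harmonic phase offset in radians;
#'   `pi/2` yields a maximally skewed waveform, `0` a symmetric one.
#' @param am_depth,am_rate Amplitude-modulation depth (0..1) and rate (Hz).
#' @param amplitude_jitter_sd Log-SD of the per-cycle multiplicative
#'   amplitude burst `exp(N(0, sd))`; right-skewed unpredictable cycle
#'   amplitudes emulate spontaneous waxing episodes and, combined with an
#'   asymmetric waveform, leave skewed innovations no linear model can
#'   whiten.
#' @param pulse_ratio Relative amplitude of a direction-specific pulse
#'   component `(max(0, sin(phase)))^3` (e.g. pill-rolling-like
#'   unidirectional accelerations). Its per-cycle amplitude fluctuates
#'   (log-SD `pulse_jitter_sd`), so the one-sided component cannot be
#'   predicted by a linear model and leaves robustly skewed residuals.
#' @param pulse_jitter_sd Log-SD of the per-cycle pulse amplitude
#'   fluctuation (default 0.5).
#' @param jerk_rate Rate (events/s) of direction-specific micro-jerks:
#'   one-sided half-sine pulses of width `jerk_width_s` with exponentially
#'   distributed amplitudes, scaled by the current regime amplitude. These
#'   sub-cycle events are unpredictable to a linear model and skew the
#'   innovation distribution (default 0 = none).
#' @param jerk_amp Mean jerk amplitude relative to `amplitude`
#'   (default 0.4).
#' @param jerk_width_s Jerk pulse width in seconds (default 0.04).
#' @param noise_jitter_sd Log-SD of a multiplicative scale on the broadband
#'   movement noise, redrawn every ~25 ms (`exp(N(0, sd))`): burst-like
#'   motor noise. Conditional-variance fluctuations this fast cannot be
#'   tracked by a GARCH(1,1) fit, leaving a scale-mixture (non-Gaussian)
#'   residual distribution (default 0 = homoskedastic noise).
#' @param noise_block_s Duration (s) of one noise-burst block (default
#'   0.035).
#' @param noise_amp_coupling Fraction of the movement noise that scales
#'   with the current regime's amplitude multiplier (0 = fully
#'   regime-independent sensor noise, 1 = fully amplitude-coupled motor
#'   noise). Quiescent regimes are then also quiet in noise.
#' @return An `oscillator_params` list.
#' @export
oscillator_params <- function(base_frequency = 5, frequency_jitter_sd = 0.05,
                              amplitude = 1, harmonic_ratio = 0,
                              harmonic_phase = 0, am_depth = 0,
                              am_rate = 0.5, amplitude_jitter_sd = 0,
                              pulse_ratio = 0, pulse_jitter_sd = 0.5,
                              jerk_rate = 0, jerk_amp = 0.4,
                              jerk_width_s = 0.04, noise_jitter_sd = 0,
                              noise_block_s = 0.035,
                              noise_amp_coupling = 0) {
  stopifnot(base_frequency > 2, base_frequency < 30,
            frequency_jitter_sd >= 0, harmonic_ratio >= 0,
            amplitude_jitter_sd >= 0, pulse_ratio >= 0, jerk_rate >= 0,
            noise_jitter_sd >= 0,
            noise_amp_coupling >= 0, noise_amp_coupling <= 1)
  structure(list(base_frequency = base_frequency,
                 frequency_jitter_sd = frequency_jitter_sd,
                 amplitude = amplitude, harmonic_ratio = harmonic_ratio,
                 harmonic_phase = harmonic_phase, am_depth = am_depth,
                 am_rate = am_rate,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 pulse_ratio = pulse_ratio,
                 pulse_jitter_sd = pulse_jitter_sd,
                 jerk_rate = jerk_rate, jerk_amp = jerk_amp,
                 jerk_width_s = jerk_width_s,
                 noise_jitter_sd = noise_jitter_sd,
                 noise_block_s = noise_block_s,
                 noise_amp_coupling = noise_amp_coupling),
            class = "oscillator_params")
}

#' Markov state-switching parameters
#'
#' Hidden-regime structure of a synthetic tremor series: number of states,
#' per-state amplitude multipliers and frequency offsets, mean dwell time
#' and the between-state transition matrix (uniform over the other states
#' by default).
#'
#' @param n_states Number of regimes (>= 1; 1 means no switching).
#' @param amp_multipliers Per-state amplitude multipliers (length
#'   `n_states`).
#' @param freq_offsets Per-state frequency offsets in Hz.
#' @param mean_dwell_s Mean dwell time per regime in seconds.
#' @param dwell_shape Gamma shape of the dwell-time distribution (1 =
#'   exponential/memoryless; larger values give quasi-periodic
#'   waxing-waning alternation with less dwell variance).
#' @param transition Optional explicit between-state transition matrix
#'   (rows sum to 1, zero diagonal).
#' @return A `state_switching_params` list.
#' @export
state_switching_params <- function(n_states = 1,
                                   amp_multipliers = rep(1, n_states),
                                   freq_offsets = rep(0, n_states),
                                   mean_dwell_s = 3.5,
                                   dwell_shape = 1,
                                   transition = NULL) {
  stopifnot(n_states >= 1, length(amp_multipliers) == n_states,
            length(freq_offsets) == n_states, mean_dwell_s > 0,
            dwell_shape > 0)
  if (is.null(transition)) {
    transition <- matrix(if (n_states > 1) 1 / (n_states - 1) else 1,
                         n_states, n_states)
    if (n_states > 1) diag(transition) <- 0
  }
  if (any(abs(rowSums(transition) - 1) > 1e-10))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  structure(list(n_states = as.integer(n_states),
                 amp_multipliers = amp_multipliers,
                 freq_offsets = freq_offsets,
                 mean_dwell_s = mean_dwell_s, dwell_shape = dwell_shape,
                 transition = transition),
            class = "state_switching_params")
}

#' Simulate one tremor series
#'
#' Generates a phase-continuous oscillation with per-cycle frequency
#' jitter, hidden Markov regime switching (exponential dwell times,
#' regimes modulating amplitude and frequency), a phase-locked second
#' harmonic controlling waveform asymmetry, slow amplitude modulation, and
#' additive Gaussian sensor noise. Deterministic given the seed.
#'
#' @param osc An [oscillator_params()].
#' @param switching A [state_switching_params()].
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @param noise_sd Additive Gaussian noise SD (same units as amplitude).
#' @param extra_tones Optional data frame with columns `freq`, `amp` of
#'   additional independent oscillations (e.g. a postural physiological
#'   component).
#' @return List with `samples`, `state_path` (per-sample regime index),
#'   `t` (seconds), `rate`.
#' @export
simulate_series <- function(osc, switching = state_switching_params(),
                            duration = 20, rate = 100, seed = 0,
                            noise_sd = 0.15, extra_tones = NULL) {
  n <- round(duration * rate)
  min_dwell <- 1 / osc$base_frequency
  if (switching$n_states > 1 && switching$mean_dwell_s < min_dwell)
    stop("mean dwell time shorter than one tremor cycle", call. = FALSE)
  with_seed(seed, {
    # hidden regime path: exponential dwell, embedded-chain transitions
    k <- switching$n_states
    state <- integer(n)
    if (k == 1) {
      state[] <- 1L
    } else {
      pos <- 1L
      s <- sample.int(k, 1)
      while (pos <= n) {
        dwell <- max(min_dwell,
                     rgamma(1, shape = switching$dwell_shape,
                            rate = switching$dwell_shape / switching$mean_dwell_s))
        len <- max(1L, round(dwell * rate))
        state[pos:min(n, pos + len - 1L)] <- s
        pos <- pos + len
        s <- sample.int(k, 1, prob = switching$transition[s, ])
      }
    }
    # per-cycle frequency jitter on the nominal cycle grid
    cyc_len <- max(2L, round(rate / osc$base_frequency))
    cyc <- (seq_len(n) - 1L) %/% cyc_len + 1L
    jit <- rnorm(max(cyc), 0, osc$frequency_jitter_sd)
    f <- osc$base_frequency + switching$freq_offsets[state] + jit[cyc]
    f <- pmin(pmax(f, 0.5), 30)
    phase <- cumsum(2 * pi * f / rate) + runif(1, 0, 2 * pi)
    t <- (seq_len(n) - 1L) / rate
    aburst <- exp(rnorm(max(cyc), 0, osc$amplitude_jitter_sd))
    amp <- osc$amplitude * switching$amp_multipliers[state] * aburst[cyc] *
      (1 + osc$am_depth * sin(2 * pi * osc$am_rate * t + runif(1, 0, 2 * pi)))
    x <- amp * (sin(phase) +
                osc$harmonic_ratio * sin(2 * phase + osc$harmonic_phase))
    if (osc$pulse_ratio > 0) {
      pj <- exp(rnorm(max(cyc), 0, osc$pulse_jitter_sd))
      x <- x + amp * osc$pulse_ratio * pj[cyc] * pmax(0, sin(phase))^3
    }
    if (osc$jerk_rate > 0) {
      n_ev <- rpois(1, osc$jerk_rate * duration)
      if (n_ev > 0) {
        ev_t <- sort(runif(n_ev, 0, duration))
        ev_a <- rexp(n_ev, 1 / (osc$jerk_amp * osc$amplitude))
        wlen <- max(2L, round(osc$jerk_width_s * rate))
        shape <- sin(pi * (seq_len(wlen) - 0.5) / wlen)
        for (ev in seq_len(n_ev)) {
          i0 <- floor(ev_t[ev] * rate) + 1L
          idx <- i0:min(n, i0 + wlen - 1L)
          reg <- switching$amp_multipliers[state[i0]]
          x[idx] <- x[idx] + ev_a[ev] * reg * shape[seq_along(idx)]
        }
      }
    }
    if (!is.null(extra_tones) && nrow(extra_tones)) {
      for (j in seq_len(nrow(extra_tones))) {
        x <- x + extra_tones$amp[j] *
          sin(2 * pi * extra_tones$freq[j] * t + runif(1, 0, 2 * pi))
      }
    }
    nscale <- if (osc$noise_jitter_sd > 0) {
      nblk <- (seq_len(n) - 1L) %/% max(1L, round(osc$noise_block_s * rate)) + 1L
      exp(rnorm(max(nblk), 0, osc$noise_jitter_sd))[nblk]
    } else 1
    if (osc$noise_amp_coupling > 0) {
      nscale <- nscale * ((1 - osc$noise_amp_coupling) +
                          osc$noise_amp_coupling *
                            switching$amp_multipliers[state])
    }
    x <- x + rnorm(n, 0, noise_sd) * nscale
    list(samples = x, state_path = state, t = t, rate = rate)
  })
}

# ---- phenotype archetypes ---------------------------------------------------

# The archetype parameters below encode the mechanistic picture the two
# model-based features respond to: ET as a single stable oscillatory regime
# with a symmetric waveform, narrow frequency jitter and steady motor
# noise; PD as two Markov-switching regimes of strongly distinct amplitude
# (waxing-waning with near-quiescent epochs), a skewed waveform from an
# asymmetric phase-locked harmonic, per-cycle amplitude bursts, broader
# frequency jitter, and burst-like (heteroskedastic) motor noise.
# Condition scaling follows the clinical phenotype: ET postural > rest
# amplitude, PD rest > postural amplitude. They are testability-oriented
# conventions, not estimates from patient data (see the methods vignette).
phenotype_defaults <- function(diagnosis) {
  if (diagnosis == "ET") {
    list(freq_range = c(5, 9), jitter_sd = 0.03, harmonic_ratio = 0.05,
         harmonic_phase = 0, am_depth = 0.10, am_rate = 0.3,
         amplitude_jitter_sd = 0.05, noise_jitter_sd = 0.1,
         noise_amp_coupling = 0.6,
         n_states = 1L, amp_multipliers = 1, freq_offsets = 0,
         mean_dwell_s = 3.5, dwell_shape = 1,
         cond_amp = c(rest = 0.4, posture = 1.0))
  } else {
    list(freq_range = c(4, 6), jitter_sd = 0.35, harmonic_ratio = 0.50,
         harmonic_phase = pi / 2, am_depth = 0.15, am_rate = 0.8,
         amplitude_jitter_sd = 0.35, noise_jitter_sd = 0.9,
         noise_amp_coupling = 0.4,
         n_states = 2L, amp_multipliers = c(1, 0.08),
         freq_offsets = c(0, -0.3), mean_dwell_s = 2.0, dwell_shape = 4,
         cond_amp = c(rest = 1.0, posture = 0.45))
  }
}

#' Default synthetic cohort configuration
#'
#' Study-condition defaults for [simulate_cohort()]: cohort sizes, recording
#' duration, affected-side amplitude ratio, sensor noise, and center
#' profiles (sampling rate and axis count). The default centers are all
#' triaxial with heterogeneous rates, mirroring a multicenter setting; a
#' monoaxial profile is available via `monoaxial = TRUE` for
#' axis-count comparisons.
#'
#' @param n_et,n_pd Patients per diagnosis (default 60 each).
#' @param duration Recording duration in seconds (default 20).
#' @param affected_ratio Affected:other hand amplitude ratio (default 3).
#' @param noise_sd Broadband movement/sensor noise SD relative to unit
#'   tremor amplitude (default 0.12).
#' @param axis_noise_sd Additional independent per-axis sensor noise
#'   (default 0.02).
#' @param posture_physio_amp Relative amplitude of the 8-12 Hz
#'   physiological component present in postural recordings (default 0.8).
#' @param posture_noise_mult Multiplier on the broadband movement noise in
#'   postural recordings (holding the limb against gravity recruits more
#'   motor noise; default 2.2).
#' @param monoaxial Use the single-axis center profile for all patients.
#' @param centers Optional explicit center profile data frame with columns
#'   `name`, `rate`, `axes`, and optionally `axis_noise` (per-center sensor
#'   noise floor; defaults to `axis_noise_sd`). The monoaxial profile
#'   models a historical single-axis sensor with a higher noise floor
#'   (0.10).
#' @param seed Master seed.
#' @return A `cohort_config` list.
#' @export
default_cohort_config <- function(n_et = 60, n_pd = 60, duration = 20,
                                  affected_ratio = 3, noise_sd = 0.12,
                                  axis_noise_sd = 0.02,
                                  posture_physio_amp = 0.8,
                                  posture_noise_mult = 2.2,
                                  monoaxial = FALSE, centers = NULL,
                                  seed = 0) {
  if (is.null(centers)) {
    centers <- if (monoaxial) {
      data.frame(name = "center_M", rate = 300, axes = 1L,
                 axis_noise = 0.10)
    } else {
      data.frame(name = paste0("center_", 1:4),
                 rate = c(1000, 500, 250, 128), axes = 3L,
                 axis_noise = axis_noise_sd)
    }
  }
  structure(list(n_et = n_et, n_pd = n_pd, duration = duration,
                 affected_ratio = affected_ratio, noise_sd = noise_sd,
                 axis_noise_sd = axis_noise_sd,
                 posture_physio_amp = posture_physio_amp,
                 posture_noise_mult = posture_noise_mult,
                 centers = centers, seed = seed),
            class = "cohort_config")
}

# Project a scalar tremor series onto accelerometer axes. The sensor sits
# in a gravity field of magnitude 9.81 (same arbitrary units); the tremor
# acceleration acts along a fixed unit vector per recording whose angle to
# gravity is bounded away from orthogonal, so the vector amplitude sum
# |g + u x| ~ 9.81 + cos(theta) x recovers the waveform approximately
# linearly. Monoaxial sensors record one axis of an unconstrained random
# orientation, so their effective gain |u_z| is uniform-ish on [0, 1] --
# the geometric reason single-axis recordings carry less information.
project_axes <- function(x, n_axes, axis_noise_sd) {
  g <- rnorm(3); g <- 9.81 * g / sqrt(sum(g^2))
  if (n_axes == 3L) {
    ct <- runif(1, 0.6, 0.95) * sample(c(-1, 1), 1)
    w <- rnorm(3); w <- w - sum(w * g) * g / sum(g^2)
    w <- w / sqrt(sum(w^2))
    u <- ct * g / 9.81 + sqrt(1 - ct^2) * w
    lapply(1:3, function(j)
      g[j] + u[j] * x + rnorm(length(x), 0, axis_noise_sd))
  } else {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    list(g[3] + u[3] * x + rnorm(length(x), 0, axis_noise_sd))
  }
}

#' Simulate all recordings of one patient
#'
#' Generates both hands in both conditions for one ET- or PD-phenotype
#' patient: a patient-level base frequency draw, an affected side with
#' `affected_ratio`-fold larger tremor amplitude, condition-specific
#' amplitude scaling (ET postural > rest; PD rest > postural), a
#' physiological 8-12 Hz component added in posture, and center-specific
#' sampling rate and axis count.
#'
#' @param diagnosis `"ET"` or `"PD"`.
#' @param config A [default_cohort_config()].
#' @param patient_id Patient identifier string.
#' @param seed Patient-level seed.
#' @param center One row of `config$centers`.
#' @return List with `recordings` (list of [raw_recording()]) and
#'   `ground_truth` (per-recording true parameters, state paths as run
#'   lengths, affected side).
#' @export
simulate_patient <- function(diagnosis, config, patient_id, seed,
                             center = config$centers[1, ]) {
  ph <- phenotype_defaults(diagnosis)
  pat <- with_seed(seed, {
    list(base_freq = runif(1, ph$freq_range[1], ph$freq_range[2]),
         affected = sample(c("left", "right"), 1),
         physio_freq = runif(1, 8, 12))
  })
  recs <- list(); gt <- list()
  i <- 0L
  for (cond in c("rest", "posture")) {
    for (hand in c("left", "right")) {
      i <- i + 1L
      amp <- ph$cond_amp[[cond]] *
        (if (hand == pat$affected) 1 else 1 / config$affected_ratio)
      osc <- oscillator_params(
        base_frequency = pat$base_freq,
        frequency_jitter_sd = ph$jitter_sd, amplitude = amp,
        harmonic_ratio = ph$harmonic_ratio,
        harmonic_phase = ph$harmonic_phase,
        am_depth = ph$am_depth, am_rate = ph$am_rate,
        amplitude_jitter_sd = ph$amplitude_jitter_sd,
        noise_jitter_sd = ph$noise_jitter_sd,
        noise_amp_coupling = ph$noise_amp_coupling)
      sw <- if (ph$n_states == 1L) state_switching_params() else
        state_switching_params(ph$n_states, ph$amp_multipliers,
                               ph$freq_offsets, ph$mean_dwell_s,
                               dwell_shape = ph$dwell_shape)
      tones <- if (cond == "posture" && config$posture_physio_amp > 0) {
        data.frame(freq = pat$physio_freq,
                   amp = config$posture_physio_amp * amp)
      } else NULL
      rec_seed <- derive_seed(seed, i)
      nsd <- config$noise_sd *
        (if (cond == "posture") config$posture_noise_mult %||% 1 else 1)
      sim <- simulate_series(osc, sw, config$duration, center$rate,
                             seed = rec_seed, noise_sd = nsd,
                             extra_tones = tones)
      ax_noise <- if (!is.null(center$axis_noise)) center$axis_noise
                  else config$axis_noise_sd
      axes <- with_seed(derive_seed(rec_seed, 7),
                        project_axes(sim$samples, center$axes, ax_noise))
      shift <- with_seed(derive_seed(rec_seed, 8), abs(rnorm(1, 0, 0.3)))
      recs[[i]] <- raw_recording(
        patient_id = patient_id, axes = axes,
        sampling_rate = center$rate, diagnosis = diagnosis,
        condition = cond, hand = hand, center = center$name,
        loading_peak_shift = shift)
      rl <- rle(sim$state_path)
      gt[[recording_key(patient_id, cond, hand)]] <- list(
        diagnosis = diagnosis, affected_side = pat$affected,
        base_frequency = pat$base_freq, n_states = ph$n_states,
        amplitude = amp, condition = cond,
        state_runs = list(values = rl$values, lengths = rl$lengths))
    }
  }
  list(recordings = recs, ground_truth = gt)
}

#' Simulate a phenotype-conditioned tremor cohort
#'
#' Generates `n_et` ET-like and `n_pd` PD-like patients (both hands, rest
#' and posture each), cycling through the configured center profiles, with
#' all randomness derived deterministically from the master seed and the
#' patient index. Optionally writes the cohort to disk in the package's
#' CSV + JSON dialect together with `ground_truth.json`.
#'
#' @param config A [default_cohort_config()].
#' @param out_dir Optional output directory; when given, series CSVs,
#'   `manifest.json` and `ground_truth.json` are written there.
#' @return A [cohort_manifest()] with the ground truth attached as
#'   attribute `"ground_truth"`.
#' @export
simulate_cohort <- function(config = default_cohort_config(),
                            out_dir = NULL) {
  recs <- list(); gt <- list()
  specs <- rbind(
    if (config$n_et > 0) data.frame(dx = "ET", idx = seq_len(config$n_et)),
    if (config$n_pd > 0) data.frame(dx = "PD", idx = seq_len(config$n_pd)))
  for (r in seq_len(nrow(specs))) {
    dx <- specs$dx[r]
    pid <- sprintf("%s%03d", tolower(dx), specs$idx[r])
    center <- config$centers[((r - 1) %% nrow(config$centers)) + 1, ]
    p <- simulate_patient(dx, config, pid,
                          seed = derive_seed(config$seed, r), center = center)
    recs <- c(recs, p$recordings)
    gt <- c(gt, p$ground_truth)
  }
  manifest <- cohort_manifest(recs)
  attr(manifest, "ground_truth") <- gt
  if (!is.null(out_dir)) {
    write_recordings(manifest, out_dir)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest
}

#' Archetype generator parameters for one phenotype
#'
#' Returns the calibrated oscillator and state-switching parameters that
#' [simulate_patient()] uses for one diagnosis and condition, with the
#' patient-level base frequency fixed or drawn from the phenotype's range.
#'
#' @param diagnosis `"ET"` or `"PD"`.
#' @param condition `"rest"` (default) or `"posture"` (amplitude scaling
#'   only; the postural physiological component is a cohort-level setting).
#' @param base_frequency Fundamental in Hz; `NULL` draws from the
#'   phenotype range using the current RNG state.
#' @return List with `oscillator` ([oscillator_params()]), `switching`
#'   ([state_switching_params()]) and `noise_sd`.
#' @export
archetype_params <- function(diagnosis, condition = "rest",
                             base_frequency = NULL) {
  ph <- phenotype_defaults(match.arg(diagnosis, c("ET", "PD")))
  bf <- base_frequency %||% runif(1, ph$freq_range[1], ph$freq_range[2])
  osc <- oscillator_params(
    base_frequency = bf, frequency_jitter_sd = ph$jitter_sd,
    amplitude = ph$cond_amp[[condition]],
    harmonic_ratio = ph$harmonic_ratio,
    harmonic_phase = ph$harmonic_phase,
    am_depth = ph$am_depth, am_rate = ph$am_rate,
    amplitude_jitter_sd = ph$amplitude_jitter_sd,
    noise_jitter_sd = ph$noise_jitter_sd,
    noise_amp_coupling = ph$noise_amp_coupling)
  sw <- if (ph$n_states == 1L) state_switching_params() else
    state_switching_params(ph$n_states, ph$amp_multipliers,
                           ph$freq_offsets, ph$mean_dwell_s,
                           dwell_shape = ph$dwell_shape)
  list(oscillator = osc, switching = sw, noise_sd = 0.12)
}

#' @rdname simulate_patient
#' @export
simulate_et_patient <- function(config, patient_id = "et001", seed = 0,
                                center = config$centers[1, ])
  simulate_patient("ET", config, patient_id, seed, center)

#' @rdname simulate_patient
#' @export
simulate_pd_patient <- function(config, patient_id = "pd001", seed = 0,
                                center = config$centers[1, ])
  simulate_patient("PD", config, patient_id, seed, center)
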