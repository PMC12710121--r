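#' Vector amplitude sum of a triaxial signal
#'
#' Per-sample Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the three
#' accelerometer axes, the scalar series used for all downstream analysis of
#' triaxial recordings. Monoaxial recordings bypass this step.
#'
#' @param x,y,z Equal-length numeric vectors, one per axis.
#' @return Numeric vector of the same length.
#' @export
vector_amplitude <- function(x, y, z) {
  if (length(y) != length(x) || length(z) != length(x))
    stop("axis lengths differ", call. = FALSE)
  sqrt(x^2 + y^2 + z^2)
}

recording_scalar_series <- function(rec) {
  if (length(rec$axes) == 3L)
    vector_amplitude(rec$axes[[1]], rec$axes[[2]], rec$axes[[3]])
  else rec$axes[[1]]
}

#' Resample a series to a lower rate with anti-alias filtering
#'
#' Zero-phase Butterworth low-pass at 80% of the output Nyquist frequency,
#' followed by interpolation onto the output time grid. Unit gain at DC and
#' across the tremor band, so amplitudes are comparable across input rates.
#' Upsampling is rejected by default: the pipeline only ever moves
#' recordings down to the canonical 100 Hz analysis rate.
#'
#' @param x Numeric series.
#' @param f_in,f_out Input and output sampling rates (Hz), `f_in >= f_out`.
#' @param allow_upsample Permit `f_out > f_in` (off by default).
#' @return Numeric series at `f_out` Hz, duration preserved within one
#'   sample period.
#' @export
resample_series <- function(x, f_in, f_out, allow_upsample = FALSE) {
  if (f_out <= 0 || f_in <= 0) stop("rates must be positive", call. = FALSE)
  if (f_out > f_in && !allow_upsample)
    stop(sprintf("upsampling requested (%g -> %g Hz); not supported", f_in, f_out),
         call. = FALSE)
  if (f_out == f_in) return(x)
  mu <- mean(x)
  bf <- signal::butter(6, 0.8 * f_out / f_in, type = "low")
  y <- as.numeric(signal::filtfilt(bf, x - mu)) + mu
  n_out <- floor(length(x) * f_out / f_in)
  t_in <- (seq_along(x) - 1) / f_in
  t_out <- (seq_len(n_out) - 1) / f_out
  approx(t_in, y, xout = t_out, rule = 2)$y
}

#' Band-pass filter a series (zero-phase Butterworth)
#'
#' 4th-order Butterworth applied forward-backward ([signal::filtfilt()]),
#' i.e. zero-phase, so the temporal state structure the HMM feature relies on
#' is not distorted.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param band Length-2 pass band in Hz, default `c(2, 30)`.
#' @param order Filter order (per pass), default 4.
#' @return Filtered series, same length.
#' @export
bandpass_filter <- function(x, fs, band = c(2, 30), order = 4) {
  if (band[2] >= fs / 2)
    stop("upper band edge must be below Nyquist", call. = FALSE)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Standardise a scalar series to the canonical analysis form
#'
#' Applies, in order: resampling to `target_rate`, extraction of a
#' `duration`-second segment (the first full segment after discarding a
#' 1 s filter/settling transient when the recording is long enough),
#' band-pass filtering, and z-normalisation (mean 0, sd 1). The applied
#' steps and the segment offset are recorded in the result's provenance.
#'
#' @param x Numeric series.
#' @param sampling_rate Input rate in Hz.
#' @param duration Segment length in seconds (default 15).
#' @param target_rate Analysis rate in Hz (default 100).
#' @param band Band-pass edges in Hz (default `c(2, 30)`).
#' @param normalize Z-normalise after filtering (default `TRUE`); when
#'   `FALSE` the series keeps its physical amplitude scale, as required for
#'   amplitude-dependent features and for side-asymmetry AUC computation.
#' @param allow_short Accept series shorter than `duration` + transient,
#'   using whatever is available (for the segment-length ablation study).
#' @param transient_s Settling transient to discard from the start when the
#'   recording allows (default 1 s).
#' @return A `preprocessed_series` object: list with `samples`,
#'   `sampling_rate`, `duration`, `normalized`, `provenance`.
#' @export
standardize_series <- function(x, sampling_rate, duration = 15,
                               target_rate = 100, band = c(2, 30),
                               normalize = TRUE, allow_short = FALSE,
                               transient_s = 1) {
  prov <- list(resampled_from = sampling_rate, band = band,
               amplitude_sum = NA)
  # remove the static (gravity) component before any filtering: filter edge
  # transients on a large DC offset would otherwise dominate the segment
  y <- resample_series(x - mean(x), sampling_rate, target_rate)
  need <- round(duration * target_rate)
  off <- round(transient_s * target_rate)
  if (length(y) < need) {
    if (!allow_short)
      stop(sprintf("series too short: %.2f s available, %.2f s required",
                   length(y) / target_rate, duration), call. = FALSE)
    off <- 0L
    need <- length(y)
  } else if (length(y) < need + off) {
    off <- length(y) - need  # partial transient only
  }
  seg <- y[(off + 1):(off + need)]
  prov$segment_offset_s <- off / target_rate
  seg <- bandpass_filter(seg, target_rate, band)
  if (normalize) {
    s <- sd(seg)
    if (s == 0) stop("zero-variance segment cannot be normalized", call. = FALSE)
    seg <- (seg - mean(seg)) / s
  }
  structure(list(
    samples = seg, sampling_rate = target_rate,
    duration = length(seg) / target_rate,
    normalized = normalize, provenance = prov
  ), class = "preprocessed_series")
}

#' @export
print.preprocessed_series <- function(x, ...) {
  cat(sprintf("<preprocessed_series> %d samples @ %g Hz (%.2f s), %s, band %g-%g Hz\n",
              length(x$samples), x$sampling_rate, x$duration,
              if (x$normalized) "z-normalized" else "raw amplitude",
              x$provenance$band[1], x$provenance$band[2]))
  invisible(x)
}

#' Preprocess a raw recording
#'
#' Reduces triaxial recordings to the vector amplitude sum, then runs
#' [standardize_series()]. Metadata is carried through untouched.
#'
#' @param rec A [raw_recording()].
#' @inheritParams standardize_series
#' @return A `preprocessed_series` with metadata attached as attribute
#'   `"meta"`.
#' @export
preprocess_recording <- function(rec, duration = 15, target_rate = 100,
                                 band = c(2, 30), normalize = TRUE,
                                 allow_short = FALSE) {
  x <- recording_scalar_series(rec)
  ps <- standardize_series(x, rec$sampling_rate, duration = duration,
                           target_rate = target_rate, band = band,
                           normalize = normalize, allow_short = allow_short)
  ps$provenance$amplitude_sum <- length(rec$axes) == 3L
  attr(ps, "meta") <- rec[c("patient_id", "center", "diagnosis",
                            "condition", "hand")]
  ps
}

#' Relative side difference in spectral power
#'
#' `(auc_right - auc_left) / (auc_right + auc_left)`, a dimensionless
#' asymmetry index in `[-1, 1]`; positive values mean the right side carries
#' more tremor power. Antisymmetric under side swap.
#'
#' @param auc_right,auc_left Non-negative band power of each side (not both
#'   zero).
#' @return Value in `[-1, 1]`.
#' @export
relative_auc_side_difference <- function(auc_right, auc_left) {
  if (auc_right < 0 || auc_left < 0)
    stop("AUC values must be non-negative", call. = FALSE)
  if (auc_right + auc_left == 0)
    stop("both sides have zero power; asymmetry undefined", call. = FALSE)
  (auc_right - auc_left) / (auc_right + auc_left)
}

#' Select the clinically more affected hand of one patient
#'
#' For each condition recorded bilaterally, computes the absolute relative
#' AUC side difference (on non-normalised amplitude-sum series, so genuine
#' amplitude asymmetry is preserved); the condition with the larger absolute
#' asymmetry decides, and the hand on the larger-power side is returned.
#' Exact ties across conditions are broken toward rest.
#'
#' @param recordings List of [raw_recording()]s of a single patient (both
#'   hands, rest and/or posture).
#' @param band Spectral band for AUC (default `c(2, 30)` Hz).
#' @param duration,target_rate Segment parameters passed to preprocessing.
#' @return List with `hand`, `condition` (the condition that drove the
#'   choice), `auc_rel` (per-condition asymmetry values), and `bilateral`
#'   (FALSE when only one hand was available and the fallback was used).
#' @export
select_more_affected_hand <- function(recordings, band = c(2, 30),
                                      duration = 15, target_rate = 100) {
  pid <- unique(vapply(recordings, `[[`, character(1), "patient_id"))
  if (length(pid) != 1L)
    stop("recordings from multiple patients passed to hand selection",
         call. = FALSE)
  conds <- vapply(recordings, `[[`, character(1), "condition")
  hands <- vapply(recordings, `[[`, character(1), "hand")
  auc_of <- function(rec) {
    ps <- preprocess_recording(rec, duration = duration,
                               target_rate = target_rate, band = band,
                               normalize = FALSE, allow_short = TRUE)
    band_power_auc(welch_psd(ps, window_s = min(5, ps$duration)), band)
  }
  rel <- c(rest = NA_real_, posture = NA_real_)
  for (cond in c("rest", "posture")) {
    ir <- which(conds == cond & hands == "right")
    il <- which(conds == cond & hands == "left")
    if (length(ir) == 1L && length(il) == 1L)
      rel[cond] <- relative_auc_side_difference(auc_of(recordings[[ir]]),
                                                auc_of(recordings[[il]]))
  }
  if (all(is.na(rel))) {
    h <- unique(hands)
    if (length(h) != 1L)
      stop("no condition recorded bilaterally and hands inconsistent",
           call. = FALSE)
    warning(sprintf("patient %s: no bilateral condition; falling back to single recorded hand (%s)",
                    pid, h), call. = FALSE)
    return(list(hand = h, condition = conds[1], auc_rel = rel,
                bilateral = FALSE))
  }
  ok <- which(!is.na(rel))
  # strict ">" keeps rest on exact ties because rest is evaluated first
  best <- ok[which.max(abs(rel[ok]))]
  cond <- names(rel)[best]
  hand <- if (rel[best] >= 0) "right" else "left"
  list(hand = hand, condition = cond, auc_rel = rel, bilateral = TRUE)
}

#' Loading-test screen for enhanced physiological tremor
#'
#' Recordings whose tremor peak frequency shifts by more than 1 Hz under
#' 500 g / 1000 g mass loading are excluded as enhanced physiological
#' tremor. The comparison is strict (`> 1` Hz drops; exactly 1 Hz keeps).
#'
#' @param rec A [raw_recording()].
#' @param threshold Shift threshold in Hz (default 1).
#' @return `TRUE` to keep the recording, `FALSE` to drop it. Recordings
#'   without a measured shift pass through with a warning.
#' @export
loading_test_filter <- function(rec, threshold = 1) {
  shift <- rec$loading_peak_shift
  if (is.null(shift) || is.na(shift)) {
    warning(sprintf("recording %s: no loading test available; kept",
                    recording_key(rec$patient_id, rec$condition, rec$hand)),
            call. = FALSE)
    return(TRUE)
  }
  shift <= threshold
}

#' Automated artifact screen
#'
#' Flags clipped or flat-lined recordings: five or more consecutive
#' identical samples, or any sample beyond 8 standard deviations after
#' z-scoring. A screening stand-in for manual visual review.
#'
#' @param x Numeric series (raw scalar series, pre-normalisation).
#' @param max_run Run length of identical samples that flags (default 5).
#' @param z_limit Absolute z-score that flags (default 8).
#' @return List with `ok` (logical) and `reasons` (character vector).
#' @export
detect_artifacts <- function(x, max_run = 5, z_limit = 8) {
  reasons <- character(0)
  r <- rle(x)
  if (any(r$lengths >= max_run)) reasons <- c(reasons, "flat_line")
  s <- sd(x)
  if (s > 0 && max(abs((x - mean(x)) / s)) > z_limit)
    reasons <- c(reasons, "clipping_outlier")
  if (s == 0) reasons <- c(reasons, "constant_signal")
  list(ok = length(reasons) == 0L, reasons = reasons)
}
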