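# Shared fixtures, generated in code.

# pure (or lightly jittered) tone sampled at `fs`
make_tone <- function(freq = 5, fs = 100, duration = 20, amplitude = 1,
                      phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amplitude * sin(2 * pi * freq * t + phase)
}

# one preprocessed archetype rest series (series-level path, no projection)
archetype_series <- function(diagnosis, seed, rate = 500, duration = 20) {
  pars <- with_seed_local(seed, archetype_params(diagnosis))
  sim <- simulate_series(pars$oscillator, pars$switching, duration, rate,
                         seed = seed + 1, noise_sd = pars$noise_sd)
  standardize_series(sim$samples, rate)
}

# evaluate `expr` under a local RNG seed, restoring the caller's stream
with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# the rest recording of the clinically affected hand of one simulated patient
affected_rest_recording <- function(patient) {
  aff <- patient$ground_truth[[1]]$affected_side
  hit <- vapply(patient$recordings,
                function(r) r$condition == "rest" && r$hand == aff,
                logical(1))
  patient$recordings[[which(hit)]]
}

# tiny deterministic feature matrix for classifier tests
toy_feature_matrix <- function(n_per_class = 20, n_noise = 0, seed = 1,
                               sep = 3) {
  with_seed_local(seed, {
    n <- 2 * n_per_class
    labels <- rep(c("ET", "PD"), each = n_per_class)
    signal <- rnorm(n) + ifelse(labels == "PD", sep, 0)
    vals <- cbind(signal = signal)
    if (n_noise > 0) {
      noise <- matrix(rnorm(n * n_noise), n,
                      dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
      vals <- cbind(vals, noise)
    }
    meta <- data.frame(key = sprintf("p%02d/rest/right", 1:n),
                       patient_id = sprintf("p%02d", 1:n),
                       diagnosis = labels, condition = "rest",
                       hand = "right")
    list(fm = feature_matrix(vals, meta), labels = factor(labels))
  })
}
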