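#' Generate a harmonic sync tune
#'
#' Builds the short reference audio played at experiment start: a sequence
#' of pure-sine notes at the given frequencies, equal-amplitude, dividing
#' `duration` equally, with 5 ms raised-cosine on/off ramps to avoid clicks,
#' peak-normalized to 0.9. Playing the frequencies in sequence (rather than
#' summing them) keeps the tune's autocorrelation sidelobes low, which makes
#' the offset-search objective single-peaked; the default frequencies are
#' non-commensurate for the same reason.
#'
#' @param duration Tune length in seconds (default 2, a typical sync-tune
#'   length).
#' @param freqs Note frequencies in Hz, all below `rate / 2`.
#' @param rate Sample rate in Hz.
#' @param seed Optional seed; when given, note phases are randomized
#'   (reproducibly). With `seed = NULL` phases are 0 and the tune is fully
#'   deterministic.
#' @return A mono [audio_track()].
#' @export
make_sync_tune <- function(duration = 2,
                           freqs = c(440, 554.37, 659.25, 783.99),
                           rate = 8000, seed = NULL) {
  if (any(freqs >= rate / 2)) {
    stop_precondition(sprintf(
      "frequencies must be below the Nyquist rate %g Hz", rate / 2
    ))
  }
  if (duration <= 0) stop_precondition("`duration` must be positive")
  n <- round(duration * rate)
  phases <- if (is.null(seed)) {
    rep(0, length(freqs))
  } else {
    withr::with_seed(seed, stats::runif(length(freqs), 0, 2 * pi))
  }
  note_len <- floor(n / length(freqs))
  out <- numeric(n)
  ramp_n <- min(round(0.005 * rate), floor(note_len / 2))
  env <- rep(1, note_len)
  if (ramp_n > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    env[seq_len(ramp_n)] <- up
    env[(note_len - ramp_n + 1):note_len] <- rev(up)
  }
  for (k in seq_along(freqs)) {
    idx <- ((k - 1) * note_len + 1):(k * note_len)
    tt <- (idx - 1) / rate
    out[idx] <- sin(2 * pi * freqs[k] * tt + phases[k]) * env
  }
  out <- out * (0.9 / max(abs(out)))
  audio_track(out, rate)
}

#' Embed a tune in a noisy track at a known offset
#'
#' Creates a ground-truthed alignment fixture: Gaussian white noise of
#' `total_duration` seconds with the tune added starting at `true_offset`
#' (snapped to the sample grid; the snapped value is what is stored as
#' truth). The noise is scaled so that the signal-to-noise ratio over the
#' tune segment equals `snr_db`. Regeneration with the same seed is
#' bit-identical.
#'
#' @param tune An [audio_track()] (mono), e.g. from [make_sync_tune()].
#' @param total_duration Length of the noisy track in seconds.
#' @param true_offset Where the tune starts, in seconds.
#' @param snr_db Signal-to-noise ratio in dB over the tune segment.
#' @param seed Integer seed for the noise.
#' @return A list of class `sync_fixture`: `target` (the tune), `sample`
#'   (the noisy track), `true_offset` (s, grid-snapped), `snr_db`, `seed`.
#' @export
embed_tune <- function(tune, total_duration, true_offset, snr_db = 10, seed = 1L) {
  assert_track(tune)
  tune <- to_mono(tune)
  rate <- tune$rate
  if (true_offset < 0) stop_precondition("`true_offset` must be non-negative")
  if (true_offset + duration(tune) > total_duration) {
    stop_precondition("`true_offset` + tune duration exceeds `total_duration`")
  }
  n <- round(total_duration * rate)
  k0 <- round(true_offset * rate)
  tv <- mono_samples(tune)

  sig_power <- mean(tv^2)
  noise_power <- sig_power / 10^(snr_db / 10)
  noise <- withr::with_seed(seed, stats::rnorm(n, sd = sqrt(noise_power)))
  noise[(k0 + 1):(k0 + length(tv))] <- noise[(k0 + 1):(k0 + length(tv))] + tv

  structure(
    list(
      target = tune,
      sample = audio_track(noise, rate),
      true_offset = k0 / rate,
      snr_db = snr_db,
      seed = seed
    ),
    class = "sync_fixture"
  )
}

#' @export
print.sync_fixture <- function(x, ...) {
  cat(sprintf(
    "<sync_fixture> %.2f s tune in %.2f s track, true offset %.4f s, SNR %g dB (seed %d)\n",
    duration(x$target), duration(x$sample), x$true_offset, x$snr_db, x$seed
  ))
  invisible(x)
}

#' Generate a group of expression series with a controlled synchrony level
#'
#' Emulates a group of subjects whose expression evidence shares a latent
#' stimulus-driven signal. Each subject's series is
#' `sqrt(true_isc) * shared + sqrt(1 - true_isc) * private_i`, where the
#' shared and private components are independent unit-variance Gaussian
#' AR(1) processes (coefficient `ar`, default 0.5 — evidence traces are
#' autocorrelated, not white). Under this construction the expected
#' pairwise correlation between any two subjects is exactly `true_isc`.
#'
#' @param n_subjects Number of subjects (>= 2; default 5, a typical small
#'   viewing group).
#' @param length Samples per subject.
#' @param rate Sample rate in Hz (default 1, i.e. already downsampled).
#' @param true_isc Target pairwise correlation in `[0, 1)`.
#' @param seed Integer seed.
#' @param ar AR(1) coefficient of both components.
#' @param channel Channel label for the generated series.
#' @return A list of class `isc_fixture`: `series` (long tibble),
#'   `true_isc`, `seed`.
#' @export
make_isc_group <- function(n_subjects = 5, length = 10000, rate = 1,
                           true_isc = 0.4, seed = 1L, ar = 0.5,
                           channel = "joy") {
  if (true_isc < 0 || true_isc >= 1) stop_precondition("`true_isc` must be in [0, 1)")
  if (n_subjects < 2) stop_precondition("need at least 2 subjects")
  sims <- withr::with_seed(seed, {
    shared <- ar1_series(length, ar)
    priv <- replicate(n_subjects, ar1_series(length, ar))
    list(shared = shared, priv = priv)
  })
  ids <- sprintf("s%02d", seq_len(n_subjects))
  series <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    v <- sqrt(true_isc) * sims$shared + sqrt(1 - true_isc) * sims$priv[, i]
    expression_series(ids[i], channel, v, rate)
  })
  structure(
    list(series = series, true_isc = true_isc, seed = seed,
         n_subjects = n_subjects, ar = ar, rate = rate),
    class = "isc_fixture"
  )
}

# Stationary unit-variance Gaussian AR(1).
ar1_series <- function(n, ar) {
  innov_sd <- sqrt(1 - ar^2)
  x <- stats::rnorm(n, sd = innov_sd)
  as.numeric(stats::filter(x, ar, method = "recursive",
                           init = stats::rnorm(1)))
}

#' Simulate an event table for an event-locked design
#'
#' Trials of `duration` seconds, conditions interleaved in random order,
#' separated by inter-trial intervals drawn from `itis` — the standard
#' jittered picture-viewing design (10 trials per condition, 2 s stimuli,
#' ITIs of 4/6/8 s by default).
#'
#' @param n_per_condition Trials per condition.
#' @param conditions Condition labels.
#' @param duration Trial duration (s).
#' @param itis Candidate inter-trial intervals (s), sampled uniformly.
#' @param start First onset (s).
#' @param seed Integer seed.
#' @return A tibble with columns `onset`, `duration`, `condition`.
#' @export
sim_event_table <- function(n_per_condition = 10,
                            conditions = c("positive", "negative"),
                            duration = 2, itis = c(4, 6, 8),
                            start = 2, seed = 1L) {
  n <- n_per_condition * length(conditions)
  withr::with_seed(seed, {
    cond <- sample(rep(conditions, n_per_condition))
    gaps <- sample(itis, n - 1, replace = TRUE)
    onsets <- start + c(0, cumsum(duration + gaps))
    tibble(onset = onsets, duration = duration, condition = cond)
  })
}

#' Generate an evidence series responding to events
#'
#' Baseline-0 series with a boxcar of height `effect_by_condition[condition]`
#' during each event, plus Gaussian noise — a ground-truthed stand-in for a
#' classifier's evidence output in an event-locked experiment.
#'
#' @param events Event tibble (`onset`, `duration`, `condition`).
#' @param effect_by_condition Named numeric vector, one entry per condition.
#' @param noise_sd Gaussian noise SD (evidence units).
#' @param rate Sample rate in Hz (default 30, a typical camera frame rate).
#' @param seed Integer seed.
#' @param subject_id,channel Labels for the generated series.
#' @param tail Extra quiet seconds appended after the last event.
#' @return A long tibble as from [expression_series()].
#' @export
make_event_responses <- function(events, effect_by_condition, noise_sd = 1.5,
                                 rate = 30, seed = 1L, subject_id = "s01",
                                 channel = "joy", tail = 2) {
  missing_cond <- setdiff(unique(events$condition), names(effect_by_condition))
  if (length(missing_cond) > 0) {
    stop_precondition(sprintf(
      "no effect size given for condition(s): %s", paste(missing_cond, collapse = ", ")
    ))
  }
  total <- max(events$onset + events$duration) + tail
  n <- round(total * rate)
  t <- (seq_len(n) - 1) / rate
  v <- numeric(n)
  for (i in seq_len(nrow(events))) {
    inside <- t >= events$onset[i] & t < events$onset[i] + events$duration[i]
    v[inside] <- v[inside] + effect_by_condition[[events$condition[i]]]
  }
  if (noise_sd > 0) {
    v <- v + withr::with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  expression_series(subject_id, channel, v, rate)
}
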