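#' Offset detection between a reference segment and a longer recording
#'
#' The central operation of the package: given a short reference audio
#' segment (the "sync tune" played at experiment start, or the stimulus
#' audio) and a longer recording that contains it, find the offset — the
#' number of seconds that must be trimmed from the start of the recording so
#' that it aligns with the reference.
#'
#' `find_offset_sliding_corr()` slides the reference along the recording on
#' a grid of candidate lags and scores each lag by the Pearson correlation
#' between the reference and the equal-length slice starting there; the
#' returned offset is the lag with the highest correlation (earliest lag on
#' ties). `find_offset_xcorr()` computes the normalized cross-correlation at
#' every sample lag via the FFT: both signals are zero-meaned, the
#' cross-products at all lags are obtained in one transform, and each lag is
#' normalized by the energies of the reference and of the recording slice so
#' that a perfect match scores 1.
#'
#' Both detectors require mono tracks at a common rate; stereo inputs are
#' down-mixed and a rate mismatch is resolved by resampling the lower-rate
#' track up to the higher rate (with a message). Zero-variance slices score
#' 0 (with a warning) rather than NaN so the argmax stays total.
#'
#' @param target The reference [audio_track()] (shorter).
#' @param sample The recording to search (longer).
#' @param search_start,search_end Search window in seconds (lag of the
#'   candidate slice start). Defaults to the full feasible range.
#' @param step Grid spacing in seconds; default 1 ms, the precision used by
#'   human raters doing the same task. Lags are snapped to whole samples.
#' @return An object of class `offset_result` with fields
#'   `offset_seconds`, `score`, `method`, and `trace` (a tibble of
#'   `lag_seconds`, `score` over the search grid).
#' @examples
#' tune <- make_sync_tune(duration = 0.5, rate = 4000)
#' fx <- embed_tune(tune, total_duration = 5, true_offset = 1.25, snr_db = 20, seed = 1)
#' find_offset_sliding_corr(fx$target, fx$sample)$offset_seconds
#' @export
find_offset_sliding_corr <- function(target, sample,
                                     search_start = 0, search_end = NULL,
                                     step = 0.001) {
  tr <- prepare_pair(target, sample)
  t <- tr$target; s <- tr$sample; rate <- tr$rate
  nt <- length(t); ns <- length(s)
  max_lag <- (ns - nt) / rate
  search_end <- search_end %||% max_lag
  if (search_end < search_start) stop_precondition("empty search window")
  if (step <= 0) stop_precondition("`step` must be positive")
  search_start <- max(0, search_start)
  search_end <- min(max_lag, search_end)

  lags_s <- seq(search_start, search_end, by = step)
  lag_idx <- pmin(pmax(round(lags_s * rate), 0L), ns - nt)

  scores_all <- sliding_pearson(t, s)
  scores <- scores_all[lag_idx + 1L]

  best <- which.max(scores) # first max = earliest lag
  new_offset_result(
    offset_seconds = lag_idx[best] / rate,
    score = scores[best],
    trace = tibble(lag_seconds = lags_s, score = scores),
    method = "sliding_corr",
    rate = rate, step = step,
    target_duration = nt / rate, sample_duration = ns / rate
  )
}

#' @rdname find_offset_sliding_corr
#' @export
find_offset_xcorr <- function(target, sample) {
  tr <- prepare_pair(target, sample)
  t0 <- tr$target - mean(tr$target)
  s0 <- tr$sample - mean(tr$sample)
  rate <- tr$rate
  nt <- length(t0); ns <- length(s0)

  dots <- xcorr_dot(t0, s0)
  win_energy <- windowed_sum(s0^2, nt)
  denom <- sqrt(sum(t0^2) * win_energy)
  scores <- ifelse(denom > 1e-12, dots / pmax(denom, 1e-300), 0)
  if (any(denom <= 1e-12)) {
    warn("zero-variance window(s) encountered; scored as 0")
  }
  scores <- pmin(pmax(scores, -1), 1)

  best <- which.max(scores)
  lags_s <- (seq_along(scores) - 1L) / rate
  new_offset_result(
    offset_seconds = lags_s[best],
    score = scores[best],
    trace = tibble(lag_seconds = lags_s, score = scores),
    method = "fft_xcorr",
    rate = rate, step = 1 / rate,
    target_duration = nt / rate, sample_duration = ns / rate
  )
}

#' Refine a coarse offset estimate on a finer grid
#'
#' Re-runs the sliding-correlation search in a window of plus or minus two
#' coarse steps around the coarse optimum, at spacing `fine_step`. Because
#' the refined grid contains the coarse optimum, the refined score is never
#' below the coarse score. Lags are snapped to whole samples, so `fine_step`
#' below one sample period cannot add precision beyond 1/rate.
#'
#' @param coarse An `offset_result` from either detector.
#' @param target,sample The tracks the coarse search used.
#' @param fine_step Fine grid spacing in seconds.
#' @return An `offset_result` (method tagged `"refined"`).
#' @export
refine_offset <- function(coarse, target, sample, fine_step) {
  if (!inherits(coarse, "offset_result")) {
    stop_precondition("`coarse` must be an offset_result")
  }
  half <- 2 * coarse$step
  res <- find_offset_sliding_corr(
    target, sample,
    search_start = max(0, coarse$offset_seconds - half),
    search_end = coarse$offset_seconds + half,
    step = fine_step
  )
  res$method <- paste0(coarse$method, "+refined")
  if (res$score < coarse$score) {
    # grid snapping can only drop the coarse point at sub-sample fine steps;
    # keep the better of the two and keep the trace consistent with it
    res$offset_seconds <- coarse$offset_seconds
    res$score <- coarse$score
    res$trace <- arrange(
      bind_rows(res$trace,
                tibble(lag_seconds = coarse$offset_seconds, score = coarse$score)),
      .data$lag_seconds
    )
  }
  res
}

#' Overlay two tracks at a candidate offset for listening
#'
#' Mixes track `a` with track `b` advanced by `offset` seconds, averaging
#' the two. At the true offset the mixed audio contains no echo; an offset
#' error of d seconds leaves a residual echo at lag d that shows up as a
#' secondary autocorrelation peak. This is the non-interactive counterpart
#' of manually nudging one waveform against the other while listening.
#'
#' @param a Reference [audio_track()].
#' @param b Track to shift; `offset` seconds are dropped from its start.
#' @param offset Seconds, within `b`'s duration.
#' @return A mono `audio_track` covering the overlap.
#' @export
shift_preview <- function(a, b, offset) {
  assert_track(a); assert_track(b)
  if (a$rate != b$rate) stop_precondition("`a` and `b` must share a sample rate")
  if (offset < 0 || offset >= duration(b)) {
    stop_precondition("`offset` must lie within `b`'s duration")
  }
  av <- mono_samples(a)
  bv <- mono_samples(b)
  bv <- bv[(round(offset * b$rate) + 1L):length(bv)]
  n <- min(length(av), length(bv))
  audio_track((av[seq_len(n)] + bv[seq_len(n)]) / 2, a$rate)
}

#' Export an offset search trace as CSV
#'
#' @param result An `offset_result`.
#' @param path Output CSV path (columns `lag_s`, `score`).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  stopifnot(inherits(result, "offset_result"))
  df <- result$trace
  names(df) <- c("lag_s", "score")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# internals ---------------------------------------------------------------

# Down-mix, match rates (resample the coarser up), check lengths.
prepare_pair <- function(target, sample) {
  assert_track(target); assert_track(sample)
  target <- to_mono(target); sample <- to_mono(sample)
  if (target$rate != sample$rate) {
    hi <- max(target$rate, sample$rate)
    inform(sprintf("resampling the %g Hz track up to %g Hz to match",
                   min(target$rate, sample$rate), hi))
    if (target$rate < hi) target <- resample_track(target, hi)
    if (sample$rate < hi) sample <- resample_track(sample, hi)
  }
  if (n_samples(target) > n_samples(sample)) {
    stop_precondition(paste0(
      "the reference is longer than the recording being searched; ",
      "if the recording starts after the reference, swap the roles ",
      "(negative offsets are outside this offset convention)"
    ))
  }
  list(target = mono_samples(target), sample = mono_samples(sample),
       rate = target$rate)
}

# Raw cross-products sum_i t[i] * s[i+k] for k = 0 .. ns-nt, via FFT.
xcorr_dot <- function(t, s) {
  nt <- length(t); ns <- length(s)
  L <- nextn(ns + nt, 2)
  ft <- fft(c(t, numeric(L - nt)))
  fs <- fft(c(s, numeric(L - ns)))
  cc <- Re(fft(fs * Conj(ft), inverse = TRUE)) / L
  cc[seq_len(ns - nt + 1L)]
}

# Rolling sums of x over windows of length w (all start positions).
windowed_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]
}

# Pearson correlation of t against every length(t)-slice of s, all lags.
sliding_pearson <- function(t, s) {
  nt <- length(t)
  sum_t <- sum(t)
  sst_t <- sum(t^2) - sum_t^2 / nt
  win_sum <- windowed_sum(s, nt)
  win_ss <- windowed_sum(s^2, nt) - win_sum^2 / nt
  win_ss <- pmax(win_ss, 0) # guard cancellation
  if (sst_t <= 1e-12) {
    warn("zero-variance reference; all correlation scores set to 0")
    return(numeric(length(win_sum)))
  }
  dots <- xcorr_dot(t, s)
  num <- dots - win_sum * (sum_t / nt)
  denom <- sqrt(sst_t * win_ss)
  bad <- denom <= 1e-10
  if (any(bad)) warn("zero-variance window(s) encountered; scored as 0")
  r <- numeric(length(num))
  r[!bad] <- num[!bad] / denom[!bad]
  pmin(pmax(r, -1), 1)
}

# offset_result -----------------------------------------------------------

new_offset_result <- function(offset_seconds, score, trace, method, rate,
                              step, target_duration, sample_duration) {
  structure(
    list(
      offset_seconds = offset_seconds, score = score, trace = trace,
      method = method, rate = rate, step = step,
      target_duration = target_duration, sample_duration = sample_duration
    ),
    class = "offset_result"
  )
}

#' @export
print.offset_result <- function(x, ...) {
  cat(sprintf("<offset_result> method=%s\n", x$method))
  cat(sprintf("  offset: %.3f s  (score %.4f over %d candidate lags)\n",
              x$offset_seconds, x$score, nrow(x$trace)))
  invisible(x)
}

#' Tidiers for offset results
#'
#' `tidy()` returns the score-versus-lag trace; `glance()` a one-row summary.
#'
#' @param x An `offset_result`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.offset_result <- function(x, ...) x$trace

#' @rdname tidy.offset_result
#' @exportS3Method generics::glance
glance.offset_result <- function(x, ...) {
  tibble(
    offset_seconds = x$offset_seconds, score = x$score, method = x$method,
    step = x$step, rate = x$rate,
    target_duration = x$target_duration, sample_duration = x$sample_duration
  )
}

#' Plot an offset search trace
#'
#' @param object An `offset_result`.
#' @param ... Unused.
#' @return A ggplot: score against candidate lag, optimum marked.
#' @exportS3Method ggplot2::autoplot
autoplot.offset_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$lag_seconds, y = .data$score)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$offset_seconds,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "candidate lag (s)", y = "alignment score",
      title = sprintf("%s: offset %.3f s", object$method, object$offset_seconds)
    ) +
    ggplot2::theme_minimal()
}
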