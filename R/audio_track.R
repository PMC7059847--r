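#' Construct an audio track
#'
#' An `audio_track` is the unit every alignment operation works on: a matrix
#' of amplitude samples (one column per channel, nominal range \[-1, 1\]) plus
#' a sampling rate in Hz. Timestamps are seconds, 0-based, measured from the
#' first sample.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param rate Sampling frequency in Hz (positive).
#' @return An object of class `audio_track`.
#' @examples
#' tone <- audio_track(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), rate = 8000)
#' duration(tone)
#' @export
audio_track <- function(samples, rate) {
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1) stop_precondition("an audio track needs at least one sample")
  if (!ncol(samples) %in% c(1L, 2L)) {
    stop_precondition(sprintf("only mono or stereo supported, got %d channels", ncol(samples)))
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop_precondition("`rate` must be a single positive number (Hz)")
  }
  structure(
    list(samples = samples, rate = as.numeric(rate)),
    class = "audio_track"
  )
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf(
    "<audio_track> %d channel(s), %d samples @ %g Hz (%.3f s)\n",
    n_channels(x), n_samples(x), x$rate, duration(x)
  ))
  invisible(x)
}

#' Track geometry helpers
#'
#' @param track An [audio_track()].
#' @return `n_samples()` and `n_channels()` return integers; `duration()`
#'   returns seconds.
#' @export
n_samples <- function(track) nrow(track$samples)

#' @rdname n_samples
#' @export
n_channels <- function(track) ncol(track$samples)

#' @rdname n_samples
#' @export
duration <- function(track) nrow(track$samples) / track$rate

is_audio_track <- function(x) inherits(x, "audio_track")

assert_track <- function(x, arg = deparse(substitute(x))) {
  if (!is_audio_track(x)) stop_precondition(sprintf("`%s` must be an audio_track", arg))
  invisible(x)
}

# mono samples as a plain vector
mono_samples <- function(track) {
  if (n_channels(track) == 1L) track$samples[, 1L] else rowMeans(track$samples)
}

#' Down-mix a track to mono
#'
#' Stereo channels are averaged per sample; a mono track is returned
#' unchanged. All correlation-based alignment in this package operates on
#' mono signals, so stereo inputs are down-mixed before searching.
#'
#' @param track An [audio_track()].
#' @return A mono `audio_track` at the same rate.
#' @export
to_mono <- function(track) {
  assert_track(track)
  if (n_channels(track) == 1L) return(track)
  audio_track(rowMeans(track$samples), track$rate)
}

#' Resample a track to a new rate
#'
#' Band-limited resampling in the frequency domain: the spectrum is
#' truncated (downsampling) or zero-padded (upsampling) and inverted at the
#' new length `round(n * new_rate / rate)`, so duration is preserved to
#' within one output sample period and — crucially for alignment work — the
#' operation introduces no group delay. The method assumes periodic
#' extension, so a few samples at either end can show wrap-around ringing
#' for signals that do not start and end near zero.
#'
#' @param track An [audio_track()].
#' @param new_rate Target rate in Hz.
#' @return An `audio_track` at `new_rate`.
#' @export
resample_track <- function(track, new_rate) {
  assert_track(track)
  if (!is.numeric(new_rate) || length(new_rate) != 1 || new_rate <= 0) {
    stop_precondition("`new_rate` must be a single positive number (Hz)")
  }
  if (new_rate == track$rate) return(track)
  n_new <- max(1L, round(n_samples(track) * new_rate / track$rate))
  out <- apply(track$samples, 2L, fft_resample, n_new = n_new)
  if (is.null(dim(out))) out <- matrix(out, ncol = n_channels(track))
  audio_track(out, new_rate)
}

# Fourier-domain resampling of one channel to n_new samples.
fft_resample <- function(x, n_new) {
  n <- length(x)
  if (n_new == n) return(x)
  X <- fft(x)
  Y <- complex(n_new)
  keep <- floor(min(n, n_new) / 2)
  Y[1] <- X[1]
  if (keep >= 1) {
    Y[2:(keep + 1)] <- X[2:(keep + 1)]
    Y[(n_new - keep + 1):n_new] <- X[(n - keep + 1):n]
  }
  # shared Nyquist bin when the smaller length is even: split it evenly to
  # keep the inverse transform (numerically) real
  if (min(n, n_new) %% 2 == 0 && n_new > n) {
    Y[keep + 1] <- X[keep + 1] / 2
    Y[n_new - keep + 1] <- X[keep + 1] / 2
  }
  Re(fft(Y, inverse = TRUE)) * (1 / n)
}
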