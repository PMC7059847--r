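#' Locate the external media decoder
#'
#' Audio extraction from video containers and video trimming are delegated
#' to an external decoder binary (ffmpeg by default). The binary is resolved
#' from, in order: the `avsync.decoder` option, the `AVSYNC_DECODER`
#' environment variable, then `ffmpeg` on the PATH. Everything else in the
#' package is pure R, so a missing decoder only disables the video-container
#' operations.
#'
#' @return Path to the decoder binary, or `""` when none is found.
#' @export
decoder_path <- function() {
  opt <- getOption("avsync.decoder", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("AVSYNC_DECODER", "")
  if (nzchar(env)) return(env)
  unname(Sys.which("ffmpeg"))
}

require_decoder <- function() {
  path <- decoder_path()
  if (!nzchar(path) || !file.exists(path)) {
    stop_environment(paste0(
      "no external media decoder found. Install ffmpeg (https://ffmpeg.org) ",
      "and make sure it is on the PATH, or point options(avsync.decoder = ...) ",
      "or the AVSYNC_DECODER environment variable at an equivalent binary."
    ))
  }
  path
}

#' Report the decoder version string
#'
#' @return First line of the decoder's `-version` output.
#' @export
decoder_version <- function() {
  bin <- require_decoder()
  out <- suppressWarnings(system2(bin, "-version", stdout = TRUE, stderr = TRUE))
  if (length(out) == 0) "" else out[[1]]
}

run_decoder <- function(args) {
  bin <- require_decoder()
  out <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  list(status = status, output = out)
}

#' Extract the audio stream of a video file
#'
#' Thin contract over the external decoder: the audio stream is decoded to a
#' temporary 16-bit PCM WAV and read back as an [audio_track()].
#'
#' @param video_path Path to a video container (mp4/mov/...).
#' @param out_rate Target sample rate in Hz, or `"native"` (default) to keep
#'   the stream's own rate.
#' @return An [audio_track()].
#' @export
extract_audio <- function(video_path, out_rate = "native") {
  if (!file.exists(video_path)) stop_not_found(sprintf("no such file: '%s'", video_path))
  tmp <- tempfile(fileext = ".wav")
  on.exit(unlink(tmp))
  args <- c("-y", "-i", shQuote(video_path), "-vn", "-acodec", "pcm_s16le")
  if (!identical(out_rate, "native")) {
    args <- c(args, "-ar", format(as.integer(out_rate)))
  }
  args <- c(args, shQuote(tmp))
  res <- run_decoder(args)
  if (res$status != 0 || !file.exists(tmp)) {
    stop_format(sprintf(
      "decoder failed on '%s' (no audio stream?): %s",
      video_path, paste(tail(res$output, 3), collapse = " | ")
    ))
  }
  read_wav(tmp)
}

#' Trim a media file to start at an offset
#'
#' For WAV input the trim is sample-exact and done in R: the output starts at
#' `offset` seconds of the input, so its duration is the input duration minus
#' `offset`. For video containers the cut is delegated to the external
#' decoder, which seeks to the nearest decodable frame at `offset`.
#'
#' @param path Input media path (`.wav` or a video container).
#' @param offset Seconds to drop from the start; must lie within the media.
#' @param out_path Output path.
#' @return `out_path`, invisibly.
#' @export
trim_media <- function(path, offset, out_path) {
  if (!file.exists(path)) stop_not_found(sprintf("no such file: '%s'", path))
  if (!is.numeric(offset) || length(offset) != 1 || offset < 0) {
    stop_precondition("`offset` must be a single non-negative number of seconds")
  }
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    track <- read_wav(path)
    if (offset >= duration(track)) {
      stop_precondition(sprintf(
        "offset %.3f s is beyond the media duration %.3f s", offset, duration(track)
      ))
    }
    first <- round(offset * track$rate) + 1L
    trimmed <- audio_track(track$samples[first:n_samples(track), , drop = FALSE], track$rate)
    attr(trimmed, "encoding") <- attr(track, "encoding")
    write_wav(trimmed, out_path)
  } else {
    res <- run_decoder(c("-y", "-ss", format(offset), "-i", shQuote(path),
                         "-c", "copy", shQuote(out_path)))
    if (res$status != 0 || !file.exists(out_path)) {
      stop_format(sprintf(
        "decoder failed trimming '%s': %s",
        path, paste(tail(res$output, 3), collapse = " | ")
      ))
    }
  }
  invisible(out_path)
}
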