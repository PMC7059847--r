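#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE files holding 16- or 24-bit integer PCM or 32-bit float
#' samples. Integer samples are scaled to \[-1, 1\] by dividing by
#' 2^(bits-1), so full-scale positive 16-bit (32767) maps to 32767/32768 —
#' slightly below 1 by construction.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_track()]; the source encoding is kept in the
#'   `"encoding"` attribute so a later [write_wav()] can reuse it.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_not_found(sprintf("no such file: '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_format(sprintf("'%s' is not a RIFF/WAVE file", path))
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_format(sprintf("'%s' is not a RIFF/WAVE file", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- parse_fmt_chunk(body)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L)) # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop_format(sprintf("'%s': missing fmt chunk", path))
  if (is.null(data_raw)) stop_format(sprintf("'%s': missing data chunk", path))

  samples <- decode_samples(data_raw, fmt)
  track <- audio_track(samples, fmt$rate)
  attr(track, "encoding") <- fmt$encoding
  track
}

parse_fmt_chunk <- function(body) {
  u16 <- function(off) {
    sum(as.integer(body[off + 1:2]) * c(1, 256))
  }
  u32 <- function(off) {
    sum(as.numeric(body[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  format_tag <- u16(0)
  channels <- u16(2)
  rate <- u32(4)
  bits <- u16(14)
  if (format_tag == 0xFFFE && length(body) >= 26) {
    # WAVE_FORMAT_EXTENSIBLE: first two bytes of the SubFormat GUID
    format_tag <- u16(24)
  }
  encoding <- if (format_tag == 1 && bits == 16) {
    "pcm16"
  } else if (format_tag == 1 && bits == 24) {
    "pcm24"
  } else if (format_tag == 3 && bits == 32) {
    "float32"
  } else {
    stop_format(sprintf(
      "unsupported WAV encoding: format tag %d, %d bits (supported: 16/24-bit PCM, 32-bit float)",
      format_tag, bits
    ))
  }
  list(encoding = encoding, channels = channels, rate = rate, bits = bits)
}

decode_samples <- function(raw, fmt) {
  vals <- switch(fmt$encoding,
    pcm16 = readBin(raw, "integer", length(raw) %/% 2L, size = 2L,
                    signed = TRUE, endian = "little") / 32768,
    pcm24 = decode_pcm24(raw) / 8388608,
    float32 = readBin(raw, "numeric", length(raw) %/% 4L, size = 4L,
                      endian = "little")
  )
  if (fmt$channels > 1L) {
    matrix(vals, ncol = fmt$channels, byrow = TRUE)
  } else {
    matrix(vals, ncol = 1L)
  }
}

decode_pcm24 <- function(raw) {
  n <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
  v <- b[1L, ] + b[2L, ] * 256 + b[3L, ] * 65536
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Write an audio track to a PCM WAV file
#'
#' @param track An [audio_track()].
#' @param path Output path.
#' @param encoding `"pcm16"`, `"pcm24"`, or `"float32"`. Defaults to the
#'   encoding the track was read with, else 16-bit PCM. Integer encodings
#'   quantize by `round(x * 2^(bits-1))`, clamped to the representable range.
#' @return `path`, invisibly.
#' @export
write_wav <- function(track, path, encoding = NULL) {
  assert_track(track)
  encoding <- encoding %||% attr(track, "encoding") %||% "pcm16"
  encoding <- match.arg(encoding, c("pcm16", "pcm24", "float32"))

  ns <- n_samples(track)
  nc <- n_channels(track)
  interleaved <- as.vector(t(track$samples))
  bytes_per <- switch(encoding, pcm16 = 2L, pcm24 = 3L, float32 = 4L)
  fmt_tag <- if (encoding == "float32") 3L else 1L
  bits <- bytes_per * 8L
  data_size <- ns * nc * bytes_per
  rate <- as.integer(round(track$rate))

  con <- tryCatch(file(path, "wb"), error = function(e) {
    abort_avsync(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
                 "avsync_io_error")
  })
  on.exit(close(con))

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_tag, con, size = 2L, endian = "little")
  writeBin(nc, con, size = 2L, endian = "little")
  writeBin(rate, con, size = 4L, endian = "little")
  writeBin(as.integer(rate * nc * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(nc * bytes_per), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")

  if (encoding == "pcm16") {
    q <- pmin(pmax(round(interleaved * 32768), -32768), 32767)
    writeBin(as.integer(q), con, size = 2L, endian = "little")
  } else if (encoding == "pcm24") {
    q <- pmin(pmax(round(interleaved * 8388608), -8388608), 8388607)
    q <- ifelse(q < 0, q + 16777216, q)
    b <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  } else {
    writeBin(interleaved, con, size = 4L, endian = "little")
  }
  invisible(path)
}
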