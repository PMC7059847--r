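# Shared fixture builders. Everything is generated in code; nothing binary
# ships with the tests.

# A short, quick tune + embedded fixture for module tests.
small_fixture <- function(true_offset = 2.345, snr_db = 15, seed = 101,
                          rate = 4000, total = 10, tune_duration = 1) {
  tune <- make_sync_tune(duration = tune_duration, rate = rate)
  embed_tune(tune, total_duration = total, true_offset = true_offset,
             snr_db = snr_db, seed = seed)
}

# Write a fake external decoder: a bash script that emulates just enough of
# the real binary's CLI (-version; last argument = output file) to exercise
# the seam. `wav` is copied to the requested output; `fail = TRUE` emulates
# an input with no audio stream.
fake_decoder <- function(wav = NULL, fail = FALSE) {
  script <- tempfile(fileext = ".sh")
  body <- if (fail) {
    "echo 'Output file does not contain any stream' >&2\nexit 1"
  } else {
    sprintf('out="${@: -1}"\ncp %s "$out"', shQuote(wav))
  }
  writeLines(c(
    "#!/bin/bash",
    'if [ "$1" = "-version" ]; then echo "fake-decoder 1.0"; exit 0; fi',
    body
  ), script)
  Sys.chmod(script, "0755")
  script
}

# The bundled benchmark offset table (13 recordings x 4 raters).
bundled_offsets <- function() {
  read_offset_table(system.file("extdata", "manual_auto_offsets.csv",
                                package = "avsync"))
}

dominant_frequency <- function(track) {
  v <- avsync:::mono_samples(track)
  spec <- Mod(stats::fft(v))[seq_len(floor(length(v) / 2))]
  (which.max(spec[-1])) * track$rate / length(v)
}
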