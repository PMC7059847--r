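# Offset detection: sliding correlation, FFT cross-correlation, refinement

test_that("searching a track against itself finds offset 0 with score 1", {
  tune <- make_sync_tune(duration = 1, rate = 4000)
  r <- find_offset_sliding_corr(tune, tune, search_start = 0, search_end = 0)
  expect_equal(r$offset_seconds, 0)
  expect_equal(r$score, 1, tolerance = 1e-9)
  x <- find_offset_xcorr(tune, tune)
  expect_equal(x$offset_seconds, 0)
  expect_equal(x$score, 1, tolerance = 1e-6)
})

test_that("an embedded tune is located within one grid step by both detectors", {
  fx <- small_fixture(true_offset = 2.345, snr_db = 10)
  r <- find_offset_sliding_corr(fx$target, fx$sample, step = 0.001)
  expect_lt(abs(r$offset_seconds - fx$true_offset), 0.001 + 1e-9)
  x <- find_offset_xcorr(fx$target, fx$sample)
  expect_lt(abs(x$offset_seconds - fx$true_offset), 1 / 4000 + 1e-9)
})

test_that("sliding correlation is invariant to scaling and DC shifts of the recording", {
  fx <- small_fixture(true_offset = 1.5, snr_db = 10)
  base <- find_offset_sliding_corr(fx$target, fx$sample, step = 0.001)
  scaled <- audio_track(fx$sample$samples * 0.3, fx$sample$rate)
  r2 <- find_offset_sliding_corr(fx$target, scaled, step = 0.001)
  expect_equal(r2$offset_seconds, base$offset_seconds)
  expect_equal(r2$score, base$score, tolerance = 1e-9)
  shifted <- audio_track(fx$sample$samples + 0.25, fx$sample$rate)
  r3 <- find_offset_sliding_corr(fx$target, shifted, step = 0.001)
  expect_equal(r3$offset_seconds, base$offset_seconds)
  expect_equal(r3$score, base$score, tolerance = 1e-7)
})

test_that("the returned score is exactly the maximum of the trace", {
  fx <- small_fixture()
  for (r in list(find_offset_sliding_corr(fx$target, fx$sample, step = 0.005),
                 find_offset_xcorr(fx$target, fx$sample))) {
    expect_identical(r$score, max(r$trace$score))
    expect_true(all(diff(r$trace$lag_seconds) > 0))
    expect_true(all(abs(r$trace$score) <= 1 + 1e-12))
  }
})

test_that("a time-reversed reference scores far below the matched one", {
  fx <- small_fixture(snr_db = 20)
  rev_target <- audio_track(rev(avsync:::mono_samples(fx$target)), fx$target$rate)
  matched <- find_offset_xcorr(fx$target, fx$sample)
  reversed <- find_offset_xcorr(rev_target, fx$sample)
  expect_lt(reversed$score, matched$score - 0.3)
})

test_that("a reference longer than the recording is rejected with guidance", {
  short <- make_sync_tune(duration = 0.5, rate = 4000)
  long <- make_sync_tune(duration = 1, rate = 4000)
  err <- expect_error(find_offset_sliding_corr(long, short),
                      class = "avsync_precondition_error")
  expect_match(conditionMessage(err), "swap")
})

test_that("zero-variance signals score 0 with a warning, never NaN", {
  flat <- audio_track(rep(0.5, 400), rate = 400)
  noise <- audio_track(stats::rnorm(4000), rate = 400)
  expect_warning(r <- find_offset_sliding_corr(flat, noise, step = 0.01),
                 "zero-variance")
  expect_false(anyNA(r$trace$score))
  expect_equal(r$score, 0)
})

test_that("rate mismatches are resolved by upsampling the coarser track", {
  fx <- small_fixture(true_offset = 1.5, snr_db = 20)
  target_lo <- resample_track(fx$target, 2000)
  expect_message(r <- find_offset_sliding_corr(target_lo, fx$sample, step = 0.001),
                 "resampling")
  expect_lt(abs(r$offset_seconds - fx$true_offset), 0.002 + 1e-9)
})

test_that("refinement tightens a coarse search and never lowers the score", {
  # coarse-to-fine needs a correlation peak wider than the coarse step, i.e.
  # low-frequency content in the reference (periods 15-43 ms >> 10 ms step)
  rate <- 10000
  tune <- make_sync_tune(duration = 1, freqs = c(23, 41, 67), rate = rate)
  fx <- embed_tune(tune, total_duration = 12, true_offset = 5.8073,
                   snr_db = 20, seed = 7)
  coarse <- find_offset_sliding_corr(fx$target, fx$sample, step = 0.010)
  fine <- refine_offset(coarse, fx$target, fx$sample, fine_step = 0.0001)
  expect_lte(abs(fine$offset_seconds - 5.8073), 0.0001 + 1e-9)
  expect_gte(fine$score, coarse$score)

  same <- refine_offset(coarse, fx$target, fx$sample, fine_step = 0.010)
  expect_equal(same$offset_seconds, coarse$offset_seconds)
})

test_that("ties break to the earliest lag", {
  # two identical embedded copies: argmax must pick the first
  rate <- 2000
  tune <- make_sync_tune(duration = 0.25, rate = rate)
  tv <- avsync:::mono_samples(tune)
  track <- numeric(3 * rate)
  track[501:(500 + length(tv))] <- tv
  track[3001:(3000 + length(tv))] <- tv
  # the all-zero stretches between the copies are zero-variance windows
  suppressWarnings(
    r <- find_offset_sliding_corr(tune, audio_track(track, rate), step = 1 / rate)
  )
  expect_equal(r$offset_seconds, 500 / rate)
})

test_that("shift_preview mixes at the chosen offset and exposes echo misalignment", {
  fx <- small_fixture(true_offset = 2, snr_db = 30, total = 6)
  b_sil <- audio_track(numeric(4000 * 4), rate = 4000)
  a <- fx$target
  expect_equal(shift_preview(a, b_sil, 0)$samples, a$samples / 2)

  # echo proxy: autocorrelation of the mix at the 200 ms error lag
  echo_peak <- function(mix, lag_s) {
    v <- avsync:::mono_samples(mix)
    k <- round(lag_s * mix$rate)
    abs(cor(v[1:(length(v) - k)], v[(k + 1):length(v)]))
  }
  aligned <- shift_preview(fx$target, fx$sample, fx$true_offset)
  misaligned <- shift_preview(fx$target, fx$sample, fx$true_offset - 0.2)
  expect_gt(echo_peak(misaligned, 0.2), echo_peak(aligned, 0.2) + 0.1)
})

test_that("tidiers and autoplot work on offset results", {
  fx <- small_fixture()
  r <- find_offset_sliding_corr(fx$target, fx$sample, step = 0.01)
  expect_named(tidy(r), c("lag_seconds", "score"))
  g <- glance(r)
  expect_equal(g$offset_seconds, r$offset_seconds)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(r, f)
  expect_named(utils::read.csv(f), c("lag_s", "score"))
})
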