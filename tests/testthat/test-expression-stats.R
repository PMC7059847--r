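# Expression time-series analytics: downsampling, epochs, t-tests, ISC

test_that("bin-average downsampling: constants pass through, 30 Hz -> 1 Hz bins average 30", {
  const <- expression_series("s1", "joy", rep(3, 90), rate = 30)
  down <- downsample_series(const, 1)
  expect_equal(nrow(down), 3)
  expect_true(all(down$value == 3))

  vals <- seq_len(60)
  s <- expression_series("s1", "joy", vals, rate = 30)
  d <- downsample_series(s, 1)
  expect_equal(nrow(d), 2)
  expect_equal(d$value, c(mean(1:30), mean(31:60)))

  expect_equal(downsample_series(s, 30)$value, s$value)
  expect_error(downsample_series(s, 60), class = "avsync_precondition_error")
  expect_error(downsample_series(s, -1), class = "avsync_precondition_error")
})

test_that("a trailing partial bin is dropped", {
  s <- expression_series("s1", "joy", seq_len(75), rate = 30) # 2.5 s
  d <- downsample_series(s, 1)
  expect_equal(nrow(d), 2)
})

test_that("epoch means recover generator plateaus and validate events", {
  events <- tibble::tibble(onset = c(1, 5), duration = 2, condition = c("pos", "neg"))
  series <- make_event_responses(events, c(pos = 8, neg = 0.5), noise_sd = 0,
                                 rate = 30, seed = 1)
  em <- epoch_means(series, events)
  expect_equal(em$trial_stat, c(8, 0.5))
  expect_equal(em$condition, c("pos", "neg"))

  const <- expression_series("s1", "joy", rep(3, 300), rate = 30)
  expect_true(all(epoch_means(const, events)$trial_stat == 3))

  expect_error(epoch_means(const, tibble::tibble(onset = 1, duration = 0, condition = "x")),
               class = "avsync_precondition_error")
  bad <- tibble::tibble(onset = 9.8, duration = 2, condition = "x")
  expect_error(epoch_means(const, bad), class = "avsync_precondition_error")
})

test_that("the max-statistic variant bounds the mean variant from above", {
  events <- tibble::tibble(onset = 1, duration = 2, condition = "pos")
  series <- make_event_responses(events, c(pos = 2), noise_sd = 1, rate = 30, seed = 3)
  expect_gte(epoch_means(series, events, stat = "max")$trial_stat,
             epoch_means(series, events, stat = "mean")$trial_stat)
})

test_that("pooled two-sample t from published group summaries matches the printed values", {
  a <- two_sample_t_summary(8.55, 0.52, 10, 0.59, 1.53, 10)
  expect_equal(round(a$t, 2), 15.58)
  expect_equal(a$df, 18)
  expect_lt(a$p_value, 0.001)
  b <- two_sample_t_summary(3.02, 1.41, 10, 0.25, 0.77, 10)
  expect_equal(round(b$t, 2), 5.45)
  expect_equal(b$df, 18)
})

test_that("raw-value and summary routes of the pooled t agree exactly", {
  withr::with_seed(5, {
    x <- stats::rnorm(10, 2)
    y <- stats::rnorm(12, 1)
  })
  raw <- two_sample_t(x, y)
  summ <- two_sample_t_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  expect_equal(raw$t, summ$t)
  expect_equal(raw$df, summ$df)
  expect_equal(raw$p_value, summ$p_value)

  expect_equal(two_sample_t(c(1, 2, 3), c(3, 2, 1))$t, 0)
  expect_lt(two_sample_t(x, y, welch = TRUE)$df, raw$df + 1e-9)
  expect_error(two_sample_t(1, c(1, 2)), class = "avsync_precondition_error")
})

test_that("pairwise ISC: pair count, symmetry to subject order, identical series", {
  g <- make_isc_group(5, 500, true_isc = 0.4, seed = 2)
  isc <- pairwise_isc(g$series)
  expect_equal(isc$n_pairs, 10)

  reordered <- dplyr::arrange(g$series, dplyr::desc(subject_id), time)
  isc2 <- pairwise_isc(reordered)
  expect_equal(sort(isc2$pair_r$r), sort(isc$pair_r$r))
  expect_equal(isc2$mean_r, isc$mean_r)

  dup <- dplyr::bind_rows(
    expression_series("a", "joy", sin(1:100), 1),
    expression_series("b", "joy", sin(1:100), 1),
    expression_series("c", "joy", sin(1:100), 1)
  )
  expect_true(all(suppressWarnings(pairwise_isc(dup))$pair_r$r == 1))
})

test_that("unequal series lengths are truncated to the shortest with a message", {
  two <- dplyr::bind_rows(
    expression_series("a", "joy", stats::rnorm(100), 1),
    expression_series("b", "joy", stats::rnorm(80), 1)
  )
  expect_message(isc <- pairwise_isc(two), "truncating")
  expect_equal(isc$length_used, 80)
})

test_that("zero-variance subjects are excluded with a warning, not propagated as NaN", {
  bad <- dplyr::bind_rows(
    expression_series("a", "joy", stats::rnorm(50), 1),
    expression_series("b", "joy", stats::rnorm(50), 1),
    expression_series("c", "joy", rep(1, 50), 1)
  )
  expect_warning(isc <- pairwise_isc(bad), "zero-variance")
  expect_equal(sum(is.na(isc$pair_r$r)), 2)
  expect_false(is.na(isc$mean_r))
})

test_that("the Fisher-z one-sample test matches a hand-computed t", {
  # z values 0.1, 0.2, 0.3 -> t = 0.2 / (0.1 / sqrt(3)) = 3.4641, df 2
  isc <- structure(list(
    pair_r = tibble::tibble(
      subject_i = c("a", "a", "b"), subject_j = c("b", "c", "c"),
      r = tanh(c(0.1, 0.2, 0.3)), z = c(0.1, 0.2, 0.3)
    ),
    mean_r = NA, sd_r = NA, n_subjects = 3, n_pairs = 3,
    channel = "joy", length_used = 10
  ), class = "isc_result")
  out <- isc_one_sample_test(isc)
  expect_equal(out$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-7)
  expect_equal(out$df, 2)

  all_zero <- isc
  all_zero$pair_r$r <- rep(0, 3)
  all_zero$pair_r$z <- rep(0, 3)
  expect_message(deg <- isc_one_sample_test(all_zero), "identical")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t))
})

test_that("atanh is the exact inverse of tanh on (-1, 1)", {
  z <- seq(-5, 5, by = 0.25)
  expect_equal(atanh(tanh(z)), z, tolerance = 1e-12)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(tanh(atanh(r)), r, tolerance = 1e-12)
})

test_that("condition comparison: paired identity gives t = 0; modes give their dfs", {
  g1 <- make_isc_group(5, 800, true_isc = 0.4, seed = 31)
  g2 <- make_isc_group(5, 800, true_isc = 0.2, seed = 32)
  a <- pairwise_isc(g1$series)
  b <- pairwise_isc(g2$series)

  self <- isc_condition_compare(a, a, mode = "paired")
  expect_equal(self$t, 0)
  expect_equal(self$df, 9)

  ts <- isc_condition_compare(a, b, mode = "two_sample")
  expect_equal(ts$df, 18) # 10 + 10 - 2
  pd <- isc_condition_compare(a, b, mode = "paired")
  expect_equal(pd$df, 9)

  # mismatched pair labels must be named in the error
  c_small <- pairwise_isc(dplyr::filter(g2$series, subject_id != "s05"))
  err <- expect_error(isc_condition_compare(a, c_small, mode = "paired"),
                      class = "avsync_precondition_error")
  expect_match(conditionMessage(err), "s05")
})

test_that("ISC result tidiers and matrix plot work", {
  g <- make_isc_group(4, 300, true_isc = 0.3, seed = 9)
  isc <- isc_one_sample_test(pairwise_isc(g$series))
  expect_equal(nrow(tidy(isc)), 6)
  gl <- glance(isc)
  expect_equal(gl$df, 5)
  expect_s3_class(ggplot2::autoplot(isc), "ggplot")
})
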