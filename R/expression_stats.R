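#' Build a tidy expression time series
#'
#' Facial-expression classifiers emit one continuous "evidence" value per
#' frame and channel (e.g. joy, disgust) — log-odds-style, unbounded. The
#' package represents such series in long, tidy form: one row per sample
#' with columns `subject_id`, `channel`, `time` (seconds, 0-based) and
#' `value`. All expression statistics take and return tibbles of this shape.
#'
#' @param subject_id Subject label.
#' @param channel Expression channel label (e.g. `"joy"`).
#' @param values Numeric evidence values, one per frame; must be finite.
#' @param rate Sampling rate in Hz.
#' @return A tibble with columns `subject_id`, `channel`, `time`, `value`.
#' @export
expression_series <- function(subject_id, channel, values, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop_precondition("`rate` must be a single positive number (Hz)")
  }
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop_precondition("evidence values must be finite")
  tibble(
    subject_id = as.character(subject_id),
    channel = as.character(channel),
    time = (seq_along(values) - 1) / rate,
    value = values
  )
}

# Sample rate from the time stamps of one series (regular sampling assumed).
infer_rate <- function(time) {
  if (length(time) < 2) stop_precondition("cannot infer a rate from fewer than 2 samples")
  1 / stats::median(diff(sort(time)))
}

#' Downsample expression series by bin averaging
#'
#' Output sample k (0-based, per subject and channel) is the mean of all
#' input samples with time in `[k/out_rate, (k+1)/out_rate)`. A trailing bin
#' not fully covered by the input is dropped. When `out_rate` equals the
#' input rate this is the identity.
#'
#' @param series Long tibble as produced by [expression_series()].
#' @param out_rate Target rate in Hz; must not exceed the input rate.
#' @return A long tibble at `out_rate`, times at the left bin edges.
#' @export
downsample_series <- function(series, out_rate) {
  if (!is.numeric(out_rate) || length(out_rate) != 1 || out_rate <= 0) {
    stop_precondition("`out_rate` must be a single positive number (Hz)")
  }
  series |>
    group_by(.data$subject_id, .data$channel) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$time)
      in_rate <- infer_rate(df$time)
      if (out_rate > in_rate + 1e-9) {
        stop_precondition(sprintf(
          "`out_rate` (%g Hz) exceeds the input rate (%g Hz)", out_rate, in_rate
        ))
      }
      t0 <- df$time[1]
      bin <- floor((df$time - t0) * out_rate + 1e-9)
      n_out <- floor(nrow(df) / in_rate * out_rate + 1e-9)
      keep <- bin < n_out
      out <- tibble(bin = bin[keep], value = df$value[keep]) |>
        group_by(.data$bin) |>
        summarise(value = mean(.data$value), .groups = "drop")
      tibble(time = t0 + out$bin / out_rate, value = out$value)
    }) |>
    ungroup() |>
    select("subject_id", "channel", "time", "value")
}

#' Per-event mean evidence
#'
#' Averages the evidence inside each event window `[onset, onset + duration)`
#' — the per-trial summary used to compare conditions in event-locked
#' designs. `stat = "max"` takes the window maximum instead of the mean.
#'
#' @param series Long tibble (one or more subjects/channels).
#' @param events Tibble with columns `onset`, `duration` (seconds) and
#'   `condition`; windows must lie inside the series.
#' @param stat `"mean"` (default) or `"max"`.
#' @return A tibble: `subject_id`, `channel`, `condition`, `onset`,
#'   `trial_stat`.
#' @export
epoch_means <- function(series, events, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  if (!all(c("onset", "duration", "condition") %in% names(events))) {
    stop_precondition("`events` needs columns onset, duration, condition")
  }
  if (any(events$duration <= 0)) {
    stop_precondition("zero- or negative-duration event(s) present")
  }
  if (any(events$onset < 0)) stop_precondition("event onsets must be non-negative")
  fn <- if (stat == "mean") mean else max

  series |>
    group_by(.data$subject_id, .data$channel) |>
    dplyr::group_modify(function(df, key) {
      end_time <- max(df$time) + stats::median(diff(sort(df$time)))
      purrr::pmap_dfr(
        events[c("onset", "duration", "condition")],
        function(onset, duration, condition) {
          if (onset + duration > end_time + 1e-9) {
            stop_precondition(sprintf(
              "event at onset %.3f s (duration %.3f s) extends beyond the series (%.3f s)",
              onset, duration, end_time
            ))
          }
          inside <- df$time >= onset - 1e-9 & df$time < onset + duration - 1e-9
          if (!any(inside)) {
            stop_precondition(sprintf("event at onset %.3f s contains no samples", onset))
          }
          tibble(condition = condition, onset = onset,
                 trial_stat = fn(df$value[inside]))
        }
      )
    }) |>
    ungroup() |>
    select("subject_id", "channel", "condition", "onset", "trial_stat")
}

#' Two-sample t-test from raw values or group summaries
#'
#' `two_sample_t()` compares two vectors of raw values; by default it pools
#' the variances (df = n1 + n2 - 2), with Welch's correction behind
#' `welch = TRUE`. `two_sample_t_summary()` computes the same pooled test
#' from published group summaries (mean, SD, n) — the two routes agree
#' exactly on the same data.
#'
#' @param x,y Numeric vectors (n >= 2 each).
#' @param welch Use Welch's unequal-variance test instead of pooling.
#' @return A one-row tibble: `t`, `df`, `p_value`, per-group `mean`, `sd`,
#'   `n`, and `method`.
#' @examples
#' two_sample_t_summary(8.55, 0.52, 10, 0.59, 1.53, 10)
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    stop_precondition("both groups need at least 2 observations")
  }
  tt <- t.test(x, y, var.equal = !welch)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p_value = tt$p.value,
    mean_1 = mean(x), sd_1 = sd(x), n_1 = length(x),
    mean_2 = mean(y), sd_2 = sd(y), n_2 = length(y),
    method = if (welch) "welch" else "pooled"
  )
}

#' @rdname two_sample_t
#' @param mean_1,sd_1,n_1,mean_2,sd_2,n_2 Group summaries.
#' @export
two_sample_t_summary <- function(mean_1, sd_1, n_1, mean_2, sd_2, n_2) {
  if (n_1 < 2 || n_2 < 2) stop_precondition("both groups need n >= 2")
  df <- n_1 + n_2 - 2
  sp <- sqrt(((n_1 - 1) * sd_1^2 + (n_2 - 1) * sd_2^2) / df)
  t_stat <- (mean_1 - mean_2) / (sp * sqrt(1 / n_1 + 1 / n_2))
  tibble(
    t = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df),
    mean_1 = mean_1, sd_1 = sd_1, n_1 = n_1,
    mean_2 = mean_2, sd_2 = sd_2, n_2 = n_2,
    method = "pooled"
  )
}

#' Pairwise intersubject correlation of expression series
#'
#' Computes the Pearson correlation of the selected channel between every
#' unordered pair of subjects — intersubject correlation (ISC), the standard
#' synchrony measure for groups experiencing the same stimulus. Series of
#' unequal length are truncated to the shortest (with a message). The
#' summary mean and SD are reported on the r scale; inference happens on the
#' Fisher-z scale via [isc_one_sample_test()].
#'
#' @param series Long tibble with at least 2 subjects.
#' @param channel Channel label to analyse (default: the only channel
#'   present).
#' @return An object of class `isc_result`: tibble `pair_r` (`subject_i`,
#'   `subject_j`, `r`, `z`), `mean_r`, `sd_r`, subject count, channel.
#' @export
pairwise_isc <- function(series, channel = NULL) {
  chans <- unique(series$channel)
  if (is.null(channel)) {
    if (length(chans) != 1) {
      stop_precondition("multiple channels present; pick one via `channel`")
    }
    channel <- chans
  }
  df <- filter(series, .data$channel == !!channel)
  subjects <- unique(df$subject_id)
  if (length(subjects) < 2) stop_precondition("ISC needs at least 2 subjects")

  mats <- lapply(subjects, function(s) {
    x <- arrange(filter(df, .data$subject_id == s), .data$time)
    x$value
  })
  lens <- lengths(mats)
  if (length(unique(lens)) > 1) {
    inform(sprintf("series lengths differ (%d-%d); truncating to the shortest",
                   min(lens), max(lens)))
  }
  L <- min(lens)
  m <- vapply(mats, function(v) v[seq_len(L)], numeric(L))
  colnames(m) <- subjects

  sds <- apply(m, 2, sd)
  flat <- subjects[sds == 0]
  if (length(flat) > 0) {
    warn(sprintf("zero-variance series for subject(s) %s; their pairs are excluded",
                 paste(flat, collapse = ", ")))
  }

  pairs <- utils::combn(seq_along(subjects), 2)
  pair_r <- tibble(
    subject_i = subjects[pairs[1, ]],
    subject_j = subjects[pairs[2, ]],
    r = apply(pairs, 2, function(ij) {
      if (sds[ij[1]] == 0 || sds[ij[2]] == 0) NA_real_ else cor(m[, ij[1]], m[, ij[2]])
    })
  )
  pair_r$z <- atanh(pmin(pmax(pair_r$r, -1 + 1e-7), 1 - 1e-7))

  valid <- pair_r$r[!is.na(pair_r$r)]
  structure(
    list(
      pair_r = pair_r,
      mean_r = mean(valid), sd_r = if (length(valid) > 1) sd(valid) else NA_real_,
      n_subjects = length(subjects), n_pairs = nrow(pair_r),
      channel = channel, length_used = L,
      t = NA_real_, df = NA_real_, p_value = NA_real_, degenerate = NA
    ),
    class = "isc_result"
  )
}

#' One-sample Fisher-z test of ISC against zero
#'
#' Transforms each pairwise r to z = atanh(r) (values at |r| = 1 are clipped
#' to 1 - 1e-7 with a warning) and runs a one-sample t-test of the z values
#' against 0, df = number of pairs - 1. Pairs sharing a subject are treated
#' as independent — the field's standard simplification, noted as such.
#'
#' @param isc An `isc_result` from [pairwise_isc()].
#' @return The `isc_result` with `t`, `df`, `p_value` (and a degenerate
#'   flag when all z values are identical) filled in.
#' @export
isc_one_sample_test <- function(isc) {
  stopifnot(inherits(isc, "isc_result"))
  z <- isc$pair_r$z[!is.na(isc$pair_r$r)]
  if (length(z) < 2) stop_precondition("need at least 2 valid pairs for the test")
  if (any(abs(isc$pair_r$r) >= 1 - 1e-7, na.rm = TRUE)) {
    warn("correlation(s) at |r| ~ 1 clipped before the Fisher transform")
  }
  isc$df <- length(z) - 1
  if (sd(z) == 0) {
    isc$degenerate <- TRUE
    inform("all Fisher-z values identical; t statistic undefined")
    isc$t <- NA_real_
    isc$p_value <- NA_real_
  } else {
    tt <- t.test(z)
    isc$degenerate <- FALSE
    isc$t <- unname(tt$statistic)
    isc$p_value <- tt$p.value
  }
  isc
}

#' Compare ISC between two conditions
#'
#' Tests whether pairwise synchrony differs between two conditions, on the
#' Fisher-z scale. `mode = "paired"` matches pairs by (subject_i, subject_j)
#' label and tests the per-pair z differences (df = pairs - 1);
#' `mode = "two_sample"` treats the two sets of z values as independent
#' samples with a pooled-variance t (df = n1 + n2 - 2). Both are offered
#' because group designs are reported both ways in practice.
#'
#' @param isc_a,isc_b `isc_result` objects for the two conditions.
#' @param mode `"two_sample"` or `"paired"`.
#' @return A one-row tibble as from [two_sample_t()] (for paired mode the
#'   group columns describe the z differences).
#' @export
isc_condition_compare <- function(isc_a, isc_b, mode = c("two_sample", "paired")) {
  mode <- match.arg(mode)
  stopifnot(inherits(isc_a, "isc_result"), inherits(isc_b, "isc_result"))
  a <- filter(isc_a$pair_r, !is.na(.data$r))
  b <- filter(isc_b$pair_r, !is.na(.data$r))
  if (mode == "two_sample") {
    return(mutate(two_sample_t(a$z, b$z), method = "two_sample_z"))
  }
  key <- c("subject_i", "subject_j")
  missing_in_b <- anti_join(a, b, by = key)
  missing_in_a <- anti_join(b, a, by = key)
  if (nrow(missing_in_b) > 0 || nrow(missing_in_a) > 0) {
    miss <- bind_rows(missing_in_b, missing_in_a)
    stop_precondition(sprintf(
      "paired mode needs matching pairs; unmatched: %s",
      paste(sprintf("(%s,%s)", miss$subject_i, miss$subject_j), collapse = ", ")
    ))
  }
  j <- left_join(a, b, by = key, suffix = c("_a", "_b"))
  d <- j$z_a - j$z_b
  if (length(d) < 2) stop_precondition("paired mode needs at least 2 pairs")
  if (sd(d) == 0) {
    # identical conditions (or a constant shift): the t statistic degenerates
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble(
      t = t_stat, df = length(d) - 1,
      p_value = if (mean(d) == 0) 1 else 0,
      mean_1 = mean(d), sd_1 = 0, n_1 = length(d),
      mean_2 = NA_real_, sd_2 = NA_real_, n_2 = NA_integer_,
      method = "paired_z"
    ))
  }
  tt <- t.test(d)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p_value = tt$p.value,
    mean_1 = mean(d), sd_1 = sd(d), n_1 = length(d),
    mean_2 = NA_real_, sd_2 = NA_real_, n_2 = NA_integer_,
    method = "paired_z"
  )
}

#' @export
print.isc_result <- function(x, ...) {
  cat(sprintf("<isc_result> channel '%s': %d subjects, %d pairs (length %d)\n",
              x$channel, x$n_subjects, x$n_pairs, x$length_used))
  cat(sprintf("  mean r = %.2f (SD = %.2f)\n", x$mean_r, x$sd_r))
  if (!is.na(x$t)) {
    cat(sprintf("  Fisher-z one-sample test: t(%d) = %.2f, p = %.3g\n",
                x$df, x$t, x$p_value))
  }
  invisible(x)
}

#' Tidiers for ISC results
#'
#' `tidy()` returns the pairwise correlations; `glance()` a one-row summary
#' with the group mean r, SD and (when computed) the Fisher-z test.
#'
#' @param x An `isc_result`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.isc_result <- function(x, ...) x$pair_r

#' @rdname tidy.isc_result
#' @exportS3Method generics::glance
glance.isc_result <- function(x, ...) {
  tibble(
    channel = x$channel, n_subjects = x$n_subjects, n_pairs = x$n_pairs,
    mean_r = x$mean_r, sd_r = x$sd_r,
    t = x$t, df = x$df, p_value = x$p_value
  )
}

#' Plot the pairwise ISC matrix
#'
#' @param object An `isc_result`.
#' @param ... Unused.
#' @return A ggplot tile map of the symmetric pairwise correlation matrix.
#' @exportS3Method ggplot2::autoplot
autoplot.isc_result <- function(object, ...) {
  pr <- object$pair_r
  full <- bind_rows(
    pr,
    tibble(subject_i = pr$subject_j, subject_j = pr$subject_i, r = pr$r, z = pr$z)
  )
  ggplot2::ggplot(full, ggplot2::aes(x = .data$subject_i, y = .data$subject_j,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = sprintf("Pairwise ISC: %s", object$channel)) +
    ggplot2::theme_minimal()
}
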