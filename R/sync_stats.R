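#' Read a manual-vs-automatic offset table
#'
#' The agreement analysis consumes a wide table with one row per aligned
#' recording: identifier columns `file_id` and `target_id`, an optional
#' `group` label (e.g. the study a recording belongs to), one column per
#' manual rater named `rater_1`, `rater_2`, ..., and the automatically
#' detected offset in `auto`. All offsets are seconds.
#'
#' A copy of a published 13-recording benchmark table (4 raters) ships with
#' the package: `system.file("extdata", "manual_auto_offsets.csv",
#' package = "avsync")`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_offset_table <- function(path) {
  if (!file.exists(path)) stop_not_found(sprintf("no such file: '%s'", path))
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_offset_table(df)
  df
}

validate_offset_table <- function(df) {
  rater_cols <- grep("^rater_", names(df), value = TRUE)
  if (nrow(df) == 0) stop_precondition("offset table is empty")
  if (length(rater_cols) == 0) {
    stop_precondition("offset table needs at least one `rater_*` column")
  }
  if (!"auto" %in% names(df)) stop_precondition("offset table needs an `auto` column")
  if (!"file_id" %in% names(df)) stop_precondition("offset table needs a `file_id` column")
  offs <- c(unlist(df[rater_cols]), df$auto)
  offs <- offs[!is.na(offs)]
  if (any(offs < 0)) stop_precondition("offsets must be non-negative seconds")
  invisible(df)
}

#' Per-rater differences between automatic and manual offsets
#'
#' The difference is always automatic minus manual, so a negative value
#' means the detector placed the offset earlier than the rater did.
#'
#' @param table A wide offset table as read by [read_offset_table()].
#' @return A tibble with one row per (recording, rater):
#'   `file_id`, `group` (if present), `rater`, `manual`, `auto`, `diff`.
#' @export
offset_differences <- function(table) {
  validate_offset_table(table)
  rater_cols <- grep("^rater_", names(table), value = TRUE)
  id_cols <- intersect(c("file_id", "target_id", "group", "auto"), names(table))
  wide <- table[c(id_cols, rater_cols)]
  # file_id need not be unique (the same recording can be aligned twice), so
  # rows are keyed by position
  wide$row <- seq_len(nrow(wide))
  long <- tidyr::pivot_longer(
    wide,
    cols = dplyr::all_of(rater_cols),
    names_to = "rater", values_to = "manual"
  )
  long <- filter(long, !is.na(.data$manual))
  mutate(long, diff = .data$auto - .data$manual)
}

#' Summarize manual-vs-automatic offset agreement
#'
#' Computes, from the per-(recording, rater) differences automatic - manual:
#' a per-recording mean and SD, a pooled mean and SD per `group` label, and
#' an overall mean, SD and one-sample t-test of the differences against 0
#' (df = number of differences - 1). SDs use the n-1 denominator; rounding
#' happens only at print time, never inside the computation.
#'
#' @param table A wide offset table (see [read_offset_table()]).
#' @return An object of class `agreement_summary` with tibble components
#'   `per_row`, `by_group`, and `overall`.
#' @examples
#' csv <- system.file("extdata", "manual_auto_offsets.csv", package = "avsync")
#' summarize_agreement(read_offset_table(csv))
#' @export
summarize_agreement <- function(table) {
  diffs <- offset_differences(table)
  if (nrow(diffs) == 0) stop_precondition("no differences to summarize")

  per_row <- summarise(
    group_by(diffs, .data$row, .data$file_id),
    n_raters = n(),
    mean_diff = mean(.data$diff),
    sd_diff = if (n() > 1) sd(.data$diff) else NA_real_,
    .groups = "drop"
  )
  per_row <- arrange(per_row, .data$row)

  by_group <- if ("group" %in% names(diffs)) {
    summarise(
      group_by(diffs, .data$group),
      n_diffs = n(),
      mean_diff = mean(.data$diff),
      sd_diff = if (n() > 1) sd(.data$diff) else NA_real_,
      .groups = "drop"
    )
  } else {
    tibble(group = character(), n_diffs = integer(),
           mean_diff = numeric(), sd_diff = numeric())
  }

  d <- diffs$diff
  overall <- tibble(
    n_diffs = length(d),
    mean_diff = mean(d),
    sd_diff = if (length(d) > 1) sd(d) else NA_real_
  )
  degenerate <- FALSE
  if (length(d) >= 2 && isTRUE(sd(d) > 0)) {
    tt <- t.test(d)
    overall$t <- unname(tt$statistic)
    overall$df <- unname(tt$parameter)
    overall$p_value <- tt$p.value
  } else {
    degenerate <- TRUE
    inform("all differences identical (or a single difference): one-sample t is undefined")
    overall$t <- NA_real_
    overall$df <- length(d) - 1
    overall$p_value <- NA_real_
  }

  structure(
    list(per_row = per_row, by_group = by_group, overall = overall,
         diffs = diffs, degenerate = degenerate),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("Agreement between automatic and manual offsets (diff = automatic - manual)\n\n")
  cat("Per recording:\n")
  pr <- mutate(x$per_row,
               mean_diff = sprintf("%.3f", .data$mean_diff),
               sd_diff = ifelse(is.na(x$per_row$sd_diff), "--",
                                sprintf("%.3f", x$per_row$sd_diff)))
  print.data.frame(as.data.frame(pr), row.names = FALSE)
  if (nrow(x$by_group) > 0) {
    cat("\nPer group:\n")
    bg <- mutate(x$by_group,
                 mean_diff = sprintf("%.3f", .data$mean_diff),
                 sd_diff = sprintf("%.3f", .data$sd_diff))
    print.data.frame(as.data.frame(bg), row.names = FALSE)
  }
  ov <- x$overall
  cat(sprintf("\nOverall: mean %.3f s (SD %.3f), n = %d\n",
              ov$mean_diff, ov$sd_diff, ov$n_diffs))
  if (x$degenerate) {
    cat("One-sample t vs 0: undefined (zero variance)\n")
  } else {
    cat(sprintf("One-sample t vs 0: t(%d) = %.2f, p = %.2f\n",
                ov$df, ov$t, ov$p_value))
  }
  invisible(x)
}

#' Tidiers for agreement summaries
#'
#' `tidy()` returns the per-recording mean/SD table; `glance()` the overall
#' mean, SD and one-sample t-test row.
#'
#' @param x An `agreement_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.agreement_summary <- function(x, ...) x$per_row

#' @rdname tidy.agreement_summary
#' @exportS3Method generics::glance
glance.agreement_summary <- function(x, ...) x$overall

#' Plot agreement differences per recording
#'
#' @param object An `agreement_summary`.
#' @param ... Unused.
#' @return A ggplot: per-rater differences by recording, zero line marked.
#' @exportS3Method ggplot2::autoplot
autoplot.agreement_summary <- function(object, ...) {
  d <- object$diffs
  d$file_id <- factor(d$file_id, levels = unique(d$file_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$file_id, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3,
                          size = 3, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "automatic - manual offset (s)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a tidy agreement summary to CSV
#'
#' @param summary An `agreement_summary`.
#' @param path Output CSV path (per-recording rows, then group and overall
#'   rows flagged in a `level` column).
#' @return `path`, invisibly.
#' @export
write_agreement_csv <- function(summary, path) {
  stopifnot(inherits(summary, "agreement_summary"))
  pr <- mutate(summary$per_row, level = "recording", .before = 1)
  bg <- summary$by_group
  out <- pr
  if (nrow(bg) > 0) {
    bg <- tibble(level = "group", file_id = bg$group, n_raters = bg$n_diffs,
                 mean_diff = bg$mean_diff, sd_diff = bg$sd_diff)
    out <- bind_rows(out, bg)
  }
  ov <- summary$overall
  out <- bind_rows(out, tibble(
    level = "overall", file_id = "all", n_raters = ov$n_diffs,
    mean_diff = ov$mean_diff, sd_diff = ov$sd_diff
  ))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
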