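# Weekly infection-vs-reference deviation statistics.
#
# The weekly analysis runs on raw daily aggregates (not the smoothed series):
# a week is summarized by the mean and sample SD of its daily blood glucose
# means and of its daily insulin/carbohydrate sums, and an infection episode
# is characterized by the percentage change of the infection week against the
# flanking preinfection and postinfection weeks.

#' Summarize one calendar week of daily aggregates
#'
#' Computes the week's mean and sample standard deviation (n-1 denominator)
#' of the daily blood glucose means, and of the daily bolus, basal and
#' carbohydrate totals.  Statistics are taken over daily values, never over
#' pooled raw samples.  Basal statistics are reported only when the week
#' actually contains basal records (pump users / pen users who log basal).
#'
#' @param series A daily `binned_series`.
#' @param window_start First day of the week (`Date`).
#' @param min_days Minimum number of days with glucose data required
#'   (default 4 of the 7).
#' @return A `week_summary` list with fields `window` (start, end-exclusive),
#'   `bg_mean`, `bg_sd` (mg/dL), `bolus_mean`, `bolus_sd`, `basal_mean`,
#'   `basal_sd` (U/day, `NA` when basal absent), `carb_mean`, `carb_sd`
#'   (g/day) and `n_days`.
#' @export
summarize_week <- function(series, window_start, min_days = 4L) {
  stopifnot(inherits(series, "binned_series"))
  if (attr(series, "bin_width") != "day")
    stop("summarize_week expects a daily series")
  window_start <- as.Date(window_start)
  d <- series_dates(series)
  in_week <- d >= window_start & d < window_start + 7
  wk <- series[in_week, , drop = FALSE]
  covered <- sum(!is.na(wk$bg_mean))
  if (covered < min_days)
    stop("week starting ", format(window_start), " has only ", covered,
         " covered day(s); need at least ", min_days)
  sd1 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  bg <- wk$bg_mean[!is.na(wk$bg_mean)]
  has_basal <- any(wk$basal_sum > 0)
  structure(list(
    window = c(window_start, window_start + 7),
    bg_mean = mean(bg), bg_sd = sd1(bg),
    bolus_mean = mean(wk$bolus_sum), bolus_sd = sd1(wk$bolus_sum),
    basal_mean = if (has_basal) mean(wk$basal_sum) else NA_real_,
    basal_sd = if (has_basal) sd1(wk$basal_sum) else NA_real_,
    carb_mean = mean(wk$carb_sum), carb_sd = sd1(wk$carb_sum),
    n_days = as.integer(covered)),
    class = "week_summary")
}

#' Percentage change of an infection-week value against a reference week
#'
#' `direction = "increase"` reports `100 * (infection - reference) /
#' reference` (used for blood glucose, insulin and the ratio, reported as
#' "over" the reference week); `direction = "reduction"` reports
#' `100 * (reference - infection) / reference` (used for carbohydrate,
#' reported as "below" the reference week).  The reference (flanking) week is
#' always the denominator.
#'
#' @param infection_value Infection-week value.
#' @param reference_value Reference-week value; must be > 0.
#' @param direction `"increase"` or `"reduction"`.
#' @return Unrounded percentage.  Round to 2 decimals for reporting.
#' @export
percent_change <- function(infection_value, reference_value,
                           direction = c("increase", "reduction")) {
  direction <- match.arg(direction)
  if (any(reference_value <= 0))
    stop("reference_value must be > 0")
  if (direction == "increase")
    100 * (infection_value - reference_value) / reference_value
  else
    100 * (reference_value - infection_value) / reference_value
}

# One deviation row; percentages kept unrounded internally, a rounded copy
# (2 decimals, the reporting precision) is added alongside.
deviation_row <- function(case_id, parameter, direction, inf, pre, post) {
  data.frame(case_id = case_id, parameter = parameter,
             pct_vs_pre = percent_change(inf, pre, direction),
             pct_vs_post = percent_change(inf, post, direction),
             direction = direction, stringsAsFactors = FALSE)
}

#' Deviation report for an infection episode from three week summaries
#'
#' @param pre,infection,post `week_summary` objects for the preinfection,
#'   infection and postinfection weeks.
#' @param case_id Case label.
#' @return A `deviation_report` data.frame with one row per parameter
#'   (`bg`, `bolus`, `carbs`, plus `basal` and `total_insulin` when basal
#'   data exist), unrounded `pct_vs_pre`/`pct_vs_post` columns and the
#'   reporting `direction` (increase for bg/insulin, reduction for carbs).
#' @export
case_report_from_summaries <- function(pre, infection, post, case_id = "case") {
  stopifnot(inherits(pre, "week_summary"), inherits(infection, "week_summary"),
            inherits(post, "week_summary"))
  rows <- list(
    deviation_row(case_id, "bg", "increase",
                  infection$bg_mean, pre$bg_mean, post$bg_mean),
    deviation_row(case_id, "bolus", "increase",
                  infection$bolus_mean, pre$bolus_mean, post$bolus_mean))
  if (!is.na(infection$basal_mean) && !is.na(pre$basal_mean) &&
      !is.na(post$basal_mean)) {
    rows <- c(rows, list(
      deviation_row(case_id, "basal", "increase",
                    infection$basal_mean, pre$basal_mean, post$basal_mean),
      deviation_row(case_id, "total_insulin", "increase",
                    infection$bolus_mean + infection$basal_mean,
                    pre$bolus_mean + pre$basal_mean,
                    post$bolus_mean + post$basal_mean)))
  }
  if (isTRUE(infection$carb_mean > 0) && isTRUE(pre$carb_mean > 0) &&
      isTRUE(post$carb_mean > 0)) {
    rows <- c(rows, list(
      deviation_row(case_id, "carbs", "reduction",
                    infection$carb_mean, pre$carb_mean, post$carb_mean)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("deviation_report", "data.frame")
  out
}

#' Deviation report for a self-reported infection episode
#'
#' Builds the three weekly summaries around the episode — preinfection
#' (7 days ending the day before onset), infection (7 days from onset) and
#' postinfection (the following 7 days) — on raw daily aggregates, and
#' reports the percentage change of each key parameter of the blood glucose
#' dynamics.  The infection week is anchored on the self-reported onset date;
#' `anchor_offset` shifts all three windows together for sensitivity checks.
#'
#' @param log An [event_log()] spanning at least `onset - 7` to `onset + 13`.
#' @param infection One-row infection `data.frame` (or a row index into
#'   `log$infections`).
#' @param anchor_offset Days by which to shift the three windows (default 0).
#' @return A `deviation_report` (see [case_report_from_summaries()]).
#' @export
case_report <- function(log, infection = 1L, anchor_offset = 0L) {
  stopifnot(inherits(log, "event_log"))
  if (is.numeric(infection) && length(infection) == 1)
    infection <- log$infections[infection, , drop = FALSE]
  if (!nrow(infection)) stop("no infection episode given")
  onset <- as.Date(infection$onset[1]) + anchor_offset
  if (log$span[1] > onset - 7 || log$span[2] < onset + 13)
    stop("log span does not cover [onset - 7, onset + 13] around ",
         format(onset))
  daily <- resample(log, "day")
  pre <- summarize_week(daily, onset - 7)
  inf <- summarize_week(daily, onset)
  post <- summarize_week(daily, onset + 7)
  case_report_from_summaries(pre, inf, post, case_id = log$patient_id)
}

#' Infection-week shift of the insulin-to-carbohydrate ratio
#'
#' Returns the percentage elevation of the infection week's mean smoothed
#' daily bolus-to-carbohydrate ratio over the patient-year's normal operating
#' point, where the operating point is the mean daily ratio over all
#' non-infection days of the same year.  During regular days the operating
#' point lies in the 0.05-0.2 U/g band; a warning is emitted when it does
#' not.
#'
#' @param smoothed A daily `smoothed_series` covering the year.
#' @param infection One-row infection `data.frame` whose week is assessed.
#' @param all_infections All episodes of the year (excluded from the
#'   baseline); defaults to `infection`.
#' @param baseline_band Expected normal operating band, default
#'   `c(0.05, 0.2)` U/g.
#' @return Unrounded percentage shift.
#' @export
ratio_shift <- function(smoothed, infection, all_infections = infection,
                        baseline_band = c(0.05, 0.2)) {
  stopifnot(inherits(smoothed, "smoothed_series"))
  if (attr(smoothed, "bin_width") != "day")
    stop("ratio_shift expects a daily smoothed series")
  d <- series_dates(smoothed)
  onset <- as.Date(infection$onset[1])
  in_week <- d >= onset & d < onset + 7
  week_ratio <- smoothed$ratio_bolus[in_week]
  week_ratio <- week_ratio[!is.na(week_ratio)]
  if (length(week_ratio) < 4)
    stop("ratio undefined on more than 3 infection-week days")
  excl <- infection_days(all_infections)
  base_ratio <- smoothed$ratio_bolus[!(d %in% excl)]
  base_ratio <- base_ratio[!is.na(base_ratio)]
  if (!length(base_ratio)) stop("no non-infection days with a defined ratio")
  op <- mean(base_ratio)
  if (op < baseline_band[1] || op > baseline_band[2])
    warning(sprintf("baseline operating point %.3f U/g lies outside [%g, %g]",
                    op, baseline_band[1], baseline_band[2]))
  percent_change(mean(week_ratio), op, "increase")
}

#' Aggregate per-case deviation percentages across infection cases
#'
#' The cross-case aggregate for each parameter and reference side is the
#' arithmetic mean of the per-case percentages; parameters missing from some
#' cases (e.g. carbohydrate in a pump-only case) are averaged over the cases
#' that report them.
#'
#' @param reports A `deviation_report` (rows from several cases combined
#'   with `rbind`).
#' @return An `aggregate_deviation` data.frame with columns `parameter`,
#'   `mean_pct_vs_pre`, `mean_pct_vs_post`, `n_cases`.
#' @export
aggregate_cases <- function(reports) {
  if (!nrow(reports)) stop("no deviation reports to aggregate")
  out <- do.call(rbind, lapply(split(reports, reports$parameter), function(g)
    data.frame(parameter = g$parameter[1],
               mean_pct_vs_pre = mean(g$pct_vs_pre),
               mean_pct_vs_post = mean(g$pct_vs_post),
               n_cases = nrow(g), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("aggregate_deviation", "data.frame")
  out
}

#' Format a deviation report at the 2-decimal reporting precision
#'
#' @param reports A `deviation_report`.
#' @return A plain data.frame with percentages rounded to 2 decimals.
#' @export
format_deviation_report <- function(reports) {
  out <- as.data.frame(reports)
  out$pct_vs_pre <- round(out$pct_vs_pre, 2)
  out$pct_vs_post <- round(out$pct_vs_post, 2)
  out
}
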