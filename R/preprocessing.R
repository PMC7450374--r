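# Resampling, imputation, smoothing and ratio construction.
#
# The preprocessing chain is: raw event log -> uniform hourly or daily bins
# (glucose averaged, insulin/carbs summed) -> cubic-spline imputation of
# missing hourly glucose -> trailing 48-hour moving average -> bolus- and
# basal-to-carbohydrate ratios computed from the smoothed series (never from
# raw narrow bins, where zero carbohydrate would blow the ratio up).

bin_hours <- function(bin_width) switch(bin_width, hour = 1L, day = 24L,
  stop("unsupported bin_width: ", bin_width, " (use 'hour' or 'day')"))

#' Resample an event log into uniform time bins
#'
#' Assigns every record to its containing bin (half-open
#' `[start, start + width)`, assignment by timestamp truncation so a 23:59
#' dose stays in its calendar day).  Within a bin, glucose measurements
#' (SMBG and CGM pooled) are averaged, insulin and carbohydrate entries are
#' summed.  Bins with no glucose sample carry `bg_mean = NA`; bins with no
#' insulin/carb entries get sum 0, since the streams are event logs where
#' absence of an entry means no intake.
#'
#' @param log An [event_log()].
#' @param bin_width `"hour"` or `"day"`.
#' @return A `binned_series`: a `data.frame` with columns `bin_start`
#'   (POSIXct), `bg_mean`, `bolus_sum`, `basal_sum`, `carb_sum`, `n_bg`,
#'   `bg_imputed`, plus attributes `bin_width` and `patient_id`.  Bins are
#'   contiguous and cover the log's whole span.
#' @export
resample <- function(log, bin_width = c("day", "hour")) {
  stopifnot(inherits(log, "event_log"))
  bin_width <- match.arg(bin_width)
  hrs <- bin_hours(bin_width)

  if (all(is.na(log$span))) {
    out <- data.frame(bin_start = parse_ts(character()), bg_mean = numeric(),
                      bolus_sum = numeric(), basal_sum = numeric(),
                      carb_sum = numeric(), n_bg = integer(),
                      bg_imputed = logical())
    return(structure(out, bin_width = bin_width, patient_id = log$patient_id,
                     class = c("binned_series", "data.frame")))
  }

  day0 <- as.POSIXct(paste(log$span[1], "00:00"), tz = "UTC")
  n_days <- as.integer(log$span[2] - log$span[1]) + 1L
  n_bins <- n_days * 24L %/% hrs
  starts <- day0 + (seq_len(n_bins) - 1L) * hrs * 3600

  idx_of <- function(ts) {
    i <- as.integer(floor(as.numeric(ts - day0, units = "hours") / hrs)) + 1L
    i[i < 1L | i > n_bins] <- NA_integer_
    i
  }
  sum_by <- function(ts, val) {
    out <- numeric(n_bins)
    i <- idx_of(ts)
    ok <- !is.na(i)
    if (any(ok)) {
      agg <- rowsum(val[ok], i[ok])
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }

  gi <- idx_of(log$glucose$timestamp)
  bg_mean <- rep(NA_real_, n_bins)
  n_bg <- integer(n_bins)
  ok <- !is.na(gi)
  if (any(ok)) {
    s <- rowsum(log$glucose$value[ok], gi[ok])
    cnt <- rowsum(rep(1L, sum(ok)), gi[ok])
    j <- as.integer(rownames(s))
    bg_mean[j] <- s[, 1] / cnt[, 1]
    n_bg[j] <- cnt[, 1]
  }

  bolus <- log$insulin[log$insulin$kind == "bolus", , drop = FALSE]
  basal <- log$insulin[log$insulin$kind == "basal", , drop = FALSE]
  out <- data.frame(
    bin_start = starts,
    bg_mean = bg_mean,
    bolus_sum = sum_by(bolus$timestamp, bolus$units),
    basal_sum = sum_by(basal$timestamp, basal$units),
    carb_sum = sum_by(log$carbs$timestamp, log$carbs$grams),
    n_bg = n_bg,
    bg_imputed = FALSE)
  structure(out, bin_width = bin_width, patient_id = log$patient_id,
            class = c("binned_series", "data.frame"))
}

#' Impute missing hourly glucose by cubic-spline interpolation
#'
#' Interior gaps in the hourly `bg_mean` series are filled with a cubic
#' spline over the non-missing bins (bin index as abscissa); leading and
#' trailing gaps, where a spline would extrapolate, are filled with the
#' nearest observed value.  Imputed bins are flagged in `bg_imputed`.
#' Insulin and carbohydrate sums are never imputed.
#'
#' @param series An hourly `binned_series`.
#' @return The series with `bg_mean` complete and `bg_imputed` set.
#' @export
impute_bg <- function(series) {
  stopifnot(inherits(series, "binned_series"))
  if (attr(series, "bin_width") != "hour")
    stop("impute_bg expects an hourly series; daily series need no imputation")
  known <- which(!is.na(series$bg_mean))
  if (length(known) < 4)
    stop("fewer than 4 non-missing glucose bins; use daily bins or supply more data")
  gaps <- which(is.na(series$bg_mean))
  if (!length(gaps)) return(series)

  interior <- gaps[gaps > min(known) & gaps < max(known)]
  if (length(interior)) {
    fit <- stats::spline(x = known, y = series$bg_mean[known],
                         xout = interior, method = "fmm")
    series$bg_mean[interior] <- fit$y
  }
  lead <- gaps[gaps < min(known)]
  if (length(lead)) series$bg_mean[lead] <- series$bg_mean[min(known)]
  trail <- gaps[gaps > max(known)]
  if (length(trail)) series$bg_mean[trail] <- series$bg_mean[max(known)]
  series$bg_imputed[gaps] <- TRUE
  series
}

# Trailing mean of the last N values (window shortened at the head), with
# missing values simply excluded from the window average.
roll_trailing_mean <- function(x, N) {
  n <- length(x)
  if (!n) return(numeric())
  val <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cs <- cumsum(val)
  cc <- cumsum(cnt)
  lag <- function(v) c(rep(0, min(N, n)), v)[seq_len(n)]
  s <- cs - lag(cs)
  k <- cc - lag(cc)
  out <- ifelse(k > 0, s / k, NA_real_)
  out
}

#' Smooth a binned series with a trailing moving average
#'
#' Applies a trailing (causal) moving-average filter to blood glucose,
#' bolus, basal and carbohydrate: the output at bin *t* is the mean of bins
#' `max(1, t-N+1) .. t`, where `N = window_hours / bin width`.  Windows at
#' the head of the series are shortened so the output has the same length as
#' the input.  A 2-day (48-hour) window removes fast timescale features
#' while keeping the delay it introduces acceptable for timely detection.
#' The insulin-to-carbohydrate ratios are then derived from the smoothed
#' series by [ratio_series()].
#'
#' @param series A `binned_series`; hourly series should be imputed first.
#' @param window_hours Window length in hours (default 48); must be a
#'   positive integer multiple of the bin width.
#' @return A `smoothed_series`: `data.frame` with columns `bin_start`, `bg`,
#'   `bolus`, `basal`, `carbs`, `ratio_bolus`, `ratio_basal`,
#'   `ratio_defined`, and attributes `bin_width`, `window_hours`,
#'   `window_bins`, `patient_id`.
#' @export
moving_average <- function(series, window_hours = 48) {
  stopifnot(inherits(series, "binned_series"))
  hrs <- bin_hours(attr(series, "bin_width"))
  if (window_hours < hrs)
    stop("window (", window_hours, " h) is smaller than the bin width (", hrs, " h)")
  if (window_hours %% hrs != 0)
    stop("window must be an integer multiple of the bin width")
  N <- as.integer(window_hours / hrs)

  out <- data.frame(
    bin_start = series$bin_start,
    bg = roll_trailing_mean(series$bg_mean, N),
    bolus = roll_trailing_mean(series$bolus_sum, N),
    basal = roll_trailing_mean(series$basal_sum, N),
    carbs = roll_trailing_mean(series$carb_sum, N),
    ratio_bolus = NA_real_,
    ratio_basal = NA_real_,
    ratio_defined = FALSE)
  out <- structure(out, bin_width = attr(series, "bin_width"),
                   window_hours = window_hours, window_bins = N,
                   patient_id = attr(series, "patient_id"),
                   class = c("smoothed_series", "data.frame"))
  ratio_series(out)
}

#' Derive insulin-to-carbohydrate ratios from a smoothed series
#'
#' `ratio_bolus = bolus / carbs` (U/g) wherever the smoothed carbohydrate is
#' strictly positive, and undefined (`NA`, `ratio_defined = FALSE`)
#' elsewhere; `ratio_basal` analogously.  Computing the ratio after
#' smoothing avoids the division blow-ups that raw narrow bins with zero
#' carbohydrate would cause: the function never emits an infinity or NaN.
#'
#' @param smoothed A `smoothed_series` with populated `bolus`/`basal`/`carbs`.
#' @return The series with ratio columns filled in.
#' @export
ratio_series <- function(smoothed) {
  stopifnot(inherits(smoothed, "smoothed_series"))
  ok <- !is.na(smoothed$carbs) & smoothed$carbs > 0
  smoothed$ratio_bolus <- ifelse(ok & !is.na(smoothed$bolus),
                                 smoothed$bolus / smoothed$carbs, NA_real_)
  smoothed$ratio_basal <- ifelse(ok & !is.na(smoothed$basal),
                                 smoothed$basal / smoothed$carbs, NA_real_)
  smoothed$ratio_defined <- ok & !is.na(smoothed$bolus)
  stopifnot(all(is.finite(smoothed$ratio_bolus) | is.na(smoothed$ratio_bolus)),
            all(is.finite(smoothed$ratio_basal) | is.na(smoothed$ratio_basal)))
  smoothed
}

#' Export a binned or smoothed series as tidy CSV
#'
#' @param x A `binned_series` or `smoothed_series`.
#' @param path Output CSV file.
#' @param force Overwrite an existing file?
#' @return `x`, invisibly.
#' @export
write_series <- function(x, path, force = FALSE) {
  if (!force && file.exists(path))
    stop(path, " exists; use force = TRUE to overwrite")
  out <- as.data.frame(x)
  out$bin_start <- format_ts(out$bin_start)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(x)
}

# Calendar dates of a series' bins.
series_dates <- function(x) as.Date(x$bin_start, tz = "UTC")
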