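# Shared fixtures, all built in code.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# A fully deterministic log: each day one CGM sample per hour at a constant
# glucose, one bolus and one carb intake at noon.  `shift_days` (Date vector)
# get multiplicative shifts, for exact-arithmetic weekly tests.
make_flat_log <- function(days = 28, start = as.Date("2021-03-01"),
                          bg = 130, bolus = 25, carbs = 200,
                          shift_days = as.Date(character()),
                          bg_mult = 1, bolus_mult = 1, carbs_mult = 1,
                          infections = NULL) {
  dates <- start + seq_len(days) - 1
  shift <- dates %in% shift_days
  g_ts <- rep(as.POSIXct(paste(dates, "00:00"), tz = "UTC"), each = 24) +
    rep(0:23 * 3600, days)
  g_val <- rep(ifelse(shift, bg * bg_mult, bg), each = 24)
  noon <- as.POSIXct(paste(dates, "12:00"), tz = "UTC")
  log <- event_log(
    "flat",
    glucose = data.frame(timestamp = g_ts, value = g_val, source = "CGM",
                         stringsAsFactors = FALSE),
    insulin = data.frame(timestamp = noon,
                         units = ifelse(shift, bolus * bolus_mult, bolus),
                         kind = "bolus", stringsAsFactors = FALSE),
    carbs = data.frame(timestamp = noon,
                       grams = ifelse(shift, carbs * carbs_mult, carbs),
                       stringsAsFactors = FALSE),
    infections = if (is.null(infections)) empty_glu_infections() else infections,
    span = c(dates[1], dates[days]))
  log
}

empty_glu_infections <- function() {
  data.frame(onset = as.Date(character()), duration_days = integer(),
             label = character(), stringsAsFactors = FALSE)
}

# Construct a binned_series directly (shape as resample() emits), for
# oracle tests that need full control over bin values.
make_binned <- function(bg, bolus = rep(0, length(bg)),
                        basal = rep(0, length(bg)),
                        carbs = rep(0, length(bg)), bin_width = "hour",
                        start = ts_utc("2021-03-01 00:00")) {
  step <- if (bin_width == "hour") 3600 else 86400
  out <- data.frame(bin_start = start + (seq_along(bg) - 1) * step,
                    bg_mean = bg, bolus_sum = bolus, basal_sum = basal,
                    carb_sum = carbs,
                    n_bg = ifelse(is.na(bg), 0L, 1L), bg_imputed = FALSE)
  structure(out, bin_width = bin_width, patient_id = "synthetic",
            class = c("binned_series", "data.frame"))
}

make_smoothed <- function(ratio, bg = rep(130, length(ratio)),
                          start = ts_utc("2021-03-01 00:00")) {
  carbs <- rep(200, length(ratio))
  out <- data.frame(bin_start = start + (seq_along(ratio) - 1) * 86400,
                    bg = bg, bolus = ratio * carbs, basal = 0, carbs = carbs,
                    ratio_bolus = ratio, ratio_basal = 0,
                    ratio_defined = !is.na(ratio))
  structure(out, bin_width = "day", window_hours = 48, window_bins = 2L,
            patient_id = "synthetic",
            class = c("smoothed_series", "data.frame"))
}

default_episode_sim <- function(seed, onset_day = 150, ...) {
  generate_patient_year(sim_config(
    seed = seed, episodes = list(episode_config(onset_day = onset_day, ...))))
}
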