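# Seeded behavioral glucose-insulin simulator.
#
# A one-compartment hourly difference equation stands in for physiological
# ODE models: the pipeline needs realistic aggregate statistics (daily
# means/sums, weekly deviations, ratio distributions), not metabolic
# fidelity.  Per hour,
#
#   BG <- BG + k_c*CH - phi(t)*k_i*IN + EGP(t) - k_d*(BG - target) + noise
#
# where phi(t) is the insulin sensitivity factor (reduced during infection),
# EGP(t) the counterregulatory-hormone-driven extra hepatic glucose input,
# CH/IN the hour's carbohydrate and bolus insulin.  The constants are
# calibrated so that a no-episode year sits at the glycemic target with a
# daily bolus-to-carbohydrate ratio at the configured operating point:
# k_i = k_c / rho0 makes a rho0-dosed meal glucose-neutral, and k_d pulls
# BG back to target with a time constant of a few hours (the patient's own
# corrections, and basal action, are absorbed into this homeostatic term).
# Physical activity is fixed at zero: the emulated logs have no activity
# stream.

.K_CARB <- 2.0   # mg/dL per gram of carbohydrate
.K_DECAY <- 0.3  # per hour, relaxation toward target
.RAMP_ONSET <- 0.4   # episode intensity already present at symptom onset
.RAMP_OFFSET <- 0.3  # residual intensity on the last reported day
.DOSE_NOISE_SD <- 0.08  # lognormal sd of the patient's meal-dose estimate
.CGM_NOISE_SD <- 4      # mg/dL sensor noise
.SMBG_NOISE_SD <- 6     # mg/dL finger-prick noise

#' Configure an infection episode for the simulator
#'
#' Episode severity follows the two-sided hormonal mechanism of acute
#' infection: counterregulatory hormones raise hepatic glucose output
#' (`egp_boost`) and reduce insulin sensitivity (`sensitivity_drop` on the
#' factor phi), while the patient eats less (`appetite_drop`) and chases the
#' resistance with extra bolus insulin, but only partially
#' (`compensation` < 1) — which is exactly what produces the signature of
#' elevated glucose despite more insulin and fewer carbohydrates.  The
#' intensity ramp is piecewise linear: already at `r = 0.4` on the reported
#' onset day (glycemic effects precede and accompany first symptoms), rising
#' to its peak at mid-episode and decaying to `r = 0.3` on the last day.
#' Defaults are calibrated so that a default episode reproduces the
#' magnitudes observed in the reference infection cases (blood glucose
#' +2-20%, bolus +20-60%, carbohydrate -15-30% against the preinfection
#' week, smoothed ratio peaking in 0.3-0.6 U/g).
#'
#' @param onset_day 1-based day index of the reported onset.
#' @param duration_days Episode length in days (reference cases: 7-14).
#' @param sensitivity_drop Peak fractional drop of phi, in \[0, 1\].
#' @param egp_boost Peak extra hepatic glucose input, mg/dL per hour.
#' @param appetite_drop Peak fractional carbohydrate reduction, in \[0, 1\].
#' @param compensation Fraction of the extra insulin need the patient
#'   actually delivers, in \[0, 1\].
#' @param label Episode label.
#' @return An `episode_config` list.
#' @export
episode_config <- function(onset_day, duration_days = 10,
                           sensitivity_drop = 0.70, egp_boost = 6,
                           appetite_drop = 0.32, compensation = 0.85,
                           label = "flu") {
  stopifnot(duration_days >= 1,
            sensitivity_drop >= 0, sensitivity_drop < 1,
            appetite_drop >= 0, appetite_drop <= 1,
            compensation >= 0, compensation <= 1,
            egp_boost >= 0)
  structure(list(onset_day = as.integer(onset_day),
                 duration_days = as.integer(duration_days),
                 sensitivity_drop = sensitivity_drop, egp_boost = egp_boost,
                 appetite_drop = appetite_drop, compensation = compensation,
                 label = label),
            class = "episode_config")
}

# Piecewise-linear intensity profile of an episode over its days.
episode_ramp <- function(duration_days) {
  if (duration_days == 1) return(1)
  i <- seq_len(duration_days) - 1
  peak <- floor((duration_days - 1) / 2)
  rise <- .RAMP_ONSET + (1 - .RAMP_ONSET) * i / max(peak, 1)
  decay <- 1 - (1 - .RAMP_OFFSET) * (i - peak) / (duration_days - 1 - peak)
  ifelse(i <= peak, rise, decay)
}

#' Configure a simulated patient-year
#'
#' Defaults emulate the self-recorded data of a motivated adult with type 1
#' diabetes on a bolus/basal regimen: 3-5 carbohydrate-counted meals a day
#' totalling about 200 +/- 40 g, a bolus-to-carbohydrate operating point of
#' 0.12 U/g (normal band 0.05-0.2), hourly CGM with 5% dropout, and a
#' glycemic target of 125 mg/dL.
#'
#' @param days Simulated days (default 365).
#' @param seed RNG seed; identical seeds give byte-identical logs.
#' @param meals_per_day Integer range, default `c(3, 5)`.
#' @param daily_carbs_mean,daily_carbs_sd Daily carbohydrate total, g.
#' @param baseline_ratio Operating point rho0, U/g, in \[0.05, 0.2\].
#' @param basal_daily Daily basal dose, U (0 emulates pen users who do not
#'   log basal).
#' @param bg_target Glycemic target, mg/dL.
#' @param noise_sd Hourly glucose process noise, mg/dL.
#' @param cgm_interval CGM sampling interval, minutes.
#' @param missing_bg_rate CGM dropout probability per sample.
#' @param episodes List of [episode_config()] objects.
#' @return A `sim_config` list.
#' @export
sim_config <- function(days = 365, seed = 1, meals_per_day = c(3, 5),
                       daily_carbs_mean = 200, daily_carbs_sd = 40,
                       baseline_ratio = 0.12, basal_daily = 19,
                       bg_target = 125, noise_sd = 15, cgm_interval = 60,
                       missing_bg_rate = 0.05, episodes = list()) {
  stopifnot(days >= 1, baseline_ratio >= 0.05, baseline_ratio <= 0.2,
            daily_carbs_sd >= 0, noise_sd >= 0,
            missing_bg_rate >= 0, missing_bg_rate <= 1,
            cgm_interval >= 1, basal_daily >= 0)
  if (inherits(episodes, "episode_config")) episodes <- list(episodes)
  if (length(episodes)) {
    on <- vapply(episodes, `[[`, integer(1), "onset_day")
    dur <- vapply(episodes, `[[`, integer(1), "duration_days")
    if (any(on < 1) || any(on + dur - 1 > days))
      stop("episode out of the simulated range")
    o <- order(on)
    if (any(on[o][-1] <= (on + dur - 1)[o][-length(o)]))
      stop("episodes overlap")
  }
  structure(list(days = as.integer(days), seed = as.integer(seed),
                 meals_per_day = as.integer(meals_per_day),
                 daily_carbs_mean = daily_carbs_mean,
                 daily_carbs_sd = daily_carbs_sd,
                 baseline_ratio = baseline_ratio, basal_daily = basal_daily,
                 bg_target = bg_target, noise_sd = noise_sd,
                 cgm_interval = as.integer(cgm_interval),
                 missing_bg_rate = missing_bg_rate, episodes = episodes),
            class = "sim_config")
}

#' Simulate one patient-year of self-recorded diabetes data
#'
#' Generates a full event log (CGM and SMBG glucose, bolus and basal
#' insulin, carbohydrate intakes, self-reported infections) together with
#' the per-day ground truth of the infection mechanism, for evaluating every
#' pipeline stage without access to real patient data.
#'
#' @param config A [sim_config()].
#' @return A list with elements `log` (an [event_log()]) and `truth`
#'   (a `ground_truth` data.frame: `date`, `day`, `infected`, `ramp`,
#'   `phi`, `egp`, `intended_bolus`, `delivered_bolus`).
#' @export
generate_patient_year <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  D <- config$days
  rho0 <- config$baseline_ratio
  k_i <- .K_CARB / rho0
  day0 <- as.Date("2021-01-04")
  dates <- day0 + seq_len(D) - 1

  # per-day infection mechanism
  ramp <- numeric(D); infected <- logical(D)
  sens <- comp <- app <- egpb <- numeric(D)
  for (ep in config$episodes) {
    idx <- ep$onset_day + seq_len(ep$duration_days) - 1
    ramp[idx] <- episode_ramp(ep$duration_days)
    infected[idx] <- TRUE
    sens[idx] <- ep$sensitivity_drop
    comp[idx] <- ep$compensation
    app[idx] <- ep$appetite_drop
    egpb[idx] <- ep$egp_boost
  }
  phi <- 1 - sens * ramp
  egp <- egpb * ramp
  rho_eff <- rho0 * (1 + comp * (1 / phi - 1))
  rho_full <- rho0 / phi  # full-compensation dose rate

  # behavioral layer: meals, boluses, basal
  meal_ts <- parse_ts(character()); meal_g <- numeric()
  bolus_ts <- parse_ts(character()); bolus_u <- numeric()
  intended <- delivered <- numeric(D)
  meal_choices <- seq(config$meals_per_day[1], config$meals_per_day[2])
  for (d in seq_len(D)) {
    n_m <- meal_choices[sample.int(length(meal_choices), 1)]
    hours <- sort(sample(7:21, n_m))
    total <- max(stats::rnorm(1, config$daily_carbs_mean,
                              config$daily_carbs_sd), 50)
    total <- total * (1 - app[d] * ramp[d])
    shares <- stats::rgamma(n_m, shape = 4)
    grams <- total * shares / sum(shares)
    mins <- sample(0:59, n_m, replace = TRUE)
    ts <- as.POSIXct(paste(dates[d], sprintf("%02d:%02d", hours, mins)),
                     tz = "UTC")
    dose_noise <- exp(stats::rnorm(n_m, 0, .DOSE_NOISE_SD) -
                        .DOSE_NOISE_SD^2 / 2)
    units <- rho_eff[d] * grams * dose_noise
    meal_ts <- c(meal_ts, ts); meal_g <- c(meal_g, grams)
    bolus_ts <- c(bolus_ts, ts); bolus_u <- c(bolus_u, units)
    # intent = full chase of the resistance, with the same estimation error
    intended[d] <- rho_full[d] * sum(grams * dose_noise)
    delivered[d] <- sum(units)
  }

  # hourly glucose dynamics
  hour_of <- function(ts) as.integer(floor(
    as.numeric(ts - as.POSIXct(paste(day0, "00:00"), tz = "UTC"),
               units = "hours"))) + 1L
  n_h <- D * 24L
  ch <- numeric(n_h); agg <- rowsum(meal_g, hour_of(meal_ts))
  ch[as.integer(rownames(agg))] <- agg[, 1]
  inb <- numeric(n_h); agg <- rowsum(bolus_u, hour_of(bolus_ts))
  inb[as.integer(rownames(agg))] <- agg[, 1]
  eps <- stats::rnorm(n_h, 0, config$noise_sd)
  day_of_hour <- rep(seq_len(D), each = 24L)
  bg <- numeric(n_h)
  state <- config$bg_target
  for (t in seq_len(n_h)) {
    d <- day_of_hour[t]
    state <- state + .K_CARB * ch[t] - phi[d] * k_i * inb[t] + egp[d] -
      .K_DECAY * (state - config$bg_target) + eps[t]
    state <- min(max(state, 40), 500)
    bg[t] <- state
  }

  # sensor layer: CGM at the configured interval (+ dropout), 1 SMBG/day
  cgm_min <- seq(0, n_h * 60 - config$cgm_interval, by = config$cgm_interval)
  cgm_hr <- pmin(cgm_min %/% 60 + 1L, n_h)
  cgm_val <- round(bg[cgm_hr] + stats::rnorm(length(cgm_hr), 0, .CGM_NOISE_SD))
  keep <- stats::runif(length(cgm_val)) >= config$missing_bg_rate
  cgm_ts <- as.POSIXct(paste(day0, "00:00"), tz = "UTC") + cgm_min * 60
  smbg_hr <- (seq_len(D) - 1) * 24L + sample(7:22, D, replace = TRUE)
  smbg_val <- round(bg[smbg_hr] + stats::rnorm(D, 0, .SMBG_NOISE_SD))
  smbg_ts <- as.POSIXct(paste(day0, "00:00"), tz = "UTC") +
    (smbg_hr - 1) * 3600 + sample(0:59, D, replace = TRUE) * 60
  clamp <- function(v) pmin(pmax(v, 40), 450)
  glucose <- rbind(
    data.frame(timestamp = cgm_ts[keep], value = clamp(cgm_val[keep]),
               source = "CGM", stringsAsFactors = FALSE),
    data.frame(timestamp = smbg_ts, value = clamp(smbg_val),
               source = "SMBG", stringsAsFactors = FALSE))

  insulin <- data.frame(timestamp = bolus_ts, units = bolus_u,
                        kind = "bolus", stringsAsFactors = FALSE)
  if (config$basal_daily > 0) {
    basal_ts <- as.POSIXct(paste(dates, "08:00"), tz = "UTC")
    insulin <- rbind(insulin,
                     data.frame(timestamp = basal_ts,
                                units = config$basal_daily, kind = "basal",
                                stringsAsFactors = FALSE))
  }
  carbs <- data.frame(timestamp = meal_ts, grams = meal_g,
                      stringsAsFactors = FALSE)
  infections <- if (length(config$episodes)) {
    data.frame(onset = day0 + vapply(config$episodes, `[[`, integer(1),
                                     "onset_day") - 1,
               duration_days = vapply(config$episodes, `[[`, integer(1),
                                      "duration_days"),
               label = vapply(config$episodes, `[[`, character(1), "label"),
               stringsAsFactors = FALSE)
  } else empty_infections()

  log <- event_log(paste0("sim-", config$seed), glucose, insulin, carbs,
                   infections, span = c(dates[1], dates[D]))
  truth <- structure(
    data.frame(date = dates, day = seq_len(D), infected = infected,
               ramp = ramp, phi = phi, egp = egp,
               intended_bolus = intended, delivered_bolus = delivered),
    class = c("ground_truth", "data.frame"))
  list(log = log, truth = truth)
}
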