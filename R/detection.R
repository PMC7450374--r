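# Prototype "microevent" (individual infection) detector.
#
# Novelty-detection branch of a personalized detection system: the smoothed
# daily bolus-to-carbohydrate ratio is scored against a personalized
# baseline density fitted on infection-free days, and an alarm-management
# rule turns scores into the three-state status normal (0), suspicious (-1)
# and infected (1).  Crisp thresholds with a 2-day persistence rule stand in
# for the sketched fuzzy-logic alarm stage, whose membership functions are
# not specified anywhere; the thresholds were tuned once on held-out
# simulation seeds and frozen.

#' Default detector thresholds on the ratio-tail score
#'
#' `c(suspicious, infected)`; see [classify_status()].
#' @export
DEFAULT_THRESHOLDS <- c(suspicious = 0.08, infected = 0.20)

#' Anomaly score of a smoothed series against a baseline ratio density
#'
#' Two scoring bases are available.  `ratio_tail` measures relative
#' exceedance of the baseline's 99th percentile `q99`:
#' `score_t = max(0, (ratio_t - q99) / q99)`.  `density_loglik` is the
#' negative log baseline density at the observed ratio, shifted so the
#' baseline median scores 0.  Bins with an undefined ratio carry the
#' previous score forward and are flagged in `carried`.
#'
#' @param smoothed A daily `smoothed_series`.
#' @param baseline A `density_estimate_1d` fitted on infection-free ratio
#'   values (training period, or the baseline of [compare_densities()]).
#' @param basis `"ratio_tail"` (default) or `"density_loglik"`.
#' @return An `anomaly_score` data.frame: `date`, `score` (nonnegative for
#'   `ratio_tail`, finite for both), `carried`; attribute `basis`.
#' @export
anomaly_score <- function(smoothed, baseline,
                          basis = c("ratio_tail", "density_loglik")) {
  stopifnot(inherits(smoothed, "smoothed_series"),
            inherits(baseline, "density_estimate_1d"))
  basis <- match.arg(basis)
  r <- smoothed$ratio_bolus
  if (basis == "ratio_tail") {
    q99 <- density_quantile(baseline, 0.99)
    raw <- pmax(0, (r - q99) / q99)
  } else {
    dens_at <- function(v) {
      f <- stats::approx(baseline$grid, baseline$density, xout = v,
                         rule = 2)$y
      pmax(f, .Machine$double.xmin)
    }
    med <- density_quantile(baseline, 0.5)
    raw <- -log(dens_at(r)) + log(dens_at(med))
  }
  score <- numeric(length(r))
  carried <- is.na(raw)
  prev <- 0
  for (i in seq_along(raw)) {
    if (is.na(raw[i])) score[i] <- prev else prev <- score[i] <- raw[i]
  }
  structure(data.frame(date = series_dates(smoothed), score = score,
                       carried = carried),
            basis = basis, class = c("anomaly_score", "data.frame"))
}

#' Classify daily anomaly scores into alarm statuses
#'
#' Status 1 (infected) requires the score to reach the `infected` threshold
#' on at least 2 consecutive days (persistence rule — a single spiking day
#' is only suspicious); otherwise status is -1 (suspicious) when the score
#' reaches the `suspicious` threshold, and 0 (normal) below it.
#'
#' @param scores An `anomaly_score` (or numeric vector).
#' @param thresholds `c(suspicious, infected)` with
#'   `0 < suspicious < infected`; default [DEFAULT_THRESHOLDS].
#' @return A `status_series` data.frame: `date` (if available), `score`,
#'   `status` in \{0, -1, 1\}.
#' @export
classify_status <- function(scores, thresholds = DEFAULT_THRESHOLDS) {
  if (!(length(thresholds) == 2 && thresholds[1] > 0 &&
        thresholds[1] < thresholds[2]))
    stop("thresholds must satisfy 0 < suspicious < infected")
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  hot <- s >= thresholds[2]
  runs <- rle(hot)
  persistent <- rep(runs$values & runs$lengths >= 2, runs$lengths)
  status <- ifelse(persistent, 1L, ifelse(s >= thresholds[1], -1L, 0L))
  out <- data.frame(score = s, status = status)
  if (is.data.frame(scores) && !is.null(scores$date))
    out <- cbind(date = scores$date, out)
  structure(out, thresholds = thresholds,
            class = c("status_series", "data.frame"))
}

#' Evaluate a status series against simulator ground truth
#'
#' @param status A `status_series` (daily).
#' @param truth A `ground_truth` data.frame of the same length.
#' @return A `detection_metrics` list: `sensitivity` (fraction of true
#'   infection days flagged 1), `false_positive_rate` (fraction of
#'   non-infection days flagged 1), `latency_days` (first flagged day minus
#'   first onset; `NA` when never flagged or no episode), `n_days`.
#' @export
evaluate_detection <- function(status, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (nrow(status) != nrow(truth))
    stop("status and truth must cover the same days")
  flagged <- status$status == 1L
  pos <- truth$infected
  sens <- if (any(pos)) mean(flagged[pos]) else NA_real_
  fpr <- if (any(!pos)) mean(flagged[!pos]) else NA_real_
  latency <- NA_real_
  if (any(pos) && any(flagged)) {
    onset <- which(pos)[1]
    latency <- which(flagged)[1] - onset
  }
  structure(list(sensitivity = sens, false_positive_rate = fpr,
                 latency_days = latency, n_days = nrow(truth)),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    "<detection_metrics> sensitivity %.3f | FPR %.3f | latency %s d | %d days\n",
    x$sensitivity, x$false_positive_rate,
    ifelse(is.na(x$latency_days), "NA", format(x$latency_days)), x$n_days))
  invisible(x)
}

#' Run the detector end to end on one patient-year
#'
#' Convenience wrapper: daily resampling, 48-hour smoothing, baseline
#' density on infection-free days (per the reported episodes in
#' `log$infections`, or a supplied training series), scoring and
#' classification.
#'
#' @param log An [event_log()].
#' @param thresholds Passed to [classify_status()].
#' @param basis Passed to [anomaly_score()].
#' @return A list: `scores`, `status`, `baseline` (the
#'   `density_estimate_1d`), `smoothed`.
#' @export
detect_microevents <- function(log, thresholds = DEFAULT_THRESHOLDS,
                               basis = "ratio_tail") {
  smoothed <- moving_average(resample(log, "day"))
  d <- series_dates(smoothed)
  excl <- infection_days(log$infections)
  base_ratio <- smoothed$ratio_bolus[!(d %in% excl)]
  base_ratio <- base_ratio[!is.na(base_ratio)]
  if (length(base_ratio) < 50)
    stop("fewer than 50 infection-free days to fit the baseline")
  baseline <- adaptive_kde_1d(base_ratio, isj_bandwidth(base_ratio))
  scores <- anomaly_score(smoothed, baseline, basis = basis)
  status <- classify_status(scores, thresholds)
  list(scores = scores, status = status, baseline = baseline,
       smoothed = smoothed)
}
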