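#' glucodetect: infection-induced deviations in self-recorded type 1 diabetes data
#'
#' Tools to import self-recorded diabetes event logs (blood glucose, insulin,
#' carbohydrate, self-reported infections), resample and smooth them, quantify
#' the weekly deviations an acute infection induces on blood glucose dynamics,
#' compare full-year and infection-excluded distributions of the
#' insulin-to-carbohydrate ratio with adaptive kernel density estimation, and
#' prototype a per-individual infection detector.  A seeded behavioral
#' simulator generates realistic patient-years so the whole pipeline is
#' testable without access to private patient data.
#'
#' @keywords internal
"_PACKAGE"

# ---- constants -------------------------------------------------------------

#' Plausibility limits for blood glucose records (mg/dL)
#'
#' Records outside this range are treated as device artifacts and dropped at
#' import, mirroring the hard limits of common CGM devices.
#' @export
GLUCOSE_PLAUSIBLE_RANGE <- c(20, 600)

.TS_FORMAT <- "%Y-%m-%d %H:%M"

# Timestamps are minute-precision local clock time; they are stored in a
# fixed zone (UTC) so that no DST arithmetic is ever applied.
parse_ts <- function(x) {
  as.POSIXct(x, format = .TS_FORMAT, tz = "UTC")
}

format_ts <- function(x) {
  format(x, format = .TS_FORMAT, tz = "UTC")
}

# ---- constructors ----------------------------------------------------------

empty_glucose <- function() {
  data.frame(timestamp = parse_ts(character()), value = numeric(),
             source = character(), stringsAsFactors = FALSE)
}
empty_insulin <- function() {
  data.frame(timestamp = parse_ts(character()), units = numeric(),
             kind = character(), stringsAsFactors = FALSE)
}
empty_carbs <- function() {
  data.frame(timestamp = parse_ts(character()), grams = numeric(),
             stringsAsFactors = FALSE)
}
empty_infections <- function() {
  data.frame(onset = as.Date(character()), duration_days = integer(),
             label = character(), stringsAsFactors = FALSE)
}

#' Construct an event log for one patient-year
#'
#' An event log bundles the raw timestamped self-recorded streams of one
#' patient over a contiguous span of days: blood glucose samples (SMBG
#' finger-pricks and/or CGM, mg/dL), insulin doses (bolus/basal, units),
#' carbohydrate intakes (grams) and self-reported infection episodes.
#'
#' @param patient_id Opaque patient identifier.
#' @param glucose `data.frame` with columns `timestamp` (POSIXct), `value`
#'   (mg/dL) and `source` (`"SMBG"` or `"CGM"`).
#' @param insulin `data.frame` with columns `timestamp`, `units` (U, >= 0) and
#'   `kind` (`"bolus"` or `"basal"`).
#' @param carbs `data.frame` with columns `timestamp` and `grams` (>= 0).
#' @param infections `data.frame` with columns `onset` (Date),
#'   `duration_days` (integer >= 1) and `label` (free text).
#' @param span Length-2 `Date` vector, first and last day covered.  Derived
#'   from the records when `NULL`.
#' @param validation Optional list of validation counters (see
#'   [read_event_log()]).
#'
#' @return An object of class `event_log`.
#' @export
event_log <- function(patient_id, glucose = empty_glucose(),
                      insulin = empty_insulin(), carbs = empty_carbs(),
                      infections = empty_infections(), span = NULL,
                      validation = list()) {
  glucose <- glucose[order(glucose$timestamp), , drop = FALSE]
  insulin <- insulin[order(insulin$timestamp), , drop = FALSE]
  carbs <- carbs[order(carbs$timestamp), , drop = FALSE]
  if (nrow(infections)) infections <- infections[order(infections$onset), , drop = FALSE]
  rownames(glucose) <- rownames(insulin) <- rownames(carbs) <- NULL
  rownames(infections) <- NULL
  if (is.null(span)) {
    all_ts <- c(glucose$timestamp, insulin$timestamp, carbs$timestamp)
    span <- if (length(all_ts)) {
      as.Date(range(all_ts), tz = "UTC")
    } else {
      as.Date(c(NA, NA))
    }
  }
  log <- structure(
    list(patient_id = as.character(patient_id), glucose = glucose,
         insulin = insulin, carbs = carbs, infections = infections,
         span = as.Date(span), validation = validation),
    class = "event_log")
  validate_event_log(log)
  log
}

#' Validate an event log against its structural invariants
#'
#' Checks plausibility of glucose values, non-negativity of insulin and
#' carbohydrate amounts, non-overlap of infection episodes, that record
#' timestamps fall within the declared span, and that all streams are sorted.
#' Validation never mutates values; import-time cleaning lives in
#' [read_event_log()].
#'
#' @param log An `event_log`.
#' @return `log`, invisibly.  Errors on violation.
#' @export
validate_event_log <- function(log) {
  stopifnot(inherits(log, "event_log"))
  g <- log$glucose
  if (nrow(g)) {
    if (any(g$value < GLUCOSE_PLAUSIBLE_RANGE[1] | g$value > GLUCOSE_PLAUSIBLE_RANGE[2]))
      stop("glucose values outside plausibility range [",
           GLUCOSE_PLAUSIBLE_RANGE[1], ", ", GLUCOSE_PLAUSIBLE_RANGE[2], "] mg/dL")
    if (!all(g$source %in% c("SMBG", "CGM")))
      stop("glucose source must be 'SMBG' or 'CGM'")
    if (is.unsorted(g$timestamp)) stop("glucose stream not sorted")
  }
  if (nrow(log$insulin)) {
    if (any(log$insulin$units < 0)) stop("insulin units must be >= 0")
    if (!all(log$insulin$kind %in% c("bolus", "basal")))
      stop("insulin kind must be 'bolus' or 'basal'")
    if (is.unsorted(log$insulin$timestamp)) stop("insulin stream not sorted")
  }
  if (nrow(log$carbs)) {
    if (any(log$carbs$grams < 0)) stop("carbohydrate grams must be >= 0")
    if (is.unsorted(log$carbs$timestamp)) stop("carbohydrate stream not sorted")
  }
  inf <- log$infections
  if (nrow(inf)) {
    if (any(inf$duration_days < 1)) stop("infection duration_days must be >= 1")
    if (nrow(inf) > 1) {
      ends <- inf$onset + inf$duration_days - 1
      if (any(inf$onset[-1] <= ends[-nrow(inf)]))
        stop("infection episodes must not overlap")
    }
  }
  if (!all(is.na(log$span))) {
    for (stream in list(log$glucose, log$insulin, log$carbs)) {
      if (nrow(stream)) {
        d <- as.Date(stream$timestamp, tz = "UTC")
        if (any(d < log$span[1] | d > log$span[2]))
          stop("record timestamps fall outside the declared span")
      }
    }
  }
  invisible(log)
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> patient", x$patient_id, "\n")
  cat("  span:", format(x$span[1]), "to", format(x$span[2]), "\n")
  cat(sprintf("  glucose: %d samples | insulin: %d doses | carbs: %d intakes | infections: %d\n",
              nrow(x$glucose), nrow(x$insulin), nrow(x$carbs), nrow(x$infections)))
  if (length(x$validation) && any(unlist(x$validation) > 0)) {
    v <- x$validation
    cat("  validation:", paste(names(v), unlist(v), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- CSV input / output ----------------------------------------------------

#' Read an event log from CSV files
#'
#' Expects a directory holding `events.csv` (long format, columns
#' `patient_id`, `timestamp` in ISO 8601 minute precision, `stream` one of
#' `glucose`/`bolus`/`basal`/`carbs`, `value`, `unit`, `source`) and
#' optionally `infections.csv` (`patient_id`, `onset` ISO date,
#' `duration_days`, `label`).
#'
#' Rows violating plausibility gates are dropped and counted, never altered:
#' glucose outside [20, 600] mg/dL, negative insulin or carbohydrate amounts.
#' Zero-unit insulin doses are kept but counted.  Exact duplicate rows are
#' collapsed to one occurrence.  Rows with unparseable timestamps are
#' collected; more than 10% of such rows is a fatal format error.
#'
#' @param path Directory containing the CSV files.
#' @return An `event_log` whose `validation` element counts
#'   `implausible_glucose`, `negative_amount`, `zero_dose`, `duplicate_rows`
#'   and `bad_timestamp` rows.
#' @seealso [write_event_log()] for the inverse operation.
#' @export
read_event_log <- function(path) {
  events_file <- file.path(path, "events.csv")
  if (!file.exists(events_file)) stop("no events.csv under ", path)
  ev <- utils::read.csv(events_file, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("patient_id", "timestamp", "stream", "value", "unit", "source")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("events.csv is missing required column(s): ", paste(missing, collapse = ", "))
  ev$value <- as.numeric(ev$value)

  counts <- list(implausible_glucose = 0L, negative_amount = 0L,
                 zero_dose = 0L, duplicate_rows = 0L, bad_timestamp = 0L)

  if (nrow(ev)) {
    dup <- duplicated(ev)
    counts$duplicate_rows <- sum(dup)
    ev <- ev[!dup, , drop = FALSE]

    ts <- parse_ts(ev$timestamp)
    bad <- is.na(ts) & nzchar(ev$timestamp)
    counts$bad_timestamp <- sum(bad)
    if (counts$bad_timestamp > 0.1 * nrow(ev))
      stop("more than 10% of rows have unparseable timestamps")
    ev <- ev[!bad, , drop = FALSE]
    ev$ts <- ts[!bad]
  } else {
    ev$ts <- parse_ts(character())
  }

  take <- function(stream) ev[ev$stream %in% stream, , drop = FALSE]

  g <- take("glucose")
  if (nrow(g)) {
    implaus <- g$value < GLUCOSE_PLAUSIBLE_RANGE[1] | g$value > GLUCOSE_PLAUSIBLE_RANGE[2]
    counts$implausible_glucose <- sum(implaus)
    g <- g[!implaus, , drop = FALSE]
  }
  glucose <- data.frame(timestamp = g$ts, value = g$value,
                        source = if (nrow(g)) ifelse(g$source %in% c("SMBG", "CGM"),
                                                     g$source, "SMBG") else character(),
                        stringsAsFactors = FALSE)

  ins <- take(c("bolus", "basal"))
  if (nrow(ins)) {
    neg <- ins$value < 0
    counts$negative_amount <- counts$negative_amount + sum(neg)
    ins <- ins[!neg, , drop = FALSE]
    counts$zero_dose <- sum(ins$value == 0)
  }
  insulin <- data.frame(timestamp = ins$ts, units = ins$value,
                        kind = ins$stream, stringsAsFactors = FALSE)

  cb <- take("carbs")
  if (nrow(cb)) {
    neg <- cb$value < 0
    counts$negative_amount <- counts$negative_amount + sum(neg)
    cb <- cb[!neg, , drop = FALSE]
  }
  carbs <- data.frame(timestamp = cb$ts, grams = cb$value,
                      stringsAsFactors = FALSE)

  infections <- empty_infections()
  inf_file <- file.path(path, "infections.csv")
  if (file.exists(inf_file)) {
    infc <- utils::read.csv(inf_file, stringsAsFactors = FALSE)
    req_inf <- c("patient_id", "onset", "duration_days", "label")
    miss_inf <- setdiff(req_inf, names(infc))
    if (length(miss_inf))
      stop("infections.csv is missing required column(s): ",
           paste(miss_inf, collapse = ", "))
    if (nrow(infc))
      infections <- data.frame(onset = as.Date(infc$onset),
                               duration_days = as.integer(infc$duration_days),
                               label = as.character(infc$label),
                               stringsAsFactors = FALSE)
  }

  pid <- unique(c(ev$patient_id, if (exists("infc")) infc$patient_id))
  pid <- pid[!is.na(pid) & nzchar(pid)]
  if (length(pid) > 1) stop("events.csv mixes multiple patient_id values")
  if (length(pid) == 0) pid <- "unknown"

  span_file <- file.path(path, "span.csv")
  span <- NULL
  if (file.exists(span_file)) {
    sp <- utils::read.csv(span_file, stringsAsFactors = FALSE)
    span <- as.Date(c(sp$start[1], sp$end[1]))
  }

  event_log(pid, glucose, insulin, carbs, infections, span = span,
            validation = counts)
}

#' Write an event log to CSV files
#'
#' Writes `events.csv`, `infections.csv` and `span.csv` under `path` in the
#' dialect that [read_event_log()] consumes.  Timestamps are written at minute
#' precision, so a write/read round trip reproduces the log exactly.
#'
#' @param log An `event_log`.
#' @param path Output directory (created if needed).
#' @param force Overwrite existing files?  Default `FALSE`.
#' @return `log`, invisibly.
#' @export
write_event_log <- function(log, path, force = FALSE) {
  stopifnot(inherits(log, "event_log"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(path, c("events.csv", "infections.csv", "span.csv"))
  if (!force && any(file.exists(files)))
    stop("output files exist under ", path, "; use force = TRUE to overwrite")

  rows <- function(ts, stream, value, unit, source) {
    n <- length(ts)
    data.frame(patient_id = rep_len(log$patient_id, n),
               timestamp = format_ts(ts), stream = rep_len(stream, n),
               value = value, unit = rep_len(unit, n),
               source = rep_len(source, n), stringsAsFactors = FALSE)
  }
  ev <- rbind(
    rows(log$glucose$timestamp, "glucose", log$glucose$value, "mg/dL",
         log$glucose$source),
    rows(log$insulin$timestamp, log$insulin$kind, log$insulin$units, "U", ""),
    rows(log$carbs$timestamp, "carbs", log$carbs$grams, "g", ""))
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  utils::write.csv(ev, files[1], row.names = FALSE)

  inf <- log$infections
  utils::write.csv(
    data.frame(patient_id = rep(log$patient_id, nrow(inf)),
               onset = format(inf$onset), duration_days = inf$duration_days,
               label = inf$label, stringsAsFactors = FALSE),
    files[2], row.names = FALSE)
  utils::write.csv(data.frame(start = format(log$span[1]),
                              end = format(log$span[2])),
                   files[3], row.names = FALSE)
  invisible(log)
}

#' Days covered by an infection episode
#'
#' @param infections `data.frame` of infection episodes (or one row).
#' @return `Date` vector of all days belonging to any episode
#'   (onset .. onset + duration_days - 1).
#' @export
infection_days <- function(infections) {
  if (!nrow(infections)) return(as.Date(character()))
  out <- lapply(seq_len(nrow(infections)), function(i)
    seq(infections$onset[i], by = "day",
        length.out = infections$duration_days[i]))
  as.Date(unlist(out), origin = "1970-01-01")
}
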