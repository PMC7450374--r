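test_that("week summaries reduce to the obvious statistics on toy weeks", {
  # seven identical days: zero variance
  b <- make_binned(bg = rep(130, 7), bolus = rep(25, 7), carbs = rep(200, 7),
                   bin_width = "day")
  w <- summarize_week(b, as.Date("2021-03-01"))
  expect_equal(c(w$bg_mean, w$bolus_mean, w$carb_mean), c(130, 25, 200))
  expect_equal(c(w$bg_sd, w$bolus_sd, w$carb_sd), c(0, 0, 0))
  expect_true(is.na(w$basal_mean))
  expect_equal(w$n_days, 7L)
  # two-day toy week, sample SD (n-1)
  b2 <- make_binned(bg = c(100, 120), bin_width = "day")
  w2 <- summarize_week(b2, as.Date("2021-03-01"), min_days = 2)
  expect_equal(w2$bg_mean, 110)
  expect_equal(w2$bg_sd, 14.142, tolerance = 1e-4)
  expect_error(summarize_week(b2, as.Date("2021-03-01")), "covered")
})

test_that("week summaries are permutation-invariant over days", {
  set.seed(21)
  bg <- runif(7, 100, 180); bolus <- runif(7, 15, 40); carbs <- runif(7, 120, 260)
  p <- sample(7)
  w1 <- summarize_week(make_binned(bg, bolus = bolus, carbs = carbs,
                                   bin_width = "day"), as.Date("2021-03-01"))
  w2 <- summarize_week(make_binned(bg[p], bolus = bolus[p], carbs = carbs[p],
                                   bin_width = "day"), as.Date("2021-03-01"))
  for (f in c("bg_mean", "bg_sd", "bolus_mean", "bolus_sd", "carb_mean",
              "carb_sd"))
    expect_equal(w1[[f]], w2[[f]])
})

test_that("a synthetic week summary matches brute-force recomputation from raw events", {
  sim <- default_episode_sim(seed = 17)
  daily <- resample(sim$log, "day")
  start <- as.Date("2021-04-05")
  w <- summarize_week(daily, start)
  days <- start + 0:6
  daily_stat <- sapply(days, function(dd) {
    pick <- function(ts) as.Date(ts, tz = "UTC") == dd
    bolus <- sim$log$insulin[sim$log$insulin$kind == "bolus", ]
    c(bg = mean(sim$log$glucose$value[pick(sim$log$glucose$timestamp)]),
      bolus = sum(bolus$units[pick(bolus$timestamp)]),
      carbs = sum(sim$log$carbs$grams[pick(sim$log$carbs$timestamp)]))
  })
  expect_equal(w$bg_mean, mean(daily_stat["bg", ]))
  expect_equal(w$bg_sd, sd(daily_stat["bg", ]))
  expect_equal(w$bolus_mean, mean(daily_stat["bolus", ]))
  expect_equal(w$carb_sd, sd(daily_stat["carbs", ]))
})

test_that("percent_change follows the reference-week-denominator convention", {
  expect_equal(percent_change(141.95, 130.74, "increase"), 8.57,
               tolerance = 0.001)
  expect_equal(percent_change(178.80, 241.11, "reduction"), 25.84,
               tolerance = 0.001)
  expect_equal(percent_change(55, 55, "increase"), 0)
  expect_equal(percent_change(55, 55, "reduction"), 0)
  expect_error(percent_change(10, 0, "increase"), "reference")
  # scale invariance
  expect_equal(percent_change(3 * 141.95, 3 * 130.74, "increase"),
               percent_change(141.95, 130.74, "increase"))
})

test_that("case_report recovers injected infection-week shifts", {
  onset <- as.Date("2021-03-15")
  log <- make_flat_log(days = 28, shift_days = onset + 0:6,
                       bg_mult = 1.10, bolus_mult = 1.45, carbs_mult = 0.80,
                       infections = data.frame(onset = onset,
                                               duration_days = 7L,
                                               label = "flu"))
  rep <- case_report(log, 1)
  get <- function(p, col) rep[rep$parameter == p, col]
  expect_equal(get("bg", "pct_vs_pre"), 10, tolerance = 0.01)
  expect_equal(get("bolus", "pct_vs_pre"), 45, tolerance = 0.01)
  expect_equal(get("carbs", "pct_vs_pre"), 20, tolerance = 0.01)
  expect_equal(get("bg", "pct_vs_post"), 10, tolerance = 0.01)
  # identical flanks: all percentages zero
  flat <- make_flat_log(days = 28,
                        infections = data.frame(onset = onset,
                                                duration_days = 7L,
                                                label = "flu"))
  rep0 <- case_report(flat, 1)
  expect_equal(rep0$pct_vs_pre, rep(0, nrow(rep0)))
  expect_equal(rep0$pct_vs_post, rep(0, nrow(rep0)))
  # insufficient span
  expect_error(case_report(make_flat_log(days = 10,
    infections = data.frame(onset = as.Date("2021-03-05"),
                            duration_days = 7L, label = "flu")), 1), "span")
})

test_that("reference-case week means reproduce the printed percentages", {
  w <- reference_case_weeks(2)
  rep <- case_report_from_summaries(w$pre, w$infection, w$post, "case2")
  expect_equal(rep$pct_vs_pre[rep$parameter == "bg"], 8.64, tolerance = 0.02)
  # the pump-using fifth case carries basal and total insulin, no carbs
  w5 <- reference_case_weeks(5)
  rep5 <- case_report_from_summaries(w5$pre, w5$infection, w5$post, "case5")
  expect_setequal(rep5$parameter, c("bg", "bolus", "basal", "total_insulin"))
  expect_equal(rep5$pct_vs_pre[rep5$parameter == "bolus"], 23.08,
               tolerance = 0.02)
})

test_that("ratio_shift measures elevation over the yearly operating point", {
  # flat year at the operating point: zero shift
  sm <- make_smoothed(rep(0.12, 100))
  inf <- data.frame(onset = as.Date("2021-04-10"), duration_days = 7L,
                    label = "flu")
  expect_equal(ratio_shift(sm, inf), 0)
  # baseline 0.12, infection week at 0.27: +125%
  r <- rep(0.12, 100)
  onset_idx <- as.integer(inf$onset - as.Date("2021-03-01")) + 1
  r[onset_idx + 0:6] <- 0.27
  expect_equal(ratio_shift(make_smoothed(r), inf), 125, tolerance = 2)
  # undefined on too many infection days
  r_na <- r; r_na[onset_idx + 0:5] <- NA
  expect_error(ratio_shift(make_smoothed(r_na), inf), "undefined")
})

test_that("cross-case aggregation is the arithmetic mean of per-case percentages", {
  mk <- function(param, pre, post) data.frame(
    case_id = paste0("c", seq_along(pre)), parameter = param,
    pct_vs_pre = pre, pct_vs_post = post,
    direction = "increase", stringsAsFactors = FALSE)
  bg <- mk("bg", rep(NA_real_, 5), c(19.12, 23.13, 7.41, 16.43, 13.84))
  bg$pct_vs_pre <- c(8.57, 8.63, 5.25, 2.28, 3.45)
  agg <- aggregate_cases(bg)
  expect_equal(agg$mean_pct_vs_post, 15.986, tolerance = 1e-6)
  carbs <- mk("carbs", c(25.84, 15.25, 18.63, 16.09), rep(0, 4))
  expect_equal(aggregate_cases(carbs)$mean_pct_vs_pre, 18.9525,
               tolerance = 1e-6)
  one <- aggregate_cases(bg[1, ])
  expect_equal(one$mean_pct_vs_post, bg$pct_vs_post[1])
  expect_error(aggregate_cases(bg[0, ]), "no deviation")
})
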