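test_that("bin aggregation averages glucose and sums insulin/carbs", {
  log <- event_log("p", glucose = data.frame(
    timestamp = ts_utc(c("2021-03-01 08:10", "2021-03-01 08:40")),
    value = c(100, 120), source = c("SMBG", "CGM")),
    insulin = data.frame(
      timestamp = ts_utc(c("2021-03-01 08:05", "2021-03-01 08:55")),
      units = c(2.0, 3.5), kind = "bolus"))
  b <- resample(log, "hour")
  i <- which(!is.na(b$bg_mean))
  expect_equal(b$bg_mean[i], 110)
  expect_equal(b$n_bg[i], 2L)
  expect_equal(b$bolus_sum[i], 5.5)
  expect_equal(sum(b$carb_sum), 0)
})

test_that("daily bin totals match a brute-force scan of the raw log", {
  sim <- default_episode_sim(seed = 3)
  daily <- resample(sim$log, "day")
  day <- as.Date("2021-06-15")
  in_day <- function(ts) as.Date(ts, tz = "UTC") == day
  i <- which(as.Date(daily$bin_start, tz = "UTC") == day)
  bolus <- sim$log$insulin[sim$log$insulin$kind == "bolus", ]
  expect_equal(daily$bolus_sum[i], sum(bolus$units[in_day(bolus$timestamp)]))
  expect_equal(daily$basal_sum[i],
               sum(sim$log$insulin$units[sim$log$insulin$kind == "basal" &
                                           in_day(sim$log$insulin$timestamp)]))
  expect_equal(daily$carb_sum[i],
               sum(sim$log$carbs$grams[in_day(sim$log$carbs$timestamp)]))
  g <- sim$log$glucose$value[in_day(sim$log$glucose$timestamp)]
  expect_equal(daily$bg_mean[i], mean(g))
})

test_that("resampling conserves stream totals (mass conservation)", {
  sim <- default_episode_sim(seed = 5)
  daily <- resample(sim$log, "day")
  hourly <- resample(sim$log, "hour")
  for (b in list(daily, hourly)) {
    expect_equal(sum(b$bolus_sum),
                 sum(sim$log$insulin$units[sim$log$insulin$kind == "bolus"]))
    expect_equal(sum(b$basal_sum),
                 sum(sim$log$insulin$units[sim$log$insulin$kind == "basal"]))
    expect_equal(sum(b$carb_sum), sum(sim$log$carbs$grams))
  }
})

test_that("imputation is the identity without gaps and exact on symmetric data", {
  b <- make_binned(bg = rep(120, 24))
  expect_equal(impute_bg(b), b)
  bg <- rep(120, 24); bg[10] <- NA
  out <- impute_bg(make_binned(bg = bg))
  expect_equal(out$bg_mean[10], 120)
  expect_true(out$bg_imputed[10])
  expect_error(impute_bg(make_binned(bg = c(1, NA, NA, NA, NA, 2))), "4")
  expect_error(impute_bg(make_binned(bg = rep(120, 5), bin_width = "day")),
               "hourly")
})

test_that("spline imputation error on a masked smooth series stays below the noise SD", {
  set.seed(91)
  n <- 24 * 28
  noise_sd <- 8
  truth <- 130 + 25 * sin(2 * pi * seq_len(n) / 24) + 0.02 * seq_len(n)
  bg <- truth + rnorm(n, 0, noise_sd)
  maes <- sapply(1:4, function(k) {
    mask <- sample(10:(n - 10), round(0.1 * n))
    bg_masked <- bg; bg_masked[mask] <- NA
    out <- impute_bg(make_binned(bg = bg_masked))
    expect_true(all(out$bg_imputed[mask]))
    mean(abs(out$bg_mean[mask] - truth[mask]))
  })
  expect_lt(mean(maes), noise_sd)
})

test_that("trailing moving average matches its definition", {
  # constants are fixed points
  b <- make_binned(bg = rep(7, 10), bolus = rep(2, 10), carbs = rep(50, 10))
  sm <- moving_average(b, 48)
  expect_equal(sm$bg, rep(7, 10))
  expect_equal(sm$bolus, rep(2, 10))
  # head shortening with a 2-bin daily window
  b2 <- make_binned(bg = c(100, 120), carbs = c(10, 20), bin_width = "day")
  sm2 <- moving_average(b2, 48)
  expect_equal(sm2$bg, c(100, 110))
  expect_equal(sm2$carbs, c(10, 15))
  # brute-force oracle on 1000 random bins
  set.seed(7)
  x <- runif(1000, 50, 300)
  N <- 48L
  oracle <- vapply(seq_along(x), function(t) mean(x[max(1, t - N + 1):t]),
                   numeric(1))
  sm3 <- moving_average(make_binned(bg = x), 48)
  expect_equal(sm3$bg, oracle, tolerance = 1e-12)
  expect_error(moving_average(make_binned(bg = x, bin_width = "day"), 12),
               "smaller")
  expect_error(moving_average(make_binned(bg = x), 36.5), "multiple")
})

test_that("smoothing is causal and shift-equivariant", {
  set.seed(8)
  x <- runif(200, 80, 200)
  base <- moving_average(make_binned(bg = x), 48)
  # perturbing a future bin never changes earlier smoothed values
  x2 <- x; x2[150] <- x2[150] + 500
  pert <- moving_average(make_binned(bg = x2), 48)
  expect_equal(pert$bg[1:149], base$bg[1:149])
  expect_false(isTRUE(all.equal(pert$bg[150], base$bg[150])))
  # adding a constant to every bin adds it to every smoothed value
  shift <- moving_average(make_binned(bg = x + 37), 48)
  expect_equal(shift$bg, base$bg + 37, tolerance = 1e-12)
})

test_that("ratios come from the smoothed series and are never non-finite", {
  b <- make_binned(bg = rep(120, 5), bolus = rep(20, 5), carbs = rep(200, 5),
                   bin_width = "day")
  sm <- moving_average(b, 24)
  expect_equal(sm$ratio_bolus, rep(0.10, 5))
  expect_true(all(sm$ratio_bolus >= 0.05 & sm$ratio_bolus <= 0.2))
  # zero smoothed carbohydrate leaves the ratio undefined, flagged, finite
  b0 <- make_binned(bg = rep(120, 3), bolus = c(5, 0, 0), carbs = c(0, 0, 0),
                    bin_width = "day")
  sm0 <- moving_average(b0, 48)
  expect_true(all(is.na(sm0$ratio_bolus)))
  expect_false(any(sm0$ratio_defined))
  expect_false(any(is.infinite(sm0$ratio_bolus)))
  sim <- default_episode_sim(seed = 13)
  smy <- moving_average(resample(sim$log, "day"))
  expect_true(all(is.finite(smy$ratio_bolus) | is.na(smy$ratio_bolus)))
})
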