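test_that("plug-in bandwidth is near the asymptotic optimum for Gaussian data", {
  set.seed(1234)
  x <- rnorm(10000)
  h <- isj_bandwidth(x)
  ref <- 1.06 * sd(x) * 10000^(-1 / 5)
  expect_lt(abs(h - ref) / ref, 0.15)
})

test_that("bandwidth selectors are scale-equivariant and translation-invariant", {
  set.seed(99)
  x <- rnorm(2000)
  h <- isj_bandwidth(x)
  expect_equal(isj_bandwidth(5.5 * x), 5.5 * h, tolerance = 1e-8)
  expect_equal(isj_bandwidth(x + 1000), h, tolerance = 1e-8)
  y <- rexp(2000)
  hb <- rot_bandwidth_2d(x, y)
  hb2 <- rot_bandwidth_2d(3 * x, y)
  expect_equal(hb2[1], 3 * hb[1], tolerance = 1e-12)
  expect_equal(hb2[2], hb[2], tolerance = 1e-12)
})

test_that("plug-in selector undersmooths a well-separated mixture relative to the normal rule", {
  set.seed(55)
  x <- c(rnorm(2500, -10), rnorm(2500, 10))
  expect_lt(isj_bandwidth(x), 1.06 * sd(x) * 5000^(-1 / 5))
})

test_that("degenerate or tiny samples are rejected", {
  expect_error(isj_bandwidth(rep(1, 100)), "zero variance")
  expect_error(isj_bandwidth(rnorm(10)), "50")
  expect_error(rot_bandwidth_2d(rnorm(5), rnorm(5)), "20")
  # perfectly correlated pairs still give finite positive bandwidths
  set.seed(2); z <- rnorm(100)
  h <- rot_bandwidth_2d(z, z)
  expect_true(all(is.finite(h) & h > 0))
})

test_that("a single kernel reproduces the Gaussian curve", {
  grid <- seq(-4, 4, length.out = 200)
  est <- adaptive_kde_1d(0, bandwidth = 1, grid = grid, adaptive = FALSE)
  expect_equal(est$density, dnorm(grid), tolerance = 1e-12)
  est2 <- adaptive_kde_2d(0, 0, c(1, 1), grid_x = grid, grid_y = grid,
                          adaptive = FALSE)
  expect_equal(est2$density, outer(dnorm(grid), dnorm(grid)),
               tolerance = 1e-12)
})

test_that("non-adaptive estimates equal the brute-force kernel sums pointwise", {
  set.seed(31)
  x <- rnorm(50, 0.12, 0.03)
  h <- 0.01
  est <- adaptive_kde_1d(x, h, adaptive = FALSE)
  oracle <- sapply(est$grid, function(g) sum(dnorm(g, x, h)) / length(x))
  expect_equal(est$density, oracle, tolerance = 1e-10)
  expect_true(all(est$local_factors == 1))

  y <- rnorm(50, 130, 15)
  est2 <- adaptive_kde_2d(y, x, c(5, 0.01), adaptive = FALSE)
  oracle2 <- matrix(0, length(est2$grid_x), length(est2$grid_y))
  for (i in seq_along(est2$grid_x))
    for (j in seq_along(est2$grid_y))
      oracle2[i, j] <- sum(dnorm(est2$grid_x[i], y, 5) *
                             dnorm(est2$grid_y[j], x, 0.01)) / 50
  expect_equal(est2$density, oracle2, tolerance = 1e-8)
})

test_that("every estimate normalizes on its grid, adaptively or not", {
  trap1 <- function(e) sum(diff(e$grid) *
                             (head(e$density, -1) + tail(e$density, -1)) / 2)
  set.seed(77)
  for (adaptive in c(TRUE, FALSE)) {
    x <- c(rnorm(120, 0.12, 0.02), rnorm(30, 0.35, 0.08))
    e <- adaptive_kde_1d(x, isj_bandwidth(x), adaptive = adaptive)
    expect_true(all(e$density >= 0))
    expect_gte(trap1(e), 0.99); expect_lte(trap1(e), 1.01)

    y <- rnorm(150, 130, 15)
    e2 <- adaptive_kde_2d(y, x, rot_bandwidth_2d(y, x), adaptive = adaptive)
    dx <- diff(e2$grid_x[1:2]); dy <- diff(e2$grid_y[1:2])
    m <- e2$density
    wx <- rep(1, nrow(m)); wx[c(1, nrow(m))] <- 0.5
    wy <- rep(1, ncol(m)); wy[c(1, ncol(m))] <- 0.5
    tot <- as.numeric(wx %*% m %*% wy) * dx * dy
    expect_true(all(m >= 0))
    expect_gte(tot, 0.98); expect_lte(tot, 1.02)
  }
})

test_that("density quantiles track the sample", {
  set.seed(12)
  x <- rnorm(5000)
  e <- adaptive_kde_1d(x, isj_bandwidth(x), adaptive = FALSE)
  expect_equal(density_quantile(e, 0.5), median(x), tolerance = 0.05)
  expect_equal(density_quantile(e, 0.99), quantile(x, 0.99)[[1]],
               tolerance = 0.15)
})

test_that("self-comparison yields only the definitional tail", {
  sim <- generate_patient_year(sim_config(seed = 41))
  sm <- moving_average(resample(sim$log, "day"))
  cmp <- compare_densities(sm, sim$log$infections)
  expect_equal(cmp$excess_tail_mass, 0.01, tolerance = 0.01)
  expect_lte(cmp$max_observed, max(sm$ratio_bolus, na.rm = TRUE))
  expect_equal(cmp$n_baseline, cmp$n_full)
})

test_that("an infection year shows excess tail mass beyond the baseline support", {
  sim <- default_episode_sim(seed = 43)
  sm <- moving_average(resample(sim$log, "day"))
  cmp <- compare_densities(sm, sim$log$infections)
  expect_gte(cmp$excess_tail_mass, 0.02)
  expect_gt(cmp$max_observed, cmp$baseline_support_hi)
  # baseline sample is exactly the full sample minus the infection days
  d <- as.Date(sm$bin_start, tz = "UTC")
  n_inf_defined <- sum(!is.na(sm$ratio_bolus) &
                         d %in% infection_days(sim$log$infections))
  expect_equal(cmp$n_full - cmp$n_baseline, n_inf_defined)
})

test_that("removing a random healthy week is indistinguishable from self-comparison", {
  tails <- sapply(1:8, function(s) {
    sim <- generate_patient_year(sim_config(seed = 300 + s))
    sm <- moving_average(resample(sim$log, "day"))
    self <- compare_densities(sm, sim$log$infections)$excess_tail_mass
    fake <- data.frame(onset = as.Date("2021-01-04") + 30 + 10 * s,
                       duration_days = 7L, label = "control")
    ctrl <- compare_densities(sm, fake)$excess_tail_mass
    c(self = self, ctrl = ctrl)
  })
  expect_lt(abs(mean(tails["ctrl", ]) - mean(tails["self", ])), 0.01)
})
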