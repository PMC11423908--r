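make_milk_study <- function(seed, dose = 2) {
  simulate_study(calibrate_defaults(dose), seed = seed, matrices = "milk")
}

test_that("time-point selection drops BLQ, honors exclusions, enforces the cap", {
  sim4 <- make_milk_study(3, dose = 4)
  # the 4 mg/kg arm is quantifiable at nine times (0.08-3 h)
  all_times <- sort(unique(sim4$data$data$time_h[!sim4$data$data$blq]))
  expect_equal(all_times, c(0.08, 0.17, 0.25, 0.5, 0.75, 1, 1.5, 2, 3))
  expect_error(select_wt_points(sim4$data, dose = 4), "exclude_times")
  pts <- select_wt_points(sim4$data, dose = 4,
                          exclude_times = c(0.17, 0.75))
  expect_equal(attr(pts, "times"), c(0.08, 0.25, 0.5, 1, 1.5, 2, 3))
  # the 2 mg/kg arm fits within seven times without exclusions
  sim2 <- make_milk_study(3, dose = 2)
  pts2 <- select_wt_points(sim2$data, dose = 2)
  expect_lte(length(attr(pts2, "times")), 7L)
  # fully censored data is an explicit error
  rows <- study_rows("S1", 2, "milk", c(0.25, 0.5, 1),
                     c(NA, NA, NA), blq = rep(TRUE, 3))
  ds <- study_dataset(rows, design = "parallel")
  expect_error(select_wt_points(ds, dose = 2), "no quantifiable")
})

test_that("the pooled regression matches the closed-form normal equations", {
  # exact line: perfect fit, zero residual SD
  t <- rep(c(0.5, 1, 2), each = 2)
  y <- 1 - 0.5 * t
  reg <- fit_wt_regression(t, y)
  expect_equal(reg$slope, -0.5, tolerance = 1e-12)
  expect_equal(reg$intercept, 1, tolerance = 1e-12)
  expect_equal(reg$s, 0, tolerance = 1e-9)
  # random points against the normal-equations oracle
  set.seed(7)
  t <- runif(20, 0, 4); y <- 0.8 - 1.1 * t + rnorm(20, 0, 0.3)
  reg <- fit_wt_regression(t, y)
  sxx <- sum((t - mean(t))^2)
  b <- sum((t - mean(t)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(t)
  expect_equal(reg$slope, b, tolerance = 1e-12)
  expect_equal(reg$intercept, a, tolerance = 1e-12)
  expect_equal(reg$s_xx, sxx, tolerance = 1e-12)
  expect_equal(reg$s, sqrt(sum((y - a - b * t)^2) / 18), tolerance = 1e-12)
  expect_equal(reg$df, 18L)
  # duplicating every point leaves the slope alone and doubles s_xx
  reg2 <- fit_wt_regression(c(t, t), c(y, y))
  expect_equal(reg2$slope, reg$slope, tolerance = 1e-12)
  expect_equal(reg2$s_xx, 2 * reg$s_xx, tolerance = 1e-12)
  expect_error(fit_wt_regression(rep(1, 5), rnorm(5)), "variance")
})

test_that("the tolerance factor behaves as the noncentral-t construction", {
  # central symmetry: at p = conf = 1/2 the factor vanishes
  expect_equal(tolerance_factor(10, d = 0.2, p = 0.5, conf = 0.5), 0,
               tolerance = 1e-10)
  # strictly increasing in the leverage d
  d <- seq(0.05, 2, length.out = 40)
  k <- tolerance_factor(18, d, 0.95, 0.95)
  expect_true(all(diff(k) > 0))
  # direct formula evaluation
  expect_equal(tolerance_factor(18, 0.3, 0.95, 0.95),
               sqrt(0.3) * qt(0.95, 18, ncp = qnorm(0.95) / sqrt(0.3)),
               tolerance = 1e-12)
  expect_error(tolerance_factor(0, 0.3), "df")
})

test_that("upper tolerance limits match a brute-force evaluation", {
  set.seed(12)
  t <- runif(24, 0, 3); y <- -1 - 0.9 * t + rnorm(24, 0, 0.25)
  reg <- fit_wt_regression(t, y)
  x0 <- c(0, 0.7, 2.5, 6)
  got <- reg$intercept + reg$slope * x0 +
    tolerance_factor(reg$df, 1 / reg$n + (x0 - reg$x_bar)^2 / reg$s_xx,
                     0.95, 0.95) * reg$s
  # brute force from first principles
  n <- 24; xb <- mean(t); sxx <- sum((t - xb)^2)
  b <- sum((t - xb) * (y - mean(y))) / sxx; a <- mean(y) - b * xb
  s <- sqrt(sum((y - a - b * t)^2) / (n - 2))
  for (i in seq_along(x0)) {
    dd <- 1 / n + (x0[i] - xb)^2 / sxx
    brute <- a + b * x0[i] + sqrt(dd) * qt(0.95, n - 2,
                                           ncp = qnorm(0.95) / sqrt(dd)) * s
    expect_equal(got[i], brute, tolerance = 1e-10)
  }
  # the margin is positive at the mean time whenever s > 0 and p > 1/2
  at_mean <- reg$intercept + reg$slope * reg$x_bar
  lim <- at_mean + tolerance_factor(reg$df, 1 / reg$n, 0.95, 0.95) * reg$s
  expect_gt(lim, at_mean)
})

test_that("withdrawal estimates agree with a dense grid scan of the limit", {
  set.seed(21)
  sim <- make_milk_study(21)
  fit <- wt_fit(sim$data, dose = 2)
  reg <- fit$regression
  tg <- seq(0, fit$t_max_search, by = 1e-4)
  U <- reg$intercept + reg$slope * tg +
    tolerance_factor(reg$df, 1 / reg$n + (tg - reg$x_bar)^2 / reg$s_xx,
                     0.95, 0.95) * reg$s
  grid_wt <- max(tg[U >= fit$cutoff])
  expect_equal(fit$wt_estimate, grid_wt, tolerance = 2e-4)
})

test_that("the reporting rule rounds fractional hours up, whole hours not", {
  expect_equal(wt_round_up(2.99), 3)
  expect_equal(wt_round_up(3.87), 4)
  expect_equal(wt_round_up(3), 3)
  expect_equal(wt_round_up(0), 0)
  # configurable granularity, e.g. a 12 h milking interval
  expect_equal(wt_round_up(3.87, to = 12), 12)
  expect_equal(wt_round_up(24, to = 12), 24)
})

test_that("scaling the concentrations or lowering the MRL never shortens the WT", {
  sim <- make_milk_study(8)
  fit <- wt_fit(sim$data, dose = 2)
  # multiply all concentrations by 3 (intercept shift of ln 3)
  up <- sim$data$data
  up$conc_ug_ml <- up$conc_ug_ml * 3
  ds_up <- study_dataset(up, lloq = sim$data$lloq, design = "parallel")
  fit_up <- wt_fit(ds_up, dose = 2)
  expect_gte(fit_up$wt_estimate, fit$wt_estimate)
  # halving the MRL cannot shorten the WT either
  fit_low <- wt_fit(sim$data, dose = 2, mrl = 25)
  expect_gte(fit_low$wt_estimate, fit$wt_estimate)
  fit_high <- wt_fit(sim$data, dose = 2, mrl = 100)
  expect_lte(fit_high$wt_estimate, fit$wt_estimate)
})

test_that("as residual spread vanishes the WT tends to the line crossing", {
  # noise-free simulated milk: pooled points still mix the Bateman rise and
  # fall, so use a pure log-linear decline built by hand
  t <- rep(c(0.25, 0.5, 1, 1.5, 2), each = 3)
  conc <- 0.4 * exp(-1.2 * t)
  rows <- do.call(rbind, lapply(1:3, function(i)
    study_rows(paste0("S", i), 2, "milk", unique(t),
               0.4 * exp(-1.2 * unique(t)))))
  ds <- study_dataset(rows, lloq = 1e-6, design = "parallel")
  fit <- wt_fit(ds, dose = 2, mrl = 50)
  crossing <- (log(0.05) - log(0.4)) / (-1.2)
  expect_equal(fit$wt_estimate, crossing, tolerance = 1e-4)
  expect_equal(fit$wt_reported, ceiling(crossing))
})

test_that("degenerate targets are caught: rising slopes and short windows", {
  rows <- do.call(rbind, lapply(1:3, function(i)
    study_rows(paste0("S", i), 2, "milk", c(0.25, 0.5, 1),
               c(0.05, 0.1, 0.2) * i)))
  ds <- study_dataset(rows, lloq = 1e-6, design = "parallel")
  expect_error(wt_fit(ds, dose = 2), "non-negative")
  sim <- make_milk_study(4)
  expect_error(wt_fit(sim$data, dose = 2, t_max_search = 0.3),
               "t_max_search")
})

test_that("the 95/95 limit attains nominal coverage for several sample sizes", {
  # Monte-Carlo oracle: the limit must exceed the true 95th percentile of an
  # individual observation in ~95% of replicates, for small and large n
  cov10 <- tolerance_coverage(n = 10, reps = 4000, seed = 101)
  cov56 <- tolerance_coverage(n = 56, reps = 4000, seed = 102)
  expect_lt(abs(cov10 - 0.95), 0.015)
  expect_lt(abs(cov56 - 0.95), 0.015)
})
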