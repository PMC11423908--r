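test_that("lambda_z is exact on noise-free log-linear data", {
  t <- 1:8
  p <- conc_profile("S1", 1, 2, "plasma", t, 10 * exp(-0.5 * t), lloq = 1e-9)
  fit <- fit_lambda_z(p)
  expect_true(fit$estimable)
  expect_equal(fit$lambda_z, 0.5, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(fit$t_last_used, 8)
  # t1/2 = ln(2)/lambda_z at the reported half-life
  expect_equal(pk_thalf(log(2) / 2.41), 2.41)
})

test_that("automatic window selection matches exhaustive enumeration", {
  set.seed(42)
  for (rep in 1:25) {
    t <- sort(c(0.25, runif(7, 0.5, 24)))
    conc <- 12 * exp(-0.4 * t) * exp(rnorm(8, 0, 0.15))
    conc[1] <- max(conc) + 1      # make Tmax unambiguous at the first point
    p <- conc_profile("S1", 1, 2, "plasma", t, conc, lloq = 1e-9)
    got <- fit_lambda_z(p)
    ora <- oracle_lambdaz(t, conc)
    expect_equal(got$lambda_z, ora$lambda, tolerance = 1e-8)
    expect_equal(got$n_points, ora$n)
    expect_equal(got$t_first_used, ora$t_first)
  }
})

test_that("too few usable points or a rising terminal phase is flagged", {
  p <- conc_profile("S1", 1, 2, "plasma", c(1, 2, 3), c(5, 4, 3), lloq = 1e-9)
  fit <- fit_lambda_z(p)   # only 2 points after Tmax
  expect_false(fit$estimable)
  rising <- conc_profile("S1", 1, 2, "plasma", 1:5, c(9, 1, 1.5, 2, 3),
                         lloq = 1e-9)
  expect_false(fit_lambda_z(rising)$estimable)
  # NCA still reports the observed quantities
  res <- nca(rising)
  expect_true(is.na(res$auc_inf) && is.na(res$cl_t))
  expect_equal(res$cmax, 9)
  expect_gt(res$auc_last, 0)
})

test_that("manual windows reproduce a requested published-style fit", {
  t <- c(0.5, 1, 2, 4, 8, 12)
  conc <- 10 * exp(-0.3 * t)
  p <- conc_profile("S1", 1, 2, "plasma", t, conc, lloq = 1e-9)
  fit <- fit_lambda_z(p, rule = "manual", t_start = 2, t_end = 12)
  expect_equal(fit$lambda_z, 0.3, tolerance = 1e-10)
  expect_equal(fit$n_points, 4L)
})

test_that("trapezoid rules give the closed-form single-interval areas", {
  rect <- conc_profile("S1", 1, 2, "plasma", c(1, 2), c(2, 2), lloq = 1e-9)
  expect_equal(unname(auc_aumc(rect, "linear")["auc_last"]), 2)
  logd <- conc_profile("S1", 1, 2, "plasma", c(1, 2), c(4, 2), lloq = 1e-9)
  expect_equal(unname(auc_aumc(logd, "linear_up_log_down")["auc_last"]),
               2 / log(2), tolerance = 1e-12)
  # rising interval falls back to the linear rule under log-down
  up <- conc_profile("S1", 1, 2, "plasma", c(1, 2), c(2, 4), lloq = 1e-9)
  expect_equal(unname(auc_aumc(up, "linear_up_log_down")["auc_last"]), 3)
})

test_that("dense mono-exponential integration matches the analytic integral", {
  lam <- log(2) / 2.41
  t <- seq(0.048, 48, length.out = 1000)
  p <- conc_profile("S1", 1, 2, "plasma", t, 13.3 * exp(-lam * t),
                    lloq = 1e-12)
  analytic <- 13.3 / lam * (1 - exp(-lam * 48))   # ∫_0^48 C0 e^(-λt) dt
  a <- auc_aumc(p, "linear", c0_policy = "back_extrapolate")
  expect_equal(unname(a["auc_last"]), analytic, tolerance = 1e-3)
  # and the log-down rule is exact for this curve
  al <- auc_aumc(p, "linear_up_log_down", c0_policy = "back_extrapolate")
  expect_equal(unname(al["auc_last"]), 13.3 / lam * (1 - exp(-lam * 48)),
               tolerance = 1e-10)
})

test_that("tail extrapolation and the printed-pair arithmetic agree", {
  # zero tail leaves the areas untouched
  v <- extrapolate_auc(5, 20, c_last = 0, t_last = 10, lambda_z = 0.3)
  expect_equal(unname(v), c(5, 20))
  # the reported 2 mg/kg pair: AUC_last 9.29 + 0.05/lambda_z ~ AUC_inf 9.46
  lam <- log(2) / 2.41
  v <- extrapolate_auc(9.29, 0, c_last = 0.05, t_last = 12, lambda_z = lam)
  expect_equal(round(unname(v["auc_inf"]), 1), 9.5)
  expect_equal(unname(v["auc_inf"]), 9.29 + 0.05 / lam, tolerance = 1e-12)
  # mono-exponential tail AUMC matches quadrature of t*C(t) on [t_last, inf)
  lam2 <- 0.25; C <- 1.7; tl <- 9
  quad <- stats::integrate(function(u) u * C * exp(-lam2 * (u - tl)), tl, Inf,
                           rel.tol = 1e-10)$value
  v2 <- extrapolate_auc(0, 0, c_last = C, t_last = tl, lambda_z = lam2)
  expect_equal(unname(v2["aumc_inf"]), quad, tolerance = 1e-3 * quad)
})

test_that("NCA recovers closed forms on dense bi-exponential truth", {
  for (dose in c(2, 4)) {
    pm <- calibrate_defaults(dose)$plasma_macro
    truth <- biexp_truth(pm, dose)
    p <- dense_profile(pm, dose, n = 1000, t_end = 48)
    # closed forms integrate from t = 0, so the time origin is reconstructed
    res <- nca(p, run_config(c0_policy = "back_extrapolate"))
    expect_equal(res$auc_inf, truth$auc, tolerance = 0.01)
    expect_equal(res$aumc_inf, truth$aumc, tolerance = 0.01)
    expect_equal(res$mrt_inf, truth$mrt, tolerance = 0.01)
    expect_equal(res$cl_t, truth$cl, tolerance = 0.01)
    expect_equal(res$v_dss, truth$vss, tolerance = 0.01)
    expect_equal(res$lambda_fit$lambda_z, truth$lambda_z, tolerance = 0.005)
    # extrapolated fraction equals the analytic tail beyond t_last
    tail <- pm[["A"]] / pm[["alpha"]] * exp(-pm[["alpha"]] * 48) +
      pm[["B"]] / pm[["beta"]] * exp(-pm[["beta"]] * 48)
    expect_equal(res$auc_extrap_pct, 100 * tail / truth$auc,
                 tolerance = 0.02)
  }
})

test_that("one-compartment closed forms hold on dense mono-exponential data", {
  lam <- 0.35; c0 <- 8; dose <- 2
  t <- seq(1e-4, 12 / lam, length.out = 2000)
  p <- conc_profile("S1", 1, dose, "plasma", t, c0 * exp(-lam * t),
                    lloq = 1e-12)
  res <- nca(p, run_config(c0_policy = "back_extrapolate"))
  expect_equal(res$mrt_inf, 1 / lam, tolerance = 0.005)
  expect_equal(res$v_dss, dose / c0, tolerance = 0.005)
})

test_that("c0 policies report the first sample or the ln-extrapolated origin", {
  t <- c(0.08, 0.17, 0.5)
  conc <- 10 * exp(-2 * t)
  p <- conc_profile("S1", 1, 2, "plasma", t, conc, lloq = 1e-9)
  expect_equal(nca(p, run_config(c0_policy = "first_observed"))$c0, conc[1])
  expect_equal(nca(p, run_config(c0_policy = "back_extrapolate"))$c0, 10,
               tolerance = 1e-10)
})

test_that("cmax ties break to the earliest time", {
  p <- conc_profile("S1", 1, 2, "milk", c(0.25, 0.5, 1), c(0.3, 0.3, 0.1),
                    lloq = 1e-9)
  res <- nca(p)
  expect_equal(res$tmax, 0.25)
  expect_equal(res$cmax, 0.3)
})

test_that("auc_last is conserved under collinear insertion and is monotone", {
  t <- c(1, 2, 4, 6)
  conc <- c(8, 6, 5, 1)
  base <- conc_profile("S1", 1, 2, "plasma", t, conc, lloq = 1e-9)
  a0 <- auc_aumc(base, "linear")[["auc_last"]]
  # insert the midpoint of the linear interpolant on (2, 4)
  t2 <- c(1, 2, 3, 4, 6); c2 <- c(8, 6, 5.5, 5, 1)
  ins <- conc_profile("S1", 1, 2, "plasma", t2, c2, lloq = 1e-9)
  expect_equal(auc_aumc(ins, "linear")[["auc_last"]], a0, tolerance = 1e-12)
  # raising any single concentration cannot decrease the area
  for (i in seq_along(conc)) {
    cc <- conc; cc[i] <- cc[i] + 0.5
    up <- conc_profile("S1", 1, 2, "plasma", t, cc, lloq = 1e-9)
    expect_gte(auc_aumc(up, "linear")[["auc_last"]], a0)
  }
})

test_that("geometric summaries follow the ratio-of-geomeans identities", {
  expect_equal(geomean(c(4, 9)), 6)
  expect_equal(geomean(5), 5)
  expect_error(geomean(c(1, -2)), "positive")
  set.seed(9)
  x <- rlnorm(12, 1, 0.4)
  dose <- 2
  expect_equal(geomean(dose / x), dose / geomean(x), tolerance = 1e-12)
  expect_equal(geomean(dose / x) * geomean(x), dose, tolerance = 1e-12)
})

test_that("summarize_nca uses geometric means except the median Tmax", {
  tab <- data.frame(matrix = "milk", dose = 2,
                    tmax = c(0.25, 0.25, 0.5, 0.75),
                    cmax = c(0.2, 0.25, 0.3, 0.35))
  s <- summarize_nca(tab, parameters = c("tmax", "cmax"))
  expect_equal(s$center[s$parameter == "tmax"], median(tab$tmax))
  expect_equal(s$summary[s$parameter == "tmax"], "median")
  expect_equal(s$center[s$parameter == "cmax"], geomean(tab$cmax))
  expect_true(all(s$min <= s$center & s$center <= s$max))
})
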