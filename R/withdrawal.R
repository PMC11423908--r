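#' Select pooled observations for the withdrawal-time regression
#'
#' Gathers all animals' quantifiable observations for one matrix and dose,
#' drops user-listed excluded times, and pools them as (time, ln conc) pairs.
#' When more distinct sampling times remain than `max_points` and no explicit
#' exclusion list was given, an error lists the candidate times, forcing the
#' analyst to choose which to drop (no selection heuristic is invented).
#'
#' @param dataset a [study_dataset()].
#' @param dose dose arm in mg/kg.
#' @param matrix `"milk"` (default) or `"plasma"`.
#' @param max_points maximum number of distinct times.
#' @param exclude_times sampling times (h) to drop; `NULL` means "none given".
#' @return a data frame with columns `subject`, `period`, `time`, `log_conc`;
#'   attribute `"times"` holds the distinct times used.
#' @export
select_wt_points <- function(dataset, dose, matrix = "milk",
                             max_points = 7L, exclude_times = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  d <- dataset$data
  d <- d[d$matrix == matrix & abs(d$dose_mg_kg - dose) < 1e-9 &
           d$time_h > 0 & !d$blq, , drop = FALSE]
  if (!nrow(d))
    stop(sprintf("no quantifiable %s observations at %g mg/kg", matrix, dose))
  if (!is.null(exclude_times) && length(exclude_times)) {
    keep <- !vapply(d$time_h,
                    function(t) any(abs(t - exclude_times) < 1e-9), logical(1))
    d <- d[keep, , drop = FALSE]
  }
  times <- sort(unique(d$time_h))
  if (length(times) > max_points && is.null(exclude_times))
    stop(sprintf(paste0(
      "%d distinct sampling times exceed the cap of %d; pass 'exclude_times' ",
      "to choose which to drop. Candidates: %s"),
      length(times), max_points, paste(times, collapse = ", ")))
  if (length(times) < 3L)
    stop("fewer than 3 distinct quantifiable times; cannot fit a depletion line")
  out <- data.frame(subject = d$subject, period = d$period, time = d$time_h,
                    log_conc = log(d$conc_ug_ml), stringsAsFactors = FALSE)
  attr(out, "times") <- times
  .milkwt_log("select_wt_points", n = nrow(out), n_times = length(times))
  out
}

#' Pooled log-linear depletion regression
#'
#' Ordinary least squares of ln(concentration) on time over all pooled
#' animal-time observations (replicates per time allowed), with the sufficient
#' statistics needed by the tolerance-limit construction.
#'
#' @param points data frame with columns `time` and `log_conc` (as produced by
#'   [select_wt_points()]), or numeric `time` with `log_conc` supplied.
#' @param log_conc optional vector when `points` is a numeric time vector.
#' @return an object of class `"wt_regression"`: `slope` (1/h), `intercept`
#'   (ln ug/mL), `s` (residual SD on the ln scale), `n`, `df = n - 2`,
#'   `x_bar`, `s_xx`, `times_used`, `n_animals`, plus `fitted` and
#'   `residuals`.
#' @export
fit_wt_regression <- function(points, log_conc = NULL) {
  if (is.numeric(points) && !is.null(log_conc))
    points <- data.frame(time = points, log_conc = log_conc)
  stopifnot(all(c("time", "log_conc") %in% names(points)))
  t <- points$time; y <- points$log_conc
  n <- length(t)
  if (n < 3L) stop("need at least 3 pooled points")
  if (length(unique(t)) < 2L) stop("zero variance in time")
  fit <- stats::lm(y ~ t)
  cf <- stats::coef(fit)
  s2 <- sum(stats::residuals(fit)^2) / (n - 2)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 s = sqrt(s2), n = n, df = n - 2L,
                 x_bar = mean(t), s_xx = sum((t - mean(t))^2),
                 times_used = sort(unique(t)),
                 n_animals = if (is.null(points$subject)) NA_integer_
                             else length(unique(points$subject)),
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit))),
            class = "wt_regression")
}

#' @export
print.wt_regression <- function(x, ...) {
  cat(sprintf("Pooled depletion regression: ln C = %.4g %+.4g t\n",
              x$intercept, x$slope))
  cat(sprintf("  n = %d (%s animals, %d times), s = %.4g, df = %d\n",
              x$n, ifelse(is.na(x$n_animals), "?", x$n_animals),
              length(x$times_used), x$s, x$df))
  invisible(x)
}

#' One-sided regression tolerance factor
#'
#' Factor `k` such that `fitted(x0) + k * s` is an upper (p, conf) tolerance
#' limit for an individual observation at `x0` in a simple linear regression:
#' `k = sqrt(d) * q`, where `d = 1/n + (x0 - x_bar)^2 / s_xx` is the leverage
#' and `q` the `conf` quantile of the noncentral t distribution with `df`
#' degrees of freedom and noncentrality `qnorm(p)/sqrt(d)`. This is the
#' standard construction behind "tolerance limit derived from the 95th
#' percentile with a confidence level of 95%" withdrawal-time software.
#'
#' @param df residual degrees of freedom (>= 1).
#' @param d leverage of the prediction point (> 0).
#' @param p percentile to be covered (fraction).
#' @param conf confidence level (fraction).
#' @return the scalar factor `k` (vectorized over `d`).
#' @export
tolerance_factor <- function(df, d, p = 0.95, conf = 0.95) {
  stopifnot(df >= 1, all(d > 0), p > 0, p < 1, conf > 0, conf < 1)
  k <- sqrt(d) * stats::qt(conf, df = df, ncp = stats::qnorm(p) / sqrt(d))
  if (any(!is.finite(k)))
    stop(sprintf("tolerance factor did not converge (df=%g, d=%s, p=%g, conf=%g)",
                 df, paste(signif(d, 4), collapse = ","), p, conf))
  k
}

# upper tolerance limit on the ln scale, vectorized over t
.wt_upper <- function(reg, t, p, conf) {
  d <- 1 / reg$n + (t - reg$x_bar)^2 / reg$s_xx
  reg$intercept + reg$slope * t +
    if (reg$s > 0) tolerance_factor(reg$df, d, p, conf) * reg$s else 0
}

#' Round a withdrawal-time estimate up to the reporting granularity
#'
#' Fractional estimates are rounded up to the next multiple of `to` (hours);
#' estimates already on the grid are reported unchanged (2.99 -> 3, 3.87 -> 4,
#' 3 -> 3 at `to = 1`).
#'
#' @param x estimate(s) in hours.
#' @param to reporting granularity in hours (1 = whole hours; e.g. 12 for a
#'   milking interval).
#' @return the reported value(s).
#' @export
wt_round_up <- function(x, to = 1) {
  stopifnot(to > 0)
  ceiling(x / to - 1e-9) * to
}

#' Fit the milk withdrawal-time model
#'
#' Pools all animals' quantifiable ln-concentrations for one matrix and dose,
#' fits the depletion line by ordinary least squares, and estimates the
#' withdrawal time (WT) as the last time at which the upper one-sided
#' (p, conf) tolerance limit of the regression still reaches the maximum
#' residue limit, i.e. the supremum of `{t : U(t) >= ln(MRL)}` located by a
#' grid scan plus bisection to 1e-6 h. The supremum definition guards against
#' a premature WT when the limit is non-monotone (leverage grows away from
#' the mean time). The reported WT rounds the estimate up to `round_to`.
#'
#' @param dataset a [study_dataset()].
#' @param dose dose arm in mg/kg.
#' @param matrix sampled matrix, default `"milk"`.
#' @param mrl maximum residue limit in ug/kg.
#' @param milk_density density (kg/L) converting the MRL to ug/mL
#'   (50 ug/kg -> 0.05 ug/mL at density 1).
#' @param p,conf percentile and confidence of the tolerance limit.
#' @param max_points,exclude_times passed to [select_wt_points()].
#' @param round_to reporting granularity in hours.
#' @param t_max_search upper end of the search window (h); default 4x the
#'   last time used. An error is raised if the limit has not fallen below the
#'   MRL by then.
#' @return an object of class `"wt_fit"` with the estimate, the reported
#'   (rounded) WT, the underlying [fit_wt_regression()] and the pooled data;
#'   supports `print`, `summary`, `coef`, `predict`, `plot`, `residuals`.
#' @examples
#' study <- simulate_crossover_study(seed = 1)
#' fit <- wt_fit(study$data, dose = 2)
#' fit
#' @export
wt_fit <- function(dataset, dose, matrix = "milk", mrl = 50,
                   milk_density = 1.0, p = 0.95, conf = 0.95,
                   max_points = 7L, exclude_times = NULL, round_to = 1,
                   t_max_search = NULL) {
  stopifnot(mrl > 0, milk_density > 0)
  points <- select_wt_points(dataset, dose = dose, matrix = matrix,
                             max_points = max_points,
                             exclude_times = exclude_times)
  reg <- fit_wt_regression(points)
  if (!is.finite(reg$slope) || reg$slope >= 0)
    stop("depletion slope is non-negative; withdrawal time not estimable")
  mrl_conc <- mrl * milk_density / 1000   # ug/kg * kg/L = ug/L -> ug/mL
  cutoff <- log(mrl_conc)
  if (is.null(t_max_search)) t_max_search <- 4 * max(reg$times_used)
  U <- function(t) .wt_upper(reg, t, p, conf)
  if (U(t_max_search) >= cutoff)
    stop(sprintf(paste0("tolerance limit still above the MRL at %g h; ",
                        "increase 't_max_search'"), t_max_search))
  grid <- seq(0, t_max_search, length.out = 2049L)
  above <- U(grid) >= cutoff
  if (!any(above)) {
    wt_est <- 0
  } else {
    i <- max(which(above))        # last grid point still at/above the MRL
    lo <- grid[i]; hi <- grid[i + 1L]
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (U(mid) >= cutoff) lo <- mid else hi <- mid
    }
    wt_est <- (lo + hi) / 2
  }
  out <- structure(list(wt_estimate = wt_est,
                        wt_reported = wt_round_up(wt_est, round_to),
                        mrl = mrl, mrl_conc = mrl_conc, p = p, conf = conf,
                        round_to = round_to, regression = reg, data = points,
                        dose = dose, matrix = matrix,
                        t_max_search = t_max_search, cutoff = cutoff),
                   class = "wt_fit")
  .milkwt_log("wt_fit", dose = dose, wt = wt_est)
  out
}

#' @export
print.wt_fit <- function(x, ...) {
  cat(sprintf("Withdrawal time, %s at %g mg/kg (MRL %g ug/kg = %g ug/mL):\n",
              x$matrix, x$dose, x$mrl, x$mrl_conc))
  cat(sprintf("  WT = %.2f h, reported %g h (%g%%ile, %g%% confidence)\n",
              x$wt_estimate, x$wt_reported, 100 * x$p, 100 * x$conf))
  invisible(x)
}

#' @export
summary.wt_fit <- function(object, ...) {
  print(object)
  print(object$regression)
  cat(sprintf("  times used (h): %s\n",
              paste(object$regression$times_used, collapse = ", ")))
  invisible(object)
}

#' @export
coef.wt_fit <- function(object, ...) {
  c(intercept = object$regression$intercept, slope = object$regression$slope)
}

#' @export
residuals.wt_fit <- function(object, ...) object$regression$residuals

#' Predicted depletion line and upper tolerance limit
#'
#' @param object a [wt_fit()].
#' @param times times (h) at which to evaluate; defaults to a fine grid over
#'   the search window.
#' @param scale `"conc"` (ug/mL) or `"log"` (ln ug/mL).
#' @param ... unused.
#' @return data frame with columns `time`, `fit`, `upper`.
#' @export
predict.wt_fit <- function(object, times = NULL, scale = c("conc", "log"),
                           ...) {
  scale <- match.arg(scale)
  if (is.null(times))
    times <- seq(0, object$t_max_search, length.out = 201L)
  reg <- object$regression
  fit <- reg$intercept + reg$slope * times
  up <- .wt_upper(reg, times, object$p, object$conf)
  if (scale == "conc") { fit <- exp(fit); up <- exp(up) }
  data.frame(time = times, fit = fit, upper = up)
}

#' Plot a withdrawal-time fit
#'
#' Pooled observations, fitted depletion line, upper tolerance limit, the MRL
#' cutoff and the estimated withdrawal time, on a semi-logarithmic scale.
#'
#' @param x a [wt_fit()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.wt_fit <- function(x, ...) {
  span <- max(x$regression$times_used)
  tmax <- min(x$t_max_search, max(1.5 * x$wt_estimate, 1.2 * span))
  pr <- predict(x, times = seq(0, tmax, length.out = 201L))
  ylim <- range(c(exp(x$data$log_conc), pr$upper, x$mrl_conc))
  graphics::plot(x$data$time, exp(x$data$log_conc), log = "y", ylim = ylim,
                 xlim = c(0, tmax), xlab = "Time (h)",
                 ylab = "Concentration (µg/mL)",
                 main = sprintf("%s withdrawal, %g mg/kg", x$matrix, x$dose),
                 ...)
  graphics::lines(pr$time, pr$fit, lwd = 2)
  graphics::lines(pr$time, pr$upper, lty = 2, lwd = 2, col = "red3")
  graphics::abline(h = x$mrl_conc, lty = 3)
  graphics::abline(v = x$wt_estimate, lty = 3, col = "red3")
  graphics::legend("topright", bty = "n", lty = c(1, 2, 3),
                   col = c("black", "red3", "black"),
                   legend = c("fitted line",
                              sprintf("%g/%g tolerance limit",
                                      100 * x$p, 100 * x$conf), "MRL"))
  invisible(x)
}

#' Monte-Carlo coverage of the regression tolerance limit
#'
#' Simulates `reps` regressions of a known straight line plus normal noise on
#' `n` equally spaced design points and reports the fraction of replicates in
#' which the upper (p, conf) tolerance limit at `x0` exceeds the true p-th
#' percentile of an individual observation at `x0`. By construction the
#' expected fraction equals `conf` for any line, noise SD, design or `x0`.
#'
#' @param n design points per replicate.
#' @param reps number of Monte-Carlo replicates.
#' @param p,conf tolerance limit settings.
#' @param x0 evaluation point; default 25% beyond the design range.
#' @param intercept,slope,sigma true line and noise SD.
#' @param seed optional seed.
#' @return the empirical coverage (scalar).
#' @export
tolerance_coverage <- function(n = 20, reps = 10000, p = 0.95, conf = 0.95,
                               x0 = NULL, intercept = 1, slope = -0.5,
                               sigma = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- seq(0, 1, length.out = n)
  if (is.null(x0)) x0 <- 1.25
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  y <- matrix(stats::rnorm(n * reps, sd = sigma), n, reps) +
    intercept + slope * x
  b <- colSums(xc * y) / sxx
  a <- colMeans(y) - b * mean(x)
  yhat <- outer(x, b) + matrix(a, n, reps, byrow = TRUE)
  s <- sqrt(colSums((y - yhat)^2) / (n - 2))
  d <- 1 / n + (x0 - mean(x))^2 / sxx
  k <- tolerance_factor(n - 2, d, p, conf)
  upper <- a + b * x0 + k * s
  true_q <- intercept + slope * x0 + stats::qnorm(p) * sigma
  mean(upper >= true_q)
}
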