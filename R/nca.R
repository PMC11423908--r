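# ---- vector cores -----------------------------------------------------------

# Exhaustive scan of terminal windows ending at the last point.
# Candidate windows start strictly after Tmax and contain >= min_points
# points; the window maximizing adjusted R^2 of the ln(conc)-vs-time OLS line
# wins, ties within 1e-4 going to the window with more points.
.lambdaz_core <- function(t, c, min_points = 3L) {
  n <- length(t)
  imax <- which.max(c)[1]            # earliest time attaining the maximum
  first <- imax + 1L                 # strictly after Tmax
  if (n - first + 1L < min_points) return(NULL)
  starts <- first:(n - min_points + 1L)
  y <- log(c)
  rsum <- function(v) rev(cumsum(rev(v)))
  S1 <- rsum(rep(1, n)); St <- rsum(t); Sy <- rsum(y)
  Stt <- rsum(t * t); Syy <- rsum(y * y); Sty <- rsum(t * y)
  m <- S1[starts]
  sxx <- Stt[starts] - St[starts]^2 / m
  syy <- Syy[starts] - Sy[starts]^2 / m
  sxy <- Sty[starts] - St[starts] * Sy[starts] / m
  slope <- sxy / sxx
  r2 <- pmin(1, ifelse(syy > 0, sxy^2 / (sxx * syy), NA_real_))
  adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
  ok <- is.finite(adj) & slope < 0
  if (!any(ok)) return(NULL)
  best <- max(adj[ok])
  cand <- which(ok & adj >= best - 1e-4)
  j <- cand[which.max(m[cand])]
  list(lambda_z = -slope[j],
       intercept_ln = (Sy[starts[j]] - slope[j] * St[starts[j]]) / m[j],
       n_points = as.integer(m[j]),
       adj_r2 = adj[j],
       t_first_used = t[starts[j]],
       t_last_used = t[n])
}

.lambdaz_manual <- function(t, c, t_start, t_end) {
  keep <- t >= t_start - 1e-9 & t <= t_end + 1e-9
  if (sum(keep) < 2L) return(NULL)
  fit <- stats::lm.fit(cbind(1, t[keep]), log(c[keep]))
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0) return(NULL)
  r <- fit$residuals
  y <- log(c[keep])
  r2 <- 1 - sum(r^2) / sum((y - mean(y))^2)
  m <- sum(keep)
  list(lambda_z = unname(-slope), intercept_ln = unname(fit$coefficients[1]),
       n_points = as.integer(m),
       adj_r2 = if (m > 2) 1 - (1 - r2) * (m - 1) / (m - 2) else r2,
       t_first_used = min(t[keep]), t_last_used = max(t[keep]))
}

# trapezoidal AUC/AUMC over quantifiable points (no extrapolation)
.auc_aumc_core <- function(t, c, method = "linear") {
  n <- length(t)
  t1 <- t[-n]; t2 <- t[-1]; c1 <- c[-n]; c2 <- c[-1]
  dt <- t2 - t1
  auc <- dt * (c1 + c2) / 2
  aumc <- dt * (t1 * c1 + t2 * c2) / 2
  if (method == "linear_up_log_down") {
    dn <- c2 < c1 & c1 > 0 & c2 > 0
    if (any(dn)) {
      r <- log(c1[dn] / c2[dn])
      auc[dn] <- dt[dn] * (c1[dn] - c2[dn]) / r
      aumc[dn] <- dt[dn] * (t1[dn] * c1[dn] - t2[dn] * c2[dn]) / r +
        dt[dn]^2 * (c1[dn] - c2[dn]) / r^2
    }
  }
  c(auc = sum(auc), aumc = sum(aumc))
}

.back_extrapolate_c0 <- function(t, c) {
  # ln-linear extrapolation to t = 0 through the first two quantifiable points
  exp(log(c[1]) - t[1] * (log(c[2]) - log(c[1])) / (t[2] - t[1]))
}

# ---- exported operations ----------------------------------------------------

#' Fit the terminal elimination rate constant (lambda_z)
#'
#' Under the automatic rule, every candidate window ending at the last
#' quantifiable point, starting strictly after Tmax and containing at least
#' `min_points` points is evaluated, and the window with the largest adjusted
#' R-squared of the log-linear regression is selected (ties within 1e-4 go to
#' the longer window). BLQ points are excluded. Under `rule = "manual"` the
#' window is `[t_start, t_end]`.
#'
#' @param profile a [conc_profile()].
#' @param rule `"best_adj_r2"` or `"manual"`.
#' @param min_points minimum number of points in a window (>= 3).
#' @param t_start,t_end manual window bounds in hours.
#' @return an object of class `"lambdaz_fit"`: `lambda_z` (1/h),
#'   `intercept_ln`, `n_points`, `adj_r2`, `t_first_used`, `t_last_used`,
#'   `estimable`. When no acceptable window exists (too few points or a
#'   non-negative best slope) `estimable` is `FALSE` and `lambda_z` is `NA`;
#'   downstream extrapolated quantities are then unavailable.
#' @export
fit_lambda_z <- function(profile, rule = c("best_adj_r2", "manual"),
                         min_points = 3L, t_start = NULL, t_end = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile, "conc_profile"), min_points >= 3)
  q <- quantifiable(profile)
  fit <- if (rule == "manual") {
    if (is.null(t_start) || is.null(t_end))
      stop("manual rule needs 't_start' and 't_end'")
    .lambdaz_manual(q$times, q$conc, t_start, t_end)
  } else if (length(q$times) >= 2L) {
    .lambdaz_core(q$times, q$conc, as.integer(min_points))
  } else NULL
  if (is.null(fit)) {
    fit <- list(lambda_z = NA_real_, intercept_ln = NA_real_,
                n_points = 0L, adj_r2 = NA_real_, t_first_used = NA_real_,
                t_last_used = NA_real_, estimable = FALSE)
  } else fit$estimable <- TRUE
  structure(fit, class = "lambdaz_fit")
}

#' @export
print.lambdaz_fit <- function(x, ...) {
  if (x$estimable) {
    cat(sprintf(
      "lambda_z = %.5g 1/h (t1/2 = %.4g h), %d points %g-%g h, adj R2 = %.5f\n",
      x$lambda_z, log(2) / x$lambda_z, x$n_points, x$t_first_used,
      x$t_last_used, x$adj_r2))
  } else cat("lambda_z not estimable\n")
  invisible(x)
}

#' Trapezoidal AUC and AUMC to the last quantifiable point
#'
#' The linear rule uses the ordinary trapezoid on concentration and on its
#' first moment; `"linear_up_log_down"` replaces strictly decreasing intervals
#' by the log-trapezoid (intervals touching a zero concentration fall back to
#' the linear rule). Under `c0_policy = "back_extrapolate"` a synthetic point
#' at t = 0, obtained by ln-linear extrapolation through the first two
#' quantifiable points, is prepended; under `"first_observed"` integration
#' starts at the first quantifiable sample.
#'
#' @param profile a [conc_profile()].
#' @param method integration rule.
#' @param c0_policy handling of the IV-bolus time origin.
#' @return named vector `c(auc_last =, aumc_last =)` in h*ug/mL and h^2*ug/mL.
#' @export
auc_aumc <- function(profile, method = c("linear", "linear_up_log_down"),
                     c0_policy = c("first_observed", "back_extrapolate")) {
  method <- match.arg(method)
  c0_policy <- match.arg(c0_policy)
  stopifnot(inherits(profile, "conc_profile"))
  q <- quantifiable(profile)
  t <- q$times; c <- q$conc
  if (length(t) < 2L) stop("need >= 2 quantifiable points")
  if (c0_policy == "back_extrapolate" && t[1] > 0) {
    t <- c(0, t)
    c <- c(.back_extrapolate_c0(q$times, q$conc), c)
  }
  v <- .auc_aumc_core(t, c, method)
  c(auc_last = unname(v["auc"]), aumc_last = unname(v["aumc"]))
}

#' Extrapolate AUC and AUMC to infinity
#'
#' Standard IV-bolus tail formulas: `auc_inf = auc_last + c_last/lambda_z` and
#' `aumc_inf = aumc_last + c_last*t_last/lambda_z + c_last/lambda_z^2`.
#'
#' @param auc_last,aumc_last areas to the last quantifiable point.
#' @param c_last,t_last last quantifiable concentration (ug/mL) and time (h).
#' @param lambda_z terminal rate constant (1/h) from an accepted fit.
#' @return named vector `c(auc_inf =, aumc_inf =)`.
#' @export
extrapolate_auc <- function(auc_last, aumc_last, c_last, t_last, lambda_z) {
  stopifnot(is.finite(lambda_z), lambda_z > 0, c_last >= 0)
  c(auc_inf = auc_last + c_last / lambda_z,
    aumc_inf = aumc_last + c_last * t_last / lambda_z + c_last / lambda_z^2)
}

#' Total body clearance, steady-state volume, half-life, extrapolated fraction
#'
#' Small named formulas shared by the NCA engine: `pk_cl(dose, auc_inf)` is
#' dose/AUC (L/h/kg for dose in mg/kg and AUC in h*ug/mL), `pk_vss(cl, mrt)`
#' is Cl x MRT (L/kg), `pk_thalf(lambda_z)` is ln(2)/lambda_z (h) and
#' `pk_auc_extrap_pct(auc_last, auc_inf)` is the extrapolated tail as a
#' percentage of the total area.
#'
#' @param dose dose in mg/kg.
#' @param auc_inf,auc_last areas in h*ug/mL.
#' @param cl clearance in L/h/kg.
#' @param mrt mean residence time in h.
#' @param lambda_z terminal rate constant in 1/h.
#' @return a numeric scalar.
#' @name pk_formulas
NULL

#' @rdname pk_formulas
#' @export
pk_cl <- function(dose, auc_inf) {
  stopifnot(dose > 0, auc_inf > 0)
  dose / auc_inf
}

#' @rdname pk_formulas
#' @export
pk_vss <- function(cl, mrt) cl * mrt

#' @rdname pk_formulas
#' @export
pk_thalf <- function(lambda_z) log(2) / lambda_z

#' @rdname pk_formulas
#' @export
pk_auc_extrap_pct <- function(auc_last, auc_inf) {
  100 * (auc_inf - auc_last) / auc_inf
}

#' Non-compartmental analysis of one profile
#'
#' Computes the full IV-bolus NCA parameter set for a single concentration-
#' time profile: `c0` (per the configured policy; the default
#' `"first_observed"` reports the concentration at the first post-dose
#' sample), `cmax`/`tmax` scanned directly from the data (earliest time wins a
#' tie), trapezoidal `auc_last`/`aumc_last`, the terminal-slope fit, areas
#' extrapolated to infinity, `auc_extrap_pct`, `mrt_inf = aumc_inf/auc_inf`,
#' `t_half_lambda_z`, `cl_t = dose/auc_inf` and `v_dss = cl_t * mrt_inf`.
#' BLQ samples are dropped entirely, so the analysed series ends at the last
#' quantifiable time. If no terminal slope is estimable the extrapolated
#' quantities are `NA` while `auc_last`, `cmax` and `tmax` are still returned.
#'
#' @param profile a [conc_profile()].
#' @param config a [run_config()].
#' @param dose dose in mg/kg; defaults to the profile's dose.
#' @return an object of class `"nca"`.
#' @examples
#' p <- conc_profile("S1", 1, 2, "plasma", times = 1:8,
#'                   conc = 10 * exp(-0.5 * (1:8)), lloq = 1e-6)
#' fit <- nca(p)
#' coef(fit)[c("auc_inf", "cl_t", "t_half_lambda_z")]
#' @export
nca <- function(profile, config = run_config(), dose = profile$dose) {
  stopifnot(inherits(profile, "conc_profile"), inherits(config, "run_config"))
  q <- quantifiable(profile)
  if (length(q$times) < 2L)
    stop(sprintf("fewer than 2 quantifiable points (subject %s, %s)",
                 profile$subject, profile$matrix))
  imax <- which.max(q$conc)[1]
  cmax <- q$conc[imax]; tmax <- q$times[imax]
  c0 <- if (config$c0_policy == "back_extrapolate")
    .back_extrapolate_c0(q$times, q$conc) else q$conc[1]
  areas <- auc_aumc(profile, config$auc_method, config$c0_policy)
  lz <- fit_lambda_z(profile, config$lambda_z_rule,
                     config$lambda_z_min_points)
  t_last <- q$times[length(q$times)]; c_last <- q$conc[length(q$conc)]
  if (lz$estimable) {
    tails <- extrapolate_auc(areas[["auc_last"]], areas[["aumc_last"]],
                             c_last, t_last, lz$lambda_z)
    auc_inf <- unname(tails["auc_inf"]); aumc_inf <- unname(tails["aumc_inf"])
    mrt <- aumc_inf / auc_inf
    cl <- pk_cl(dose, auc_inf)
    res <- list(auc_inf = auc_inf, aumc_inf = aumc_inf,
                auc_extrap_pct = pk_auc_extrap_pct(areas[["auc_last"]],
                                                   auc_inf),
                mrt_inf = mrt, t_half_lambda_z = pk_thalf(lz$lambda_z),
                cl_t = cl, v_dss = pk_vss(cl, mrt))
  } else {
    res <- list(auc_inf = NA_real_, aumc_inf = NA_real_,
                auc_extrap_pct = NA_real_, mrt_inf = NA_real_,
                t_half_lambda_z = NA_real_, cl_t = NA_real_, v_dss = NA_real_)
  }
  structure(c(list(subject = profile$subject, period = profile$period,
                   dose = dose, matrix = profile$matrix,
                   c0 = c0, cmax = cmax, tmax = tmax,
                   auc_last = unname(areas["auc_last"]),
                   aumc_last = unname(areas["aumc_last"]),
                   t_last = t_last, c_last = c_last,
                   n_quantifiable = length(q$times)),
              res, list(lambda_fit = lz)),
            class = "nca")
}

#' @export
print.nca <- function(x, digits = 4, ...) {
  cat(sprintf("NCA: subject %s, %s, %g mg/kg\n", x$subject, x$matrix, x$dose))
  v <- coef(x)
  print(signif(v, digits))
  invisible(x)
}

#' @export
coef.nca <- function(object, ...) {
  nm <- c("c0", "cmax", "tmax", "auc_last", "auc_inf", "auc_extrap_pct",
          "aumc_last", "aumc_inf", "mrt_inf", "t_half_lambda_z", "cl_t",
          "v_dss")
  unlist(object[nm])
}

#' NCA parameter table for every profile of a study
#'
#' Runs [nca()] on each profile and returns one row per
#' (subject, matrix, dose, period). Dose-based parameters (`cl_t`, `v_dss`)
#' are reported for plasma only; for milk they describe no physiological
#' quantity and are set to `NA`.
#'
#' @param dataset a [study_dataset()].
#' @param config a [run_config()].
#' @return a data frame.
#' @export
nca_table <- function(dataset, config = run_config()) {
  pr <- profiles(dataset)
  if (!length(pr)) stop("dataset has no profiles")
  rows <- lapply(pr, function(p) {
    fit <- nca(p, config)
    d <- data.frame(subject = fit$subject, period = fit$period,
                    dose = fit$dose, matrix = fit$matrix,
                    as.list(coef(fit)),
                    lambda_z = fit$lambda_fit$lambda_z,
                    lambda_z_n = fit$lambda_fit$n_points,
                    lambda_z_adj_r2 = fit$lambda_fit$adj_r2,
                    stringsAsFactors = FALSE)
    if (fit$matrix == "milk") d$cl_t <- d$v_dss <- NA_real_
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .milkwt_log("nca_table", n = nrow(out))
  out
}
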