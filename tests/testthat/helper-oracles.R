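# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, closed forms and stats:: fits.

# brute-force terminal-window search: every (start, end = last) window,
# refitted with lm(), best adjusted R^2 wins (ties -> more points)
oracle_lambdaz <- function(t, conc, min_points = 3) {
  y <- log(conc)
  n <- length(t)
  imax <- which.max(conc)[1]
  best <- NULL
  for (s in seq(imax + 1, n - min_points + 1)) {
    if (s < 1 || n - s + 1 < min_points) next
    fit <- stats::lm(y[s:n] ~ t[s:n])
    sl <- unname(coef(fit)[2])
    if (!is.finite(sl) || sl >= 0) next
    adj <- summary(fit)$adj.r.squared
    if (is.null(best) || adj > best$adj + 1e-4 ||
        (adj >= best$adj - 1e-4 && (n - s + 1) > best$n)) {
      best <- list(lambda = -sl, adj = adj, n = n - s + 1, t_first = t[s])
    }
  }
  best
}

# loop-based enumeration of the signed-rank null over all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  nz <- d[d != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  cnt_le <- 0; cnt_ge <- 0; total <- 2^n
  for (mask in 0:(total - 1)) {
    bits <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    w <- sum(r[bits])
    if (w <= W + 1e-9) cnt_le <- cnt_le + 1
    if (w >= W - 1e-9) cnt_ge <- cnt_ge + 1
  }
  min(1, 2 * min(cnt_le / total, cnt_ge / total))
}

# loop-based enumeration of the rank-sum null over all group assignments
oracle_rank_sum_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  sets <- utils::combn(n, na)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= W + 1e-9), mean(ws >= W - 1e-9)))
}

# bi-exponential closed forms
biexp_truth <- function(pm, dose) {
  A <- pm[["A"]]; al <- pm[["alpha"]]; B <- pm[["B"]]; be <- pm[["beta"]]
  auc <- A / al + B / be
  mrt <- (A / al^2 + B / be^2) / auc
  list(auc = auc, aumc = A / al^2 + B / be^2, mrt = mrt,
       cl = dose / auc, vss = dose / auc * mrt, lambda_z = be)
}

# dense noise-free profile from macro-constants (t = 0 included)
dense_profile <- function(pm, dose, n = 1000, t_end = 48, matrix = "plasma") {
  t <- seq(0, t_end, length.out = n + 1)[-1]   # profile times must be > 0
  conc <- pm[["A"]] * exp(-pm[["alpha"]] * t) + pm[["B"]] * exp(-pm[["beta"]] * t)
  conc_profile("D1", 1, dose, matrix, t, conc, lloq = 1e-12)
}

# tidy rows for hand-built datasets
study_rows <- function(subject, dose, matrix, times, conc, period = 1,
                       blq = is.na(conc)) {
  data.frame(subject = subject, period = period, dose_mg_kg = dose,
             matrix = matrix, time_h = times, conc_ug_ml = conc, blq = blq,
             stringsAsFactors = FALSE)
}
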