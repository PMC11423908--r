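# two-sided p from an enumerated null distribution of the statistic
.two_sided_p <- function(null_stats, observed, weights = NULL) {
  eps <- 1e-9
  if (is.null(weights)) weights <- rep(1, length(null_stats))
  tot <- sum(weights)
  lo <- sum(weights[null_stats <= observed + eps]) / tot
  hi <- sum(weights[null_stats >= observed - eps]) / tot
  min(1, 2 * min(lo, hi))
}

#' Exact Wilcoxon signed-rank test
#'
#' Statistic `W` = sum of the ranks of |differences| carrying a positive
#' sign, with mid-ranks for tied magnitudes and zero differences dropped.
#' For `n <= exact_limit` non-zero differences the two-sided p-value is
#' computed by full enumeration of all `2^n` sign assignments of the observed
#' magnitudes (so ties are handled exactly); beyond that a normal
#' approximation with tie correction is used and flagged.
#'
#' @param diffs paired differences.
#' @param exact_limit largest `n` for full enumeration.
#' @return an object of class `"pk_test"` with `statistic`, `p_two_sided`,
#'   `n_effective`, `method`, `exact`, `degenerate`.
#' @export
exact_signed_rank <- function(diffs, exact_limit = 15L) {
  d <- diffs[is.finite(diffs)]
  if (!length(d)) stop("no finite differences")
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L)
    return(structure(list(statistic = NA_real_, p_two_sided = 1,
                          n_effective = 0L, method = "signed_rank_exact",
                          exact = TRUE, degenerate = TRUE),
                     class = "pk_test"))
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  if (n <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- drop(signs %*% r)
    p <- .two_sided_p(Wall, W)
    exact <- TRUE
  } else {
    mu <- sum(r) / 2
    sig <- sqrt(sum(r^2) / 4)
    p <- min(1, 2 * stats::pnorm(-abs(W - mu) / sig))
    exact <- FALSE
  }
  structure(list(statistic = W, p_two_sided = p, n_effective = n,
                 method = "signed_rank_exact", exact = exact,
                 degenerate = FALSE), class = "pk_test")
}

#' Exact Wilcoxon rank-sum test
#'
#' Statistic = sum of the (mid-)ranks of the first group in the pooled
#' sample. The two-sided p-value enumerates all `choose(n_a + n_b, n_a)`
#' assignments of the pooled values to the first group whenever that count
#' does not exceed `max_enumeration`; otherwise a tie-corrected normal
#' approximation is used and flagged.
#'
#' @param a,b the two groups (non-empty numeric vectors).
#' @param max_enumeration enumeration budget.
#' @return an object of class `"pk_test"`.
#' @export
exact_rank_sum <- function(a, b, max_enumeration = 2e5) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  if (choose(na + nb, na) <= max_enumeration) {
    idx <- utils::combn(na + nb, na)
    Wall <- colSums(matrix(r[idx], nrow = na))
    p <- .two_sided_p(Wall, W)
    exact <- TRUE
  } else {
    N <- na + nb
    mu <- na * (N + 1) / 2
    ties <- table(r)
    sig <- sqrt(na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    p <- min(1, 2 * stats::pnorm(-abs(W - mu) / sig))
    exact <- FALSE
  }
  structure(list(statistic = W, p_two_sided = p,
                 n_effective = as.integer(na + nb),
                 method = "rank_sum_exact", exact = exact,
                 degenerate = FALSE), class = "pk_test")
}

#' @export
print.pk_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, two-sided p = %.4g (n = %d%s)\n",
              x$method, x$statistic, x$p_two_sided, x$n_effective,
              if (isTRUE(x$exact)) ", exact" else ", approximate"))
  if (isTRUE(x$degenerate)) cat("  all differences zero\n")
  if (!is.null(x$parameter))
    cat(sprintf("  parameter: %s%s; significant at 0.05: %s\n", x$parameter,
                if (isTRUE(x$normalized)) " (dose-normalized)" else "",
                if (isTRUE(x$significant)) "yes" else "no"))
  invisible(x)
}

#' Compare NCA parameters between the two dose arms
#'
#' Pairs subjects of a crossover, optionally dose-normalizes the higher arm
#' to the reference dose ([dose_normalize()]), and applies an exact Wilcoxon
#' test. The paired signed-rank test is the default for the crossover
#' pairing; `method = "rank_sum"` treats the arms as independent groups.
#'
#' @param tab_ref,tab_alt rows of an [nca_table()] (single matrix) for the
#'   reference and alternative dose arm.
#' @param parameter column to compare, e.g. `"auc_inf"` or `"cmax"`.
#' @param normalize dose-normalize the alternative arm to the reference dose.
#' @param method `"signed_rank"` (paired) or `"rank_sum"`.
#' @param alpha significance level for the convenience flag.
#' @return a `"pk_test"` with fields `parameter`, `normalized`,
#'   `significant` added.
#' @export
compare_doses <- function(tab_ref, tab_alt, parameter = "auc_inf",
                          normalize = TRUE,
                          method = c("signed_rank", "rank_sum"),
                          alpha = 0.05) {
  method <- match.arg(method)
  for (tb in list(tab_ref, tab_alt))
    if (!all(c("subject", "dose", parameter) %in% names(tb)))
      stop("tables need 'subject', 'dose' and the parameter column")
  ref_dose <- unique(tab_ref$dose); alt_dose <- unique(tab_alt$dose)
  if (length(ref_dose) != 1L || length(alt_dose) != 1L)
    stop("each table must hold a single dose arm")
  v_ref <- tab_ref[[parameter]]
  v_alt <- tab_alt[[parameter]]
  if (normalize) v_alt <- dose_normalize(v_alt, alt_dose, ref_dose)
  if (method == "signed_rank") {
    i <- match(tab_ref$subject, tab_alt$subject)
    if (anyNA(i) || nrow(tab_ref) != nrow(tab_alt))
      stop("subject sets differ between arms; cannot pair")
    res <- exact_signed_rank(v_alt[i] - v_ref)
  } else {
    res <- exact_rank_sum(v_ref, v_alt)
  }
  res$parameter <- parameter
  res$normalized <- normalize
  res$significant <- res$p_two_sided < alpha
  res
}
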