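#' Single concentration-time profile
#'
#' The atom of all computation: one subject x matrix x dose concentration-time
#' series after an IV bolus, with below-LLOQ (BLQ) censoring flags. BLQ
#' observations carry no numeric value (`NA`), only the flag; each analysis
#' stage decides its own BLQ policy rather than substituting 0 or LLOQ/2.
#'
#' @param subject subject identifier (coerced to character).
#' @param period study period (1 or 2).
#' @param dose administered dose in mg/kg body weight; must be positive.
#' @param matrix `"plasma"` or `"milk"`.
#' @param times sampling times in hours since dosing, strictly increasing,
#'   all `> 0` (the pre-dose time-0 sample is a control and is not part of a
#'   profile; see [profiles()]).
#' @param conc concentrations in ug/mL, aligned with `times`; `NA` where BLQ.
#' @param blq logical BLQ flags aligned with `times`. Defaults to
#'   `is.na(conc)`.
#' @param lloq lower limit of quantification in ug/mL (> 0). Every
#'   quantifiable concentration must be `>= lloq`.
#'
#' @return An object of class `"conc_profile"`.
#' @seealso [censor_lloq()], [nca()]
#' @export
conc_profile <- function(subject, period, dose, matrix, times, conc,
                         blq = NULL, lloq = 0.04) {
  matrix <- match.arg(matrix, c("plasma", "milk"))
  subject <- as.character(subject)
  period <- as.integer(period)
  if (is.null(blq)) blq <- is.na(conc)
  stopifnot(length(times) == length(conc), length(times) == length(blq))
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0)
    stop("'dose' must be a single positive number (mg/kg)")
  if (!is.numeric(lloq) || lloq <= 0)
    stop("'lloq' must be positive (ug/mL)")
  if (any(times <= 0))
    stop("profile times must be > 0 h (time 0 is the pre-dose control)")
  if (any(diff(times) <= 0))
    stop(sprintf("times must be strictly increasing (subject %s, %s)",
                 subject, matrix))
  blq <- as.logical(blq)
  if (anyNA(blq)) stop("'blq' flags must be TRUE/FALSE")
  if (any(!blq & is.na(conc)))
    stop(sprintf("missing concentration without BLQ flag (subject %s, %s)",
                 subject, matrix))
  if (any(conc[!blq] < 0, na.rm = TRUE))
    stop(sprintf("negative concentration (subject %s, %s)", subject, matrix))
  if (any(conc[!blq] < lloq - 1e-12, na.rm = TRUE))
    stop(sprintf("quantifiable concentration below LLOQ %g (subject %s, %s)",
                 lloq, subject, matrix))
  conc[blq] <- NA_real_
  structure(
    list(subject = subject, period = period, dose = dose, matrix = matrix,
         times = as.numeric(times), conc = as.numeric(conc), blq = blq,
         lloq = lloq),
    class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  nq <- sum(!x$blq)
  cat(sprintf("Concentration-time profile: subject %s, %s, %g mg/kg (period %d)\n",
              x$subject, x$matrix, x$dose, x$period))
  cat(sprintf("  %d samples (%d quantifiable, LLOQ %g ug/mL), %g-%g h\n",
              length(x$times), nq, x$lloq, min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(subject = x$subject, period = x$period, dose_mg_kg = x$dose,
             matrix = x$matrix, time_h = x$times, conc_ug_ml = x$conc,
             blq = x$blq, stringsAsFactors = FALSE)
}

# quantifiable (time, conc) pairs, in time order
quantifiable <- function(profile) {
  keep <- !profile$blq
  list(times = profile$times[keep], conc = profile$conc[keep])
}

#' Apply lower-limit-of-quantification censoring
#'
#' Flags every concentration strictly below `lloq` as BLQ and withholds its
#' numeric value; concentrations at or above `lloq` are untouched.
#'
#' @param profile a [conc_profile()].
#' @param lloq censoring limit in ug/mL.
#' @return the censored `conc_profile` (with `lloq` updated).
#' @export
censor_lloq <- function(profile, lloq) {
  stopifnot(inherits(profile, "conc_profile"), lloq > 0)
  below <- !profile$blq & profile$conc < lloq
  profile$conc[below] <- NA_real_
  profile$blq <- profile$blq | below
  profile$lloq <- lloq
  profile
}

#' Study dataset of concentration-time measurements
#'
#' Wraps a tidy measurement table (one row per sample) together with the study
#' design. Time-0 rows are pre-dose controls: they are retained in the table
#' but excluded from every profile and computation.
#'
#' @param data data frame with columns `subject`, `period`, `dose_mg_kg`,
#'   `matrix`, `time_h`, `conc_ug_ml`, `blq`.
#' @param lloq lower limit of quantification in ug/mL.
#' @param design `"crossover"` or `"parallel"`. In a crossover every subject
#'   must appear at both doses.
#' @param washout_days washout between crossover periods (days; metadata only).
#' @return an object of class `"study_dataset"`.
#' @seealso [read_study()], [write_study()], [profiles()]
#' @export
study_dataset <- function(data, lloq = 0.04,
                          design = c("crossover", "parallel"),
                          washout_days = 15) {
  design <- match.arg(design)
  req <- c("subject", "period", "dose_mg_kg", "matrix", "time_h",
           "conc_ug_ml", "blq")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("dataset contains no rows")
  data <- data[req]
  data$subject <- as.character(data$subject)
  data$period <- as.integer(data$period)
  data$matrix <- as.character(data$matrix)
  data$blq <- as.logical(data$blq)
  if (!all(data$matrix %in% c("plasma", "milk")))
    stop("'matrix' must be 'plasma' or 'milk'")
  key <- interaction(data$subject, data$matrix, data$dose_mg_kg, data$period,
                     data$time_h, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (subject, matrix, dose, period, time) row(s)")
  if (any(data$conc_ug_ml < 0, na.rm = TRUE))
    stop("negative concentration value(s)")
  # order and per-profile monotonicity
  grp <- interaction(data$subject, data$matrix, data$dose_mg_kg, data$period,
                     drop = TRUE)
  data <- data[order(grp, data$time_h), , drop = FALSE]
  rownames(data) <- NULL
  x <- structure(list(data = data, lloq = lloq, design = design,
                      washout_days = washout_days),
                 class = "study_dataset")
  # constructing the profiles validates them (increasing times, LLOQ, ...)
  pr <- profiles(x)
  if (design == "crossover") {
    for (s in unique(data$subject)) {
      if (length(unique(data$dose_mg_kg[data$subject == s])) < 2L)
        stop(sprintf("crossover design but subject %s has a single dose", s))
    }
  }
  .milkwt_log("study_dataset", n_profiles = length(pr), design = design)
  x
}

#' Extract concentration-time profiles from a study dataset
#'
#' Builds one [conc_profile()] per (subject, matrix, dose, period), dropping
#' the time-0 control rows.
#'
#' @param dataset a [study_dataset()].
#' @param matrix,dose optional filters.
#' @return a list of `conc_profile` objects.
#' @export
profiles <- function(dataset, matrix = NULL, dose = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  d <- dataset$data[dataset$data$time_h > 0, , drop = FALSE]
  if (!is.null(matrix)) d <- d[d$matrix == matrix, , drop = FALSE]
  if (!is.null(dose)) d <- d[abs(d$dose_mg_kg - dose) < 1e-9, , drop = FALSE]
  if (nrow(d) == 0L) return(list())
  sp <- split(d, interaction(d$subject, d$matrix, d$dose_mg_kg, d$period,
                             drop = TRUE))
  out <- lapply(sp, function(g)
    conc_profile(g$subject[1], g$period[1], g$dose_mg_kg[1], g$matrix[1],
                 g$time_h, g$conc_ug_ml, g$blq, lloq = dataset$lloq))
  names(out) <- vapply(out, function(p)
    paste(p$subject, p$matrix, p$dose, sep = "/"), character(1))
  out[order(names(out))]
}

#' @export
print.study_dataset <- function(x, ...) {
  d <- x$data
  cat(sprintf("Study dataset (%s design): %d subjects, doses %s mg/kg\n",
              x$design, length(unique(d$subject)),
              paste(sort(unique(d$dose_mg_kg)), collapse = ", ")))
  cat(sprintf("  %d rows (%d BLQ, %d pre-dose controls), LLOQ %g ug/mL\n",
              nrow(d), sum(d$blq & d$time_h > 0), sum(d$time_h == 0), x$lloq))
  invisible(x)
}

#' @export
as.data.frame.study_dataset <- function(x, ...) x$data

#' Semi-logarithmic concentration-time plot of a study
#'
#' One line per subject, concentration on a log axis; BLQ samples are omitted.
#'
#' @param x a [study_dataset()].
#' @param matrix,dose which profiles to draw.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, `x`.
#' @export
plot.study_dataset <- function(x, matrix = "plasma",
                               dose = unique(x$data$dose_mg_kg)[1], ...) {
  pr <- profiles(x, matrix = matrix, dose = dose)
  if (!length(pr)) stop("no profiles to plot")
  ts <- sort(unique(unlist(lapply(pr, function(p) p$times))))
  m <- sapply(pr, function(p) {
    q <- quantifiable(p)
    v <- rep(NA_real_, length(ts))
    v[match(q$times, ts)] <- q$conc
    v
  })
  graphics::matplot(ts, m, type = "b", pch = 1, lty = 1, log = "y",
                    xlab = "Time (h)", ylab = "Concentration (µg/mL)",
                    main = sprintf("%s, %g mg/kg", matrix, dose), ...)
  graphics::abline(h = x$lloq, lty = 3)
  invisible(x)
}
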