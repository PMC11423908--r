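#' Milk-penetration exposure ratios
#'
#' Quantifies drug passage into milk as the ratio of milk to plasma exposure
#' for the same subject and dose: `auc_ratio_inf = milk AUC_0-inf / plasma
#' AUC_0-inf` and the analogous `auc_ratio_last`. Ratios are formed per
#' subject and summarized geometrically across subjects, so the geometric
#' mean of the ratios equals the ratio of geometric means.
#'
#' @param milk,plasma [nca()] fits (or any list with fields `auc_inf`,
#'   `auc_last` and optionally `cmax`, `tmax`, `subject`, `dose`) for the same
#'   subject and dose.
#' @return an object of class `"penetration"` with fields `auc_ratio_last`,
#'   `auc_ratio_inf`, `milk_cmax`, `milk_tmax`, `subject`, `dose`.
#' @export
penetration_ratios <- function(milk, plasma) {
  if (!is.null(milk$subject) && !is.null(plasma$subject) &&
      (!identical(milk$subject, plasma$subject) ||
       !isTRUE(all.equal(milk$dose, plasma$dose))))
    stop("milk and plasma results must come from the same subject and dose")
  if (is.na(plasma$auc_last) || plasma$auc_last <= 0 ||
      is.null(plasma$auc_inf) || is.na(plasma$auc_inf) || plasma$auc_inf <= 0)
    stop("plasma AUCs must be positive")
  structure(list(
    auc_ratio_last = milk$auc_last / plasma$auc_last,
    auc_ratio_inf = milk$auc_inf / plasma$auc_inf,
    milk_cmax = if (is.null(milk$cmax)) NA_real_ else milk$cmax,
    milk_tmax = if (is.null(milk$tmax)) NA_real_ else milk$tmax,
    subject = milk$subject, dose = milk$dose), class = "penetration")
}

#' @export
print.penetration <- function(x, ...) {
  cat(sprintf("Milk penetration (subject %s, %g mg/kg):\n",
              if (is.null(x$subject)) "?" else x$subject,
              if (is.null(x$dose)) NA else x$dose))
  cat(sprintf("  AUC ratio (0-last) %.4g, AUC ratio (0-inf) %.4g\n",
              x$auc_ratio_last, x$auc_ratio_inf))
  cat(sprintf("  milk Cmax %.4g ug/mL at Tmax %.4g h\n",
              x$milk_cmax, x$milk_tmax))
  invisible(x)
}

#' Per-subject milk/plasma ratio table
#'
#' Pairs milk and plasma rows of an [nca_table()] by subject and dose and
#' returns one row of penetration ratios per pair.
#'
#' @param tab an [nca_table()] containing both matrices.
#' @return a data frame with columns `subject`, `dose`, `auc_ratio_last`,
#'   `auc_ratio_inf`, `milk_cmax`, `milk_tmax`.
#' @export
penetration_table <- function(tab) {
  mk <- tab[tab$matrix == "milk", , drop = FALSE]
  pl <- tab[tab$matrix == "plasma", , drop = FALSE]
  if (!nrow(mk) || !nrow(pl)) stop("need both milk and plasma NCA rows")
  m <- merge(mk, pl, by = c("subject", "dose"), suffixes = c(".milk", ".plasma"))
  if (!nrow(m)) stop("no subject/dose pairs shared between matrices")
  data.frame(subject = m$subject, dose = m$dose,
             auc_ratio_last = m$auc_last.milk / m$auc_last.plasma,
             auc_ratio_inf = m$auc_inf.milk / m$auc_inf.plasma,
             milk_cmax = m$cmax.milk, milk_tmax = m$tmax.milk,
             stringsAsFactors = FALSE)
}

#' Milk/plasma concentration ratio at a shared sampling time
#'
#' No interpolation is performed: `t` must be a quantifiable sampled time in
#' both matrices, otherwise the ratio is not computable and `NA` is returned
#' (with the reason as an attribute).
#'
#' @param milk,plasma [conc_profile()] objects.
#' @param t time in hours.
#' @return milk/plasma concentration ratio, or `NA` when not computable.
#' @export
conc_ratio_at_time <- function(milk, plasma, t) {
  stopifnot(inherits(milk, "conc_profile"), inherits(plasma, "conc_profile"))
  pick <- function(p) {
    i <- which(abs(p$times - t) < 1e-9)
    if (!length(i) || p$blq[i]) NA_real_ else p$conc[i]
  }
  cm <- pick(milk); cp <- pick(plasma)
  if (is.na(cm) || is.na(cp)) {
    return(structure(NA_real_,
                     reason = "time unsampled or BLQ in one of the matrices"))
  }
  cm / cp
}

#' Linear dose normalization
#'
#' Rescales a dose-proportional parameter observed at `dose` to a reference
#' dose: `value * ref_dose / dose`.
#'
#' @param value parameter value(s).
#' @param dose dose at which `value` was observed (mg/kg, > 0).
#' @param ref_dose reference dose (mg/kg, > 0).
#' @return the normalized value(s).
#' @export
dose_normalize <- function(value, dose, ref_dose) {
  stopifnot(all(dose > 0), all(ref_dose > 0))
  value * ref_dose / dose
}
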