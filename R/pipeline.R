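#' Run the full analysis pipeline on a study
#'
#' Convenience wrapper chaining the stages: per-profile NCA, geometric
#' summaries, milk-penetration ratios, per-dose withdrawal-time fits, and the
#' exact paired comparison of dose-normalized plasma `auc_inf` and `cmax`
#' between the two arms of a crossover.
#'
#' @param dataset a [study_dataset()].
#' @param config a [run_config()]. `config$excluded_times` is applied to any
#'   dose arm whose quantifiable milk times exceed `config$max_wt_time_points`.
#' @param wt_exclude optional named list (names = dose) of time vectors to
#'   exclude from the WT regression, overriding `config$excluded_times`.
#' @return a list with elements `nca`, `summary`, `penetration`, `wt`
#'   (one [wt_fit()] or error message per dose) and `comparison` (for
#'   crossover data).
#' @export
analyze_study <- function(dataset, config = run_config(),
                          wt_exclude = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  tab <- nca_table(dataset, config)
  doses <- sort(unique(tab$dose))
  pen <- if (all(c("milk", "plasma") %in% tab$matrix))
    penetration_table(tab) else NULL
  wt <- list()
  for (d in doses) {
    excl <- if (!is.null(wt_exclude)) wt_exclude[[as.character(d)]]
            else if (length(config$excluded_times)) config$excluded_times
            else NULL
    wt[[as.character(d)]] <- tryCatch(
      wt_fit(dataset, dose = d, mrl = config$mrl,
             milk_density = config$milk_density, p = config$tolerance_p,
             conf = config$tolerance_conf,
             max_points = config$max_wt_time_points, exclude_times = excl),
      error = function(e) conditionMessage(e))
  }
  comparison <- NULL
  if (dataset$design == "crossover" && length(doses) == 2L) {
    pl <- tab[tab$matrix == "plasma", , drop = FALSE]
    lo <- pl[pl$dose == doses[1], , drop = FALSE]
    hi <- pl[pl$dose == doses[2], , drop = FALSE]
    comparison <- list(
      auc_inf = compare_doses(lo, hi, "auc_inf"),
      cmax = compare_doses(lo, hi, "cmax"))
  }
  list(nca = tab, summary = summarize_nca(tab), penetration = pen,
       wt = wt, comparison = comparison)
}
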