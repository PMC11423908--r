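#' Read a tidy concentration-time CSV
#'
#' Expects one measurement per row with columns `subject`, `period`,
#' `dose_mg_kg`, `matrix`, `time_h`, `conc_ug_ml`, `blq`. Lines beginning with
#' `#` (the provenance header written by [write_study()]) are ignored. Time-0
#' rows are kept as pre-dose controls but excluded from all profiles.
#'
#' @param path CSV file path.
#' @param lloq lower limit of quantification in ug/mL.
#' @param design,washout_days passed to [study_dataset()].
#' @return a [study_dataset()].
#' @export
read_study <- function(path, lloq = 0.04, design = "crossover",
                       washout_days = 15) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse CSV '", path, "': ",
                             conditionMessage(e)))
  if (nrow(d) == 0L || ncol(d) == 0L) stop("empty file: ", path)
  study_dataset(d, lloq = lloq, design = design, washout_days = washout_days)
}

.config_hash <- function(config) {
  if (is.null(config)) return("none")
  s <- utf8ToInt(paste(format(unlist(config), digits = 15), collapse = "|"))
  sprintf("%08x", sum(s * seq_along(s)) %% .Machine$integer.max)
}

.provenance_lines <- function(seed = NULL, config = NULL) {
  c(sprintf("# milkwt %s", as.character(utils::packageVersion("milkwt"))),
    sprintf("# seed: %s", if (is.null(seed)) "none" else format(seed)),
    sprintf("# config: %s", .config_hash(config)))
}

#' Write a study dataset (or any stage output) to CSV
#'
#' Values are written with full precision; a short provenance header (package
#' version, seed, config hash) precedes the data as `#` comment lines, so that
#' `read_study(write_study(x))` round-trips.
#'
#' @param x a [study_dataset()] or data frame.
#' @param path output path.
#' @param seed,config optional provenance to record.
#' @return invisibly, `path`.
#' @export
write_study <- function(x, path, seed = NULL, config = NULL) {
  d <- as.data.frame(x)
  if (nrow(d) == 0L) stop("refusing to write an empty result")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing"))
  on.exit(close(con))
  writeLines(.provenance_lines(seed, config), con)
  utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result object to JSON with provenance
#'
#' @param x a list or fit object (e.g. a [wt_fit()] result).
#' @param path output path.
#' @param seed optional seed to record.
#' @return invisibly, `path`.
#' @export
write_results_json <- function(x, path, seed = NULL) {
  if (inherits(x, "wt_fit")) {
    x <- list(wt_estimate_h = x$wt_estimate, wt_reported_h = x$wt_reported,
              mrl_ug_kg = x$mrl, mrl_conc_ug_ml = x$mrl_conc, p = x$p,
              conf = x$conf, dose_mg_kg = x$dose, matrix = x$matrix,
              regression = x$regression[c("slope", "intercept", "s", "n",
                                          "df", "x_bar", "s_xx",
                                          "times_used", "n_animals")])
  }
  if (length(x) == 0L) stop("refusing to write an empty result")
  out <- list(provenance = list(
    package = "milkwt",
    version = as.character(utils::packageVersion("milkwt")),
    seed = seed),
    results = x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects the tunable settings of the pipeline. Defaults follow common NCA
#' practice for IV-bolus studies and the EMA-style 95/95 withdrawal-time
#' construction: linear trapezoidal integration, automatic terminal-slope
#' selection by best adjusted R-squared, `C0` taken as the first post-dose
#' observation, MRL 50 ug/kg converted to ug/mL with a milk density of
#' 1.0 kg/L, and at most 7 distinct time points in the withdrawal regression.
#'
#' @param auc_method `"linear"` or `"linear_up_log_down"` trapezoid.
#' @param lambda_z_rule `"best_adj_r2"` (automatic) or `"manual"`.
#' @param lambda_z_min_points minimum points in a terminal-slope window (>= 3).
#' @param c0_policy `"first_observed"` or `"back_extrapolate"`.
#' @param mrl maximum residue limit in ug/kg.
#' @param milk_density milk density in kg/L used to convert the MRL to ug/mL.
#' @param tolerance_p,tolerance_conf percentile and confidence level of the
#'   one-sided tolerance limit (fractions in (0, 1)).
#' @param max_wt_time_points cap on distinct times in the WT regression.
#' @param excluded_times sampling times (h) to drop from the WT regression.
#' @param seed optional integer seed recorded with outputs.
#' @return an object of class `"run_config"` (a named list).
#' @export
run_config <- function(auc_method = c("linear", "linear_up_log_down"),
                       lambda_z_rule = c("best_adj_r2", "manual"),
                       lambda_z_min_points = 3L,
                       c0_policy = c("first_observed", "back_extrapolate"),
                       mrl = 50, milk_density = 1.0,
                       tolerance_p = 0.95, tolerance_conf = 0.95,
                       max_wt_time_points = 7L,
                       excluded_times = numeric(0),
                       seed = NULL) {
  auc_method <- match.arg(auc_method)
  lambda_z_rule <- match.arg(lambda_z_rule)
  c0_policy <- match.arg(c0_policy)
  stopifnot(lambda_z_min_points >= 3, mrl > 0,
            tolerance_p > 0, tolerance_p < 1,
            tolerance_conf > 0, tolerance_conf < 1,
            milk_density > 0, max_wt_time_points >= 3)
  structure(list(auc_method = auc_method, lambda_z_rule = lambda_z_rule,
                 lambda_z_min_points = as.integer(lambda_z_min_points),
                 c0_policy = c0_policy, mrl = mrl,
                 milk_density = milk_density, tolerance_p = tolerance_p,
                 tolerance_conf = tolerance_conf,
                 max_wt_time_points = as.integer(max_wt_time_points),
                 excluded_times = as.numeric(excluded_times), seed = seed),
            class = "run_config")
}

#' Read a run configuration from a JSON or YAML file
#'
#' Keys mirror the [run_config()] argument names exactly; unknown keys are an
#' error.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml")
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
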