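#' Geometric mean
#'
#' `exp(mean(log(x)))`; every value must be strictly positive.
#'
#' @param x positive numeric vector (NA removed when `na.rm = TRUE`).
#' @param na.rm drop missing values first.
#' @return a scalar.
#' @export
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (!length(x)) stop("no values to average")
  if (anyNA(x)) stop("missing values; use na.rm = TRUE")
  if (any(x <= 0)) {
    bad <- which(x <= 0)
    stop("geometric mean needs positive values; offending index ",
         paste(bad, collapse = ", "))
  }
  exp(mean(log(x)))
}

#' Across-subject summaries of NCA parameters
#'
#' Geometric mean (min-max) per matrix x dose for every parameter except
#' `tmax`, which is summarized by its median (min-max), matching the usual
#' presentation of crossover PK studies.
#'
#' @param tab a table from [nca_table()], or a vector of values together with
#'   `parameter`.
#' @param parameters which parameter columns to summarize.
#' @return a data frame with columns `matrix`, `dose`, `parameter`, `n`,
#'   `center`, `min`, `max`, `summary`.
#' @export
summarize_nca <- function(tab,
                          parameters = c("c0", "cmax", "tmax", "auc_last",
                                         "auc_inf", "auc_extrap_pct",
                                         "mrt_inf", "t_half_lambda_z",
                                         "cl_t", "v_dss")) {
  stopifnot(is.data.frame(tab), all(c("matrix", "dose") %in% names(tab)))
  parameters <- intersect(parameters, names(tab))
  groups <- unique(tab[c("matrix", "dose")])
  out <- list()
  for (i in seq_len(nrow(groups))) {
    g <- tab[tab$matrix == groups$matrix[i] &
               tab$dose == groups$dose[i], , drop = FALSE]
    for (p in parameters) {
      v <- g[[p]][!is.na(g[[p]])]
      if (!length(v)) next
      med <- identical(p, "tmax")
      center <- if (med) stats::median(v) else geomean(v)
      out[[length(out) + 1L]] <- data.frame(
        matrix = groups$matrix[i], dose = groups$dose[i], parameter = p,
        n = length(v), center = center, min = min(v), max = max(v),
        summary = if (med) "median" else "geometric mean",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
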