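#' Assemble and validate a per-trial summary table
#'
#' A trial table holds one row per randomized comparison: the hazard ratio
#' and confidence interval for the surrogate endpoint (e.g. rPFS) and for the
#' true endpoint (e.g. OS), the randomized sample size, and
#' proportional-hazards flags per endpoint. All downstream functions consume
#' this table or the log-scale effects derived from it.
#'
#' @param trial_id character vector of unique trial labels.
#' @param n_patients positive integer vector, total randomized per comparison.
#' @param hr_surrogate,lcl_surrogate,ucl_surrogate hazard ratio and CI bounds
#'   for the surrogate endpoint (all strictly positive, `lcl < hr < ucl`).
#' @param hr_true,lcl_true,ucl_true same for the true endpoint.
#' @param ph_ok_surrogate,ph_ok_true logical: proportional-hazards assumption
#'   satisfied for that endpoint.
#' @param notes optional character annotations.
#' @param level confidence level of the intervals, in (0, 1).
#'
#' @return A `data.frame` of class `trial_table` with the columns above and a
#'   `level` attribute.
#' @export
trial_table <- function(trial_id, n_patients,
                        hr_surrogate, lcl_surrogate, ucl_surrogate,
                        hr_true, lcl_true, ucl_true,
                        ph_ok_surrogate = TRUE, ph_ok_true = TRUE,
                        notes = "", level = 0.95) {
  tab <- data.frame(
    trial_id = as.character(trial_id),
    n_patients = as.integer(n_patients),
    hr_surrogate = as.numeric(hr_surrogate),
    lcl_surrogate = as.numeric(lcl_surrogate),
    ucl_surrogate = as.numeric(ucl_surrogate),
    hr_true = as.numeric(hr_true),
    lcl_true = as.numeric(lcl_true),
    ucl_true = as.numeric(ucl_true),
    ph_ok_surrogate = as.logical(ph_ok_surrogate),
    ph_ok_true = as.logical(ph_ok_true),
    notes = as.character(notes),
    stringsAsFactors = FALSE
  )
  validate_trial_table(tab, level = level)
  attr(tab, "level") <- level
  class(tab) <- c("trial_table", "data.frame")
  tab
}

validate_trial_table <- function(tab, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("confidence level must be a single number in (0, 1)", call. = FALSE)
  if (anyDuplicated(tab$trial_id))
    stop("duplicated trial_id in trial table", call. = FALSE)
  if (any(!is.finite(tab$n_patients)) || any(tab$n_patients <= 0))
    stop("n_patients must be positive", call. = FALSE)
  for (ep in c("surrogate", "true")) {
    hr <- tab[[paste0("hr_", ep)]]
    lo <- tab[[paste0("lcl_", ep)]]
    hi <- tab[[paste0("ucl_", ep)]]
    bad <- !is.finite(hr) | !is.finite(lo) | !is.finite(hi) |
      hr <= 0 | lo <= 0 | hi <= 0
    if (any(bad))
      stop(sprintf("row %d (%s): non-positive or missing HR/bound for %s endpoint",
                   which(bad)[1L], tab$trial_id[which(bad)[1L]], ep), call. = FALSE)
    out <- hr <= lo | hr >= hi
    if (any(out))
      stop(sprintf("row %d (%s): point estimate outside CI for %s endpoint",
                   which(out)[1L], tab$trial_id[which(out)[1L]], ep), call. = FALSE)
  }
  invisible(tab)
}

#' Read a per-trial summary table from CSV
#'
#' Expects a comma-separated, UTF-8 file with a header naming the columns of
#' [trial_table()] (the `ph_ok_*` and `notes` columns are optional and
#' default to `TRUE` / `""`). Row order is preserved.
#'
#' @param path file path.
#' @param level confidence level of the intervals (default 0.95).
#' @return a validated `trial_table`.
#' @export
read_trial_table <- function(path, level = 0.95) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  required <- c("trial_id", "n_patients",
                "hr_surrogate", "lcl_surrogate", "ucl_surrogate",
                "hr_true", "lcl_true", "ucl_true")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing column(s) in trial table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$ph_ok_surrogate)) raw$ph_ok_surrogate <- TRUE
  if (is.null(raw$ph_ok_true)) raw$ph_ok_true <- TRUE
  if (is.null(raw$notes)) raw$notes <- ""
  trial_table(raw$trial_id, raw$n_patients,
              raw$hr_surrogate, raw$lcl_surrogate, raw$ucl_surrogate,
              raw$hr_true, raw$lcl_true, raw$ucl_true,
              raw$ph_ok_surrogate, raw$ph_ok_true, raw$notes,
              level = level)
}

#' Write a trial table to CSV
#'
#' @param tab a `trial_table`.
#' @param path output file path.
#' @export
write_trial_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Convert HR + CI rows to log-scale effects with standard errors
#'
#' Hazard ratios are log-transformed; the standard error of each log HR is
#' recovered from the confidence interval as
#' `se = (log(ucl) - log(lcl)) / (2 * z)` with `z` the exact standard-normal
#' quantile at the interval's level (1.959964 at 95%). This is the standard
#' summary-data reconstruction and is exact when the interval was Wald-type
#' on the log scale.
#'
#' @param tab a `trial_table`.
#' @param level confidence level of the intervals; defaults to the table's
#'   own `level` attribute.
#' @return a `data.frame` of class `effect_table` with columns `trial_id`,
#'   `y1`, `se1` (surrogate log HR and SE), `y2`, `se2` (true endpoint), and
#'   `n_patients` carried along for sample-size weighting.
#' @export
to_effects <- function(tab, level = attr(tab, "level") %||% 0.95) {
  z <- z_level(level)
  degen <- tab$ucl_surrogate == tab$lcl_surrogate |
    tab$ucl_true == tab$lcl_true
  if (any(degen))
    stop(sprintf("row %d (%s): degenerate CI (upper == lower), se would be 0",
                 which(degen)[1L], tab$trial_id[which(degen)[1L]]), call. = FALSE)
  eff <- data.frame(
    trial_id = tab$trial_id,
    y1 = log(tab$hr_surrogate),
    se1 = (log(tab$ucl_surrogate) - log(tab$lcl_surrogate)) / (2 * z),
    y2 = log(tab$hr_true),
    se2 = (log(tab$ucl_true) - log(tab$lcl_true)) / (2 * z),
    n_patients = tab$n_patients,
    stringsAsFactors = FALSE
  )
  attr(eff, "level") <- level
  class(eff) <- c("effect_table", "data.frame")
  eff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_effects <- function(effects, min_trials = 1L) {
  need <- c("trial_id", "y1", "se1", "y2", "se2")
  if (!all(need %in% names(effects)))
    stop("effects must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(effects) < min_trials)
    stop(sprintf("at least %d trials required, got %d", min_trials, nrow(effects)),
         call. = FALSE)
  ok <- is.finite(effects$y1) & is.finite(effects$y2) &
    effects$se1 > 0 & effects$se2 > 0
  if (!all(ok))
    stop("non-finite effect or non-positive SE in row ", which(!ok)[1L], call. = FALSE)
  invisible(effects)
}

#' Build a named analysis set from a trial table
#'
#' Three conventional sets are supported: `primary` keeps every trial whose
#' proportional-hazards assumption holds on both endpoints; `sensitivity_1`
#' keeps all trials regardless of PH status; `sensitivity_2` additionally
#' removes PH violators and a configured list of outlying trials.
#'
#' @param tab a `trial_table`.
#' @param name one of `"primary"`, `"sensitivity_1"`, `"sensitivity_2"`.
#' @param outlier_ids trial ids removed by `sensitivity_2` (defaults to the
#'   two trials flagged as visual outliers in the bundled mCRPC analysis).
#' @return list of class `analysis_set` with `name`, `included_ids`,
#'   `exclusion_reasons` (named character vector) and the subset `records`.
#' @export
build_analysis_set <- function(tab, name = c("primary", "sensitivity_1", "sensitivity_2"),
                               outlier_ids = c("NCT02294461", "ERA 223")) {
  name <- match.arg(name)
  ph_ok <- tab$ph_ok_surrogate & tab$ph_ok_true
  excl <- character(0)
  if (name == "primary") {
    excl <- setNames(rep("ph_violation", sum(!ph_ok)), tab$trial_id[!ph_ok])
  } else if (name == "sensitivity_2") {
    excl <- c(
      setNames(rep("ph_violation", sum(!ph_ok)), tab$trial_id[!ph_ok]),
      setNames(rep("outlier", length(outlier_ids)), outlier_ids)
    )
    unknown <- setdiff(outlier_ids, tab$trial_id)
    if (length(unknown))
      stop("outlier id(s) not in trial table: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  keep <- !(tab$trial_id %in% names(excl))
  records <- tab[keep, , drop = FALSE]
  attr(records, "level") <- attr(tab, "level")
  class(records) <- class(tab)
  structure(
    list(name = name,
         included_ids = tab$trial_id[keep],
         exclusion_reasons = excl,
         records = records),
    class = "analysis_set"
  )
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("Analysis set '%s': %d trials, %d patients\n",
              x$name, length(x$included_ids), sum(x$records$n_patients)))
  if (length(x$exclusion_reasons)) {
    cat("Excluded:\n")
    for (id in names(x$exclusion_reasons))
      cat(sprintf("  %s (%s)\n", id, x$exclusion_reasons[[id]]))
  }
  invisible(x)
}
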