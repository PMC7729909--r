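#' Compare a variable's value frequencies before and after anonymization
#'
#' Percentages are computed over each dataset's own record count, so the
#' comparison isolates distributional bias from the mere loss of records.
#'
#' @param before,after Non-empty dataset tibbles over the same schema.
#' @param variable Variable to compare.
#' @param config Optional [pipeline_config()]; when given, the full domain
#'   is tabulated (absent codes at 0%), otherwise the union of observed
#'   values.
#' @return A tibble with columns `value`, `freq_before`, `freq_after` (in
#'   %) and `abs_diff` (percentage points); the mean absolute difference is
#'   `mean(result$abs_diff)`.
#' @export
compare_distributions <- function(before, after, variable, config = NULL) {
  if (nrow(before) == 0L || nrow(after) == 0L) {
    stop("both datasets must be non-empty", call. = FALSE)
  }
  if (!variable %in% names(before) || !variable %in% names(after)) {
    stop("unknown variable '", variable, "'", call. = FALSE)
  }
  domain <- if (!is.null(config)) config_domain(config, variable) else {
    unique(c(before[[variable]], after[[variable]]))
  }
  fb <- 100 * empirical_distribution(before[[variable]], domain)
  fa <- 100 * empirical_distribution(after[[variable]], domain)
  tibble::tibble(value = domain, freq_before = unname(fb), freq_after = unname(fa),
                 abs_diff = abs(unname(fa) - unname(fb)))
}

#' Case fatality rate of a dataset
#'
#' Deaths among documented cases divided by the number of cases, in
#' percent. Which outcome codes count as deaths is read from the `dead`
#' branch of the outcome variable's hierarchy (so by default both
#' COVID-attributed and other deaths), or can be given explicitly.
#'
#' @param data A non-empty dataset tibble.
#' @param config A [pipeline_config()].
#' @param status_var Name of the outcome variable.
#' @param dead_values Optional explicit character vector of death codes
#'   (e.g. `"dead-covid"` only).
#' @return CFR in percent.
#' @export
case_fatality_rate <- function(data, config = leoss_config(),
                               status_var = "Last known patient status",
                               dead_values = NULL) {
  if (nrow(data) == 0L) stop("CFR of an empty dataset is undefined", call. = FALSE)
  if (!status_var %in% names(data)) stop("missing outcome variable '", status_var, "'", call. = FALSE)
  if (is.null(dead_values)) {
    h <- config$hierarchies[[status_var]]
    if (is.null(h)) stop("no hierarchy for '", status_var, "'; give dead_values explicitly", call. = FALSE)
    dead_values <- names(h$paths)[vapply(h$paths, function(p) "dead" %in% p, logical(1L))]
    if (length(dead_values) == 0L) {
      stop("hierarchy of '", status_var, "' has no 'dead' branch; give dead_values explicitly",
           call. = FALSE)
    }
  }
  100 * mean(data[[status_var]] %in% dead_values)
}

#' Log odds ratio of death for patients above an age cutoff
#'
#' Collapses the banded age variable to a binary old/young indicator
#' (strictly above `age_cutoff_band` in domain order) and the outcome to
#' dead/alive, then returns the log odds ratio `ln(ad / bc)` of the
#' resulting 2x2 table — identical to the slope of a univariate logistic
#' regression of death on the binary age indicator. If any cell of the
#' table is zero the coefficient does not exist; `NA` is returned with
#' `defined = FALSE` (this is a value of the statistic, not an error — it
#' is the expected regime for small early-registry snapshots with no
#' deaths).
#'
#' @param data A dataset tibble.
#' @param config A [pipeline_config()].
#' @param age_cutoff_band Highest band counted as "young"; bands after it
#'   in the domain order are "old". The default corresponds to an age
#'   cutoff of 45 years under the bundled schema.
#' @param age_var,status_var Column names.
#' @param dead_values Death codes (default: the hierarchy's `dead` branch,
#'   see [case_fatality_rate()]).
#' @return A list: `coefficient` (log odds ratio or `NA`), `defined`,
#'   `table` (the 2x2 contingency table).
#' @export
log_odds_death_by_age <- function(data, config = leoss_config(),
                                  age_cutoff_band = "36-45",
                                  age_var = "Age at diagnosis",
                                  status_var = "Last known patient status",
                                  dead_values = NULL) {
  domain <- config_domain(config, age_var)
  cut_idx <- match(age_cutoff_band, domain)
  if (is.na(cut_idx)) stop("age_cutoff_band '", age_cutoff_band, "' is not an age band", call. = FALSE)
  if (is.null(dead_values)) {
    h <- config$hierarchies[[status_var]]
    dead_values <- names(h$paths)[vapply(h$paths, function(p) "dead" %in% p, logical(1L))]
  }
  old <- match(data[[age_var]], domain) > cut_idx
  dead <- data[[status_var]] %in% dead_values
  tab <- matrix(c(sum(old & dead), sum(old & !dead),
                  sum(!old & dead), sum(!old & !dead)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(age = c("old", "young"), outcome = c("dead", "alive")))
  if (any(tab == 0L)) {
    return(list(coefficient = NA_real_, defined = FALSE, table = tab))
  }
  list(coefficient = log((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])),
       defined = TRUE, table = tab)
}

#' Output-quality and residual-risk report for an anonymization run
#'
#' Assembles the before/after comparison that accompanies each release:
#' per-variable value frequencies and their mean absolute difference
#' (reported both over all variables and over the clinical, non-key
#' variables only), the suppressed fraction, the case fatality rate on both
#' sides with its signed difference (`after - before`, so a positive value
#' means the release overestimates the CFR), re-identification risk
#' profiles, and the age–death log odds ratio. The report contains only
#' aggregate frequencies — never record-level values of suppressed records —
#' so it is itself safe to share with external partners.
#'
#' @param before The primary dataset.
#' @param after The released dataset (its record ids must be a subset of
#'   `before`'s).
#' @param config A [pipeline_config()].
#' @return An object of class `quality_report`. `tidy()` returns the long
#'   per-value frequency table, `glance()` the one-row summary;
#'   [write_report()] serializes to JSON.
#' @export
quality_report <- function(before, after, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nrow(before) == 0L) stop("the primary dataset must be non-empty", call. = FALSE)
  if (!all(after$record_id %in% before$record_id)) {
    stop("'after' must be a subset of 'before' (same record ids)", call. = FALSE)
  }
  empty <- nrow(after) == 0L
  vars <- config_vars(config)
  comparisons <- if (empty) NULL else {
    stats::setNames(lapply(vars, function(v) compare_distributions(before, after, v, config)), vars)
  }
  mean_abs <- function(vs) {
    if (empty) return(NA_real_)
    mean(unlist(lapply(comparisons[vs], `[[`, "abs_diff")))
  }
  clinical_vars <- setdiff(vars, config$key_vars)
  cfr_before <- case_fatality_rate(before, config)
  cfr_after <- if (empty) NA_real_ else case_fatality_rate(after, config)
  structure(list(
    n_before = nrow(before), n_after = nrow(after),
    suppressed_fraction = (nrow(before) - nrow(after)) / nrow(before),
    comparisons = comparisons,
    mean_abs_diff_all = mean_abs(vars),
    mean_abs_diff_clinical = mean_abs(clinical_vars),
    cfr_before = cfr_before, cfr_after = cfr_after,
    cfr_diff = if (empty) NA_real_ else cfr_after - cfr_before,
    risk_before = risk_profile(before, config$key_vars),
    risk_after = if (empty) NULL else risk_profile(after, config$key_vars),
    log_odds_before = log_odds_death_by_age(before, config),
    log_odds_after = if (empty) list(coefficient = NA_real_, defined = FALSE) else
      log_odds_death_by_age(after, config),
    params = list(k = config$k, t = config$t, min_value_count = config$min_value_count)
  ), class = "quality_report")
}

#' @rdname quality_report
#' @param x A `quality_report`.
#' @param ... Unused.
#' @method tidy quality_report
#' @export
tidy.quality_report <- function(x, ...) {
  if (is.null(x$comparisons)) {
    return(tibble::tibble(variable = character(0L), value = character(0L),
                          freq_before = numeric(0L), freq_after = numeric(0L),
                          abs_diff = numeric(0L)))
  }
  dplyr::bind_rows(x$comparisons, .id = "variable")
}

#' @rdname quality_report
#' @method glance quality_report
#' @export
glance.quality_report <- function(x, ...) {
  tibble::tibble(
    n_before = x$n_before, n_after = x$n_after,
    suppressed_fraction = x$suppressed_fraction,
    mean_abs_diff_all = x$mean_abs_diff_all,
    mean_abs_diff_clinical = x$mean_abs_diff_clinical,
    cfr_before = x$cfr_before, cfr_after = x$cfr_after, cfr_diff = x$cfr_diff,
    highest_risk_before = x$risk_before$highest,
    highest_risk_after = if (is.null(x$risk_after)) NA_real_ else x$risk_after$highest,
    log_odds_before = x$log_odds_before$coefficient,
    log_odds_after = x$log_odds_after$coefficient
  )
}

#' @export
print.quality_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f%%", v)
  cat("<quality_report>\n",
      "  records: ", x$n_before, " -> ", x$n_after,
      " (suppressed ", sprintf("%.2f%%", 100 * x$suppressed_fraction), ")\n",
      "  mean |freq diff|: ", pct(x$mean_abs_diff_all), " (all variables), ",
      pct(x$mean_abs_diff_clinical), " (clinical variables)\n",
      "  CFR: ", pct(x$cfr_before), " -> ", pct(x$cfr_after),
      " (diff ", if (is.na(x$cfr_diff)) "n/a" else sprintf("%+.2f pp", x$cfr_diff), ")\n",
      "  highest risk: ", pct(100 * x$risk_before$highest), " -> ",
      if (is.null(x$risk_after)) "n/a" else pct(100 * x$risk_after$highest), "\n",
      "  age>cutoff vs death log-odds: ",
      if (x$log_odds_before$defined) sprintf("%.3f", x$log_odds_before$coefficient) else "undefined",
      " -> ",
      if (isTRUE(x$log_odds_after$defined)) sprintf("%.3f", x$log_odds_after$coefficient) else "undefined",
      "\n", sep = "")
  invisible(x)
}

#' Write a quality report to JSON
#'
#' @param report A [quality_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "quality_report"))
  out <- list(
    summary = as.list(glance(report)),
    params = report$params,
    risk_before = as.list(report$risk_before),
    risk_after = if (is.null(report$risk_after)) NULL else as.list(report$risk_after),
    frequencies = tidy(report)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Trend of release properties over a growing registry
#'
#' For each snapshot of a growth series and its release, tabulates the
#' suppressed fraction, the case fatality rate on both sides and the
#' absolute CFR bias, plus the released highest risk. For an empty release
#' the released CFR is `NA` and the bias is taken as the primary CFR
#' (complete loss of the signal).
#'
#' @param series A [simulate_growth_series()] result.
#' @param config A [pipeline_config()].
#' @param results Optional precomputed [continuous_release()] output.
#' @return A tibble with one row per snapshot.
#' @export
release_trend <- function(series, config, results = NULL) {
  if (is.null(results)) results <- continuous_release(series, config)
  stopifnot(length(results) == length(series))
  rows <- Map(function(snapshot, res) {
    cfr_primary <- case_fatality_rate(snapshot, config)
    empty <- nrow(res$released) == 0L
    cfr_released <- if (empty) NA_real_ else case_fatality_rate(res$released, config)
    tibble::tibble(
      size = nrow(snapshot), n_released = nrow(res$released),
      suppressed_fraction = length(res$suppressed_ids) / nrow(snapshot),
      cfr_primary = cfr_primary, cfr_released = cfr_released,
      cfr_abs_bias = if (empty) cfr_primary else abs(cfr_released - cfr_primary),
      highest_risk = if (empty) NA_real_ else risk_profile(res$released, config$key_vars)$highest
    )
  }, series, unclass(results))
  dplyr::bind_rows(rows)
}
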