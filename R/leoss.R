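#' Bundled 16-variable COVID-19 registry PUF schema
#'
#' The default schema mirrors the public-use file of an open COVID-19
#' cohort registry: four demographic/timestamp key variables, four derived
#' clinical-phase indicators, and eight sensitive variables describing
#' interventions, superinfections, recovery symptoms and outcome. Age is
#' banded (top-coded above 85), diagnosis dates are coarsened to month and
#' year, and phase-dependent variables use the explicit `"NA"` code whenever
#' the phase did not occur (so a phase indicator of `"no"` forces `"NA"` in
#' every variable of that phase).
#'
#' @return A list with components `variables` (16 [variable_spec()] objects)
#'   and `hierarchies` (a [hierarchy()] per sensitive variable: a
#'   two-level alive/dead tree for the outcome, a two-level
#'   none/infected/NA tree for superinfections, flat trees elsewhere).
#' @seealso [leoss_config()] to get a ready-to-run [pipeline_config()].
#' @export
leoss_schema <- function() {
  age_bands <- c("<=25", "26-35", "36-45", "46-55", "56-65", "66-75", "76-85", ">85")
  yn <- c("yes", "no")
  yn_na <- c("yes", "no", "NA")
  superinf <- c("none", "bacterial", "fungal", "bacterial+fungal", "NA")
  status <- c("alive-recovered", "alive-not-recovered", "dead-covid", "dead-other")

  variables <- list(
    variable_spec("Age at diagnosis", "key", age_bands),
    variable_spec("Gender", "key", c("male", "female")),
    variable_spec("Month first diagnosis", "key", as.character(1:12)),
    variable_spec("Year first diagnosis", "key", "2020"),
    variable_spec("Uncomplicated phase", "derived", yn),
    variable_spec("Complicated phase", "derived", yn),
    variable_spec("Critical phase", "derived", yn),
    variable_spec("Recovery phase", "derived", yn),
    variable_spec("Vasopressors in complicated phase", "sensitive", yn_na, na_code = "NA"),
    variable_spec("Vasopressors in critical phase", "sensitive", yn_na, na_code = "NA"),
    variable_spec("Invasive ventilation in critical phase", "sensitive", yn_na, na_code = "NA"),
    variable_spec("Superinfection in uncomplicated phase", "sensitive", superinf, na_code = "NA"),
    variable_spec("Superinfection in complicated phase", "sensitive", superinf, na_code = "NA"),
    variable_spec("Superinfection in critical phase", "sensitive", superinf, na_code = "NA"),
    variable_spec("Symptoms in recovery phase", "sensitive", yn_na, na_code = "NA"),
    variable_spec("Last known patient status", "sensitive", status)
  )

  # Superinfection: none and NA sit conceptually directly under the root
  # (ground distance 1 to everything else); the singleton chain nodes keep
  # all leaves at equal depth. Infected subtypes are mutually at distance 1/2.
  superinf_tree <- function(var) {
    hierarchy(var, list(
      "none" = "none", "bacterial" = "infected", "fungal" = "infected",
      "bacterial+fungal" = "infected", "NA" = "NA"
    ))
  }
  status_tree <- hierarchy("Last known patient status", list(
    "alive-recovered" = "alive", "alive-not-recovered" = "alive",
    "dead-covid" = "dead", "dead-other" = "dead"
  ))

  hierarchies <- list(
    flat_hierarchy("Vasopressors in complicated phase", yn_na),
    flat_hierarchy("Vasopressors in critical phase", yn_na),
    flat_hierarchy("Invasive ventilation in critical phase", yn_na),
    superinf_tree("Superinfection in uncomplicated phase"),
    superinf_tree("Superinfection in complicated phase"),
    superinf_tree("Superinfection in critical phase"),
    flat_hierarchy("Symptoms in recovery phase", yn_na),
    status_tree
  )
  names(hierarchies) <- vapply(hierarchies, `[[`, character(1L), "variable")
  list(variables = variables, hierarchies = hierarchies)
}

#' Default pipeline configuration for the bundled registry schema
#'
#' Convenience wrapper: [leoss_schema()] plus the default release policy
#' (`k = 11`, `t = 0.5`, `min_value_count = 10`).
#'
#' @param ... Parameter overrides passed to [pipeline_config()] (e.g. `k`,
#'   `t`, `min_value_count`).
#' @return A [pipeline_config()].
#' @examples
#' config <- leoss_config()
#' length(config$variables)
#' @export
leoss_config <- function(...) {
  schema <- leoss_schema()
  pipeline_config(schema$variables, schema$hierarchies, ...)
}

#' Bundled qualitative risk scores for the registry variables
#'
#' Expert replicability / availability / distinguishability judgments
#' (1 = low, 2 = medium, 3 = high) for the 16 PUF variables, as used to
#' decide which variables an adversary could exploit for linkage attacks.
#' Feed them to [classify_key_variables()]; with the default threshold the
#' four demographic/timestamp variables come out as keys.
#'
#' @return A tibble with columns `variable`, `replicability`, `availability`,
#'   `distinguishability`.
#' @export
leoss_variable_scores <- function() {
  tibble::tribble(
    ~variable, ~replicability, ~availability, ~distinguishability,
    "Age at diagnosis", 3L, 3L, 3L,
    "Gender", 3L, 3L, 2L,
    "Month first diagnosis", 1L, 3L, 2L,
    "Year first diagnosis", 1L, 3L, 2L,
    "Uncomplicated phase", 1L, 2L, 1L,
    "Complicated phase", 1L, 2L, 2L,
    "Critical phase", 1L, 2L, 2L,
    "Recovery phase", 1L, 2L, 1L,
    "Vasopressors in complicated phase", 1L, 1L, 2L,
    "Vasopressors in critical phase", 1L, 1L, 2L,
    "Invasive ventilation in critical phase", 1L, 1L, 2L,
    "Superinfection in uncomplicated phase", 1L, 1L, 2L,
    "Superinfection in complicated phase", 1L, 1L, 2L,
    "Superinfection in critical phase", 1L, 1L, 2L,
    "Symptoms in recovery phase", 1L, 1L, 2L,
    "Last known patient status", 1L, 2L, 2L
  )
}
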