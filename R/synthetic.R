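#' Parameters of the synthetic registry generator
#'
#' The generator emulates the marginal structure of an early-pandemic
#' COVID-19 hospital registry: a roughly 60/40 male/female split, an age
#' distribution skewed towards middle-aged and older patients, diagnosis
#' months concentrated at the start of the observation window, a nested
#' chain of clinical phases (uncomplicated -> complicated -> critical, with
#' the critical-phase share calibrated to about 24%), age-dependent
#' mortality on a logit scale, and rare superinfection categories (fungal
#' and combined bacterial+fungal involvement well below 1% each, per phase).
#'
#' Phase-conditional intervention rates (vasopressors, ventilation,
#' recovery-phase symptoms) are plausible placeholders, not fitted to any
#' published registry table.
#'
#' @param p_male Probability of `Gender == "male"`.
#' @param age_band_weights Probability vector over the 8 age bands.
#' @param month_weights Probability vector over diagnosis months 3..12
#'   (calendar year 2020).
#' @param p_complicated_given_uncomplicated,p_critical_given_complicated
#'   Phase-chain transition probabilities (every case has an uncomplicated
#'   phase; the defaults give a critical-phase share of about 0.243).
#' @param p_recovery Probability that a surviving patient has completed a
#'   recovery phase.
#' @param death_logit_intercept,death_logit_age_slope Logit-scale intercept
#'   and per-age-band slope of the death probability, applied to patients
#'   who reached at least the complicated phase (band index 0 for the
#'   youngest band).
#' @param p_dead_covid_given_dead Probability a death is attributed to
#'   COVID-19 rather than another cause.
#' @param superinfection_weights Probability vector over
#'   `none`, `bacterial`, `fungal`, `bacterial+fungal`, used within each
#'   phase the patient went through.
#' @param p_vasopressor_complicated,p_vasopressor_critical,
#'   p_ventilation_critical,p_symptoms_recovery Phase-conditional
#'   intervention/symptom probabilities.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(p_male = 0.60,
                             age_band_weights = c(0.04, 0.08, 0.13, 0.18, 0.22, 0.18, 0.12, 0.05),
                             month_weights = c(0.45, 0.25, 0.12, 0.06, 0.04, 0.03, 0.02, 0.01, 0.01, 0.01),
                             p_complicated_given_uncomplicated = 0.40,
                             p_critical_given_complicated = 0.6068,
                             p_recovery = 0.85,
                             death_logit_intercept = -4.5,
                             death_logit_age_slope = 0.55,
                             p_dead_covid_given_dead = 0.85,
                             superinfection_weights = c(none = 0.93, bacterial = 0.055,
                                                        fungal = 0.01, "bacterial+fungal" = 0.005),
                             p_vasopressor_complicated = 0.15,
                             p_vasopressor_critical = 0.45,
                             p_ventilation_critical = 0.55,
                             p_symptoms_recovery = 0.30) {
  params <- list(p_male = p_male, age_band_weights = age_band_weights,
                 month_weights = month_weights,
                 p_complicated_given_uncomplicated = p_complicated_given_uncomplicated,
                 p_critical_given_complicated = p_critical_given_complicated,
                 p_recovery = p_recovery,
                 death_logit_intercept = death_logit_intercept,
                 death_logit_age_slope = death_logit_age_slope,
                 p_dead_covid_given_dead = p_dead_covid_given_dead,
                 superinfection_weights = superinfection_weights,
                 p_vasopressor_complicated = p_vasopressor_complicated,
                 p_vasopressor_critical = p_vasopressor_critical,
                 p_ventilation_critical = p_ventilation_critical,
                 p_symptoms_recovery = p_symptoms_recovery)
  for (nm in c("age_band_weights", "month_weights", "superinfection_weights")) {
    w <- params[[nm]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop("'", nm, "' must be a probability vector summing to 1", call. = FALSE)
    }
  }
  if (length(params$age_band_weights) != 8L) stop("age_band_weights must have 8 entries", call. = FALSE)
  if (length(params$month_weights) != 10L) stop("month_weights must cover months 3..12", call. = FALSE)
  probs <- params[grepl("^p_", names(params))]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(params, class = "generator_params")
}

# run code under a fixed RNG state without disturbing the caller's stream
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a registry-like primary dataset
#'
#' Draws `n` structurally consistent case records under
#' [generator_params()]: clinical phases nest (critical implies complicated
#' implies uncomplicated), every phase-dependent variable equals the
#' explicit `"NA"` code exactly when its phase did not occur, death requires
#' at least a complicated phase, and death probability increases with the
#' age band. Output is deterministic given `seed`.
#'
#' @param n Number of records (`n = 0` gives an empty dataset).
#' @param seed Optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @param params A [generator_params()] object.
#' @return A dataset tibble over [leoss_schema()] with `record_id = 1..n`.
#' @examples
#' d <- simulate_primary(100, seed = 1)
#' table(d$Gender)
#' @export
simulate_primary <- function(n, seed = NULL, params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  n <- as.integer(n)
  schema <- leoss_schema()
  age_bands <- schema$variables[[1L]]$domain
  superinf_codes <- names(params$superinfection_weights)

  with_seed_(seed, {
    age_idx <- sample.int(8L, n, replace = TRUE, prob = params$age_band_weights)
    gender <- ifelse(stats::runif(n) < params$p_male, "male", "female")
    month <- sample(3:12, n, replace = TRUE, prob = params$month_weights)

    complicated <- stats::runif(n) < params$p_complicated_given_uncomplicated
    critical <- complicated & (stats::runif(n) < params$p_critical_given_complicated)

    p_death <- stats::plogis(params$death_logit_intercept +
                               params$death_logit_age_slope * (age_idx - 1L))
    dead <- complicated & (stats::runif(n) < p_death)
    dead_covid <- dead & (stats::runif(n) < params$p_dead_covid_given_dead)
    recovered <- !dead & (stats::runif(n) < params$p_recovery)
    status <- dplyr::case_when(
      dead & dead_covid ~ "dead-covid",
      dead ~ "dead-other",
      recovered ~ "alive-recovered",
      .default = "alive-not-recovered"
    )

    yn <- function(cond, p) {
      ifelse(cond, ifelse(stats::runif(n) < p, "yes", "no"), "NA")
    }
    superinf <- function(cond) {
      draw <- sample(superinf_codes, n, replace = TRUE, prob = params$superinfection_weights)
      ifelse(cond, draw, "NA")
    }

    tibble::tibble(
      record_id = seq_len(n),
      "Age at diagnosis" = age_bands[age_idx],
      "Gender" = gender,
      "Month first diagnosis" = as.character(month),
      "Year first diagnosis" = rep("2020", n),
      "Uncomplicated phase" = rep("yes", n),
      "Complicated phase" = ifelse(complicated, "yes", "no"),
      "Critical phase" = ifelse(critical, "yes", "no"),
      "Recovery phase" = ifelse(recovered, "yes", "no"),
      "Vasopressors in complicated phase" = yn(complicated, params$p_vasopressor_complicated),
      "Vasopressors in critical phase" = yn(critical, params$p_vasopressor_critical),
      "Invasive ventilation in critical phase" = yn(critical, params$p_ventilation_critical),
      "Superinfection in uncomplicated phase" = superinf(rep(TRUE, n)),
      "Superinfection in complicated phase" = superinf(complicated),
      "Superinfection in critical phase" = superinf(critical),
      "Symptoms in recovery phase" = yn(recovered, params$p_symptoms_recovery),
      "Last known patient status" = status
    )
  })
}

#' Simulate a structureless uniform development file
#'
#' Draws each cell independently and uniformly from its variable's domain,
#' with no structural consistency between columns. Such a file shares the
#' schema of the real data but none of its distribution, so it can be
#' shared freely to develop an anonymization pipeline against.
#'
#' @param n Number of records (default 1000).
#' @param config A [pipeline_config()] supplying the schema.
#' @param seed Optional integer seed.
#' @return A dataset tibble with `record_id = 1..n`.
#' @export
simulate_development_file <- function(n = 1000L, config = leoss_config(), seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  n <- as.integer(n)
  with_seed_(seed, {
    cols <- lapply(config$variables, function(spec) {
      spec$domain[sample.int(length(spec$domain), n, replace = TRUE)]
    })
    dplyr::bind_cols(tibble::tibble(record_id = seq_len(n)), tibble::as_tibble(cols))
  })
}

#' Simulate nested registry snapshots of growing size
#'
#' Models a registry that only ever accrues cases: one primary dataset of
#' `max(sizes)` records is drawn, and snapshot `i` is its first `sizes[i]`
#' records. Shared records are therefore cell-identical across snapshots.
#'
#' @param sizes Strictly increasing integer vector of snapshot sizes.
#' @inheritParams simulate_primary
#' @return A list of class `puf_growth_series`: one dataset tibble per
#'   size, named by size.
#' @examples
#' series <- simulate_growth_series(c(150, 500), seed = 7)
#' vapply(series, nrow, integer(1))
#' @export
simulate_growth_series <- function(sizes, seed = NULL, params = generator_params()) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || any(diff(sizes) <= 0L)) {
    stop("sizes must be a strictly increasing integer vector", call. = FALSE)
  }
  full <- simulate_primary(max(sizes), seed = seed, params = params)
  out <- lapply(sizes, function(sz) full[seq_len(sz), , drop = FALSE])
  names(out) <- as.character(sizes)
  structure(out, class = "puf_growth_series", sizes = sizes)
}
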