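#' Anonymize a dataset by record suppression
#'
#' Enforces the three release requirements by removing whole records and
#' nothing else (suppression-only, non-perturbative): released records are
#' byte-for-byte copies of input records, so record removal is the only
#' possible source of bias. The engine iterates three checks to a fixpoint:
#'
#' 1. **k-anonymity** on the key variables: every equivalence class smaller
#'    than `k` is suppressed entirely.
#' 2. **t-closeness** for each sensitive variable: classes whose
#'    hierarchy-aware earth mover's distance to the currently retained
#'    overall distribution exceeds `t` are suppressed entirely. The
#'    reference distribution is recomputed from the retained set at every
#'    iteration, so the released file itself satisfies the model.
#' 3. **Value frequency**: records carrying any value shared by fewer than
#'    `min_value_count` retained individuals are suppressed (explicit
#'    not-applicable codes are exempt, see [check_value_frequency()]).
#'
#' Derived variables (phase indicators) are excluded from checks 1 and 2
#' but are still released: their values are implied by the checked
#' phase-dependent variables, so protecting those protects the indicators
#' too. The loop terminates in at most `nrow(data)` iterations because the
#' retained set strictly shrinks on every non-final pass; an empty release
#' is a legal (flagged) outcome. The engine is fully deterministic.
#'
#' @param data A validated dataset tibble.
#' @param config A [pipeline_config()].
#' @return An object of class `puf_anonymization`: a list with `released`
#'   (tibble), `suppressed_ids`, `iterations`, `audit` (per-step tibble:
#'   `iteration`, `requirement`, `detail`, `n_suppressed`, `record_ids`)
#'   and `config`. Use [generics::tidy()] for the audit trail and
#'   [generics::glance()] for a one-row summary.
#' @examples
#' d <- simulate_primary(400, seed = 1)
#' res <- anonymize(d, leoss_config())
#' glance(res)
#' @export
anonymize <- function(data, config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_dataset(data, config)
  retained <- data
  audit <- list()
  iterations <- 0L

  log_step <- function(requirement, detail, ids) {
    audit[[length(audit) + 1L]] <<- tibble::tibble(
      iteration = iterations, requirement = requirement, detail = detail,
      n_suppressed = length(ids), record_ids = list(sort(ids))
    )
  }

  repeat {
    iterations <- iterations + 1L
    changed <- FALSE

    # (a) k-anonymity on the key variables
    if (nrow(retained) > 0L) {
      classes <- partition_classes(retained, config$key_vars)
      violating <- check_k_anonymity(classes, config$k)
      if (nrow(violating) > 0L) {
        ids <- unlist(violating$record_ids)
        retained <- dplyr::filter(retained, !.data$record_id %in% ids)
        log_step("k_anonymity",
                 sprintf("%d class(es) below k = %d", nrow(violating), config$k), ids)
        changed <- TRUE
      }
    }

    # (b) t-closeness per sensitive variable, against the retained set
    if (nrow(retained) > 0L && length(config$sensitive_vars) > 0L) {
      classes <- partition_classes(retained, config$key_vars)
      ids <- integer(0L)
      offending <- character(0L)
      for (v in config$sensitive_vars) {
        violating <- check_t_closeness(retained, config$key_vars, v, config$t,
                                       config$hierarchies[[v]], classes = classes)
        if (nrow(violating) > 0L) {
          ids <- union(ids, unlist(violating$record_ids))
          offending <- c(offending, v)
        }
      }
      if (length(ids)) {
        retained <- dplyr::filter(retained, !.data$record_id %in% ids)
        log_step("t_closeness",
                 sprintf("violations for: %s (t = %g)",
                         paste(offending, collapse = ", "), config$t), ids)
        changed <- TRUE
      }
    }

    # (c) minimum value frequency over all variables
    if (nrow(retained) > 0L) {
      freq <- check_value_frequency(retained, config)
      if (length(freq$record_ids)) {
        retained <- dplyr::filter(retained, !.data$record_id %in% freq$record_ids)
        log_step("value_frequency",
                 sprintf("%d rare (variable, value) pair(s) below %d",
                         nrow(freq$rare_values), config$min_value_count),
                 freq$record_ids)
        changed <- TRUE
      }
    }

    if (!changed || nrow(retained) == 0L) break
  }

  audit <- if (length(audit)) dplyr::bind_rows(audit) else {
    tibble::tibble(iteration = integer(0L), requirement = character(0L),
                   detail = character(0L), n_suppressed = integer(0L),
                   record_ids = list())
  }
  structure(list(released = retained,
                 suppressed_ids = sort(setdiff(data$record_id, retained$record_id)),
                 iterations = iterations, audit = audit, config = config,
                 n_input = nrow(data)),
            class = "puf_anonymization")
}

#' @export
print.puf_anonymization <- function(x, ...) {
  cat("<puf_anonymization> ", nrow(x$released), " of ", x$n_input,
      " records released (", length(x$suppressed_ids), " suppressed, ",
      sprintf("%.2f%%", 100 * length(x$suppressed_ids) / max(x$n_input, 1L)),
      "), ", x$iterations, " iteration(s)\n", sep = "")
  if (nrow(x$released) == 0L) cat("  NOTE: empty release\n")
  invisible(x)
}

#' @rdname anonymize
#' @param x A `puf_anonymization` object.
#' @param ... Unused.
#' @method tidy puf_anonymization
#' @export
tidy.puf_anonymization <- function(x, ...) x$audit

#' @rdname anonymize
#' @method glance puf_anonymization
#' @export
glance.puf_anonymization <- function(x, ...) {
  highest <- if (nrow(x$released) > 0L) {
    risk_profile(x$released, x$config$key_vars)$highest
  } else NA_real_
  tibble::tibble(n_input = x$n_input, n_released = nrow(x$released),
                 n_suppressed = length(x$suppressed_ids),
                 suppressed_fraction = length(x$suppressed_ids) / max(x$n_input, 1L),
                 iterations = x$iterations, highest_risk = highest,
                 empty_release = nrow(x$released) == 0L)
}

#' Anonymize a growing registry, snapshot by snapshot
#'
#' Safe continuous release: each snapshot is anonymized independently from
#' the full current primary data, never by appending newly anonymized
#' increments to an earlier release (which can silently break the privacy
#' requirements). Every release therefore satisfies all requirements on its
#' own.
#'
#' @param series A [simulate_growth_series()] result, or any list of
#'   dataset tibbles of non-decreasing size.
#' @param config A [pipeline_config()].
#' @return A list of class `puf_release_series` of [anonymize()] results,
#'   one per snapshot. `tidy()` returns the per-snapshot summary table.
#' @export
continuous_release <- function(series, config) {
  results <- lapply(series, anonymize, config = config)
  structure(results, class = "puf_release_series")
}

#' @rdname continuous_release
#' @param x A `puf_release_series` object.
#' @param ... Unused.
#' @method tidy puf_release_series
#' @export
tidy.puf_release_series <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), glance))
}

#' @export
print.puf_release_series <- function(x, ...) {
  cat("<puf_release_series> of", length(x), "snapshot(s)\n")
  print(tidy(x))
  invisible(x)
}

#' Independently verify a release against the privacy requirements
#'
#' Re-checks a dataset against k-anonymity, t-closeness and the
#' value-frequency rule by direct calls to the three checkers — never by
#' trusting an engine audit log. An empty dataset is vacuously compliant.
#'
#' @param released A dataset tibble (typically `anonymize(...)$released`).
#' @param config A [pipeline_config()].
#' @return A list with `ok` (logical) and `violations`, a tibble with
#'   columns `requirement`, `detail`, `n_classes_or_values`.
#' @export
verify <- function(released, config) {
  stopifnot(inherits(config, "pipeline_config"))
  violations <- list()
  add <- function(requirement, detail, n) {
    violations[[length(violations) + 1L]] <<- tibble::tibble(
      requirement = requirement, detail = detail, n_classes_or_values = n)
  }
  if (nrow(released) > 0L) {
    classes <- partition_classes(released, config$key_vars)
    kv <- check_k_anonymity(classes, config$k)
    if (nrow(kv) > 0L) {
      add("k_anonymity", sprintf("%d class(es) below k = %d", nrow(kv), config$k), nrow(kv))
    }
    for (v in config$sensitive_vars) {
      tv <- check_t_closeness(released, config$key_vars, v, config$t,
                              config$hierarchies[[v]], classes = classes)
      if (nrow(tv) > 0L) {
        add("t_closeness", sprintf("'%s': %d class(es) beyond t = %g", v, nrow(tv), config$t),
            nrow(tv))
      }
    }
    fv <- check_value_frequency(released, config)
    if (nrow(fv$rare_values) > 0L) {
      add("value_frequency",
          paste("rare values:",
                paste(sprintf("%s='%s' (%d)", fv$rare_values$variable,
                              fv$rare_values$value, fv$rare_values$n), collapse = "; ")),
          nrow(fv$rare_values))
    }
  }
  violations <- if (length(violations)) dplyr::bind_rows(violations) else {
    tibble::tibble(requirement = character(0L), detail = character(0L),
                   n_classes_or_values = integer(0L))
  }
  list(ok = nrow(violations) == 0L, violations = violations)
}
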