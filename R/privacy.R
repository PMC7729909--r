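#' Partition a dataset into equivalence classes on the key variables
#'
#' An equivalence class is a maximal group of records sharing the same
#' combination of key-variable (quasi-identifier) values; the classes form
#' an exhaustive, disjoint partition of the dataset. Classes are returned in
#' sorted signature order so audits are reproducible.
#'
#' @param data A dataset tibble with a `record_id` column.
#' @param key_vars Character vector of key variable names (non-empty).
#' @return A tibble with one row per class: the key columns, `n` (class
#'   size) and `record_ids` (list column of member record ids).
#' @export
partition_classes <- function(data, key_vars) {
  if (length(key_vars) == 0L) stop("no key variables given: cannot partition", call. = FALSE)
  missing_cols <- setdiff(key_vars, names(data))
  if (length(missing_cols)) stop("unknown key variable(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_vars))) |>
    dplyr::summarise(n = dplyr::n(),
                     record_ids = list(sort(.data$record_id)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(key_vars)))
}

#' Find equivalence classes violating k-anonymity
#'
#' A dataset is k-anonymous when every equivalence class has at least `k`
#' members, i.e. every record is indistinguishable from at least `k - 1`
#' others on the key variables.
#'
#' @param classes Output of [partition_classes()].
#' @param k Positive integer.
#' @return The subset of `classes` with `n < k`; zero rows iff the dataset
#'   is k-anonymous.
#' @export
check_k_anonymity <- function(classes, k) {
  stopifnot(is.numeric(k), k >= 1)
  dplyr::filter(classes, .data$n < k)
}

#' Prosecutor re-identification risk profile
#'
#' Each record's prosecutor risk is `1 / (size of its equivalence class)`:
#' the probability that an adversary who knows the key-variable values of a
#' target individual picks the right record. The profile aggregates the
#' per-record risks to their minimum, maximum and mean.
#'
#' @inheritParams partition_classes
#' @return A one-row tibble: `n_records`, `n_classes`, `lowest`, `highest`,
#'   `average` (risks as proportions in (0, 1]).
#' @export
risk_profile <- function(data, key_vars) {
  if (nrow(data) == 0L) stop("cannot profile an empty dataset", call. = FALSE)
  classes <- partition_classes(data, key_vars)
  risks <- rep(1 / classes$n, classes$n)
  tibble::tibble(n_records = nrow(data), n_classes = nrow(classes),
                 lowest = min(risks), highest = max(risks), average = mean(risks))
}

#' Empirical distribution of a categorical variable
#'
#' Relative frequencies over the full domain (codes absent from the data get
#' probability 0). An empty input has no distribution and is an error.
#'
#' @param values Character vector of observed codes.
#' @param domain Character vector of all domain codes.
#' @return Named numeric vector over `domain`, summing to 1.
#' @export
empirical_distribution <- function(values, domain) {
  if (length(values) == 0L) stop("cannot form a distribution from zero records", call. = FALSE)
  bad <- setdiff(unique(values), domain)
  if (length(bad)) stop("value(s) outside the domain: ", paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(values, levels = domain))
  stats::setNames(as.numeric(counts) / length(values), domain)
}

#' Hierarchy-aware earth mover's distance between two distributions
#'
#' Earth mover's distance over the leaves of a semantic value hierarchy,
#' with ground distance `height(lowest common ancestor) / H` between two
#' codes (`H` = tree height). Computed by the recursive tree formula: for
#' each node, `extra` is the signed surplus of `p` over `q` summed across
#' its leaves; each internal node `N` with children `c_1..c_m` contributes
#'
#' `cost(N) = height(N)/H * min(sum_i max(extra(c_i), 0), sum_i max(-extra(c_i), 0))`
#'
#' and the distance is the sum of these costs. The result lies in `[0, 1]`,
#' is symmetric, is 0 iff `p == q`, and equals the minimum-cost transport
#' value under the same ground distance. On a flat hierarchy (`H = 1`) it
#' reduces to total variation distance.
#'
#' @param p,q Named numeric probability vectors over the hierarchy's leaves
#'   (any order; each must sum to 1 within `1e-6` and be non-negative).
#' @param h A [hierarchy()].
#' @return The distance, a number in `[0, 1]`.
#' @examples
#' h <- flat_hierarchy("x", c("a", "b"))
#' hierarchical_emd(c(a = 1, b = 0), c(a = 0, b = 1), h)  # 1
#' @export
hierarchical_emd <- function(p, q, h) {
  stopifnot(inherits(h, "puf_hierarchy"))
  leaves <- hierarchy_leaves(h)
  for (d in list(p = p, q = q)) {
    if (is.null(names(d)) || !setequal(names(d), leaves)) {
      stop("distribution support must match the hierarchy's leaves", call. = FALSE)
    }
    if (any(d < -1e-12) || abs(sum(d) - 1) > 1e-6) {
      stop("distributions must be non-negative and sum to 1", call. = FALSE)
    }
  }
  H <- h$height
  surplus <- as.numeric(p[leaves]) - as.numeric(q[leaves])
  # full root-to-leaf label paths, one row per leaf (last column = leaf code)
  path_mat <- matrix("", nrow = length(leaves), ncol = H)
  for (i in seq_along(leaves)) {
    path_mat[i, ] <- c(h$paths[[leaves[i]]], leaves[i])
  }
  cost <- 0
  node_extra <- function(idx, depth) {
    if (depth == H) return(surplus[idx])
    keys <- path_mat[idx, depth + 1L]
    extras <- vapply(split(idx, factor(keys, levels = unique(keys))),
                     node_extra, numeric(1L), depth = depth + 1L)
    cost <<- cost + ((H - depth) / H) *
      min(sum(pmax(extras, 0)), sum(pmax(-extras, 0)))
    sum(extras)
  }
  node_extra(seq_along(leaves), 0L)
  min(max(cost, 0), 1)
}

#' Find equivalence classes violating t-closeness
#'
#' t-closeness requires that, within every equivalence class, the empirical
#' distribution of a sensitive variable deviates from the reference
#' distribution (by default, the whole dataset's) by at most `t` under
#' [hierarchical_emd()].
#'
#' @inheritParams partition_classes
#' @param sensitive_var Name of the sensitive variable.
#' @param t Threshold in (0, 1]; a class violates iff its distance exceeds
#'   `t` strictly.
#' @param h The variable's [hierarchy()].
#' @param classes Optional precomputed [partition_classes()] output.
#' @return The violating classes, with an `emd` column appended.
#' @export
check_t_closeness <- function(data, key_vars, sensitive_var, t, h, classes = NULL) {
  stopifnot(inherits(h, "puf_hierarchy"), is.numeric(t), t > 0)
  if (!sensitive_var %in% names(data)) {
    stop("unknown sensitive variable '", sensitive_var, "'", call. = FALSE)
  }
  if (nrow(data) == 0L) {
    return(dplyr::mutate(partition_classes(data, key_vars), emd = numeric(0L)))
  }
  if (is.null(classes)) classes <- partition_classes(data, key_vars)
  domain <- hierarchy_leaves(h)
  overall <- empirical_distribution(data[[sensitive_var]], domain)
  values_by_id <- stats::setNames(data[[sensitive_var]], data$record_id)
  emd <- vapply(classes$record_ids, function(ids) {
    hierarchical_emd(empirical_distribution(values_by_id[as.character(ids)], domain),
                     overall, h)
  }, numeric(1L))
  dplyr::filter(dplyr::mutate(classes, emd = emd), .data$emd > t)
}

#' Find attribute values carried by too few records
#'
#' The value-frequency rule demands that every value actually present in a
#' release is shared by at least `min_count` individuals, protecting people
#' with rare characteristics on single variables. Values absent from the
#' data are vacuously safe. Occurrences of a variable's explicit
#' not-applicable code are exempt by default: in this schema they are forced
#' by an absent clinical phase and carry no information beyond the phase
#' indicator, which is itself checked.
#'
#' @param data A dataset tibble.
#' @param config A [pipeline_config()]; supplies the variable list and
#'   `na_code`s.
#' @param min_count Positive integer (defaults to the config's
#'   `min_value_count`).
#' @param vars Variables to scan (default: all schema variables).
#' @param exempt_na Exempt each variable's `na_code` from the rule.
#' @return A list with `rare_values` (tibble `variable`, `value`, `n`) and
#'   `record_ids` (sorted ids of all records carrying at least one rare
#'   value).
#' @export
check_value_frequency <- function(data, config, min_count = config$min_value_count,
                                  vars = config_vars(config), exempt_na = TRUE) {
  stopifnot(inherits(config, "pipeline_config"), min_count >= 1)
  rare <- list()
  ids <- integer(0L)
  for (v in vars) {
    counts <- table(data[[v]])
    na_code <- config$variables[[v]]$na_code
    for (val in names(counts)) {
      if (exempt_na && !is.null(na_code) && val == na_code) next
      n <- as.integer(counts[[val]])
      if (n >= 1L && n < min_count) {
        rare[[length(rare) + 1L]] <- tibble::tibble(variable = v, value = val, n = n)
        ids <- c(ids, data$record_id[data[[v]] == val])
      }
    }
  }
  rare_values <- if (length(rare)) dplyr::bind_rows(rare) else {
    tibble::tibble(variable = character(0L), value = character(0L), n = integer(0L))
  }
  list(rare_values = rare_values, record_ids = sort(unique(ids)))
}
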