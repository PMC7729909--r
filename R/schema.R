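#' Define a categorical variable
#'
#' A variable specification describes one column of a registry table: its
#' name, its disclosure-control role, the ordered set of categorical codes it
#' may take, and (optionally) which code stands for "not applicable".
#'
#' Roles follow the usual quasi-identifier taxonomy:
#' * `"key"` — quasi-identifier, checked under k-anonymity;
#' * `"sensitive"` — protected from inference via t-closeness;
#' * `"derived"` — value is implied by other columns (e.g. a clinical-phase
#'   indicator implied by whether phase-specific fields are populated) and is
#'   therefore excluded from the key and sensitive checks;
#' * `"other"` — carried along, only subject to the value-frequency rule.
#'
#' @param name Variable name (column header).
#' @param role One of `"key"`, `"sensitive"`, `"derived"`, `"other"`.
#' @param domain Character vector of unique, non-empty categorical codes, in
#'   display order.
#' @param na_code Optional code (member of `domain`) meaning
#'   "not applicable / not collected". Values are stored as this literal
#'   code, never as a missing cell.
#' @return An object of class `variable_spec`.
#' @examples
#' variable_spec("Gender", "key", c("male", "female"))
#' @export
variable_spec <- function(name, role = c("key", "sensitive", "derived", "other"),
                          domain, na_code = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  domain <- as.character(domain)
  if (length(domain) == 0L || anyDuplicated(domain) || any(!nzchar(domain))) {
    stop("domain of '", name, "' must be a non-empty set of unique, non-empty codes",
         call. = FALSE)
  }
  if (!is.null(na_code)) {
    na_code <- as.character(na_code)
    if (!na_code %in% domain) {
      stop("na_code '", na_code, "' of '", name, "' is not in its domain", call. = FALSE)
    }
  }
  structure(list(name = name, role = role, domain = domain, na_code = na_code),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat("<variable_spec> ", x$name, " [", x$role, "]: ",
      paste(x$domain, collapse = ", "),
      if (!is.null(x$na_code)) paste0(" (na_code = ", x$na_code, ")"), "\n", sep = "")
  invisible(x)
}

#' Define a semantic value hierarchy
#'
#' A hierarchy arranges the domain of a sensitive variable as a rooted tree
#' whose leaves are exactly the domain codes and whose leaves all sit at the
#' same depth `H` (number of edges from root to leaf). It supplies the ground
#' distance used by [hierarchical_emd()]: two codes are at distance
#' `height(lowest common ancestor) / H`, so siblings under a deep internal
#' node are semantically close while codes that only meet at the root are at
#' distance 1.
#'
#' `paths` gives, for every leaf, the labels of its internal ancestors from
#' the root downwards (excluding the implicit root and the leaf itself); all
#' paths must have the same length `H - 1`. A leaf that sits conceptually
#' directly under the root in a deeper tree is represented by a chain of
#' single-child internal nodes, which leaves all its ground distances at 1.
#'
#' @param variable Name of the variable the hierarchy structures.
#' @param paths Named list: leaf code -> character vector of ancestor labels
#'   (possibly `character(0)` for a flat tree). Names must be exactly the
#'   variable's domain.
#' @return An object of class `puf_hierarchy` with fields `variable`,
#'   `height` (the common leaf depth `H >= 1`) and `paths`.
#' @seealso [flat_hierarchy()] for the degenerate one-level tree.
#' @examples
#' hierarchy("Last known patient status", list(
#'   "alive-recovered" = "alive",
#'   "alive-not-recovered" = "alive",
#'   "dead-covid" = "dead",
#'   "dead-other" = "dead"
#' ))
#' @export
hierarchy <- function(variable, paths) {
  stopifnot(is.list(paths), !is.null(names(paths)))
  leaves <- names(paths)
  if (anyDuplicated(leaves)) stop("duplicate leaves in hierarchy for '", variable, "'", call. = FALSE)
  depths <- vapply(paths, length, integer(1L)) + 1L
  if (length(unique(depths)) != 1L) {
    stop("hierarchy for '", variable, "' is unbalanced: all root-to-leaf paths ",
         "must have equal length (got depths ", paste(sort(unique(depths)), collapse = ", "),
         ")", call. = FALSE)
  }
  h <- unname(depths[1L])
  if (h < 1L) stop("hierarchy for '", variable, "' must have height >= 1", call. = FALSE)
  paths <- lapply(paths, as.character)
  structure(list(variable = variable, height = h, paths = paths),
            class = "puf_hierarchy")
}

#' Flat (single-level) hierarchy over a domain
#'
#' All leaves hang directly off the root (`H = 1`), so every pair of distinct
#' codes is at ground distance 1 and [hierarchical_emd()] reduces to total
#' variation distance.
#'
#' @inheritParams hierarchy
#' @param domain Character vector of leaf codes.
#' @return A `puf_hierarchy` of height 1.
#' @export
flat_hierarchy <- function(variable, domain) {
  paths <- stats::setNames(rep(list(character(0L)), length(domain)), domain)
  hierarchy(variable, paths)
}

#' @export
print.puf_hierarchy <- function(x, ...) {
  cat("<puf_hierarchy> ", x$variable, " (height ", x$height, ", ",
      length(x$paths), " leaves)\n", sep = "")
  for (leaf in names(x$paths)) {
    cat("  root", paste(c(x$paths[[leaf]], leaf), collapse = " > "), "\n", sep = " > ")
  }
  invisible(x)
}

hierarchy_leaves <- function(h) names(h$paths)

#' Assemble and validate a pipeline configuration
#'
#' Bundles the variable schema, the semantic hierarchies and the privacy
#' parameters that drive [anonymize()]. Key and sensitive variable lists
#' default to the roles declared in `variables`; every sensitive variable
#' must come with a hierarchy whose leaves match its domain exactly.
#'
#' Default parameters encode the release policy for an open registry file:
#' `k = 11` (maximum prosecutor risk 1/11 = 9.09%, the EMA risk ceiling),
#' `t = 0.5` for t-closeness under the hierarchy-aware earth mover's
#' distance, and a minimum of 10 individuals behind every published value.
#'
#' @param variables List of [variable_spec()] objects (order defines column
#'   order).
#' @param hierarchies Named list of [hierarchy()] objects, one per sensitive
#'   variable (extra hierarchies for non-sensitive variables are allowed and
#'   used e.g. by [case_fatality_rate()]).
#' @param k k-anonymity parameter (positive integer).
#' @param t t-closeness threshold in (0, 1].
#' @param min_value_count Minimum number of records behind any published
#'   value (positive integer).
#' @param key_threshold Score sum above which a variable counts as a key in
#'   [classify_key_variables()].
#' @param key_vars,sensitive_vars Optional explicit overrides of the
#'   role-derived variable lists.
#' @param seed Optional integer recorded for provenance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(variables, hierarchies = list(), k = 11L, t = 0.5,
                            min_value_count = 10L, key_threshold = 5L,
                            key_vars = NULL, sensitive_vars = NULL, seed = NULL) {
  stopifnot(is.list(variables), length(variables) > 0L)
  if (!all(vapply(variables, inherits, logical(1L), "variable_spec"))) {
    stop("all elements of 'variables' must be variable_spec objects", call. = FALSE)
  }
  names(variables) <- vapply(variables, `[[`, character(1L), "name")
  if (anyDuplicated(names(variables))) stop("duplicate variable names", call. = FALSE)

  roles <- vapply(variables, `[[`, character(1L), "role")
  if (is.null(key_vars)) key_vars <- names(variables)[roles == "key"]
  if (is.null(sensitive_vars)) sensitive_vars <- names(variables)[roles == "sensitive"]
  unknown <- setdiff(c(key_vars, sensitive_vars), names(variables))
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(intersect(key_vars, sensitive_vars))) {
    stop("key_vars and sensitive_vars must be disjoint", call. = FALSE)
  }
  if (length(key_vars) == 0L) stop("at least one key variable is required", call. = FALSE)

  k <- as.integer(k)
  min_value_count <- as.integer(min_value_count)
  key_threshold <- as.integer(key_threshold)
  stopifnot(k >= 1L, min_value_count >= 1L, is.numeric(t), t > 0, t <= 1)

  if (length(hierarchies)) {
    hnames <- vapply(hierarchies, `[[`, character(1L), "variable")
    names(hierarchies) <- hnames
  }
  for (v in sensitive_vars) {
    if (!v %in% names(hierarchies)) {
      stop("sensitive variable '", v, "' has no hierarchy", call. = FALSE)
    }
  }
  for (v in names(hierarchies)) {
    if (!v %in% names(variables)) stop("hierarchy for unknown variable '", v, "'", call. = FALSE)
    if (!setequal(hierarchy_leaves(hierarchies[[v]]), variables[[v]]$domain)) {
      stop("hierarchy leaves for '", v, "' do not match its domain", call. = FALSE)
    }
  }

  structure(list(variables = variables, hierarchies = hierarchies,
                 key_vars = key_vars, sensitive_vars = sensitive_vars,
                 k = k, t = t, min_value_count = min_value_count,
                 key_threshold = key_threshold, seed = seed),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> ", length(x$variables), " variables (",
      length(x$key_vars), " key, ", length(x$sensitive_vars), " sensitive)\n",
      "  k = ", x$k, ", t = ", x$t, ", min_value_count = ", x$min_value_count,
      ", key_threshold = ", x$key_threshold, "\n", sep = "")
  invisible(x)
}

config_vars <- function(config) names(config$variables)

config_domain <- function(config, variable) {
  spec <- config$variables[[variable]]
  if (is.null(spec)) stop("unknown variable '", variable, "'", call. = FALSE)
  spec$domain
}
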