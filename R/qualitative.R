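#' Classify variables as quasi-identifiers from qualitative risk scores
#'
#' Implements the qualitative linkage-risk assessment in which each variable
#' is scored for replicability (can an adversary observe the value again?),
#' availability (is it recorded in accessible external sources?) and
#' distinguishability (how much does it narrow down an individual?), each on
#' a 1 = low / 2 = medium / 3 = high scale. A variable is classified as a
#' key (quasi-identifier) when the sum of its three scores strictly exceeds
#' `threshold`; with the default of 5, a sum of 5 is still non-key.
#'
#' Scores are expert judgments supplied by the user (or shipped via
#' [leoss_variable_scores()]); this function only mechanizes the arithmetic
#' and the classification.
#'
#' @param scores Data frame with columns `variable`, `replicability`,
#'   `availability`, `distinguishability`, each score in `{1, 2, 3}`.
#' @param threshold Strict lower bound on the score sum for key status.
#' @return A tibble with the input columns plus `score_sum` and `is_key`,
#'   in input order.
#' @examples
#' classify_key_variables(leoss_variable_scores())
#' @export
classify_key_variables <- function(scores, threshold = 5L) {
  scores <- tibble::as_tibble(scores)
  needed <- c("variable", "replicability", "availability", "distinguishability")
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols)) {
    stop("scores are missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(scores) == 0L) stop("scores must contain at least one variable", call. = FALSE)
  for (col in needed[-1L]) {
    v <- scores[[col]]
    if (!is.numeric(v) || any(!v %in% 1:3)) {
      stop("column '", col, "' must only contain scores in {1, 2, 3}", call. = FALSE)
    }
  }
  dplyr::mutate(
    scores,
    score_sum = as.integer(.data$replicability + .data$availability + .data$distinguishability),
    is_key = .data$score_sum > threshold
  )
}
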