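# Small two-key / one-sensitive schema used across unit tests.
tiny_config <- function(k = 2L, t = 0.5, min_value_count = 1L, ...) {
  vars <- list(
    variable_spec("group", "key", c("A", "B", "C")),
    variable_spec("side", "key", c("left", "right")),
    variable_spec("outcome", "sensitive", c("yes", "no", "rare"))
  )
  pipeline_config(vars, list(flat_hierarchy("outcome", c("yes", "no", "rare"))),
                  k = k, t = t, min_value_count = min_value_count, ...)
}

# Build a tiny dataset from per-class counts: rows(group, side, outcome, n)
tiny_dataset <- function(...) {
  rows <- dplyr::bind_rows(...)
  out <- rows[rep(seq_len(nrow(rows)), rows$n), c("group", "side", "outcome")]
  dplyr::bind_cols(tibble::tibble(record_id = seq_len(nrow(out))), out)
}

trow <- function(group, side, outcome, n) {
  tibble::tibble(group = group, side = side, outcome = outcome, n = n)
}
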