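#' Plot the audit trail of an anonymization run
#'
#' Bar chart of records suppressed per fixpoint iteration, coloured by the
#' requirement that triggered the suppression.
#'
#' @param object A [anonymize()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot puf_anonymization
#' @export
autoplot.puf_anonymization <- function(object, ...) {
  audit <- object$audit
  if (nrow(audit) == 0L) {
    audit <- tibble::tibble(iteration = 1L, requirement = "none", n_suppressed = 0L)
  }
  ggplot2::ggplot(audit, ggplot2::aes(x = factor(.data$iteration),
                                      y = .data$n_suppressed,
                                      fill = .data$requirement)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "fixpoint iteration", y = "records suppressed",
                  fill = "requirement",
                  title = "Suppression by requirement and iteration") +
    ggplot2::theme_minimal()
}

#' Plot release properties over a growing registry
#'
#' Faceted line plot of the suppressed fraction and of the case fatality
#' rate before/after anonymization against the primary dataset size —
#' the standard view of how "hiding in the crowd" protection relaxes as the
#' registry grows.
#'
#' @param object A [release_trend()] tibble (also works when called with a
#'   `puf_release_series` plus the matching `series`/`config`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_release_trend <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, size = .data$size, panel = "suppressed fraction",
                     series = "released", value = .data$suppressed_fraction),
    dplyr::transmute(object, size = .data$size, panel = "case fatality rate (%)",
                     series = "primary", value = .data$cfr_primary),
    dplyr::transmute(object, size = .data$size, panel = "case fatality rate (%)",
                     series = "released", value = .data$cfr_released)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "primary dataset size", y = NULL, colour = NULL,
                  title = "Release properties over registry growth") +
    ggplot2::theme_minimal()
}

#' Plot before/after value frequencies from a quality report
#'
#' @param object A [quality_report()].
#' @param variables Variables to show (default: the sensitive variables
#'   present in the report).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quality_report
#' @export
autoplot.quality_report <- function(object, variables = NULL, ...) {
  long <- tidy(object)
  if (nrow(long) == 0L) stop("report of an empty release has no frequencies to plot", call. = FALSE)
  if (!is.null(variables)) long <- dplyr::filter(long, .data$variable %in% variables)
  long <- tidyr::pivot_longer(long, c("freq_before", "freq_after"),
                              names_to = "side", values_to = "freq",
                              names_prefix = "freq_")
  long$side <- factor(long$side, levels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$freq,
                                     fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "frequency (%)", fill = NULL,
                  title = "Value frequencies before and after anonymization") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
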