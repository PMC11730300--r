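#' @exportS3Method ggplot2::autoplot
autoplot.ecg_record <- function(object, leads = c("II", "V1", "V5"), ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(t(object$signals[leads, , drop = FALSE])) |>
      dplyr::mutate(time = (dplyr::row_number() - 1) / object$fs),
    -"time", names_to = "lead", values_to = "mv"
  )
  df$lead <- factor(df$lead, levels = leads)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lead)) +
    ggplot2::labs(x = "time (s)", y = "mV") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ecgage_km <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years of follow-up", y = "survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.aligned_relevance <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$tau_ms, .data$relevance)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$lead), ncol = 3) +
    ggplot2::labs(x = "time relative to R-peak (ms)",
                  y = "mean normalized relevance") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.age_validation <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(.data$chronological_age,
                                   .data$predicted_age,
                                   colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "predicted ECG-age (years)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of lead importance
#'
#' @param importance Named 12-vector from [lead_importance()].
#' @return A ggplot object.
#' @export
plot_lead_importance <- function(importance) {
  df <- tibble::tibble(lead = factor(names(importance), levels = ECG_LEADS),
                       weight = as.numeric(importance))
  ggplot2::ggplot(df, ggplot2::aes(.data$lead, .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "lead importance (share of total relevance)") +
    ggplot2::theme_minimal()
}
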