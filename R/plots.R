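#' Kaplan-Meier step plot of an evaluation report's risk groups
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  km <- object$km |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, surv = 1), .x[, c("time", "surv")]
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Months", y = "Survival probability", colour = "Risk group",
      title = sprintf("%s (%s): C-index %.3f, log-rank p = %.2g",
                      object$cohort, object$endpoint,
                      object$cindex$estimate, object$logrank$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Risk-score distribution split by risk group
#'
#' @param report An `evaluation_report`.
#' @return A ggplot object.
#' @export
plot_risk_distribution <- function(report) {
  df <- dplyr::left_join(report$scores, report$groups, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$score, fill = .data$group)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = report$cutoff, linetype = 2) +
    ggplot2::labs(x = "Risk score (log relative hazard)", y = "Patients",
                  fill = "Risk group") +
    ggplot2::theme_minimal()
}

#' Penalized-effect plot of a gene signature
#'
#' @param object A `gene_signature`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_signature <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::arrange(.data$lasso_beta) |>
    dplyr::mutate(gene_id = factor(.data$gene_id, levels = .data$gene_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$lasso_beta, .data$gene_id)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = "Penalized log hazard ratio per SD", y = NULL) +
    ggplot2::theme_minimal()
}

#' Point-scale sketch of a nomogram
#'
#' One horizontal segment per covariate from 0 to its maximum points,
#' mirroring the printed nomogram layout.
#'
#' @param object A `nomogram_spec`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nomogram_spec <- function(object, ...) {
  vars <- object$variables
  ggplot2::ggplot(vars) +
    ggplot2::geom_segment(ggplot2::aes(
      x = 0, xend = .data$max_points,
      y = .data$term, yend = .data$term
    ), linewidth = 2, lineend = "round") +
    ggplot2::labs(x = "Points", y = NULL,
                  title = paste("Horizons (months):",
                                paste(object$horizons, collapse = ", "))) +
    ggplot2::theme_minimal()
}
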