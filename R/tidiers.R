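#' Tidy a Cox fit into a one-row-per-term tibble
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A tibble with term, estimate, std_error, hazard_ratio, conf_low,
#'   conf_high, p_value.
#' @export
tidy.cox_fit <- function(x, ...) x$terms

#' @rdname tidy.cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, loglik = x$loglik,
    loglik_null = x$loglik_null, iter = x$iter, ties = x$ties
  )
}

#' Tidy a gene signature
#'
#' @param x A `gene_signature`.
#' @param ... Unused.
#' @return The per-gene tibble (gene_id, uni_beta, uni_se, uni_p, lasso_beta).
#' @export
tidy.gene_signature <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("gene_id", "uni_beta", "uni_se", "uni_p", "lasso_beta")])
}

#' @rdname tidy.gene_signature
#' @export
glance.gene_signature <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x), lambda = attr(x, "lambda"), alpha = attr(x, "alpha"),
    target_size = attr(x, "target_size")
  )
}

#' Tidy a trained neural Cox model's training log
#'
#' @param x A `deepcox_model`.
#' @param ... Unused.
#' @return The per-epoch training log tibble.
#' @export
tidy.deepcox_model <- function(x, ...) x$training_log

#' @rdname tidy.deepcox_model
#' @export
glance.deepcox_model <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    hidden = paste(x$config$hidden, collapse = "x"),
    dropout = x$config$dropout,
    epochs_run = nrow(x$training_log),
    best_monitor_loglik = x$best_monitor_loglik,
    monitor = x$monitor, seed = x$seed
  )
}

#' Tidy an evaluation report into a long metric tibble
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A tibble with columns metric, value.
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble::tibble(
    metric = c(
      "cindex", "cindex_conf_low", "cindex_conf_high",
      paste0("auc_", x$auc$horizon),
      "logrank_chisq", "logrank_p", "risk_cutoff"
    ),
    value = c(
      x$cindex$estimate, x$cindex$conf_low, x$cindex$conf_high,
      x$auc$auc, x$logrank$chisq, x$logrank$p_value, x$cutoff
    )
  )
}

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    cohort = x$cohort, endpoint = x$endpoint, n = x$n, n_events = x$n_events,
    cindex = x$cindex$estimate, logrank_p = x$logrank$p_value
  )
}
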