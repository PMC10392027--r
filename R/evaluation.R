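#' Harrell's concordance index
#'
#' A pair (i, j) is usable when the shorter observed time belongs to a
#' subject with an event: either \eqn{t_i < t_j} with \eqn{\delta_i = 1}, or
#' a tied time where exactly one of the two has an event. The pair counts as
#' concordant when the event subject carries the larger risk score; tied
#' scores credit 0.5. Higher score must mean worse prognosis.
#'
#' @param scores Numeric risk scores, or the tibble from [predict_risk()].
#' @param outcomes Data frame with `time` and `event` aligned to scores.
#' @return Concordance in [0, 1].
#' @export
concordance_index <- function(scores, outcomes) {
  s <- if (is.data.frame(scores)) scores$score else scores
  time <- outcomes$time
  event <- outcomes$event
  check_outcomes(time, event, require_event = FALSE)
  if (length(s) != length(time)) rlang::abort("scores and outcomes lengths differ.")
  num <- 0
  den <- 0
  for (i in which(event == 1)) {
    cmp <- which(time > time[i] | (time == time[i] & event == 0))
    if (!length(cmp)) next
    den <- den + length(cmp)
    num <- num + sum(s[i] > s[cmp]) + 0.5 * sum(s[i] == s[cmp])
  }
  if (den == 0) rlang::abort("No usable pairs for the concordance index.")
  num / den
}

#' Bootstrap confidence interval for the concordance index
#'
#' Nonparametric bootstrap over samples with percentile 2.5/97.5 bounds;
#' replicates without usable pairs are redrawn (with a warning if they exceed
#' 5% of draws). Deterministic given the seed.
#'
#' @inheritParams concordance_index
#' @param n_boot Number of bootstrap replicates (>= 200; default 1000).
#' @param seed Integer seed.
#' @return A one-row tibble: `estimate`, `conf_low`, `conf_high`.
#' @export
cindex_ci <- function(scores, outcomes, n_boot = 1000L, seed = 1L) {
  s <- if (is.data.frame(scores)) scores$score else scores
  if (n_boot < 200) rlang::abort("n_boot must be >= 200.")
  point <- concordance_index(s, outcomes)
  n <- length(s)
  stat <- withr::with_seed(seed, {
    redraws <- 0L
    vals <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(concordance_index(s[idx], outcomes[idx, ]), error = function(e) NA_real_)
        if (!is.na(v)) break
        redraws <- redraws + 1L
      }
      vals[b] <- v
    }
    list(vals = vals, redraws = redraws)
  })
  if (stat$redraws > 0.05 * n_boot) {
    rlang::warn(sprintf("%d bootstrap replicates had no usable pairs and were redrawn.", stat$redraws))
  }
  q <- stats::quantile(stat$vals, c(0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(estimate = point, conf_low = q[1], conf_high = q[2])
}

# KM estimate of the censoring survival function G(t), with an evaluator
# supporting left limits G(t-).
censoring_km <- function(outcomes) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1,
                          data = as.data.frame(outcomes))
  times <- sf$time
  surv <- sf$surv
  function(t, left = FALSE) {
    if (left) {
      idx <- findInterval(t - .Machine$double.eps^0.5, times)
    } else {
      idx <- findInterval(t, times)
    }
    ifelse(idx == 0, 1, surv[pmax(idx, 1)])
  }
}

#' Time-dependent AUC under censoring (cumulative/dynamic, IPCW)
#'
#' Discrimination of event-by-horizon status: cases are subjects with an
#' observed event by `horizon`, controls are subjects still at risk beyond
#' it. Cases are weighted by \eqn{1/\hat G(t_i^-)} and controls by
#' \eqn{1/\hat G(t)}, where \eqn{\hat G} is the Kaplan-Meier estimate of the
#' censoring distribution, making the estimator consistent under independent
#' censoring. Without censoring before the horizon it reduces exactly to the
#' rank-statistic (Mann-Whitney) AUC of score against event-by-horizon.
#'
#' @inheritParams concordance_index
#' @param horizon Time horizon in months.
#' @return AUC in [0, 1].
#' @export
time_dependent_auc <- function(scores, outcomes, horizon) {
  s <- if (is.data.frame(scores)) scores$score else scores
  time <- outcomes$time
  event <- outcomes$event
  check_outcomes(time, event, require_event = FALSE)
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon)
  if (!length(cases)) rlang::abort(paste0("No events by horizon t = ", horizon, "."))
  if (!length(controls)) rlang::abort(paste0("No subjects beyond horizon t = ", horizon, "."))
  G <- censoring_km(outcomes)
  w_case <- 1 / G(time[cases], left = TRUE)
  w_ctrl <- 1 / G(horizon)
  num <- 0
  for (k in seq_along(cases)) {
    i <- cases[k]
    num <- num + w_case[k] * w_ctrl *
      (sum(s[i] > s[controls]) + 0.5 * sum(s[i] == s[controls]))
  }
  num / (sum(w_case) * w_ctrl * length(controls))
}

#' Dichotomize risk scores into low/high groups
#'
#' The default rule is the median of the training scores; the cutoff is
#' stored so validation cohorts reuse the training cutoff rather than their
#' own. High risk means score strictly above the cutoff.
#'
#' @inheritParams concordance_index
#' @param cutoff A fixed cutoff (e.g. from the training cohort); `NULL`
#'   computes the median of `scores`.
#' @return A list: `group` (factor low/high), `cutoff`.
#' @export
dichotomize_risk <- function(scores, cutoff = NULL) {
  s <- if (is.data.frame(scores)) scores$score else scores
  if (length(unique(s)) == 1L) rlang::abort("All risk scores identical; cannot dichotomize.")
  if (is.null(cutoff)) cutoff <- stats::median(s)
  group <- factor(ifelse(s > cutoff, "high", "low"), levels = c("low", "high"))
  if (all(group == "high") || all(group == "low")) {
    rlang::warn("All samples fall on one side of the risk cutoff.")
  }
  list(group = group, cutoff = cutoff)
}

#' Evaluate a trained model on a cohort
#'
#' Composes prediction, concordance (with bootstrap CI), time-dependent AUC
#' at the requested horizons, risk dichotomization, per-group Kaplan-Meier
#' curves and the log-rank test into one report.
#'
#' @param model A `deepcox_model`.
#' @param expr Cohort expression with frozen preprocessing applied.
#' @param clinical Clinical tibble for the cohort (see [validate_clinical()]).
#' @param horizons Numeric months for time-dependent AUC (default c(12, 36, 60)).
#' @param cutoff Risk cutoff from the training cohort; `NULL` uses this
#'   cohort's median (training use only).
#' @param endpoint Label stored in the report (e.g. "OS", "PFS").
#' @param n_boot Bootstrap replicates for the C-index CI.
#' @param seed Integer seed for the bootstrap.
#' @return An `evaluation_report`: cohort metadata, `cindex` tibble, `auc`
#'   tibble (horizon, auc), `logrank` tibble, `cutoff`, `groups`, `km` tibble
#'   (per-group curves), `scores`.
#' @export
evaluate_cohort <- function(model, expr, clinical, horizons = c(12, 36, 60),
                            cutoff = NULL, endpoint = "OS", n_boot = 1000L,
                            seed = 1L) {
  clinical <- validate_clinical(clinical)
  if (nrow(clinical) == 0) rlang::abort("Empty cohort.")
  scores <- predict_risk(model, expr)
  outcomes <- as_outcomes(clinical, scores$sample_id)
  cindex <- cindex_ci(scores$score, outcomes, n_boot = n_boot, seed = seed)
  auc <- purrr::map_dfr(horizons, function(h) {
    val <- tryCatch(time_dependent_auc(scores$score, outcomes, h),
                    error = function(e) NA_real_)
    tibble::tibble(horizon = h, auc = val)
  })
  dich <- dichotomize_risk(scores$score, cutoff)
  grp <- dich$group
  lr <- logrank_test(outcomes[grp == "low", ], outcomes[grp == "high", ])
  km <- dplyr::bind_rows(
    dplyr::mutate(km_curve(outcomes[grp == "low", ]), group = "low"),
    dplyr::mutate(km_curve(outcomes[grp == "high", ]), group = "high")
  )
  structure(
    list(
      cohort = clinical$cohort[1], endpoint = endpoint,
      n = nrow(clinical), n_events = sum(outcomes$event),
      cindex = cindex, auc = auc, logrank = lr,
      cutoff = dich$cutoff,
      groups = tibble::tibble(sample_id = scores$sample_id, group = grp),
      km = km, scores = scores
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> cohort ", x$cohort, " (", x$endpoint, "); n = ",
      x$n, ", events = ", x$n_events, "\n", sep = "")
  cat(sprintf("  C-index %.3f (95%% CI %.3f-%.3f)\n",
              x$cindex$estimate, x$cindex$conf_low, x$cindex$conf_high))
  for (i in seq_len(nrow(x$auc))) {
    cat(sprintf("  AUC at %g months: %.3f\n", x$auc$horizon[i], x$auc$auc[i]))
  }
  cat(sprintf("  log-rank low vs high: chisq = %.2f, p = %.3g\n",
              x$logrank$chisq, x$logrank$p_value))
  invisible(x)
}

#' Write an evaluation report as structured key-value text plus CSV tables
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary_lines <- c(
    paste0("cohort\t", report$cohort),
    paste0("endpoint\t", report$endpoint),
    paste0("n\t", report$n),
    paste0("n_events\t", report$n_events),
    sprintf("cindex\t%.17g", report$cindex$estimate),
    sprintf("cindex_low\t%.17g", report$cindex$conf_low),
    sprintf("cindex_high\t%.17g", report$cindex$conf_high),
    sprintf("auc_%g\t%.17g", report$auc$horizon, report$auc$auc),
    sprintf("logrank_chisq\t%.17g", report$logrank$chisq),
    sprintf("logrank_p\t%.17g", report$logrank$p_value),
    sprintf("risk_cutoff\t%.17g", report$cutoff)
  )
  writeLines(summary_lines, file.path(dir, "report.tsv"))
  utils::write.csv(report$km, file.path(dir, "km_curves.csv"), row.names = FALSE)
  utils::write.csv(report$scores, file.path(dir, "risk_scores.csv"), row.names = FALSE)
  invisible(dir)
}
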