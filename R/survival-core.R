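#' Breslow partial log-likelihood of a risk-score vector
#'
#' Computes the Cox partial log-likelihood
#' \deqn{\ell(\eta) = \sum_{i: \delta_i = 1}\Big[\eta_i -
#'   \log \sum_{j: t_j \ge t_i} e^{\eta_j}\Big]}
#' with the Breslow convention for tied event times (all events at a time
#' share the full risk-set denominator) and a log-sum-exp guard against
#' overflow. This is the training loss of the neural Cox head and the
#' likelihood behind every classical fit in the package.
#'
#' @param eta Numeric vector of per-sample risk scores (log relative hazard).
#' @param outcomes Data frame with columns `time` (> 0) and `event` (0/1);
#'   at least one event required.
#' @return The partial log-likelihood, a single number.
#' @export
cox_partial_loglik <- function(eta, outcomes) {
  time <- outcomes$time
  event <- outcomes$event
  check_outcomes(time, event)
  if (length(eta) != length(time)) rlang::abort("eta and outcomes lengths differ.")
  if (!all(is.finite(eta))) rlang::abort("eta must be finite.")
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]
  e_s <- event[ord]
  eta_s <- eta[ord]
  m <- max(eta_s)
  # risk set of a time = every position up to the end of its tie group
  last_in_group <- stats::ave(seq_along(t_s), match(t_s, unique(t_s)), FUN = max)
  if (m - min(eta_s) < 500) {
    log_denom <- log(cumsum(exp(eta_s - m)))[last_in_group] + m
  } else {
    # a single global shift underflows when a risk set's own maximum is far
    # below the overall maximum; fall back to a running log-sum-exp
    lse <- numeric(length(eta_s))
    acc <- -Inf
    for (k in seq_along(eta_s)) {
      b <- eta_s[k]
      acc <- if (is.infinite(acc)) b else max(acc, b) + log1p(exp(-abs(acc - b)))
      lse[k] <- acc
    }
    log_denom <- lse[last_in_group]
  }
  sum((eta_s - log_denom)[e_s == 1])
}

# Gradient of the Breslow partial log-likelihood with respect to eta.
# d ell / d eta_i = delta_i - exp(eta_i) * sum_{event times t <= t_i} d_t / S_t
cox_partial_loglik_grad <- function(eta, outcomes) {
  time <- outcomes$time
  event <- outcomes$event
  n <- length(eta)
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]
  e_s <- event[ord]
  eta_s <- eta[ord]
  m <- max(eta_s)
  w <- exp(eta_s - m)
  cs <- cumsum(w)
  grp <- match(t_s, unique(t_s))
  last_in_group <- stats::ave(seq_along(t_s), grp, FUN = max)
  denom <- cs[last_in_group] # scaled by e^{-m}
  d_over_S <- e_s / denom
  # cumulative from the end (earliest times) toward position i:
  # events with t <= t_i are positions i..n in decreasing-time order
  tail_sum <- rev(cumsum(rev(d_over_S)))
  # within a tie group every member shares the same risk-set membership:
  # events at t_i include i itself, so take the tail starting at the group's
  # first position
  first_in_group <- stats::ave(seq_along(t_s), grp, FUN = min)
  g_s <- e_s - w * tail_sum[first_in_group]
  g <- numeric(n)
  g[ord] <- g_s
  g
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Breslow partial likelihood by Newton iteration (via
#' \code{survival::coxph}), returning log hazard ratios with Wald standard
#' errors, 95% confidence intervals, p-values, and the Breslow baseline
#' cumulative hazard evaluated at the covariate means.
#'
#' @param X Numeric matrix or data frame, samples x covariates, with column
#'   names. No covariate may be constant.
#' @param outcomes Data frame with columns `time` and `event`.
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @return A `cox_fit` object: `terms` tibble (term, estimate, std_error,
#'   hazard_ratio, conf_low, conf_high, p_value), `loglik` (maximized partial
#'   log-likelihood), `baseline` tibble (time, cumhaz, surv at covariate
#'   means), `means`, `n`, `n_events`, convergence metadata.
#' @export
fit_cox <- function(X, outcomes, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  check_outcomes(outcomes$time, outcomes$event)
  if (nrow(X) != nrow(outcomes)) rlang::abort("X rows must match outcomes.")
  if (nrow(X) <= ncol(X)) rlang::abort("Need more samples than covariates.")
  const <- which(apply(X, 2L, function(v) stats::sd(v) == 0))
  if (length(const)) {
    rlang::abort(paste0(
      "Constant covariate(s): ", paste(colnames(X)[const], collapse = ", ")
    ))
  }
  y <- survival::Surv(outcomes$time, outcomes$event)
  warnings <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(y ~ X, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::setNames(as.numeric(fit$coefficients), colnames(X))
  d <- diag(as.matrix(fit$var))
  se <- ifelse(is.finite(d) & d >= 0, sqrt(pmax(d, 0)), NaN)
  if (length(warnings) || any(!is.finite(se)) || any(abs(beta) > 20)) {
    rlang::warn(paste0(
      "Cox fit may not have converged; estimates can be unreliable",
      if (length(warnings)) paste0(" (", warnings[1], ")") else ""
    ))
  }
  z <- beta / se
  terms <- tibble::tibble(
    term = colnames(X),
    estimate = beta,
    std_error = se,
    hazard_ratio = exp(beta),
    conf_low = exp(beta - 1.96 * se),
    conf_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z))
  )
  sf <- survival::survfit(fit)
  baseline <- tibble::tibble(time = sf$time, cumhaz = sf$cumhaz, surv = exp(-sf$cumhaz))
  structure(
    list(
      terms = terms,
      loglik = fit$loglik[2],
      loglik_null = fit$loglik[1],
      baseline = baseline,
      means = stats::setNames(fit$means, colnames(X)),
      n = nrow(X), n_events = sum(outcomes$event),
      iter = fit$iter, ties = ties, warnings = warnings
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n = ", x$n, ", events = ", x$n_events,
      ", partial loglik = ", format(x$loglik), "\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' Linear predictor and survival predictions from a Cox fit
#'
#' Survival at time t for covariates x is \eqn{\bar S(t)^{\exp(lp - \bar{lp})}}
#' where \eqn{\bar S} is the baseline survival at the covariate means and
#' \eqn{\bar{lp}} the mean linear predictor.
#'
#' @param fit A `cox_fit`.
#' @param X New covariate matrix (samples x covariates, same columns).
#' @param times Horizon(s) in months.
#' @return A samples x times matrix of survival probabilities.
#' @export
predict_survival_cox <- function(fit, X, times) {
  X <- as.matrix(X)[, fit$terms$term, drop = FALSE]
  lp <- drop(X %*% fit$terms$estimate)
  lp_bar <- sum(fit$terms$estimate * fit$means)
  if (any(times > max(fit$baseline$time))) {
    rlang::abort("Horizon beyond the last observed event/censoring time.")
  }
  H <- stats::stepfun(fit$baseline$time, c(0, fit$baseline$cumhaz))(times)
  out <- outer(exp(lp - lp_bar), H, function(r, h) exp(-h * r))
  dimnames(out) <- list(rownames(X), paste0("t", times))
  out
}

#' Kaplan-Meier survival curve
#'
#' @param outcomes Data frame with columns `time` and `event`.
#' @return A tibble with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(outcomes) {
  check_outcomes(outcomes$time, outcomes$event, require_event = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(outcomes))
  tibble::tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, surv = sf$surv
  )
}

#' Two-group log-rank test
#'
#' @param outcomes_a,outcomes_b Data frames with columns `time` and `event`.
#' @return A one-row tibble: `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(outcomes_a, outcomes_b) {
  check_outcomes(outcomes_a$time, outcomes_a$event, require_event = FALSE)
  check_outcomes(outcomes_b$time, outcomes_b$event, require_event = FALSE)
  if (sum(outcomes_a$event) + sum(outcomes_b$event) == 0) {
    rlang::abort("No events in either group; log-rank undefined.")
  }
  dat <- data.frame(
    time = c(outcomes_a$time, outcomes_b$time),
    event = c(outcomes_a$event, outcomes_b$event),
    group = rep(c("A", "B"), c(nrow(outcomes_a), nrow(outcomes_b)))
  )
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  tibble::tibble(
    chisq = sd$chisq, df = 1L,
    p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  )
}
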