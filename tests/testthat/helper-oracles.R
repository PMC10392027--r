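# Independent reference implementations used to validate the package's
# numerical core. Deliberately naive and written against the definitions,
# not against the package code paths.

# Breslow partial log-likelihood by direct risk-set enumeration.
oracle_partial_loglik <- function(eta, time, event) {
  total <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    total <- total + eta[i] - log(sum(exp(eta[risk])))
  }
  total
}

# Single-covariate Cox fit by grid search over beta.
oracle_grid_cox <- function(x, time, event, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ev <- which(event == 1)
  ll <- numeric(length(grid))
  for (i in ev) {
    risk <- which(time >= time[i])
    # log sum_j exp(beta * x_j) over the risk set, for every grid beta
    lse <- log(colSums(exp(outer(x[risk], grid))))
    ll <- ll + x[i] * grid - lse
  }
  grid[which.max(ll)]
}

# L1-penalized Cox by proximal gradient (ISTA with backtracking) on the
# objective (1/n) * negative partial log-likelihood + lambda * ||beta||_1.
oracle_prox_lasso_cox <- function(X, time, event, lambda,
                                  max_iter = 200000, tol = 1e-13) {
  n <- nrow(X)
  negll <- function(b) -oracle_partial_loglik(drop(X %*% b), time, event) / n
  grad <- function(b) {
    eta <- drop(X %*% b)
    g <- numeric(n)
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      w <- exp(eta[risk]) / sum(exp(eta[risk]))
      g[i] <- g[i] + 1
      g[risk] <- g[risk] - w
    }
    -drop(crossprod(X, g)) / n
  }
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  b <- rep(0, ncol(X))
  L <- 1
  f_old <- negll(b)
  for (it in seq_len(max_iter)) {
    g <- grad(b)
    repeat {
      b_new <- soft(b - g / L, lambda / L)
      d <- b_new - b
      if (negll(b_new) <= f_old + sum(g * d) + L / 2 * sum(d^2) + 1e-15) break
      L <- L * 2
    }
    f_new <- negll(b_new)
    obj_old <- f_old + lambda * sum(abs(b))
    obj_new <- f_new + lambda * sum(abs(b_new))
    b <- b_new
    f_old <- f_new
    L <- max(L / 1.5, 1e-4)
    if (abs(obj_old - obj_new) < tol * (abs(obj_old) + 1e-10)) break
  }
  b
}

# Harrell's C by brute-force enumeration of all usable pairs.
oracle_cindex <- function(score, time, event) {
  num <- 0
  den <- 0
  n <- length(score)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # order the pair so a has the smaller time
      a <- if (time[i] <= time[j]) i else j
      b <- if (time[i] <= time[j]) j else i
      usable <- (time[a] < time[b] && event[a] == 1) ||
        (time[a] == time[b] && event[a] + event[b] == 1)
      if (time[a] == time[b] && event[a] + event[b] == 1) {
        # the event subject of a tied-time pair is the "case"
        if (event[b] == 1) { tmp <- a; a <- b; b <- tmp }
      }
      if (!usable) next
      den <- den + 1
      if (score[a] > score[b]) num <- num + 1
      else if (score[a] == score[b]) num <- num + 0.5
    }
  }
  num / den
}

# Two-group log-rank chi-square by direct 2x2 tabulation per event time.
oracle_logrank <- function(timeA, eventA, timeB, eventB) {
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grp <- rep(c(0L, 1L), c(length(timeA), length(timeB)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & grp == 1L)
    n0 <- sum(at_risk & grp == 0L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1L)
    nn <- n0 + n1
    if (nn < 2) next
    o_minus_e <- o_minus_e + d1 - d * n1 / nn
    v <- v + d * (n1 / nn) * (n0 / nn) * (nn - d) / (nn - 1)
  }
  o_minus_e^2 / v
}

# Small random survival instance for oracle comparisons.
random_surv_instance <- function(n, p = 1, tie_prob = 0) {
  X <- matrix(stats::rnorm(n * p), n, p)
  time <- stats::rexp(n) + 0.1
  if (tie_prob > 0) time <- round(time, 1) + 0.05
  event <- stats::rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[sample(n, 1)] <- 1L
  list(X = X, time = time, event = event,
       outcomes = tibble::tibble(time = time, event = event))
}

# Shared small simulated cohort for expensive module tests (memoised).
.test_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed = 42, n = 120, n_genes = 60, n_signal = 5,
                         effect = 0.7, cohort = "training") {
  key <- paste(seed, n, n_genes, n_signal, effect, cohort, sep = "_")
  if (is.null(.test_cohort_cache[[key]])) {
    .test_cohort_cache[[key]] <- simulate_cohort(sim_config(
      n_samples = n, n_genes = n_genes, n_signal = n_signal,
      signal_effect = effect, cohort = cohort, seed = seed
    ))
  }
  .test_cohort_cache[[key]]
}

outcomes_of <- function(cohort) {
  tibble::tibble(time = cohort$clinical$time_months,
                 event = cohort$clinical$event)
}
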