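#' Univariate Cox screening of genes
#'
#' Fits a single-covariate proportional-hazards model per gene on z-scored
#' expression and flags genes with Wald p below `alpha`. Fits are independent
#' across genes, so the result is invariant to gene order. Zero-variance
#' genes are skipped with a warning and never pass.
#'
#' @param expr An `expr_matrix` of z-scored expression, or a genes x samples
#'   numeric matrix.
#' @param outcomes Data frame with columns `time` and `event`, aligned to the
#'   expression samples.
#' @param alpha Wald p-value threshold (default 0.05).
#' @return A tibble with one row per gene: `gene_id`, `estimate`,
#'   `std_error`, `p_value`, `pass`.
#' @export
univariate_screen <- function(expr, outcomes, alpha = 0.05) {
  v <- if (inherits(expr, "expr_matrix")) expr$values else expr
  check_outcomes(outcomes$time, outcomes$event)
  if (ncol(v) != nrow(outcomes)) rlang::abort("Samples must match outcomes rows.")
  y <- survival::Surv(outcomes$time, outcomes$event)
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100)
  res <- purrr::map(seq_len(nrow(v)), function(g) {
    x <- v[g, ]
    if (stats::sd(x) == 0) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    f <- survival::coxph.fit(
      x = matrix(x, ncol = 1), y = y, strata = NULL, offset = NULL,
      init = 0, control = ctrl, weights = NULL, method = "breslow",
      rownames = NULL
    )
    beta <- as.numeric(f$coefficients)
    se <- sqrt(as.numeric(f$var))
    c(beta, se, 2 * stats::pnorm(-abs(beta / se)))
  })
  mat <- do.call(rbind, res)
  n_const <- sum(is.na(mat[, 1]))
  if (n_const > 0) {
    rlang::warn(paste0(n_const, " zero-variance gene(s) skipped in univariate screen."))
  }
  tibble::tibble(
    gene_id = rownames(v),
    estimate = mat[, 1], std_error = mat[, 2], p_value = mat[, 3],
    pass = !is.na(mat[, 3]) & mat[, 3] < alpha
  )
}

#' Smallest penalty with an all-zero LASSO-Cox solution
#'
#' \eqn{\lambda_{max} = \max_j |n^{-1} \sum_{i: \delta_i=1}
#'   (x_{ij} - \bar x_j(R_i))|}, the sup-norm of the (1/n)-scaled partial
#' score at the origin; at or above it the L1 subgradient condition holds
#' with every coefficient zero.
#'
#' @param X Samples x genes matrix (standardized columns).
#' @param outcomes Data frame with `time` and `event`.
#' @return A single number.
#' @export
cox_lambda_max <- function(X, outcomes) {
  X <- as.matrix(X)
  g <- cox_partial_loglik_grad(rep(0, nrow(X)), outcomes)
  max(abs(crossprod(X, g))) / nrow(X)
}

#' L1-penalized Cox regression at a fixed penalty
#'
#' Minimizes \eqn{-n^{-1}\ell(X\beta) + \lambda \|\beta\|_1} (Breslow ties)
#' by coordinate descent via \code{glmnet} on unstandardized columns, warm-
#' started along a short path from \eqn{\lambda_{max}} for stability. At
#' \eqn{\lambda = 0} the solution matches the unpenalized fit.
#'
#' @param X Samples x genes matrix with column names; columns should be
#'   standardized upstream (frozen preprocessing z-scores).
#' @param outcomes Data frame with `time` and `event`.
#' @param lambda Nonnegative penalty.
#' @return Named numeric vector of penalized coefficients (length = ncol(X)).
#' @export
lasso_cox <- function(X, outcomes, lambda) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  check_outcomes(outcomes$time, outcomes$event)
  if (lambda < 0) rlang::abort("lambda must be >= 0.")
  lmax <- cox_lambda_max(X, outcomes)
  if (lambda >= lmax) {
    return(stats::setNames(rep(0, ncol(X)), colnames(X)))
  }
  path <- exp(seq(log(lmax), log(max(lambda, 1e-8 * lmax)), length.out = 25))
  if (lambda < 1e-8 * lmax) path <- c(path, lambda)
  y <- survival::Surv(outcomes$time, outcomes$event)
  fit <- glmnet::glmnet(X, y, family = "cox", lambda = path,
                        standardize = FALSE, thresh = 1e-12, maxit = 1e6)
  # the requested lambda is the final path point, so no refit interpolation
  beta <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  stats::setNames(beta, colnames(X))
}

make_event_stratified_folds <- function(event, n_folds, seed, max_tries = 5) {
  for (try in seq_len(max_tries)) {
    folds <- withr::with_seed(seed + try - 1L, {
      f <- integer(length(event))
      for (lvl in c(0L, 1L)) {
        idx <- which(event == lvl)
        f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      f
    })
    ok <- all(vapply(seq_len(n_folds), function(k) {
      sum(event[folds == k]) > 0 && sum(event[folds != k]) > 0
    }, logical(1)))
    if (ok) return(folds)
  }
  rlang::abort("Could not build folds with events in every fold after 5 attempts.")
}

#' Cross-validated penalty path for LASSO-Cox
#'
#' Builds a log-spaced grid from \eqn{\lambda_{max}} down to
#' \eqn{0.01\,\lambda_{max}} and scores each penalty by k-fold
#' cross-validated partial likelihood with event-stratified folds, using the
#' Verweij-van Houwelingen held-out contribution
#' \eqn{\ell_{all}(\hat\beta_{-k}) - \ell_{-k}(\hat\beta_{-k})}. The chosen
#' penalty maximizes the summed held-out partial likelihood. Deterministic
#' given the seed.
#'
#' @param X Samples x genes matrix (standardized columns).
#' @param outcomes Data frame with `time` and `event`.
#' @param n_folds Number of folds, >= 3 (default 5).
#' @param seed Integer seed for fold assignment.
#' @param n_lambda Grid size (default 50).
#' @return A list: `path` tibble (lambda, cv_loglik, cv_se, n_active),
#'   `lambda_opt` (CV maximizer), `lambda_1se` (largest penalty within one
#'   standard error of the maximum), `folds`.
#' @export
lambda_path_cv <- function(X, outcomes, n_folds = 5, seed = 1L, n_lambda = 50) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  if (n_folds < 3) rlang::abort("n_folds must be >= 3.")
  check_outcomes(outcomes$time, outcomes$event)
  lmax <- cox_lambda_max(X, outcomes)
  grid <- exp(seq(log(lmax), log(0.01 * lmax), length.out = n_lambda))
  folds <- make_event_stratified_folds(outcomes$event, n_folds, seed)
  y <- survival::Surv(outcomes$time, outcomes$event)
  cv <- matrix(0, n_lambda, n_folds)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    fit <- glmnet::glmnet(X[tr, , drop = FALSE],
                          y[tr, , drop = FALSE], family = "cox",
                          lambda = grid, standardize = FALSE,
                          thresh = 1e-10, maxit = 1e6)
    b <- as.matrix(stats::coef(fit, s = grid, exact = FALSE))
    eta_all <- X %*% b
    for (l in seq_len(n_lambda)) {
      ll_all <- cox_partial_loglik(eta_all[, l], outcomes)
      ll_tr <- cox_partial_loglik(eta_all[tr, l], outcomes[tr, ])
      cv[l, k] <- ll_all - ll_tr
    }
  }
  cv_loglik <- rowSums(cv)
  # standard error of the summed held-out log-likelihood across folds
  cv_se <- apply(cv, 1L, stats::sd) * sqrt(n_folds)
  full <- glmnet::glmnet(X, y, family = "cox", lambda = grid,
                         standardize = FALSE, thresh = 1e-10, maxit = 1e6)
  n_active <- vapply(seq_len(n_lambda), function(l) {
    sum(as.matrix(stats::coef(full, s = grid[l], exact = FALSE)) != 0)
  }, numeric(1))
  best <- which.max(cv_loglik)
  # one-standard-error rule: largest penalty whose CV value is within one
  # standard error of the best; guards against over-selection when the CV
  # curve is flat (e.g. after a marginal pre-screen on the same data)
  within_1se <- which(cv_loglik >= cv_loglik[best] - cv_se[best])
  list(
    path = tibble::tibble(lambda = grid, cv_loglik = cv_loglik,
                          cv_se = cv_se, n_active = n_active),
    lambda_opt = grid[best],
    lambda_1se = grid[min(within_1se)],
    folds = folds
  )
}

# Cross-validate the penalty for the full screen-then-lasso cascade.
# Each training fold repeats the univariate screen on its own samples and
# fits the lasso path on its own survivors, so the held-out Verweij-van
# Houwelingen contribution ll_all(beta_-k) - ll_-k(beta_-k) never scores a
# gene set that was selected using the held-out samples. Returns the
# one-standard-error penalty from the supplied grid.
cv_cascade_lambda <- function(v, outcomes, alpha, grid, seed, n_folds = 5) {
  folds <- make_event_stratified_folds(outcomes$event, n_folds, seed)
  n_lambda <- length(grid)
  cv <- matrix(0, n_lambda, n_folds)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    scr_k <- suppressWarnings(
      univariate_screen(v[, tr, drop = FALSE], outcomes[tr, ], alpha)
    )
    surv_k <- scr_k$gene_id[scr_k$pass]
    if (length(surv_k) == 0) next  # null model: zero contribution at all lambda
    Xk <- t(v[surv_k, , drop = FALSE])
    y_tr <- survival::Surv(outcomes$time[tr], outcomes$event[tr])
    fit <- glmnet::glmnet(Xk[tr, , drop = FALSE], y_tr, family = "cox",
                          lambda = grid, standardize = FALSE,
                          thresh = 1e-10, maxit = 1e6)
    b <- as.matrix(stats::coef(fit, s = grid, exact = FALSE))
    eta_all <- Xk %*% b
    for (l in seq_len(n_lambda)) {
      ll_all <- cox_partial_loglik(eta_all[, l], outcomes)
      ll_tr <- cox_partial_loglik(eta_all[tr, l], outcomes[tr, ])
      cv[l, k] <- ll_all - ll_tr
    }
  }
  cv_loglik <- rowSums(cv)
  cv_se <- apply(cv, 1L, stats::sd) * sqrt(n_folds)
  best <- which.max(cv_loglik)
  grid[min(which(cv_loglik >= cv_loglik[best] - cv_se[best]))]
}

#' Build the prognostic gene signature
#'
#' The selection cascade behind the model: univariate Cox screening removes
#' genes without marginal survival association, then L1-penalized Cox
#' regression on the survivors zeroes multivariately uninformative genes.
#' With `target_size` given, the penalty is the grid point whose active set
#' is closest in size to the target (ties broken toward the smaller penalty).
#' Otherwise the penalty is cross-validated with the univariate screen
#' repeated inside every training fold — scoring held-out folds against a
#' screen that already saw them would reward purely spurious selections —
#' and chosen by the one-standard-error rule, which stays parsimonious when
#' the cross-validation curve is flat.
#'
#' @param expr Z-scored `expr_matrix` (training cohort) or genes x samples
#'   matrix.
#' @param outcomes Data frame with `time` and `event`.
#' @param alpha Univariate screen threshold (default 0.05).
#' @param target_size Desired signature size (default 100); `NULL` for
#'   cross-validated selection.
#' @param seed Seed for fold assignment when cross-validating.
#' @param n_lambda Penalty grid size.
#' @return A `gene_signature`: tibble with `gene_id`, `uni_beta`, `uni_se`,
#'   `uni_p`, `lasso_beta`; attributes `lambda`, `alpha`, `target_size`,
#'   `seed`.
#' @export
build_signature <- function(expr, outcomes, alpha = 0.05, target_size = 100,
                            seed = 1L, n_lambda = 50) {
  v <- if (inherits(expr, "expr_matrix")) expr$values else expr
  screen <- univariate_screen(v, outcomes, alpha)
  surv_genes <- screen$gene_id[screen$pass]
  if (length(surv_genes) == 0) {
    rlang::abort("No genes passed the univariate screen; consider relaxing alpha.")
  }
  X <- t(v[surv_genes, , drop = FALSE])
  lmax <- cox_lambda_max(X, outcomes)
  # target mode scans a denser grid so small active sets are reachable
  n_grid <- if (is.null(target_size)) n_lambda else max(4L * n_lambda, 200L)
  grid <- exp(seq(log(lmax), log(0.01 * lmax), length.out = n_grid))
  y <- survival::Surv(outcomes$time, outcomes$event)
  fit <- glmnet::glmnet(X, y, family = "cox", lambda = grid,
                        standardize = FALSE, thresh = 1e-10, maxit = 1e6)
  if (!is.null(target_size)) {
    sizes <- vapply(seq_along(grid), function(l) {
      sum(as.matrix(stats::coef(fit, s = grid[l], exact = FALSE)) != 0)
    }, numeric(1))
    gap <- abs(sizes - target_size)
    # grid is decreasing; the last index among ties is the smaller lambda
    best <- max(which(gap == min(gap)))
    lambda <- grid[best]
  } else {
    lambda <- cv_cascade_lambda(v, outcomes, alpha = alpha, grid = grid,
                                seed = seed)
  }
  beta <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  names(beta) <- colnames(X)
  active <- names(beta)[beta != 0]
  sig <- screen |>
    dplyr::filter(.data$gene_id %in% active) |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      uni_beta = .data$estimate, uni_se = .data$std_error,
      uni_p = .data$p_value,
      lasso_beta = beta[.data$gene_id]
    )
  structure(sig, class = c("gene_signature", class(sig)),
            lambda = lambda, alpha = alpha,
            target_size = target_size %||% NA_integer_, seed = seed)
}

#' Write / read a gene signature as comma-separated text
#'
#' @param signature A `gene_signature`.
#' @param path File path.
#' @return `path` (write) or a `gene_signature` (read).
#' @export
write_signature <- function(signature, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#gene_signature lambda=%.17g alpha=%.17g",
                     attr(signature, "lambda"), attr(signature, "alpha")), con)
  writeLines("gene_id,uni_beta,uni_se,uni_p,lasso_beta", con)
  writeLines(sprintf("%s,%.17g,%.17g,%.17g,%.17g",
                     signature$gene_id, signature$uni_beta, signature$uni_se,
                     signature$uni_p, signature$lasso_beta), con)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^#gene_signature", header)) rlang::abort("Not a gene_signature file.")
  meta <- regmatches(header, gregexpr("[a-z]+=[-0-9.e+]+", header))[[1]]
  vals <- stats::setNames(
    as.numeric(sub(".*=", "", meta)), sub("=.*", "", meta)
  )
  tab <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  sig <- tibble::as_tibble(tab)
  structure(sig, class = c("gene_signature", class(sig)),
            lambda = unname(vals["lambda"]), alpha = unname(vals["alpha"]),
            target_size = NA_integer_, seed = NA_integer_)
}
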