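test_that("univariate screen equals per-gene fit_cox", {
  co <- small_cohort(seed = 61, n = 80, n_genes = 15)
  prep <- preprocess_fit(co$expression)
  out <- outcomes_of(co)
  scr <- univariate_screen(prep$expression, out)
  for (g in scr$gene_id[1:5]) {
    x <- matrix(prep$expression$values[g, ], ncol = 1,
                dimnames = list(NULL, g))
    ref <- fit_cox(x, out)$terms
    row <- scr[scr$gene_id == g, ]
    expect_equal(unname(row$estimate), unname(ref$estimate), tolerance = 1e-10)
    expect_equal(unname(row$p_value), unname(ref$p_value), tolerance = 1e-10)
  }
})

test_that("univariate screen skips constant genes with a warning", {
  co <- small_cohort(seed = 62, n = 40, n_genes = 10)
  prep <- preprocess_fit(co$expression)
  v <- prep$expression$values
  v[1, ] <- 0
  em <- prep$expression
  em$values <- v
  expect_warning(scr <- univariate_screen(em, outcomes_of(co)), "variance")
  expect_false(rownames(v)[1] %in% scr$gene_id[scr$pass])
})

test_that("screen passes null genes at roughly the nominal rate", {
  co <- simulate_cohort(sim_config(n_samples = 300, n_genes = 2000,
                                   n_signal = 0, clinical_effects = numeric(0),
                                   seed = 63))
  prep <- preprocess_fit(co$expression)
  scr <- univariate_screen(prep$expression, outcomes_of(co))
  expect_lt(abs(mean(scr$pass) - 0.05), 0.015)
})

test_that("lambda_max zeroes the lasso and matches the subgradient bound", {
  set.seed(64)
  n <- 120
  X <- matrix(rnorm(5 * n), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  time <- rexp(n, exp(0.4 * X[, 1]))
  out <- tibble::tibble(time = time, event = rbinom(n, 1, 0.8))
  lmax <- cox_lambda_max(X, out)
  # direct evaluation of max_j |(1/n) sum_{i:event}(x_ij - risk-set mean)|
  direct <- max(abs(vapply(seq_len(5), function(j) {
    s <- 0
    for (i in which(out$event == 1)) {
      risk <- which(out$time >= out$time[i])
      s <- s + X[i, j] - mean(X[risk, j])
    }
    s / n
  }, numeric(1))))
  expect_equal(lmax, direct, tolerance = 1e-12)
  expect_true(all(lasso_cox(X, out, lmax) == 0))
  expect_true(all(lasso_cox(X, out, lmax * 1.5) == 0))
  expect_false(all(lasso_cox(X, out, lmax * 0.5) == 0))
})

test_that("lasso at lambda zero matches the unpenalized fit", {
  set.seed(65)
  n <- 200
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, paste0("g", 1:3)))
  time <- rexp(n, exp(0.5 * X[, 1] - 0.4 * X[, 2]))
  out <- tibble::tibble(time = time, event = rbinom(n, 1, 0.85))
  b_lasso <- lasso_cox(X, out, 0)
  b_cox <- fit_cox(X, out)$terms$estimate
  expect_lt(max(abs(b_lasso - b_cox)), 1e-3)
})

test_that("lasso agrees with the proximal-gradient oracle", {
  set.seed(66)
  n <- 100
  X <- matrix(rnorm(5 * n), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  time <- rexp(n, exp(drop(X %*% c(0.5, -0.5, 0.3, 0, 0))))
  event <- rbinom(n, 1, 0.8)
  out <- tibble::tibble(time = time, event = event)
  lmax <- cox_lambda_max(X, out)
  for (lam in c(0.3, 0.05) * lmax) {
    expect_lt(max(abs(lasso_cox(X, out, lam) -
                      oracle_prox_lasso_cox(X, time, event, lam))), 1e-4)
  }
})

test_that("cross-validated lambda path is deterministic and well-formed", {
  co <- small_cohort(seed = 67, n = 150, n_genes = 40, n_signal = 5)
  prep <- preprocess_fit(co$expression)
  X <- t(prep$expression$values)
  out <- outcomes_of(co)
  a <- lambda_path_cv(X, out, seed = 7, n_lambda = 20)
  b <- lambda_path_cv(X, out, seed = 7, n_lambda = 20)
  expect_identical(a$path, b$path)
  expect_identical(a$lambda_opt, b$lambda_opt)
  expect_equal(nrow(a$path), 20)
  expect_true(all(diff(a$path$lambda) < 0))
  expect_true(a$lambda_opt %in% a$path$lambda)
})

test_that("event-stratified folds always contain events", {
  set.seed(68)
  event <- c(rep(1L, 12), rep(0L, 38))
  folds <- deepcox:::make_event_stratified_folds(event, n_folds = 5, seed = 3)
  for (k in 1:5) expect_gt(sum(event[folds != k]), 0)
})

test_that("build_signature hits a size target and records provenance", {
  co <- small_cohort(seed = 69, n = 200, n_genes = 120, n_signal = 10,
                     effect = 0.6)
  prep <- preprocess_fit(co$expression)
  sig <- build_signature(prep$expression, outcomes_of(co), target_size = 8,
                         seed = 3)
  expect_s3_class(sig, "gene_signature")
  expect_true(abs(nrow(sig) - 8) <= 3)
  expect_true(all(sig$lasso_beta != 0))
  expect_false(any(duplicated(sig$gene_id)))
  expect_true(is.numeric(attr(sig, "lambda")))
  one <- build_signature(prep$expression, outcomes_of(co), target_size = 1,
                         seed = 3)
  expect_equal(nrow(one), 1)
})

test_that("build_signature errors when the screen is empty", {
  co <- simulate_cohort(sim_config(n_samples = 60, n_genes = 30, n_signal = 0,
                                   clinical_effects = numeric(0), seed = 70))
  prep <- preprocess_fit(co$expression)
  expect_error(
    build_signature(prep$expression, outcomes_of(co), alpha = 1e-12,
                    target_size = 5, seed = 1),
    "alpha|screen"
  )
})

test_that("signature text round trip is faithful", {
  co <- small_cohort(seed = 71, n = 150, n_genes = 60, n_signal = 5)
  prep <- preprocess_fit(co$expression)
  sig <- build_signature(prep$expression, outcomes_of(co), target_size = 5,
                         seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$gene_id, sig$gene_id)
  expect_equal(unname(back$lasso_beta), unname(sig$lasso_beta),
               tolerance = 1e-15)
  expect_equal(unname(back$uni_p), unname(sig$uni_p), tolerance = 1e-15)
})
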