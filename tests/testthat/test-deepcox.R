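train_matrix <- function(cohort) {
  prep <- preprocess_fit(cohort$expression)
  t(prep$expression$values)
}

test_that("deepcox_config validates inputs and resolves skip", {
  cfg <- deepcox_config()
  expect_true(cfg$skip)
  expect_false(deepcox_config(hidden = integer(0))$skip)
  expect_false(deepcox_config(skip = FALSE)$skip)
  expect_error(deepcox_config(dropout = 1), "dropout")
  expect_error(deepcox_config(hidden = c(8L, 0L)), "hidden")
  expect_error(deepcox_config(val_fraction = 1), "val_fraction")
})

test_that("training is deterministic given the seed", {
  co <- small_cohort(seed = 81, n = 100, n_genes = 12, n_signal = 3)
  X <- train_matrix(co)
  out <- outcomes_of(co)
  cfg <- deepcox_config(hidden = 8L, epochs = 15L)
  m1 <- train_deepcox(X, out, cfg, seed = 4)
  m2 <- train_deepcox(X, out, cfg, seed = 4)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$skip, m2$skip)
  expect_identical(m1$training_log, m2$training_log)
})

test_that("zero-hidden-layer model scores are exactly linear", {
  co <- small_cohort(seed = 82, n = 90, n_genes = 8, n_signal = 2)
  X <- train_matrix(co)
  out <- outcomes_of(co)
  m <- train_deepcox(X, out,
                     deepcox_config(hidden = integer(0), dropout = 0,
                                    epochs = 20L, val_fraction = 0),
                     seed = 1)
  w <- drop(m$weights[[1]])
  expect_equal(unname(predict_risk(m, X)$score), unname(drop(X %*% w)),
               tolerance = 1e-12)
})

test_that("prediction is dropout-free, order-invariant, and alignment-safe", {
  co <- small_cohort(seed = 83, n = 100, n_genes = 10, n_signal = 3)
  X <- train_matrix(co)
  out <- outcomes_of(co)
  m <- train_deepcox(X, out, deepcox_config(hidden = 8L, epochs = 10L),
                     seed = 2)
  p1 <- predict_risk(m, X)
  p2 <- predict_risk(m, X)
  expect_identical(p1, p2)
  perm <- sample(nrow(X))
  p3 <- predict_risk(m, X[perm, , drop = FALSE])
  expect_equal(p3$score[order(match(p3$sample_id, p1$sample_id))],
               p1$score, tolerance = 1e-12)
  cperm <- X[, sample(ncol(X)), drop = FALSE]
  expect_equal(predict_risk(m, cperm)$score, p1$score, tolerance = 1e-12)
  dup <- X[c(1, 1), , drop = FALSE]
  pd <- predict_risk(m, dup)
  expect_equal(pd$score[1], pd$score[2])
})

test_that("predict_risk demands all signature genes", {
  co <- small_cohort(seed = 84, n = 80, n_genes = 10, n_signal = 2)
  X <- train_matrix(co)
  m <- train_deepcox(X, outcomes_of(co),
                     deepcox_config(hidden = 4L, epochs = 5L), seed = 3)
  expect_error(predict_risk(m, X[, -1, drop = FALSE]), "lacks")
})

test_that("training needs events and warns on scarce events", {
  co <- small_cohort(seed = 85, n = 60, n_genes = 8, n_signal = 2)
  X <- train_matrix(co)
  out <- outcomes_of(co)
  none <- out
  none$event <- 0L
  expect_error(train_deepcox(X, none, deepcox_config(epochs = 2L), seed = 1),
               "event")
  few <- out
  few$event <- 0L
  few$event[1:5] <- 1L
  w <- testthat::capture_warnings(
    train_deepcox(X, few, deepcox_config(hidden = 4L, epochs = 2L), seed = 1)
  )
  expect_true(any(grepl("events", w)))
})

test_that("the skip path warm start is preserved when training cannot beat it", {
  co <- small_cohort(seed = 86, n = 120, n_genes = 10, n_signal = 3)
  X <- train_matrix(co)
  out <- outcomes_of(co)
  fit <- fit_cox(X, out)
  init <- stats::setNames(fit$terms$estimate, colnames(X))
  m <- suppressWarnings(train_deepcox(
    X, out, deepcox_config(hidden = 8L, epochs = 0L), seed = 1,
    init_linear = init
  ))
  expect_equal(unname(drop(m$skip)), unname(fit$terms$estimate))
  # with a zeroed output layer the initial prediction is the warm start
  expect_equal(unname(predict_risk(m, X)$score),
               unname(drop(X %*% fit$terms$estimate)), tolerance = 1e-12)
})

test_that("init_linear is validated", {
  co <- small_cohort(seed = 87, n = 60, n_genes = 6, n_signal = 2)
  X <- train_matrix(co)
  out <- outcomes_of(co)
  expect_error(
    train_deepcox(X, out, deepcox_config(epochs = 1L), seed = 1,
                  init_linear = c(a = 1)),
    "init_linear"
  )
})

test_that("mini-batch training runs and within-batch risk sets are used", {
  co <- small_cohort(seed = 88, n = 300, n_genes = 10, n_signal = 3)
  X <- train_matrix(co)
  out <- outcomes_of(co)
  m <- train_deepcox(X, out,
                     deepcox_config(hidden = 8L, epochs = 5L,
                                    batch_size = 64L), seed = 5)
  expect_s3_class(m, "deepcox_model")
  expect_true(nrow(m$training_log) >= 1)
})

test_that("model save/load round trip preserves predictions bitwise", {
  co <- small_cohort(seed = 89, n = 100, n_genes = 10, n_signal = 3)
  X <- train_matrix(co)
  m <- train_deepcox(X, outcomes_of(co),
                     deepcox_config(hidden = c(8L, 4L), epochs = 10L),
                     seed = 6)
  path <- withr::local_tempfile(fileext = ".txt")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict_risk(back, X)$score, predict_risk(m, X)$score)
  expect_identical(back$genes, m$genes)
  expect_identical(back$skip, m$skip)
})

test_that("load_model rejects corrupted containers", {
  co <- small_cohort(seed = 90, n = 60, n_genes = 6, n_signal = 2)
  X <- train_matrix(co)
  m <- train_deepcox(X, outcomes_of(co),
                     deepcox_config(hidden = 4L, epochs = 3L), seed = 7)
  path <- withr::local_tempfile(fileext = ".txt")
  save_model(m, path)
  lines <- readLines(path)
  writeLines(lines[1:4], path)
  expect_error(load_model(path), "orrupted|header")
  writeLines(sub("^#deepcox_model v1", "#deepcox_model v99", lines), path)
  expect_error(load_model(path), "version")
  writeLines(head(lines, -2), path)
  expect_error(load_model(path), "orrupted|truncated|mismatch")
  writeLines(c("garbage"), path)
  expect_error(load_model(path), "header")
})

test_that("full-batch sample order does not affect the fit", {
  co <- small_cohort(seed = 91, n = 100, n_genes = 8, n_signal = 2)
  X <- train_matrix(co)
  out <- outcomes_of(co)
  cfg <- deepcox_config(hidden = 6L, dropout = 0, epochs = 10L,
                        val_fraction = 0)
  m1 <- train_deepcox(X, out, cfg, seed = 8)
  perm <- withr::with_seed(99, sample(nrow(X)))
  m2 <- train_deepcox(X[perm, , drop = FALSE], out[perm, ], cfg, seed = 8)
  ll1 <- utils::tail(m1$training_log$train_loglik, 1)
  ll2 <- utils::tail(m2$training_log$train_loglik, 1)
  expect_lt(abs(ll1 - ll2), 1e-6)
})

test_that("nonlinear signal rewards hidden layers over a linear fit", {
  # hazard driven by a product interaction of two latent gene values
  set.seed(92)
  n <- 1000
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(paste0("s", 1:n),
                                                  c("gA", "gB")))
  eta <- 1.5 * X[, 1] * X[, 2]
  time <- rexp(n, exp(eta))
  out <- tibble::tibble(time = time, event = rep(1L, n))
  tr <- 1:600
  te <- 601:1000
  lin <- fit_cox(X[tr, ], out[tr, ])
  c_lin <- concordance_index(drop(X[te, ] %*% lin$terms$estimate), out[te, ])
  m <- suppressWarnings(train_deepcox(
    X[tr, ], out[tr, ],
    deepcox_config(hidden = c(16L, 8L), dropout = 0, epochs = 300L,
                   lr = 0.01, patience = 30L), seed = 9
  ))
  c_net <- concordance_index(predict_risk(m, X[te, ])$score, out[te, ])
  expect_gt(c_net, c_lin + 0.03)
})
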