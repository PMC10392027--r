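make_expr <- function(values, batch, normalized = FALSE) {
  dimnames(values) <- list(paste0("g", seq_len(nrow(values))),
                           paste0("s", seq_len(ncol(values))))
  expr_matrix(values, batch = batch, is_normalized = normalized)
}

test_that("normalize computes log2 counts-per-million", {
  em <- make_expr(matrix(c(9, 1), 2, 1), batch = "a")
  nm <- normalize_expression(em)
  expect_true(nm$is_normalized)
  expect_equal(unname(nm$values[, 1]), c(log2(900001), log2(100001)))
  # column sums of 2^x - 1 recover one million per sample
  em2 <- make_expr(matrix(rpois(50, 40) + 1, 10, 5), batch = rep("a", 5))
  nm2 <- normalize_expression(em2)
  expect_equal(unname(colSums(2^nm2$values - 1)), rep(1e6, 5))
})

test_that("normalize guards against double transformation and zero samples", {
  em <- make_expr(matrix(c(1, 2, 0, 0), 2, 2), batch = c("a", "a"))
  expect_error(normalize_expression(em), "s2")
  nm <- normalize_expression(make_expr(matrix(1:4, 2, 2), batch = c("a", "a")))
  expect_error(normalize_expression(nm), "normalized")
  expect_identical(normalize_expression(nm, on_normalized = "passthrough"), nm)
})

test_that("adjust_batches equalizes per-gene batch means", {
  set.seed(1)
  v <- matrix(rnorm(200, 8), 10, 20)
  batch <- rep(c("a", "b"), each = 10)
  v[, batch == "b"] <- v[, batch == "b"] + 2  # constant shift
  em <- make_expr(v, batch, normalized = TRUE)
  adj <- adjust_batches(em)
  for (g in 1:10) {
    ma <- mean(adj$expression$values[g, batch == "a"])
    mb <- mean(adj$expression$values[g, batch == "b"])
    expect_lt(abs(ma - mb), 1e-9)
  }
})

test_that("single batch adjustment is the identity", {
  set.seed(2)
  em <- make_expr(matrix(rnorm(40, 5), 4, 10), rep("a", 10), normalized = TRUE)
  adj <- adjust_batches(em)
  expect_lt(max(abs(adj$expression$values - em$values)), 1e-9)
})

test_that("adjust_batches requires two samples per batch", {
  em <- make_expr(matrix(rnorm(9, 5), 3, 3), c("a", "a", "b"), normalized = TRUE)
  expect_error(adjust_batches(em), "atch")
})

test_that("batch adjustment removes simulated batch associations", {
  co <- simulate_cohort(sim_config(n_samples = 90, n_genes = 150, n_signal = 0,
                                   batch_sd = 2, seed = 14))
  nm <- normalize_expression(co$expression)
  batch <- factor(nm$batch)
  frac_sig <- function(values) {
    p <- apply(values, 1, function(x) stats::anova(stats::lm(x ~ batch))[1, 5])
    mean(p < 0.01)
  }
  expect_gt(frac_sig(nm$values), 0.5)
  adj <- adjust_batches(nm)
  expect_lt(frac_sig(adj$expression$values), 0.02)
})

test_that("filter_genes keeps genes expressed in enough samples", {
  v <- matrix(1, 3, 10)
  v[1, 2:10] <- 0            # expressed in 1/10
  v[2, 6:10] <- 0            # expressed in 5/10
  em <- make_expr(v, rep("a", 10), normalized = TRUE)
  expect_identical(rownames(filter_genes(em, 0.2)$values), c("g2", "g3"))
  expect_identical(rownames(filter_genes(em, 0)$values), c("g1", "g2", "g3"))
  expect_identical(rownames(filter_genes(em, 1)$values), "g3")
  expect_error(filter_genes(em, 1.01), "min_frac_expressed")
})

test_that("preprocess_fit z-scores and freezes parameters", {
  co <- small_cohort(seed = 21, n = 60, n_genes = 30)
  prep <- preprocess_fit(co$expression)
  z <- prep$expression$values
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)
  expect_s3_class(prep$params, "preprocess_params")
  expect_identical(prep$params$kept_gene_ids, rownames(z))
})

test_that("apply_frozen reproduces the fit-time transform on training data", {
  co <- small_cohort(seed = 22, n = 50, n_genes = 25)
  prep <- preprocess_fit(co$expression)
  re <- apply_frozen(co$expression, prep$params)
  expect_equal(re$values, prep$expression$values, tolerance = 1e-12)
})

test_that("apply_frozen never refits: params are untouched, shifts map through", {
  co <- small_cohort(seed = 23, n = 40, n_genes = 20)
  prep <- preprocess_fit(co$expression)
  hash_before <- digest_params <- unlist(prep$params[c("center", "scale")])
  v1 <- simulate_cohort(sim_config(n_samples = 30, n_genes = 20,
                                   cohort = "validation", seed = 24))
  z1 <- apply_frozen(v1$expression, prep$params)
  expect_identical(unlist(prep$params[c("center", "scale")]), hash_before)
  # globally doubling raw values shifts log2-CPM by 0 (CPM is scale-free),
  # so the frozen transform must be invariant to a global scale factor
  v2 <- v1$expression
  v2$values <- v2$values * 2
  z2 <- apply_frozen(v2, prep$params)
  expect_equal(z2$values, z1$values, tolerance = 1e-10)
})

test_that("apply_frozen fills missing genes at center with a warning", {
  co <- small_cohort(seed = 25, n = 40, n_genes = 20)
  prep <- preprocess_fit(co$expression)
  v <- simulate_cohort(sim_config(n_samples = 30, n_genes = 20,
                                  cohort = "validation", seed = 26))
  kept <- prep$params$kept_gene_ids
  drop_gene <- kept[1]
  sub <- v$expression
  keep_rows <- setdiff(rownames(sub$values), drop_gene)
  sub <- expr_matrix(sub$values[keep_rows, , drop = FALSE], batch = sub$batch)
  expect_warning(z <- apply_frozen(sub, prep$params), "missing")
  expect_true(all(z$values[drop_gene, ] == 0))
})

test_that("apply_frozen errors when too many signature genes are missing", {
  co <- small_cohort(seed = 27, n = 40, n_genes = 20)
  prep <- preprocess_fit(co$expression)
  v <- simulate_cohort(sim_config(n_samples = 30, n_genes = 20,
                                  cohort = "validation", seed = 28))
  kept <- prep$params$kept_gene_ids
  drop_genes <- kept[seq_len(ceiling(0.5 * length(kept)))]
  keep_rows <- setdiff(rownames(v$expression$values), drop_genes)
  sub <- expr_matrix(v$expression$values[keep_rows, , drop = FALSE],
                     batch = v$expression$batch)
  expect_error(apply_frozen(sub, prep$params), "20%|missing")
})

test_that("preprocess params survive a text round trip", {
  co <- small_cohort(seed = 29, n = 40, n_genes = 20)
  prep <- preprocess_fit(co$expression)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_preprocess_params(prep$params, path)
  back <- read_preprocess_params(path)
  expect_equal(back$center, prep$params$center, tolerance = 1e-15)
  expect_equal(back$scale, prep$params$scale, tolerance = 1e-15)
  expect_identical(back$kept_gene_ids, prep$params$kept_gene_ids)
  v <- simulate_cohort(sim_config(n_samples = 20, n_genes = 20,
                                  cohort = "validation", seed = 30))
  expect_equal(apply_frozen(v$expression, back)$values,
               apply_frozen(v$expression, prep$params)$values,
               tolerance = 1e-12)
})
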