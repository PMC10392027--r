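#' Configuration for the end-to-end pipeline
#'
#' Ties the stages together: preprocessing on the training cohort, gene
#' selection, neural Cox training, evaluation of the training cohort and of
#' any number of prospectively held validation cohorts (projected through the
#' frozen preprocessing), multivariable independence analysis and nomogram
#' construction. Exactly one training cohort is allowed, and every stage's
#' randomness derives deterministically from the global seed.
#'
#' @param training A cohort: list with `expression` (raw `expr_matrix`) and
#'   `clinical` (tibble).
#' @param validation Named list of cohorts of the same shape (may be empty).
#' @param endpoint Endpoint label ("OS" or "PFS").
#' @param min_frac_expressed Gene-filter threshold.
#' @param alpha Univariate screen threshold.
#' @param target_size Signature size target (`NULL` for CV selection).
#' @param model A [deepcox_config()].
#' @param horizons Months for time-dependent AUC and the nomogram.
#' @param n_boot Bootstrap replicates for C-index CIs.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(training, validation = list(), endpoint = "OS",
                            min_frac_expressed = 0.2, alpha = 0.05,
                            target_size = 100, model = deepcox_config(),
                            horizons = c(12, 36, 60), n_boot = 1000L,
                            seed = 1L) {
  check_cohort <- function(cohort, label) {
    if (!is.list(cohort) || !inherits(cohort$expression, "expr_matrix") ||
        !is.data.frame(cohort$clinical)) {
      rlang::abort(paste0("Cohort `", label, "` needs $expression (expr_matrix) and $clinical."))
    }
  }
  check_cohort(training, "training")
  if (length(validation)) {
    if (is.null(names(validation)) || any(!nzchar(names(validation)))) {
      rlang::abort("Validation cohorts must be named.")
    }
    purrr::iwalk(validation, check_cohort)
    train_ids <- sort(training$clinical$sample_id)
    for (nm in names(validation)) {
      if (identical(sort(validation[[nm]]$clinical$sample_id), train_ids)) {
        rlang::abort(paste0("Cohort `", nm, "` duplicates the training cohort."))
      }
    }
  }
  structure(
    list(training = training, validation = validation, endpoint = endpoint,
         min_frac_expressed = min_frac_expressed, alpha = alpha,
         target_size = target_size, model = model, horizons = horizons,
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full survival-modelling pipeline
#'
#' Executes preprocess, select, train and evaluate in order, persisting every
#' intermediate artifact (frozen preprocessing parameters, gene signature,
#' model weights, evaluation reports, multivariable HR table, nomogram) under
#' `out_dir` together with a manifest recording versions, seeds and input
#' hashes. Rerunning with an identical config reproduces identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return A `pipeline_result` list: `params`, `signature`, `model`,
#'   `reports` (named list of `evaluation_report`s, training first),
#'   `multivariable` (`cox_fit`), `nomogram`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("deepcox_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # preprocess (training only; parameters frozen thereafter)
  prep <- preprocess_fit(config$training$expression, config$min_frac_expressed)
  write_preprocess_params(prep$params, file.path(out_dir, "preprocess_params.tsv"))
  train_clin <- validate_clinical(config$training$clinical)
  train_out <- as_outcomes(train_clin, sample_ids(prep$expression))

  # select
  signature <- build_signature(
    prep$expression, train_out, alpha = config$alpha,
    target_size = config$target_size, seed = seed
  )
  write_signature(signature, file.path(out_dir, "signature.csv"))

  # train, warm-starting the linear path at the selection-stage coefficients
  X <- t(prep$expression$values[signature$gene_id, , drop = FALSE])
  model <- train_deepcox(X, train_out, config$model, seed = seed,
                         init_linear = stats::setNames(signature$lasso_beta,
                                                       signature$gene_id))
  save_model(model, file.path(out_dir, "model.txt"))

  # evaluate: training cohort sets the risk cutoff, validation reuses it
  train_scores <- predict_risk(model, prep$expression)
  cutoff <- stats::median(train_scores$score)
  reports <- list()
  reports[["training"]] <- evaluate_cohort(
    model, prep$expression, train_clin, horizons = config$horizons,
    cutoff = cutoff, endpoint = config$endpoint, n_boot = config$n_boot,
    seed = seed
  )
  for (nm in names(config$validation)) {
    vc <- config$validation[[nm]]
    expr_v <- apply_frozen(vc$expression, prep$params)
    reports[[nm]] <- evaluate_cohort(
      model, expr_v, validate_clinical(vc$clinical),
      horizons = config$horizons, cutoff = cutoff,
      endpoint = config$endpoint, n_boot = config$n_boot, seed = seed
    )
  }
  for (nm in names(reports)) {
    write_evaluation_report(reports[[nm]], file.path(out_dir, paste0("report_", nm)))
  }

  # downstream: independence analysis + nomogram on the training cohort
  multi <- multivariable_adjustment(train_scores, train_clin)
  utils::write.csv(tidy(multi), file.path(out_dir, "multivariable_hr.csv"),
                   row.names = FALSE)
  cov_df <- tibble::tibble(
    risk_score = train_scores$score,
    platelet_count = train_clin$platelet_count, age = train_clin$age,
    ca125 = log(train_clin$ca125), residual = train_clin$residual,
    stage = train_clin$stage
  )
  horizons_in_range <- config$horizons[config$horizons <= max(multi$baseline$time)]
  nomogram <- if (length(horizons_in_range)) {
    build_nomogram(multi, horizons_in_range, cov_df)
  } else {
    NULL
  }

  manifest <- c(
    paste0("pipeline_version\t1"),
    paste0("seed\t", seed),
    paste0("endpoint\t", config$endpoint),
    paste0("signature_size\t", nrow(signature)),
    paste0("risk_cutoff\t", sprintf("%.17g", cutoff)),
    paste0("artifact\t", basename(list.files(out_dir, recursive = TRUE)), "\t",
           unname(tools::md5sum(list.files(out_dir, recursive = TRUE, full.names = TRUE))))
  )
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))

  structure(
    list(params = prep$params, signature = signature, model = model,
         reports = reports, multivariable = multi, nomogram = nomogram,
         manifest = manifest, out_dir = out_dir),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> signature of ", nrow(x$signature), " genes; cohorts: ",
      paste(names(x$reports), collapse = ", "), "\n", sep = "")
  for (r in x$reports) print(r)
  invisible(x)
}
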