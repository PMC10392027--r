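#' Configuration for the synthetic survival-transcriptome generator
#'
#' Defines a cohort simulated under a Weibull-baseline proportional-hazards
#' model: a small set of signal genes drives hazard through standardized
#' (log-scale) expression, clinical covariates contribute additively on the
#' log-hazard scale, batches shift log-expression, and follow-up is cut by
#' random (exponential) plus administrative censoring.
#'
#' Defaults emulate the platelet RNA-seq study setting this package targets: a
#' training cohort of 303 ovarian-cancer patients profiled over a few thousand
#' genes across three hospital batches, a small set of strongly prognostic
#' driver genes, survival measured in months with a median follow-up around
#' three years.
#'
#' @param n_samples Number of samples (default 303).
#' @param n_genes Number of genes (default 3000).
#' @param n_signal Number of hazard-driving genes (default 10). Deliberately
#'   much smaller than a typical selected signature: in practice a multigene
#'   signature contains a handful of drivers plus correlated or null
#'   passengers, and a univariate screen only has power for per-gene effects
#'   strong enough to survive the attenuation caused by the rest of the
#'   (omitted) linear predictor.
#' @param signal_effect Log-hazard per SD of signal-gene expression
#'   (default 0.8); signs alternate across signal genes.
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (shape k, scale in months; defaults 1.2 and 45).
#' @param censor_rate Exponential dropout-censoring rate per month
#'   (default 1/150, giving roughly 40% censoring with the other defaults —
#'   ovarian-cancer overall-survival cohorts are event-rich).
#' @param admin_cutoff Administrative censoring horizon in months (default 66).
#' @param n_batches Number of batches (default 3).
#' @param batch_sd SD of additive per-gene log2-scale batch offsets
#'   (default 0.5).
#' @param corr_block_rho Equicorrelation among signal genes, in [0, 1)
#'   (default 0.3).
#' @param clinical_effects Named numeric vector of log-hazard coefficients on
#'   standardized clinical covariates; names among `age`, `stage`, `residual`,
#'   `ca125`, `platelet_count`. Default gives stage and residual disease
#'   modest effects.
#' @param batch_scale_effects If `TRUE`, batches also distort per-gene scale
#'   (stress-test mode; default `FALSE`).
#' @param couple_platelets If `TRUE`, platelet counts are shifted upwards with
#'   the tumour-driven linear predictor, emulating paraneoplastic
#'   thrombocytosis confounding (default `FALSE`).
#' @param cohort Cohort label stored in the clinical table.
#' @param seed Integer seed; the same config (including seed) reproduces the
#'   cohort bit for bit.
#' @param panel_seed Seed of the gene-panel stream that draws per-gene
#'   baseline log2 abundances. Baselines are properties of the genes, not of
#'   a cohort, so cohorts simulated with different `seed` but the same
#'   `panel_seed` (the default) share them — which is what lets frozen
#'   training preprocessing transfer to validation cohorts.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 303, n_genes = 3000, n_signal = 10,
                       signal_effect = 0.8, baseline_shape = 1.2,
                       baseline_scale = 45, censor_rate = 1 / 150,
                       admin_cutoff = 66, n_batches = 3, batch_sd = 0.5,
                       corr_block_rho = 0.3,
                       clinical_effects = c(stage = 0.35, residual = 0.3),
                       batch_scale_effects = FALSE, couple_platelets = FALSE,
                       cohort = "training", seed = 1L, panel_seed = 20160901L) {
  if (n_samples < 1 || n_genes < 1) rlang::abort("n_samples and n_genes must be positive.")
  if (n_signal < 0 || n_signal > n_genes) rlang::abort("Require 0 <= n_signal <= n_genes.")
  if (baseline_shape <= 0 || baseline_scale <= 0) rlang::abort("Weibull parameters must be > 0.")
  if (censor_rate <= 0) rlang::abort("censor_rate must be > 0.")
  if (admin_cutoff <= 0) rlang::abort("admin_cutoff must be > 0.")
  if (n_batches < 1) rlang::abort("n_batches must be >= 1.")
  if (batch_sd < 0) rlang::abort("batch_sd must be >= 0.")
  if (corr_block_rho < 0 || corr_block_rho >= 1) rlang::abort("corr_block_rho must be in [0, 1).")
  if (length(clinical_effects) &&
      !all(names(clinical_effects) %in% c("age", "stage", "residual", "ca125", "platelet_count"))) {
    rlang::abort("Unknown clinical_effects name.")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
      n_signal = as.integer(n_signal), signal_effect = signal_effect,
      baseline_shape = baseline_shape, baseline_scale = baseline_scale,
      censor_rate = censor_rate, admin_cutoff = admin_cutoff,
      n_batches = as.integer(n_batches), batch_sd = batch_sd,
      corr_block_rho = corr_block_rho, clinical_effects = clinical_effects,
      batch_scale_effects = batch_scale_effects,
      couple_platelets = couple_platelets, cohort = cohort,
      seed = as.integer(seed), panel_seed = as.integer(panel_seed)
    ),
    class = "sim_config"
  )
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Simulate a survival-transcriptome cohort with known ground truth
#'
#' Draws per-gene standardized Gaussian log-expression (optionally
#' equicorrelated within the signal block), adds per-batch additive offsets,
#' and exponentiates (base 2) around gene-specific baselines to a positive
#' count-like scale. The hazard acts on the standardized latent values:
#' \eqn{\eta_i = \sum_k \beta_k \tilde x_{ik} + } clinical terms, and event
#' times follow the Weibull inverse-transform
#' \eqn{T_i = \lambda(-\log U_i / e^{\eta_i})^{1/k}}. Observed follow-up is
#' censored by the minimum of an exponential dropout time and the
#' administrative cutoff.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (raw-scale [expr_matrix()]),
#'   `clinical` (tibble, see [validate_clinical()]) and `truth` (a list with
#'   `signal_gene_ids`, `true_betas`, `baseline_params`,
#'   `true_linear_predictor`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  p <- cfg$n_genes
  gid <- sprintf("G%05d", seq_len(p))
  sid <- sprintf("%s_S%04d", toupper(substr(cfg$cohort, 1, 2)), seq_len(n))

  # Standardized latent log-expression; signal genes share a factor when
  # corr_block_rho > 0 (equicorrelated block).
  z <- matrix(stats::rnorm(p * n), nrow = p, dimnames = list(gid, sid))
  sig_idx <- seq_len(cfg$n_signal)
  if (cfg$n_signal > 1 && cfg$corr_block_rho > 0) {
    f <- stats::rnorm(n)
    z[sig_idx, ] <- sqrt(cfg$corr_block_rho) * matrix(f, cfg$n_signal, n, byrow = TRUE) +
      sqrt(1 - cfg$corr_block_rho) * z[sig_idx, , drop = FALSE]
  }

  # Alternating-sign effects on the standardized scale.
  betas <- if (cfg$n_signal > 0) {
    cfg$signal_effect * rep_len(c(1, -1), cfg$n_signal)
  } else {
    numeric(0)
  }

  # Clinical covariates (independent of expression unless couple_platelets).
  age <- rtrunc_norm(n, 52, 8, 25, 85)
  stage <- sample(1:4, n, replace = TRUE, prob = c(0.05, 0.10, 0.60, 0.25))
  residual <- stats::rbinom(n, 1, 0.55)
  ca125 <- stats::rlnorm(n, meanlog = 6, sdlog = 1.2)
  platelet <- rtrunc_norm(n, 300, 80, lower = 1)

  clin_vals <- list(
    age = age, stage = stage, residual = residual, ca125 = log(ca125),
    platelet_count = platelet
  )
  eta <- if (cfg$n_signal > 0) {
    drop(crossprod(z[sig_idx, , drop = FALSE], betas))
  } else {
    rep(0, n)
  }
  for (nm in names(cfg$clinical_effects)) {
    v <- clin_vals[[nm]]
    s <- stats::sd(v)
    if (s > 0) eta <- eta + cfg$clinical_effects[[nm]] * (v - mean(v)) / s
  }

  if (cfg$couple_platelets) {
    platelet <- platelet + 40 * (eta - mean(eta)) / max(stats::sd(eta), 1e-12)
    platelet <- pmax(platelet, 1)
  }

  # Weibull-PH event times by inverse-transform sampling.
  u <- stats::runif(n)
  t_event <- cfg$baseline_scale * (-log(u) / exp(eta))^(1 / cfg$baseline_shape)
  t_cens <- pmin(stats::rexp(n, rate = cfg$censor_rate), cfg$admin_cutoff)
  time <- pmin(t_event, t_cens)
  time <- pmax(time, 1e-6)  # guard against zero after rounding
  event <- as.integer(t_event <= t_cens)

  # Batch structure: additive per-gene log2 offsets (optionally scale
  # distortion), then exponentiation around gene baselines to positive values.
  batch <- sprintf("b%d", 1L + (seq_len(n) - 1L) %% cfg$n_batches)
  mu_g <- withr::with_seed(cfg$panel_seed, stats::runif(p, 2, 10))
  # Site effects are properties of (gene, site), shared by every cohort drawn
  # from the same panel stream — cohorts recruited at the same hospitals see
  # the same batch offsets, which is what makes a frozen training batch
  # adjustment meaningful on validation cohorts.
  site <- withr::with_seed(cfg$panel_seed + 1L, {
    list(
      offsets = matrix(stats::rnorm(p * cfg$n_batches, 0, cfg$batch_sd),
                       nrow = p,
                       dimnames = list(gid, sprintf("b%d", seq_len(cfg$n_batches)))),
      scales = if (cfg$batch_scale_effects) {
        matrix(exp(stats::rnorm(p * cfg$n_batches, 0, 0.2)), nrow = p)
      } else {
        matrix(1, p, cfg$n_batches)
      }
    )
  })
  offsets <- site$offsets
  scales <- site$scales
  bi <- match(batch, colnames(offsets))
  logx <- z * scales[, bi] + mu_g + offsets[, bi]
  values <- 2^logx

  expr <- expr_matrix(values, batch = batch, is_normalized = FALSE)
  clinical <- tibble::tibble(
    sample_id = sid, time_months = unname(time), event = unname(event),
    age = age,
    stage = stage, residual = residual, ca125 = ca125,
    platelet_count = platelet, batch = batch, cohort = cfg$cohort
  )
  truth <- list(
    signal_gene_ids = gid[sig_idx],
    true_betas = stats::setNames(betas, gid[sig_idx]),
    baseline_params = c(shape = cfg$baseline_shape, scale = cfg$baseline_scale),
    true_linear_predictor = stats::setNames(eta, sid)
  )
  list(expression = expr, clinical = clinical, truth = truth)
}

#' Write the simulation ground truth as a key-value sidecar
#'
#' @param truth The `truth` element of [simulate_cohort()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  lines <- c(
    paste0("baseline_shape\t", sprintf("%.17g", truth$baseline_params[["shape"]])),
    paste0("baseline_scale\t", sprintf("%.17g", truth$baseline_params[["scale"]])),
    paste0("signal_gene\t", names(truth$true_betas), "\t",
           sprintf("%.17g", truth$true_betas)),
    paste0("linear_predictor\t", names(truth$true_linear_predictor), "\t",
           sprintf("%.17g", truth$true_linear_predictor))
  )
  writeLines(lines, path)
  invisible(path)
}
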