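#' Multivariable independence analysis of the risk score
#'
#' Fits a proportional-hazards model of the endpoint on the model risk score
#' together with the established clinical predictors — platelet count,
#' patient age, CA125 (log-transformed), residual tumour and FIGO stage
#' (ordinal-coded) — to ask whether the score carries prognostic information
#' beyond the clinic.
#'
#' @param scores Tibble from [predict_risk()] (`sample_id`, `score`).
#' @param clinical Clinical tibble (see [validate_clinical()]).
#' @param covariates Clinical covariates to adjust for; default the full
#'   panel above.
#' @return A `cox_fit` with one row per covariate in its `terms` tibble.
#' @export
multivariable_adjustment <- function(scores, clinical,
                                     covariates = c("platelet_count", "age",
                                                    "ca125", "residual", "stage")) {
  clinical <- validate_clinical(clinical)
  idx <- match(scores$sample_id, clinical$sample_id)
  if (anyNA(idx)) rlang::abort("Scores contain samples absent from the clinical table.")
  clin <- clinical[idx, ]
  X <- cbind(risk_score = scores$score)
  for (cv in covariates) {
    v <- clin[[cv]]
    if (cv == "ca125") v <- log(v)
    X <- cbind(X, stats::setNames(data.frame(v), cv))
  }
  X <- as.matrix(X)
  Xs <- scale(X)
  cn <- kappa(crossprod(Xs) / (nrow(Xs) - 1), exact = TRUE)
  if (!is.finite(cn) || cn > 1e8) {
    cors <- abs(stats::cor(X))
    diag(cors) <- 0
    worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    rlang::abort(paste0(
      "Collinear covariates (condition number ", format(cn, digits = 3), "): ",
      colnames(X)[worst[1]], " and ", colnames(X)[worst[2]]
    ))
  }
  fit_cox(X, as_outcomes(clin))
}

#' Build a regression nomogram from a Cox fit
#'
#' Each covariate is mapped to points
#' \eqn{p_k(x) = 100\,|\beta_k|\,(x - x_k^\ast)/B}, where \eqn{x_k^\ast} is
#' the end of the covariate's range minimizing \eqn{\beta_k x} (so points are
#' nonnegative and increase with hazard) and
#' \eqn{B = \max_k |\beta_k|\,\mathrm{range}_k}; the covariate with the
#' largest \eqn{|\beta|\cdot}range therefore spans exactly 0-100 points.
#' Total points map affinely back to the linear predictor,
#' \eqn{lp(T) = \sum_k \beta_k x_k^\ast + BT/100}, and survival at horizon t
#' is \eqn{\bar S(t)^{\exp(lp(T) - \bar{lp})}} with the Breslow baseline at
#' the covariate means.
#'
#' @param fit A `cox_fit` (e.g. from [multivariable_adjustment()]).
#' @param horizons Months at which the nomogram reads off survival.
#' @param ranges Named list of `c(lo, hi)` per covariate, or a data frame of
#'   covariate values whose observed ranges are used.
#' @return A `nomogram_spec`.
#' @export
build_nomogram <- function(fit, horizons, ranges) {
  stopifnot(inherits(fit, "cox_fit"))
  if (any(horizons > max(fit$baseline$time))) {
    rlang::abort("Nomogram horizon beyond the last observed time.")
  }
  terms <- fit$terms$term
  if (is.data.frame(ranges)) {
    ranges <- purrr::map(as.list(ranges[terms]), range)
  }
  if (!all(terms %in% names(ranges))) rlang::abort("`ranges` must cover every covariate.")
  beta <- stats::setNames(fit$terms$estimate, terms)
  lo <- vapply(ranges[terms], `[`, numeric(1), 1L)
  hi <- vapply(ranges[terms], `[`, numeric(1), 2L)
  width <- hi - lo
  x_star <- ifelse(beta >= 0, lo, hi)
  B <- max(abs(beta) * width)
  if (B <= 0) rlang::abort("All covariates have zero effect or zero range.")
  vars <- tibble::tibble(
    term = terms, beta = beta, range_lo = lo, range_hi = hi,
    x_star = x_star,
    points_per_unit = 100 * abs(beta) / B,
    max_points = 100 * abs(beta) * width / B
  )
  structure(
    list(
      variables = vars, B = B,
      lp_min = sum(beta * x_star),
      lp_bar = sum(beta * fit$means[terms]),
      baseline = fit$baseline,
      horizons = horizons
    ),
    class = "nomogram_spec"
  )
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat("<nomogram_spec> horizons (months): ", paste(x$horizons, collapse = ", "), "\n", sep = "")
  print(x$variables)
  invisible(x)
}

#' Read survival probabilities off a nomogram
#'
#' Sums per-variable points for the supplied covariates (values outside the
#' declared range are clamped with a warning), converts the total to the
#' linear predictor and evaluates baseline survival at every horizon.
#'
#' @param spec A `nomogram_spec`.
#' @param covariates Named numeric vector, or a data frame with one column
#'   per covariate (one row per subject).
#' @return A tibble: `total_points` plus one `surv_<t>` column per horizon.
#' @export
predict_from_nomogram <- function(spec, covariates) {
  stopifnot(inherits(spec, "nomogram_spec"))
  if (!is.data.frame(covariates)) covariates <- as.data.frame(as.list(covariates))
  vars <- spec$variables
  missing <- setdiff(vars$term, names(covariates))
  if (length(missing)) {
    rlang::abort(paste0("Missing covariate(s): ", paste(missing, collapse = ", ")))
  }
  clamped <- FALSE
  pts <- matrix(0, nrow(covariates), nrow(vars))
  for (k in seq_len(nrow(vars))) {
    x <- covariates[[vars$term[k]]]
    below <- x < vars$range_lo[k]
    above <- x > vars$range_hi[k]
    if (any(below | above)) clamped <- TRUE
    x <- pmin(pmax(x, vars$range_lo[k]), vars$range_hi[k])
    pts[, k] <- vars$points_per_unit[k] * abs(x - vars$x_star[k])
  }
  if (clamped) rlang::warn("Covariate value(s) outside the nomogram range were clamped.")
  total <- rowSums(pts)
  lp <- spec$lp_min + spec$B * total / 100
  H <- stats::stepfun(spec$baseline$time, c(0, spec$baseline$cumhaz))(spec$horizons)
  surv <- outer(exp(lp - spec$lp_bar), H, function(r, h) exp(-h * r))
  out <- tibble::as_tibble(surv, .name_repair = ~ paste0("surv_", spec$horizons))
  dplyr::bind_cols(tibble::tibble(total_points = total), out)
}
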