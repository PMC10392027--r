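#' Validate a clinical table
#'
#' The clinical table is a tibble with one row per sample and the columns
#' `sample_id`, `time_months` (> 0), `event` (0/1), `age`, `stage` (ordinal
#' 1-4), `residual` (0 = R0 resection, 1 = residual disease), `ca125`,
#' `platelet_count` (x 10^9/L), `batch`, `cohort`. Unknown extra columns are
#' preserved untouched.
#'
#' @param clinical A data frame.
#' @return The validated table as a tibble.
#' @export
validate_clinical <- function(clinical) {
  clinical <- tibble::as_tibble(clinical)
  required <- c(
    "sample_id", "time_months", "event", "age", "stage", "residual",
    "ca125", "platelet_count", "batch", "cohort"
  )
  missing <- setdiff(required, names(clinical))
  if (length(missing)) {
    rlang::abort(paste0("Clinical table missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(clinical$sample_id)) rlang::abort("Duplicate sample_id in clinical table.")
  bad_t <- which(!is.finite(clinical$time_months) | clinical$time_months <= 0)
  if (length(bad_t)) {
    rlang::abort(paste0(
      "Nonpositive or missing time_months for sample(s): ",
      paste(utils::head(clinical$sample_id[bad_t], 5), collapse = ", ")
    ))
  }
  if (!all(clinical$event %in% c(0, 1))) {
    rlang::abort("`event` must be 0 (censored) or 1 (event observed).")
  }
  if (!all(clinical$stage %in% 1:4)) rlang::abort("`stage` must be an ordinal in 1..4.")
  if (!all(clinical$residual %in% c(0, 1))) rlang::abort("`residual` must be 0/1.")
  clinical
}

#' Read a clinical table from comma-separated text
#'
#' @param path File path.
#' @return A validated clinical tibble.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_clinical(tab)
}

#' Write a clinical table as comma-separated text
#'
#' @param clinical A clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(validate_clinical(clinical), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: extract an outcome tibble (time, event) aligned to sample ids.
as_outcomes <- function(clinical, sample_order = NULL) {
  out <- tibble::tibble(
    sample_id = clinical$sample_id,
    time = clinical$time_months,
    event = as.integer(clinical$event)
  )
  if (!is.null(sample_order)) {
    idx <- match(sample_order, out$sample_id)
    if (anyNA(idx)) rlang::abort("Clinical table does not cover all expression samples.")
    out <- out[idx, ]
  }
  out
}

check_outcomes <- function(time, event, require_event = TRUE) {
  if (length(time) != length(event)) rlang::abort("time and event lengths differ.")
  if (length(time) == 0L) rlang::abort("Empty outcome set.")
  if (any(!is.finite(time) | time <= 0)) rlang::abort("All times must be positive and finite.")
  if (!all(event %in% c(0, 1))) rlang::abort("event must be 0/1.")
  if (require_event && sum(event) == 0) {
    rlang::abort("No observed events; the partial likelihood is undefined.")
  }
  invisible(TRUE)
}
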