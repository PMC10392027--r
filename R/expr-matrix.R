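#' Expression matrix container
#'
#' A light S3 container for a genes x samples expression matrix together with
#' per-sample batch labels and a flag recording whether values are on the raw
#' (nonnegative count-like) or normalized (log2-CPM) scale. All downstream
#' functions take and return this container; per-sample metadata beyond the
#' batch label lives in the clinical table.
#'
#' @param values Numeric genes x samples matrix with unique, non-empty rownames
#'   (gene ids) and colnames (sample ids). All values must be finite; raw
#'   values must be nonnegative.
#' @param batch Per-sample batch labels (character or factor), recycled from a
#'   single value. Defaults to a single batch.
#' @param is_normalized Logical flag; `FALSE` means raw nonnegative values.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, batch = "b1", is_normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    rlang::abort("`values` must carry gene ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    rlang::abort("Duplicate gene identifiers in expression matrix.")
  }
  if (anyDuplicated(colnames(values))) {
    rlang::abort("Duplicate sample identifiers in expression matrix.")
  }
  if (!all(is.finite(values))) {
    rlang::abort("Expression values must all be finite.")
  }
  if (!is_normalized && any(values < 0)) {
    rlang::abort("Raw expression values must be nonnegative.")
  }
  batch <- as.character(batch)
  if (length(batch) == 1L) batch <- rep(batch, ncol(values))
  if (length(batch) != ncol(values)) {
    rlang::abort("`batch` must have one label per sample.")
  }
  names(batch) <- colnames(values)
  structure(
    list(values = values, batch = batch, is_normalized = is_normalized),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(
    "<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values), " samples; ",
    length(unique(x$batch)), " batch(es); ",
    if (x$is_normalized) "normalized (log2-CPM)" else "raw", " scale\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(expr) rownames(expr$values)
sample_ids <- function(expr) colnames(expr$values)

#' Read an expression matrix from delimited text
#'
#' Expects genes in rows and a header of sample ids; the first column holds
#' gene ids. Tab- and comma-separated files are auto-detected from the header
#' line.
#'
#' @param path File path.
#' @param batch Optional per-sample batch labels (named by sample id or in
#'   column order).
#' @param is_normalized Scale flag to attach; see [expr_matrix()].
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, batch = "b1", is_normalized = FALSE) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(
    path, sep = delim, header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "\""
  )
  if (ncol(tab) < 2L) rlang::abort("Expression file needs a gene-id column plus >= 1 sample.")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    rlang::abort(paste0("Duplicate gene rows: ", paste(utils::head(dup, 5), collapse = ", ")))
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    cells <- paste0(ids[bad[, 1L]], ":", colnames(values)[bad[, 2L]])
    rlang::abort(paste0(
      "Missing expression values at ", paste(utils::head(cells, 5), collapse = ", "),
      if (nrow(bad) > 5) sprintf(" (and %d more)", nrow(bad) - 5L) else ""
    ))
  }
  rownames(values) <- ids
  if (!is.null(names(batch)) && length(batch) > 1L) batch <- batch[colnames(values)]
  expr_matrix(values, batch = batch, is_normalized = is_normalized)
}

#' Write an expression matrix as tab-separated text
#'
#' First column `gene_id`, remaining columns samples; full double precision so
#' a write/read round trip is lossless.
#'
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr$values)), collapse = "\t"), con)
  body <- apply(expr$values, 1L, function(v) paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(expr$values), body, sep = "\t"), con)
  invisible(path)
}
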