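#' Library-size normalization: counts-per-million then log2
#'
#' Scales each sample to a library of 10^6 and applies `log2(x + 1)`. The
#' result is flagged normalized; calling [normalize_expression()] on an
#' already-normalized matrix either errors (default) or passes through,
#' never double-transforms.
#'
#' @param expr A raw-scale [expr_matrix()].
#' @param on_normalized What to do with already-normalized input: `"error"`
#'   (default) or `"passthrough"`.
#' @return A normalized `expr_matrix`.
#' @export
normalize_expression <- function(expr, on_normalized = c("error", "passthrough")) {
  stopifnot(inherits(expr, "expr_matrix"))
  on_normalized <- match.arg(on_normalized)
  if (expr$is_normalized) {
    if (on_normalized == "passthrough") return(expr)
    rlang::abort("Input is already normalized; refusing to double-transform.")
  }
  lib <- colSums(expr$values)
  zero <- which(lib == 0)
  if (length(zero)) {
    rlang::abort(paste0(
      "All-zero sample(s): ", paste(colnames(expr$values)[zero], collapse = ", ")
    ))
  }
  cpm <- sweep(expr$values, 2L, lib / 1e6, "/")
  expr_matrix(log2(cpm + 1), batch = expr$batch, is_normalized = TRUE)
}

#' Per-gene location-scale batch adjustment
#'
#' For every gene, each batch's values are centred at the batch mean, rescaled
#' so the batch standard deviation matches the pooled standard deviation, and
#' re-anchored at the pooled mean. After adjustment the per-gene batch means
#' coincide. A single batch is returned unchanged.
#'
#' @param expr A normalized `expr_matrix` with >= 2 samples per batch.
#' @return A list with the adjusted `expr_matrix` (`expression`) and a tibble
#'   of the per-gene, per-batch offsets and scale factors applied
#'   (`batch_params`).
#' @export
adjust_batches <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$is_normalized) rlang::abort("adjust_batches expects normalized input.")
  batches <- unique(expr$batch)
  sizes <- table(expr$batch)
  if (length(batches) > 1 && any(sizes < 2)) {
    rlang::abort(paste0(
      "Batch(es) with < 2 samples: ",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    ))
  }
  v <- expr$values
  pooled_mean <- rowMeans(v)
  pooled_sd <- apply(v, 1L, stats::sd)
  if (length(batches) == 1L) {
    params <- tibble::tibble(
      gene_id = rownames(v), batch = batches,
      center = 0, scale = 1
    )
    return(list(expression = expr, batch_params = params,
                pooled_mean = pooled_mean, pooled_sd = pooled_sd))
  }
  out <- v
  params <- vector("list", length(batches))
  for (k in seq_along(batches)) {
    idx <- which(expr$batch == batches[k])
    m_b <- rowMeans(v[, idx, drop = FALSE])
    s_b <- apply(v[, idx, drop = FALSE], 1L, stats::sd)
    ratio <- ifelse(s_b > 0, pooled_sd / s_b, 0)
    out[, idx] <- (v[, idx, drop = FALSE] - m_b) * ratio + pooled_mean
    params[[k]] <- tibble::tibble(
      gene_id = rownames(v), batch = batches[k], center = m_b, scale = ratio
    )
  }
  list(
    expression = expr_matrix(out, batch = expr$batch, is_normalized = TRUE),
    batch_params = dplyr::bind_rows(params),
    pooled_mean = pooled_mean, pooled_sd = pooled_sd
  )
}

#' Drop genes expressed in too few samples
#'
#' Keeps genes with value > 0 in at least `min_frac_expressed` of samples,
#' preserving order.
#'
#' @param expr A normalized `expr_matrix`.
#' @param min_frac_expressed Fraction in [0, 1]; default 0.2.
#' @return Filtered `expr_matrix`.
#' @export
filter_genes <- function(expr, min_frac_expressed = 0.2) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$is_normalized) rlang::abort("filter_genes expects normalized input.")
  if (min_frac_expressed < 0 || min_frac_expressed > 1) {
    rlang::abort("min_frac_expressed must be in [0, 1].")
  }
  frac <- rowMeans(expr$values > 0)
  keep <- frac >= min_frac_expressed
  if (!any(keep)) rlang::abort("Gene filter removed every gene.")
  expr_matrix(expr$values[keep, , drop = FALSE], batch = expr$batch, is_normalized = TRUE)
}

#' Fit the full training-cohort preprocessing transform
#'
#' Composes the leakage-free training transform: log2-CPM normalization,
#' per-gene location-scale batch adjustment, low-expression gene filtering,
#' and per-gene z-scoring. The returned frozen parameters (training gene
#' list, per-gene centre and scale) are everything needed to project a new
#' cohort onto the training scale with [apply_frozen()].
#'
#' @param expr A raw-scale `expr_matrix` (the training cohort).
#' @param min_frac_expressed Gene-filter threshold; see [filter_genes()].
#' @return A list with `expression` (z-scored training matrix) and `params`
#'   (a `preprocess_params` object).
#' @export
preprocess_fit <- function(expr, min_frac_expressed = 0.2) {
  norm <- normalize_expression(expr)
  adj <- adjust_batches(norm)
  filt <- filter_genes(adj$expression, min_frac_expressed)
  center <- rowMeans(filt$values)
  scale <- apply(filt$values, 1L, stats::sd)
  degenerate <- which(scale <= 0)
  if (length(degenerate)) {
    keep <- scale > 0
    rlang::warn(paste0(length(degenerate), " constant gene(s) dropped during z-scoring."))
    filt <- expr_matrix(filt$values[keep, , drop = FALSE], batch = filt$batch, is_normalized = TRUE)
    center <- center[keep]
    scale <- scale[keep]
  }
  z <- (filt$values - center) / scale
  params <- structure(
    list(
      kept_gene_ids = rownames(filt$values),
      center = center, scale = scale,
      batch_params = adj$batch_params,
      pooled_mean = adj$pooled_mean,
      pooled_sd = adj$pooled_sd,
      library_method = "log2-CPM",
      min_frac_expressed = min_frac_expressed,
      version = 1L
    ),
    class = "preprocess_params"
  )
  list(
    expression = expr_matrix(z, batch = filt$batch, is_normalized = TRUE),
    params = params
  )
}

#' @export
print.preprocess_params <- function(x, ...) {
  cat("<preprocess_params> ", length(x$kept_gene_ids), " genes; ",
      x$library_method, "; min_frac_expressed = ", x$min_frac_expressed, "\n", sep = "")
  invisible(x)
}

#' Apply frozen training preprocessing to a new cohort
#'
#' Normalizes the new cohort (log2-CPM), restricts it to the training gene
#' list and z-scores with the training centre/scale only. When every batch
#' label of the cohort was seen at fit time (e.g. re-projecting the training
#' cohort itself), the stored per-batch location-scale adjustment is applied
#' first so the result reproduces the fit-time transform; unseen batches get
#' centre/scale only. No statistic of the new cohort alters the parameters,
#' enforcing the prospective-validation contract. Genes absent from the new
#' cohort are filled at the training centre (z = 0) with a warning; more than
#' 20% missing is an error.
#'
#' @param expr A raw- or normalized-scale `expr_matrix` from another cohort.
#' @param params A `preprocess_params` from [preprocess_fit()].
#' @return A z-scored `expr_matrix` over the training gene list.
#' @export
apply_frozen <- function(expr, params) {
  stopifnot(inherits(params, "preprocess_params"))
  norm <- normalize_expression(expr, on_normalized = "passthrough")
  bp <- params$batch_params
  if (!is.null(bp) && length(unique(bp$batch)) > 1 &&
      all(norm$batch %in% bp$batch)) {
    v <- norm$values
    pooled_mean <- params$pooled_mean[rownames(v)]
    pooled_sd <- params$pooled_sd[rownames(v)]
    for (b in unique(norm$batch)) {
      idx <- which(norm$batch == b)
      pb <- bp[bp$batch == b, ]
      ctr <- stats::setNames(pb$center, pb$gene_id)[rownames(v)]
      rat <- stats::setNames(pb$scale, pb$gene_id)[rownames(v)]
      ok <- !is.na(ctr)
      v[ok, idx] <- (v[ok, idx, drop = FALSE] - ctr[ok]) * rat[ok] + pooled_mean[ok]
    }
    norm <- expr_matrix(v, batch = norm$batch, is_normalized = TRUE)
  }
  want <- params$kept_gene_ids
  have <- intersect(want, rownames(norm$values))
  missing <- setdiff(want, have)
  if (length(missing) > 0.2 * length(want)) {
    rlang::abort(sprintf(
      "%d of %d training genes missing from cohort (> 20%%).",
      length(missing), length(want)
    ))
  }
  out <- matrix(0, nrow = length(want), ncol = ncol(norm$values),
                dimnames = list(want, colnames(norm$values)))
  z <- (norm$values[have, , drop = FALSE] - params$center[have]) / params$scale[have]
  out[have, ] <- z
  if (length(missing)) {
    rlang::warn(paste0(
      length(missing), " training gene(s) missing; filled at training centre: ",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  expr_matrix(out, batch = norm$batch, is_normalized = TRUE)
}

#' Serialize / restore preprocessing parameters as versioned text
#'
#' @param params A `preprocess_params`.
#' @param path File path.
#' @return `path` (write) or a `preprocess_params` (read).
#' @export
write_preprocess_params <- function(params, path) {
  stopifnot(inherits(params, "preprocess_params"))
  con <- file(path, "w")
  on.exit(close(con))
  kept <- params$kept_gene_ids
  bp <- params$batch_params[params$batch_params$gene_id %in% kept, ]
  writeLines(c(
    paste0("#preprocess_params v", params$version),
    paste0("library_method\t", params$library_method),
    paste0("min_frac_expressed\t", sprintf("%.17g", params$min_frac_expressed)),
    paste0("gene\t", kept, "\t",
           sprintf("%.17g", params$center), "\t", sprintf("%.17g", params$scale)),
    paste0("pooled\t", kept, "\t",
           sprintf("%.17g", params$pooled_mean[kept]), "\t",
           sprintf("%.17g", params$pooled_sd[kept])),
    paste0("batch\t", bp$batch, "\t", bp$gene_id, "\t",
           sprintf("%.17g", bp$center), "\t", sprintf("%.17g", bp$scale))
  ), con)
  invisible(path)
}

#' @rdname write_preprocess_params
#' @export
read_preprocess_params <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#preprocess_params v", lines[1])) {
    rlang::abort("Not a preprocess_params file.")
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  key <- vapply(fields, `[[`, "", 1L)
  genes <- fields[key == "gene"]
  gid <- vapply(genes, `[[`, "", 2L)
  pooled <- fields[key == "pooled"]
  pid <- vapply(pooled, `[[`, "", 2L)
  bt <- fields[key == "batch"]
  batch_params <- if (length(bt)) {
    tibble::tibble(
      gene_id = vapply(bt, `[[`, "", 3L),
      batch = vapply(bt, `[[`, "", 2L),
      center = as.numeric(vapply(bt, `[[`, "", 4L)),
      scale = as.numeric(vapply(bt, `[[`, "", 5L))
    )
  } else {
    NULL
  }
  structure(
    list(
      kept_gene_ids = gid,
      center = stats::setNames(as.numeric(vapply(genes, `[[`, "", 3L)), gid),
      scale = stats::setNames(as.numeric(vapply(genes, `[[`, "", 4L)), gid),
      batch_params = batch_params,
      pooled_mean = stats::setNames(as.numeric(vapply(pooled, `[[`, "", 3L)), pid),
      pooled_sd = stats::setNames(as.numeric(vapply(pooled, `[[`, "", 4L)), pid),
      library_method = fields[key == "library_method"][[1]][2],
      min_frac_expressed = as.numeric(fields[key == "min_frac_expressed"][[1]][2]),
      version = as.integer(sub("^#preprocess_params v", "", lines[1]))
    ),
    class = "preprocess_params"
  )
}
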