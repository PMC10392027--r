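#' Training configuration for the neural Cox model
#'
#' The network is a fully connected multilayer perceptron with ReLU
#' activations and inverted dropout on the hidden layers, ending in a single
#' linear risk unit without bias (the partial likelihood is shift-invariant,
#' so an output bias is unidentifiable). It is trained by minimizing the
#' negative Breslow partial log-likelihood with the Adam optimizer.
#'
#' @param hidden Integer vector of hidden-layer widths; `integer(0)` gives a
#'   plain linear Cox model. Default `c(64, 32)`.
#' @param skip If `TRUE` (default), a direct linear path from the inputs to
#'   the risk output is added to the multilayer-perceptron output, so the
#'   network contains the linear Cox model as a special case and the hidden
#'   layers only have to learn corrections to it. The skip weights start at
#'   zero and are exempt from weight decay. Ignored (treated as `FALSE`) when
#'   `hidden` is empty, where it would be redundant.
#' @param dropout Dropout rate in [0, 1), applied to hidden activations
#'   during training only. Default 0.1.
#' @param lr Adam learning rate (default 1e-3).
#' @param weight_decay L2 penalty added to the gradient (default 1e-4).
#' @param epochs Maximum training epochs (default 200).
#' @param batch_size Mini-batch size; full-batch training is used when the
#'   training set has fewer than 256 samples or `batch_size >= n`. Each
#'   mini-batch's loss uses risk sets within the batch. Default 64.
#' @param val_fraction Held-out fraction for early stopping, event-stratified
#'   (default 0.2); 0 monitors the training partial likelihood instead.
#' @param patience Early-stopping patience in epochs (default 10). When the
#'   monitor plateaus, the best weights are restored and the learning rate is
#'   halved (up to `n_reductions` times) before training finally stops.
#' @param n_reductions Number of learning-rate halvings on plateau before
#'   stopping (default 0: plain early stopping).
#' @return A `deepcox_config` list.
#' @export
deepcox_config <- function(hidden = c(64L, 32L), dropout = 0.1, lr = 1e-3,
                           weight_decay = 1e-4, epochs = 200L,
                           batch_size = 64L, val_fraction = 0.2,
                           patience = 10L, n_reductions = 0L, skip = TRUE) {
  if (dropout < 0 || dropout >= 1) rlang::abort("dropout must be in [0, 1).")
  if (any(hidden < 1)) rlang::abort("hidden widths must be positive.")
  if (val_fraction < 0 || val_fraction >= 1) rlang::abort("val_fraction must be in [0, 1).")
  structure(
    list(hidden = as.integer(hidden), dropout = dropout, lr = lr,
         weight_decay = weight_decay, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), val_fraction = val_fraction,
         patience = as.integer(patience), n_reductions = as.integer(n_reductions),
         skip = isTRUE(skip) && length(hidden) > 0),
    class = "deepcox_config"
  )
}

relu <- function(x) pmax(x, 0)

dc_init_weights <- function(p, hidden, skip = FALSE) {
  dims <- c(p, hidden, 1L)
  weights <- list()
  biases <- list()
  for (l in seq_len(length(dims) - 1L)) {
    fan_in <- dims[l]
    weights[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], 0, sqrt(2 / fan_in)),
                           dims[l], dims[l + 1L])
    biases[l] <- if (l < length(dims) - 1L) list(rep(0, dims[l + 1L])) else list(NULL)
  }
  # With a skip path, start the output layer at zero so the initial model is
  # the (zero) linear path and the nonlinear correction grows from nothing.
  if (skip) weights[[length(weights)]][] <- 0
  list(weights = weights, biases = biases,
       skip = if (skip) matrix(0, p, 1L) else NULL)
}

# Forward pass; when training, applies inverted dropout with the supplied
# rate and returns cached activations and masks for backprop.
dc_forward <- function(par, X, dropout = 0, training = FALSE) {
  L <- length(par$weights)
  h <- X
  acts <- vector("list", L)  # input to each layer
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    acts[[l]] <- h
    z <- h %*% par$weights[[l]]
    if (l < L) {
      z <- sweep(z, 2L, par$biases[[l]], "+")
      h <- relu(z)
      if (training && dropout > 0) {
        m <- matrix(stats::rbinom(length(h), 1, 1 - dropout), nrow(h)) / (1 - dropout)
        h <- h * m
        masks[[l]] <- m
      }
    } else {
      h <- z
    }
  }
  if (!is.null(par$skip)) h <- h + X %*% par$skip
  list(eta = drop(h), acts = acts, masks = masks, X = X)
}

# Backprop of d loss / d eta through the cached forward pass.
dc_backward <- function(par, fwd, d_eta) {
  L <- length(par$weights)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- matrix(d_eta, ncol = 1)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$acts[[l]], delta)
    if (l < L) gb[[l]] <- colSums(delta)
    if (l > 1L) {
      back <- delta %*% t(par$weights[[l]])
      if (!is.null(fwd$masks[[l - 1L]])) back <- back * fwd$masks[[l - 1L]]
      # ReLU derivative on the pre-dropout activation sign; the cached input
      # of layer l is the post-activation h, zero exactly where ReLU clipped
      back <- back * (fwd$acts[[l]] > 0)
      delta <- back
    }
  }
  gs <- if (!is.null(par$skip)) crossprod(fwd$X, matrix(d_eta, ncol = 1)) else NULL
  list(weights = gW, biases = gb, skip = gs)
}

split_event_stratified <- function(event, fraction) {
  n <- length(event)
  val <- logical(n)
  for (lvl in c(0L, 1L)) {
    idx <- which(event == lvl)
    k <- round(fraction * length(idx))
    if (k > 0) val[sample(idx, k)] <- TRUE
  }
  val
}

#' Train the neural Cox proportional-hazards model
#'
#' Minimizes the negative Breslow partial log-likelihood of the network's
#' scalar risk output over the training samples. Mini-batch risk sets are
#' formed within each batch; full-batch training (exact likelihood) is used
#' for small cohorts. Early stopping monitors the partial log-likelihood of
#' an event-stratified held-out fraction and restores the best weights. All
#' randomness (split, initialization, dropout, batch order) flows from one
#' seed, so identical inputs yield identical weights.
#'
#' @param X Samples x genes numeric matrix (signature genes, frozen
#'   preprocessing applied), with row and column names.
#' @param outcomes Data frame with `time` and `event` aligned to rows of `X`.
#' @param config A [deepcox_config()].
#' @param seed Integer seed.
#' @param init_linear Optional named numeric vector of linear coefficients
#'   (one per column of `X`) used to warm-start the linear path: the skip
#'   weights when `config$skip` is on, else the single layer of a
#'   zero-hidden-layer model. Passing the penalized coefficients from the
#'   selection stage means training starts from an already-shrunken linear
#'   risk score and early stopping keeps it unless the network genuinely
#'   improves the held-out partial likelihood.
#' @return A `deepcox_model`: gene list, config, weights/biases, training log
#'   (tibble of epoch, train/monitor partial log-likelihood), seed.
#' @export
train_deepcox <- function(X, outcomes, config = deepcox_config(), seed = 1L,
                          init_linear = NULL) {
  stopifnot(inherits(config, "deepcox_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) rlang::abort("X must carry gene column names.")
  check_outcomes(outcomes$time, outcomes$event)
  if (nrow(X) != nrow(outcomes)) rlang::abort("X rows must match outcomes.")
  if (sum(outcomes$event) < 2) rlang::abort("Need at least 2 events to train.")
  if (sum(outcomes$event) < 20) {
    rlang::warn("Fewer than 20 events; the fit may be unstable.")
  }
  if (!is.null(init_linear)) {
    if (is.null(names(init_linear)) || !all(colnames(X) %in% names(init_linear))) {
      rlang::abort("init_linear must be named with a value for every column of X.")
    }
    init_linear <- init_linear[colnames(X)]
  }
  withr::with_seed(seed, dc_train_impl(X, outcomes, config, seed, init_linear))
}

dc_train_impl <- function(X, outcomes, cfg, seed, init_linear = NULL) {
  n <- nrow(X)
  val <- if (cfg$val_fraction > 0) split_event_stratified(outcomes$event, cfg$val_fraction) else rep(FALSE, n)
  if (sum(outcomes$event[val]) == 0 && any(val)) {
    # degenerate tiny split: fall back to training monitor
    val <- rep(FALSE, n)
  }
  tr_idx <- which(!val)
  va_idx <- which(val)
  Xtr <- X[tr_idx, , drop = FALSE]
  otr <- outcomes[tr_idx, ]
  n_tr <- length(tr_idx)

  par <- dc_init_weights(ncol(X), cfg$hidden, cfg$skip %||% FALSE)
  if (!is.null(init_linear)) {
    if (!is.null(par$skip)) {
      par$skip[] <- init_linear
    } else if (length(cfg$hidden) == 0L) {
      par$weights[[1L]][] <- init_linear
    }
    # warm starts with hidden layers but no skip path have nowhere to go;
    # silently ignoring them would be misleading
    if (is.null(par$skip) && length(cfg$hidden) > 0L) {
      rlang::warn("init_linear ignored: config has hidden layers but no skip path.")
    }
  }
  # Adam state
  mom <- list(
    m = purrr::map(par$weights, ~ .x * 0), v = purrr::map(par$weights, ~ .x * 0),
    mb = purrr::map(par$biases, ~ if (is.null(.x)) NULL else .x * 0),
    vb = purrr::map(par$biases, ~ if (is.null(.x)) NULL else .x * 0),
    ms = if (is.null(par$skip)) NULL else par$skip * 0,
    vs = if (is.null(par$skip)) NULL else par$skip * 0
  )
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  monitor <- function(p) {
    if (length(va_idx)) {
      cox_partial_loglik(dc_forward(p, X[va_idx, , drop = FALSE])$eta, outcomes[va_idx, ])
    } else {
      cox_partial_loglik(dc_forward(p, Xtr)$eta, otr)
    }
  }

  best_par <- par
  best_val <- monitor(par)
  wait <- 0L
  lr <- cfg$lr
  reductions <- 0L
  full_batch <- n_tr < 256 || cfg$batch_size >= n_tr
  skipped_warned <- FALSE
  log <- vector("list", cfg$epochs)
  improved_ever <- FALSE

  for (epoch in seq_len(cfg$epochs)) {
    ord <- if (full_batch) seq_len(n_tr) else sample(n_tr)
    batches <- if (full_batch) list(ord) else split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (bidx in batches) {
      ob <- otr[bidx, ]
      if (sum(ob$event) < 2) {
        if (!skipped_warned) {
          rlang::warn("Skipping mini-batch with fewer than 2 events.")
          skipped_warned <- TRUE
        }
        next
      }
      fwd <- dc_forward(par, Xtr[bidx, , drop = FALSE], cfg$dropout, training = TRUE)
      d_eta <- -cox_partial_loglik_grad(fwd$eta, ob) / length(bidx)
      grad <- dc_backward(par, fwd, d_eta)
      step <- step + 1L
      for (l in seq_along(par$weights)) {
        g <- grad$weights[[l]] + cfg$weight_decay * par$weights[[l]]
        mom$m[[l]] <- b1 * mom$m[[l]] + (1 - b1) * g
        mom$v[[l]] <- b2 * mom$v[[l]] + (1 - b2) * g^2
        mhat <- mom$m[[l]] / (1 - b1^step)
        vhat <- mom$v[[l]] / (1 - b2^step)
        par$weights[[l]] <- par$weights[[l]] - lr * mhat / (sqrt(vhat) + eps)
        if (!is.null(par$biases[[l]])) {
          gb <- grad$biases[[l]]
          mom$mb[[l]] <- b1 * mom$mb[[l]] + (1 - b1) * gb
          mom$vb[[l]] <- b2 * mom$vb[[l]] + (1 - b2) * gb^2
          par$biases[[l]] <- par$biases[[l]] -
            lr * (mom$mb[[l]] / (1 - b1^step)) / (sqrt(mom$vb[[l]] / (1 - b2^step)) + eps)
        }
      }
      if (!is.null(par$skip)) {
        # skip path is exempt from weight decay: it carries the linear signal
        gs <- grad$skip
        mom$ms <- b1 * mom$ms + (1 - b1) * gs
        mom$vs <- b2 * mom$vs + (1 - b2) * gs^2
        par$skip <- par$skip -
          lr * (mom$ms / (1 - b1^step)) / (sqrt(mom$vs / (1 - b2^step)) + eps)
      }
    }
    ll_tr <- cox_partial_loglik(dc_forward(par, Xtr)$eta, otr)
    ll_mon <- monitor(par)
    log[[epoch]] <- tibble::tibble(epoch = epoch, train_loglik = ll_tr, monitor_loglik = ll_mon)
    if (ll_mon > best_val + 1e-8) {
      best_val <- ll_mon
      best_par <- par
      wait <- 0L
      improved_ever <- TRUE
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) {
        if (reductions < cfg$n_reductions) {
          reductions <- reductions + 1L
          lr <- lr / 2
          par <- best_par
          wait <- 0L
        } else {
          break
        }
      }
    }
  }
  if (!improved_ever) {
    rlang::warn("Training never improved on the initial weights; returning initial model.")
  }
  structure(
    list(
      genes = colnames(X), config = cfg,
      weights = best_par$weights, biases = best_par$biases,
      skip = if (is.null(best_par$skip)) NULL else unname(best_par$skip),
      training_log = dplyr::bind_rows(log),
      monitor = if (length(va_idx)) "validation" else "training",
      best_monitor_loglik = best_val,
      seed = seed, version = 1L
    ),
    class = "deepcox_model"
  )
}

#' @export
print.deepcox_model <- function(x, ...) {
  cat("<deepcox_model> ", length(x$genes), " input genes; hidden = [",
      paste(x$config$hidden, collapse = ", "), "]; dropout = ",
      x$config$dropout, "; best ", x$monitor, " partial loglik = ",
      format(x$best_monitor_loglik), "\n", sep = "")
  invisible(x)
}

#' Predict risk scores from a trained model
#'
#' Forward pass in evaluation mode (dropout disabled); scores are on the log
#' relative-hazard scale, higher meaning worse prognosis, and are invariant
#' to sample order.
#'
#' @param model A `deepcox_model`.
#' @param expr Z-scored `expr_matrix` containing the signature genes
#'   ([apply_frozen()] output), or a samples x genes matrix with column names.
#' @return A tibble: `sample_id`, `score`.
#' @export
predict_risk <- function(model, expr) {
  stopifnot(inherits(model, "deepcox_model"))
  if (inherits(expr, "expr_matrix")) {
    missing <- setdiff(model$genes, rownames(expr$values))
    if (length(missing)) {
      rlang::abort(paste0(
        "Expression lacks signature gene(s): ",
        paste(utils::head(missing, 5), collapse = ", ")
      ))
    }
    X <- t(expr$values[model$genes, , drop = FALSE])
  } else {
    X <- as.matrix(expr)
    missing <- setdiff(model$genes, colnames(X))
    if (length(missing)) {
      rlang::abort(paste0(
        "Matrix lacks signature gene(s): ",
        paste(utils::head(missing, 5), collapse = ", ")
      ))
    }
    X <- X[, model$genes, drop = FALSE]
  }
  eta <- dc_forward(list(weights = model$weights, biases = model$biases,
                         skip = model$skip), X)$eta
  tibble::tibble(
    sample_id = rownames(X) %||% paste0("s", seq_len(nrow(X))),
    score = as.numeric(eta)
  )
}

write_num_block <- function(con, tag, mat) {
  writeLines(sprintf("%s\t%d\t%d", tag, nrow(mat), ncol(mat)), con)
  writeLines(apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")), con)
}

#' Persist / restore a trained model as versioned text
#'
#' The container is a plain-text header (version, architecture, gene list,
#' seed) followed by full-precision weight blocks, so a save/load round trip
#' preserves predictions bitwise.
#'
#' @param model A `deepcox_model`.
#' @param path File path.
#' @return `path` (save) or a `deepcox_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "deepcox_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#deepcox_model v", model$version),
    paste0("hidden\t", paste(model$config$hidden, collapse = ",")),
    paste0("dropout\t", sprintf("%.17g", model$config$dropout)),
    paste0("seed\t", model$seed),
    paste0("genes\t", paste(model$genes, collapse = ","))
  ), con)
  for (l in seq_along(model$weights)) {
    write_num_block(con, paste0("W", l), model$weights[[l]])
    if (!is.null(model$biases[[l]])) {
      write_num_block(con, paste0("b", l), matrix(model$biases[[l]], nrow = 1))
    }
  }
  if (!is.null(model$skip)) write_num_block(con, "S", model$skip)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#deepcox_model v", lines[1])) {
    rlang::abort("Not a deepcox_model file (bad header).")
  }
  version <- as.integer(sub("^#deepcox_model v", "", lines[1]))
  if (is.na(version) || version != 1L) rlang::abort("Unsupported model version.")
  kv <- strsplit(lines[2:5], "\t", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  if (!identical(keys, c("hidden", "dropout", "seed", "genes"))) {
    rlang::abort("Corrupted model file: malformed header.")
  }
  hidden_str <- if (length(kv[[1]]) > 1) kv[[1]][2] else ""
  hidden <- if (nzchar(hidden_str)) as.integer(strsplit(hidden_str, ",")[[1]]) else integer(0)
  dropout <- as.numeric(kv[[2]][2])
  seed <- as.integer(kv[[3]][2])
  genes <- strsplit(kv[[4]][2], ",")[[1]]
  i <- 6L
  weights <- list()
  biases <- list()
  skip <- NULL
  l <- 0L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(hdr) != 3L) rlang::abort("Corrupted model file: malformed block header.")
    nr <- as.integer(hdr[2]); nc <- as.integer(hdr[3])
    if (is.na(nr) || is.na(nc) || i + nr > length(lines)) {
      rlang::abort("Corrupted model file: truncated block.")
    }
    vals <- strsplit(lines[(i + 1L):(i + nr)], "\t", fixed = TRUE)
    mat <- do.call(rbind, lapply(vals, as.numeric))
    if (anyNA(mat) || ncol(mat) != nc) rlang::abort("Corrupted model file: bad numeric block.")
    if (grepl("^W", hdr[1])) {
      l <- l + 1L
      weights[[l]] <- mat
      biases[l] <- list(NULL)
    } else if (identical(hdr[1], "S")) {
      skip <- mat
    } else {
      biases[[l]] <- as.numeric(mat)
    }
    i <- i + nr + 1L
  }
  if (length(weights) != length(hidden) + 1L || nrow(weights[[1]]) != length(genes)) {
    rlang::abort("Corrupted model file: architecture mismatch.")
  }
  if (!is.null(skip) && (nrow(skip) != length(genes) || ncol(skip) != 1L)) {
    rlang::abort("Corrupted model file: skip-weight shape mismatch.")
  }
  structure(
    list(
      genes = genes,
      config = deepcox_config(hidden = hidden, dropout = dropout,
                              skip = !is.null(skip)),
      weights = weights, biases = biases, skip = skip,
      training_log = tibble::tibble(), monitor = NA_character_,
      best_monitor_loglik = NA_real_, seed = seed, version = version
    ),
    class = "deepcox_model"
  )
}
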