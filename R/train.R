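#' Training hyperparameters
#'
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation-AUC
#'   improvement); the parameters of the best epoch are returned.
#' @param val_frac Fraction of TCRs (all their records together, so a receptor
#'   never straddles the split) held out for validation.
#' @param seed Seed controlling initialization, the validation split and
#'   batch shuffling; identical `(data, cfg, hyper)` reproduce training
#'   exactly in single-threaded BLAS.
#' @return A `gmlp_hyper` list.
#' @export
train_hyper <- function(lr = 2e-3, batch_size = 256L, epochs = 12L,
                        patience = 2L, val_frac = 0.1, seed = 1L) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "gmlp_hyper")
}

# Encode a record table into the batched stream layout used by the model.
encode_records_batch <- function(records, cfg, matrix = load_blosum50()) {
  batch <- list(B = nrow(records))
  for (s in cfg_streams(cfg)) {
    col <- switch(s, alpha = "cdr3a", beta = "cdr3b", pep = "peptide")
    if (!col %in% names(records) || anyNA(records[[col]])) {
      stop(sprintf("chain_mode '%s' requires column '%s' without missing values",
                   cfg$chain_mode, col))
    }
    eb <- encode_batch(records[[col]], cfg_stream_len(cfg, s), matrix)
    batch[[s]] <- list(x = eb$x, mask = eb$mask)
  }
  batch
}

subset_batch <- function(batch, idx, cfg) {
  out <- list(B = length(idx))
  for (s in setdiff(names(batch), "B")) {
    L <- cfg_stream_len(cfg, s)
    rows <- as.vector(outer(seq_len(L), (idx - 1L) * L, "+"))
    out[[s]] <- list(x = batch[[s]]$x[rows, , drop = FALSE],
                     mask = batch[[s]]$mask[rows])
  }
  out
}

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the hybrid gMLP model
#'
#' Minimizes mean binary cross-entropy with Adam; early stopping monitors ROC
#' AUC on an internal validation split that keeps all records of a TCR on one
#' side. Returns the parameters of the best validation epoch.
#'
#' @param records Data frame with columns `cdr3b`, `peptide`, `label` (and
#'   `cdr3a` for the alpha-aware chain modes).
#' @param cfg A `gmlp_config`.
#' @param hyper A `gmlp_hyper`.
#' @param verbose Print per-epoch losses.
#' @return A `gmlp_model`: list with `cfg`, `params`, `hyper`, `log` (per-epoch
#'   data frame) and `version`.
#' @export
train_gmlp <- function(records, cfg = model_config(), hyper = train_hyper(),
                       verbose = FALSE) {
  records <- as.data.frame(records)
  labels <- as.numeric(records$label)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes")
  }
  n <- nrow(records)
  batch_all <- encode_records_batch(records, cfg)

  with_seed(derive_seed(hyper$seed, 1L), {
    keys <- tcr_key(records)
    uk <- unique(keys)
    n_val_tcr <- max(1L, round(length(uk) * hyper$val_frac))
    val_keys <- sample(uk, n_val_tcr)
    val_idx <- which(keys %in% val_keys)
    train_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(labels[val_idx])) < 2L || length(unique(labels[train_idx])) < 2L) {
      # tiny or degenerate inputs: fall back to a plain stratified record split
      val_idx <- unlist(lapply(split(seq_len(n), labels), function(ix) {
        ix[sample.int(length(ix), max(1L, round(length(ix) * hyper$val_frac)))]
      }), use.names = FALSE)
      train_idx <- setdiff(seq_len(n), val_idx)
    }
  })
  val_batch <- subset_batch(batch_all, val_idx, cfg)
  y_val <- labels[val_idx]

  params <- init_params(cfg, derive_seed(hyper$seed, 2L))
  skel <- params
  theta <- flatten_params(params)
  state <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)

  best <- list(auc = -Inf, theta = theta, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), val_auc = numeric())
  wait <- 0L
  for (epoch in seq_len(hyper$epochs)) {
    ord <- with_seed(derive_seed(hyper$seed, 100L + epoch),
                     sample(train_idx))
    nb <- ceiling(length(ord) / hyper$batch_size)
    epoch_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * hyper$batch_size + 1L):min(bi * hyper$batch_size, length(ord))]
      mb <- subset_batch(batch_all, idx, cfg)
      y <- labels[idx]
      params <- unflatten_params(theta, skel)
      fw <- model_forward_batch(mb, params, cfg)
      epoch_loss <- epoch_loss + binary_cross_entropy(fw$prob, y) * length(idx)
      dlogits <- (fw$prob - y) / length(idx)
      grads <- model_backward_batch(dlogits, fw$cache, params, cfg)
      up <- adam_step(theta, flatten_params(grads), state, hyper$lr)
      theta <- up$theta
      state <- up$state
    }
    params <- unflatten_params(theta, skel)
    val_prob <- model_forward_batch(val_batch, params, cfg)$prob
    val_loss <- binary_cross_entropy(val_prob, y_val)
    val_auc <- roc_auc(val_prob, y_val)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = epoch_loss / length(train_idx),
                                 val_loss = val_loss, val_auc = val_auc))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f auc %.4f",
                      epoch, epoch_loss / length(train_idx), val_loss, val_auc))
    }
    if (val_auc > best$auc + 1e-6) {
      best <- list(auc = val_auc, theta = theta, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hyper$patience) break
    }
  }
  structure(list(cfg = cfg, params = unflatten_params(best$theta, skel),
                 hyper = hyper, log = log, best_epoch = best$epoch,
                 version = as.character(utils::packageVersion("tcrgmlp"))),
            class = "gmlp_model")
}

#' Predict binding probabilities
#'
#' @param object A `gmlp_model`.
#' @param newdata Record data frame (same columns as training).
#' @param batch_size Scoring chunk size.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.gmlp_model <- function(object, newdata, batch_size = 1024L, ...) {
  newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  if (n == 0L) return(numeric())
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    mb <- encode_records_batch(newdata[idx, , drop = FALSE], object$cfg)
    out[idx] <- model_forward_batch(mb, object$params, object$cfg)$prob
  }
  out
}

#' @export
print.gmlp_model <- function(x, ...) {
  cat(sprintf("gMLP binding model (%s): %d blocks/stream, d_model=%d, d_ffn=%d\n",
              x$cfg$chain_mode, x$cfg$n_blocks, x$cfg$d_model, x$cfg$d_ffn))
  cat(sprintf("  %d parameters; best epoch %d (val AUC %.3f)\n",
              length(flatten_params(x$params)), x$best_epoch,
              max(x$log$val_auc)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles config, parameters, training hyperparameters and the
#' package version. Loading validates the structure and refuses mismatched
#' parameter shapes.
#'
#' @param model A `gmlp_model`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gmlp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gmlp_model") ||
      !all(c("cfg", "params", "hyper") %in% names(model))) {
    stop("not a gmlp_model checkpoint")
  }
  ref <- init_params(model$cfg, 1L)
  if (length(flatten_params(ref)) != length(flatten_params(model$params))) {
    stop("checkpoint parameters do not match its configuration")
  }
  model
}

#' Read / write a model configuration as YAML
#'
#' The YAML mirrors [model_config()] and [train_hyper()] field-for-field under
#' `model:` and `training:` keys.
#'
#' @param path YAML file path.
#' @return `read_config()` returns `list(cfg, hyper)`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(model_config, y$model %||% list())
  hyper <- do.call(train_hyper, y$training %||% list())
  list(cfg = cfg, hyper = hyper)
}

#' @rdname read_config
#' @param cfg A `gmlp_config`.
#' @param hyper A `gmlp_hyper`.
#' @export
write_config <- function(cfg, hyper, path) {
  yaml::write_yaml(list(model = unclass(cfg), training = unclass(hyper)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
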