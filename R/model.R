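#' Model configuration
#'
#' Hyper-structure of the hybrid gMLP network. Each input stream (CDR3 alpha,
#' CDR3 beta, peptide -- which streams exist is set by `chain_mode`) passes its
#' BLOSUM50 encoding through its own stack of `n_blocks` gMLP blocks. The
#' post-gMLP alpha and beta features are concatenated on the token axis and
#' serve as keys/values for two attention paths run in parallel with the
#' peptide features as queries: full multi-head attention and windowed local
#' attention (block softmax over consecutive key windows of `local_window`
#' tokens, window outputs superimposed). The two attention outputs are
#' concatenated channel-wise, mean-pooled over peptide tokens, and fed to a
#' dense/GELU head ending in one sigmoid unit.
#'
#' @param d_model Channel width of the streams. Default 20, the BLOSUM50
#'   encoding width, so encodings feed the blocks directly; any other value
#'   adds a learned linear input projection per stream.
#' @param d_ffn Hidden width of the gMLP channel projection; must be even
#'   (the spatial gating unit splits it into halves).
#' @param n_blocks Number of identical gMLP blocks per stream (default 3).
#' @param n_heads,head_dim Attention heads and per-head width (head_dim
#'   capped at 128).
#' @param local_window Key window size of the local attention path (default 2).
#' @param max_cdr3 Padded CDR3 length; also the upper length filter (18).
#' @param pep_len Required peptide length (9).
#' @param head_layers Integer vector of hidden layer sizes of the prediction
#'   head.
#' @param chain_mode "paired", "beta_only" or "alpha_only".
#' @param sgu_norm Layer-normalize the gated channel half inside the SGU
#'   before the spatial projection (default TRUE).
#' @return A `gmlp_config` list.
#' @export
model_config <- function(d_model = 20L, d_ffn = 32L, n_blocks = 3L,
                         n_heads = 1L, head_dim = 32L, local_window = 2L,
                         max_cdr3 = 18L, pep_len = 9L,
                         head_layers = c(32L, 16L),
                         chain_mode = c("paired", "beta_only", "alpha_only"),
                         sgu_norm = TRUE) {
  chain_mode <- match.arg(chain_mode)
  if (d_ffn %% 2L != 0L) stop("d_ffn must be even: the SGU splits channels into two halves")
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  if (local_window < 1L) stop("local_window must be >= 1")
  if (head_dim > 128L) stop("head_dim must be <= 128")
  if (n_heads < 1L) stop("n_heads must be >= 1")
  structure(list(d_model = as.integer(d_model), d_ffn = as.integer(d_ffn),
                 n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
                 head_dim = as.integer(head_dim),
                 local_window = as.integer(local_window),
                 max_cdr3 = as.integer(max_cdr3), pep_len = as.integer(pep_len),
                 head_layers = as.integer(head_layers),
                 chain_mode = chain_mode, sgu_norm = isTRUE(sgu_norm)),
            class = "gmlp_config")
}

cfg_streams <- function(cfg) {
  switch(cfg$chain_mode,
         paired = c("alpha", "beta", "pep"),
         beta_only = c("beta", "pep"),
         alpha_only = c("alpha", "pep"))
}

cfg_stream_len <- function(cfg, stream) {
  if (stream == "pep") cfg$pep_len else cfg$max_cdr3
}

cfg_chain_len <- function(cfg) {
  if (cfg$chain_mode == "paired") 2L * cfg$max_cdr3 else cfg$max_cdr3
}

glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

init_block <- function(cfg, L) {
  d <- cfg$d_model
  f <- cfg$d_ffn
  h <- f %/% 2L
  list(ln_g = rep(1, d), ln_b = rep(0, d),
       U = glorot(d, f), bu = rep(0, f),
       sgu = list(W = matrix(stats::runif(L * L, -0.01, 0.01), L, L),
                  b = rep(1, L),
                  ln_g = rep(1, h), ln_b = rep(0, h)),
       V = glorot(h, d), bv = rep(0, d))
}

init_attention <- function(cfg) {
  d <- cfg$d_model
  H <- cfg$n_heads * cfg$head_dim
  list(Wq = glorot(d, H), bq = rep(0, H),
       Wk = glorot(d, H), bk = rep(0, H),
       Wv = glorot(d, H), bv = rep(0, H),
       Wo = glorot(H, d), bo = rep(0, d))
}

#' Initialize model parameters
#'
#' Spatial-gating-unit weights follow the stabilized gMLP scheme: each spatial
#' projection entry is drawn uniformly from \[-0.01, 0.01\] and the per-token
#' gate bias is set to 1, so every block behaves like a plain channel FFN at
#' the start of training and cross-token mixing is learned gradually. All
#' dense projections use Glorot-uniform fan-scaled initialization; layer-norm
#' affine parameters start at (1, 0); the spatial maps framing the local
#' attention start at identity. Deterministic given `(cfg, seed)`.
#'
#' @param cfg A `gmlp_config`.
#' @param seed Integer seed.
#' @return Nested list of numeric parameter tensors.
#' @export
init_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    d <- cfg$d_model
    Lp <- cfg$pep_len
    streams <- lapply(stats::setNames(nm = cfg_streams(cfg)), function(s) {
      L <- cfg_stream_len(cfg, s)
      blocks <- lapply(seq_len(cfg$n_blocks), function(i) init_block(cfg, L))
      if (d != 20L) {
        list(in_proj = list(W = glorot(20L, d), b = rep(0, d)), blocks = blocks)
      } else {
        list(blocks = blocks)
      }
    })
    head_sizes <- c(2L * d, cfg$head_layers, 1L)
    head <- lapply(seq_len(length(head_sizes) - 1L), function(i) {
      list(W = glorot(head_sizes[i], head_sizes[i + 1L]),
           b = rep(0, head_sizes[i + 1L]))
    })
    list(streams = streams,
         attn_global = init_attention(cfg),
         attn_local = c(init_attention(cfg),
                        list(q_spat = diag(Lp),
                             ln_q_g = rep(1, d), ln_q_b = rep(0, d),
                             post_spat = diag(Lp),
                             ln_post_g = rep(1, d), ln_post_b = rep(0, d))),
         head = head)
  })
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  walk <- function(s) {
    if (is.list(s)) return(lapply(s, walk))
    n <- length(s)
    v <- flat[pos + seq_len(n)]
    pos <<- pos + n
    dim(v) <- dim(s)
    v
  }
  out <- walk(skeleton)
  stopifnot(pos == length(flat))
  out
}

check_finite <- function(x, layer) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values produced in layer '%s'", layer))
  }
  invisible(x)
}

# Batched forward pass. `batch` is a list with, per present stream, x
# ((B*L) x 20) and mask (length B*L), plus B. Returns probabilities and the
# caches needed for the backward pass.
model_forward_batch <- function(batch, params, cfg, check = FALSE) {
  B <- batch$B
  d <- cfg$d_model
  Lp <- cfg$pep_len
  streams <- cfg_streams(cfg)
  s_out <- list()
  s_cache <- list()
  for (s in streams) {
    L <- cfg_stream_len(cfg, s)
    X <- batch[[s]]$x
    mask <- batch[[s]]$mask
    sp <- params$streams[[s]]
    caches <- list()
    if (!is.null(sp$in_proj)) {
      ip <- dense_fw(X, sp$in_proj$W, sp$in_proj$b)
      caches$in_proj <- ip$cache
      X <- ip$out
    }
    bc <- vector("list", cfg$n_blocks)
    for (i in seq_len(cfg$n_blocks)) {
      blk <- gmlp_block_fw(X, sp$blocks[[i]], mask, L, cfg$sgu_norm)
      bc[[i]] <- blk$cache
      X <- blk$out
    }
    if (check) check_finite(X, paste0("gmlp_", s))
    caches$blocks <- bc
    s_out[[s]] <- X
    s_cache[[s]] <- caches
  }

  Lc <- cfg_chain_len(cfg)
  Lm <- cfg$max_cdr3
  mask_mat <- function(s) t(matrix(batch[[s]]$mask, nrow = cfg_stream_len(cfg, s)))
  if (cfg$chain_mode == "paired") {
    a_pos <- as.vector(outer(seq_len(Lm), (seq_len(B) - 1L) * Lc, "+"))
    b_pos <- as.vector(outer(Lm + seq_len(Lm), (seq_len(B) - 1L) * Lc, "+"))
    C <- matrix(0, B * Lc, d)
    C[a_pos, ] <- s_out$alpha
    C[b_pos, ] <- s_out$beta
    key_mask <- cbind(mask_mat("alpha"), mask_mat("beta"))
    concat_idx <- list(a_pos = a_pos, b_pos = b_pos)
  } else {
    chain <- setdiff(streams, "pep")
    C <- s_out[[chain]]
    key_mask <- mask_mat(chain)
    concat_idx <- NULL
  }
  Xp <- s_out$pep

  ag <- attention_fw(Xp, C, params$attn_global, key_mask, B, Lp, Lc,
                     cfg$n_heads, cfg$head_dim, mode = "global")
  if (check) check_finite(ag$out, "attn_global")

  pl <- params$attn_local
  qs <- spatial_fw(Xp, pl$q_spat, Lp)
  qn <- layer_norm_fw(qs$out, pl$ln_q_g, pl$ln_q_b)
  al <- attention_fw(qn$out, C, pl, key_mask, B, Lp, Lc,
                     cfg$n_heads, cfg$head_dim, mode = "local",
                     window = cfg$local_window)
  ps <- spatial_fw(al$out, pl$post_spat, Lp)
  pn <- layer_norm_fw(ps$out, pl$ln_post_g, pl$ln_post_b)
  if (check) check_finite(pn$out, "attn_local")

  Fmat <- cbind(ag$out, pn$out)
  pooled <- rowsum(Fmat, rep(seq_len(B), each = Lp)) / Lp

  Z <- pooled
  hc <- vector("list", length(params$head))
  n_head <- length(params$head)
  for (i in seq_len(n_head)) {
    dn <- dense_fw(Z, params$head[[i]]$W, params$head[[i]]$b)
    if (i < n_head) {
      ge <- gelu_fw(dn$out)
      hc[[i]] <- list(dense = dn$cache, gelu = ge$cache)
      Z <- ge$out
    } else {
      hc[[i]] <- list(dense = dn$cache)
      Z <- dn$out
    }
  }
  logits <- as.vector(Z)
  check_finite(logits, "head")
  list(prob = stats::plogis(logits), logits = logits,
       cache = list(streams = s_cache, concat_idx = concat_idx,
                    ag = ag$cache, qs = qs$cache, qn = qn$cache,
                    al = al$cache, ps = ps$cache, pn = pn$cache,
                    head = hc, B = B, Lp = Lp, Lc = Lc,
                    stream_names = streams))
}

# Backward pass: dlogits is the gradient of the loss w.r.t. the logits
# (length B). Returns gradients in the exact shape of `params`.
model_backward_batch <- function(dlogits, cache, params, cfg) {
  B <- cache$B
  Lp <- cache$Lp
  dZ <- matrix(dlogits, ncol = 1L)
  n_head <- length(params$head)
  head_g <- vector("list", n_head)
  for (i in rev(seq_len(n_head))) {
    if (i < n_head) dZ <- gelu_bw(dZ, cache$head[[i]]$gelu)
    db <- dense_bw(dZ, cache$head[[i]]$dense)
    head_g[[i]] <- list(W = db$dW, b = db$db)
    dZ <- db$dX
  }
  dpooled <- dZ
  dF <- dpooled[rep(seq_len(B), each = Lp), , drop = FALSE] / Lp
  d <- cfg$d_model
  d_ag_out <- dF[, seq_len(d), drop = FALSE]
  d_pn_out <- dF[, d + seq_len(d), drop = FALSE]

  pnb <- layer_norm_bw(d_pn_out, cache$pn)
  psb <- spatial_bw(pnb$dX, cache$ps)
  alb <- attention_bw(psb$dX, cache$al)
  qnb <- layer_norm_bw(alb$dQ_in, cache$qn)
  qsb <- spatial_bw(qnb$dX, cache$qs)
  attn_local_g <- c(alb$grads,
                    list(q_spat = qsb$dW, ln_q_g = qnb$dg, ln_q_b = qnb$db,
                         post_spat = psb$dW, ln_post_g = pnb$dg,
                         ln_post_b = pnb$db))

  agb <- attention_bw(d_ag_out, cache$ag)
  dXp <- agb$dQ_in + qsb$dX
  dC <- agb$dKV_in + alb$dKV_in

  if (cfg$chain_mode == "paired") {
    d_alpha <- dC[cache$concat_idx$a_pos, , drop = FALSE]
    d_beta <- dC[cache$concat_idx$b_pos, , drop = FALSE]
    d_stream_out <- list(alpha = d_alpha, beta = d_beta, pep = dXp)
  } else {
    chain <- setdiff(cache$stream_names, "pep")
    d_stream_out <- stats::setNames(list(dC, dXp), c(chain, "pep"))
  }

  streams_g <- list()
  for (s in cache$stream_names) {
    sc <- cache$streams[[s]]
    dX <- d_stream_out[[s]]
    blocks_g <- vector("list", cfg$n_blocks)
    for (i in rev(seq_len(cfg$n_blocks))) {
      bb <- gmlp_block_bw(dX, sc$blocks[[i]])
      blocks_g[[i]] <- bb$grads
      dX <- bb$dX
    }
    sg <- list()
    if (!is.null(sc$in_proj)) {
      ipb <- dense_bw(dX, sc$in_proj)
      sg$in_proj <- list(W = ipb$dW, b = ipb$db)
    }
    sg$blocks <- blocks_g
    streams_g[[s]] <- sg
  }
  # order must mirror init_params exactly for flatten alignment
  list(streams = streams_g[cfg_streams(cfg)],
       attn_global = agb$grads[names(params$attn_global)],
       attn_local = attn_local_g[names(params$attn_local)],
       head = head_g)
}

#' Forward pass for a single encoded example
#'
#' Runs the full network on one [encode_example()] result and returns the
#' predicted binding probability. Inference is deterministic; any non-finite
#' intermediate raises an error naming the offending layer.
#'
#' @param example An `encoded_example` whose streams match `cfg$chain_mode`.
#' @param params Parameters from [init_params()] or a trained model.
#' @param cfg The `gmlp_config` the parameters were built with.
#' @return Binding probability in \[0, 1\].
#' @export
model_forward <- function(example, params, cfg) {
  stopifnot(inherits(example, "encoded_example"))
  if (example$chain_mode != cfg$chain_mode) {
    stop(sprintf("example encoded for chain_mode '%s' but config is '%s'",
                 example$chain_mode, cfg$chain_mode))
  }
  batch <- list(B = 1L)
  for (s in cfg_streams(cfg)) {
    slot <- switch(s, alpha = "alpha", beta = "beta", pep = "peptide")
    enc <- example[[slot]]
    if (is.null(enc)) stop(sprintf("missing stream '%s'", slot))
    batch[[s]] <- list(x = enc$matrix, mask = enc$mask)
  }
  model_forward_batch(batch, params, cfg, check = TRUE)$prob
}

#' Mean binary cross-entropy
#'
#' Probabilities are clamped to \[1e-7, 1 - 1e-7\] before taking logs.
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param labels Binary vector of the same length.
#' @return Scalar mean loss.
#' @export
binary_cross_entropy <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) {
    stop("probabilities and labels must have the same length")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- pmin(pmax(probabilities, 1e-7), 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
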