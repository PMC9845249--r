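# Batched layer primitives for the gMLP network.
#
# Layout convention: a stream of B examples, each a sequence of L tokens with d
# channels, is stored as a (B*L) x d matrix with the token index varying
# fastest (rows 1..L are example 1, rows L+1..2L example 2, ...). Masks are
# logical vectors of length B*L in the same order. This makes channel
# projections a single matrix product and lets the spatial (token-axis)
# projection be applied to all examples and channels at once by reshaping to
# an L x (B*d) matrix, which is valid because R matrices are column-major.
#
# Every *_fw returns list(out = ..., cache = ...); the matching *_bw takes the
# upstream gradient and the cache and returns gradients for inputs and
# parameters. Gradients were derived by hand and are verified against central
# finite differences in the test suite.

.ln_eps <- 1e-5

# y = g * (x - mu)/sqrt(var + eps) + b, per row (token) over channels
layer_norm_fw <- function(X, g, b) {
  r <- ln_fw_cpp(X, g, b, .ln_eps)
  list(out = r$out, cache = list(xhat = r$xhat, s = r$s, g = g))
}

layer_norm_bw <- function(dY, cache) {
  ln_bw_cpp(dY, cache$xhat, cache$s, cache$g)
}

dense_fw <- function(X, W, b = NULL) {
  out <- X %*% W
  if (!is.null(b)) out <- out + rep(b, each = nrow(X))
  list(out = out, cache = list(X = X, W = W, has_b = !is.null(b)))
}

dense_bw <- function(dY, cache) {
  list(dX = tcrossprod(dY, cache$W),
       dW = crossprod(cache$X, dY),
       db = if (cache$has_b) colSums(dY) else NULL)
}

# exact GELU: x * Phi(x)
gelu_fw <- function(X) {
  r <- gelu_fw_cpp(X)
  list(out = r$out, cache = list(X = X, Phi = r$Phi))
}

gelu_bw <- function(dY, cache) {
  gelu_bw_cpp(dY, cache$X, cache$Phi)
}

# Spatial (token-axis) projection: for each example and channel, the length-L
# token vector is premultiplied by W (L x L). X is (B*L) x d.
spatial_fw <- function(X, W, L) {
  d <- ncol(X)
  n <- nrow(X)
  M <- matrix(X, nrow = L)            # L x (B*d), columns ordered (example, channel)
  Y <- W %*% M
  list(out = matrix(Y, nrow = n, ncol = d), cache = list(M = M, W = W, L = L, n = n, d = d))
}

spatial_bw <- function(dY, cache) {
  D <- matrix(dY, nrow = cache$L)
  list(dX = matrix(crossprod(cache$W, D), nrow = cache$n, ncol = cache$d),
       dW = tcrossprod(D, cache$M))
}

# Spatial Gating Unit. Z is (B*L) x d_ffn; channel halves (z1, z2); z2 is
# layer-normalized (optional), padded token rows are zeroed so the learned
# spatial mixing cannot read padding, then projected over the token axis by W;
# the per-token bias b is added (broadcast over channels) and the result gates
# z1 elementwise.
sgu_fw <- function(Z, p, mask, L, use_norm = TRUE) {
  f <- ncol(Z)
  stopifnot(f %% 2L == 0L)
  h <- f %/% 2L
  n <- nrow(Z)
  z1 <- Z[, seq_len(h), drop = FALSE]
  z2 <- Z[, h + seq_len(h), drop = FALSE]
  if (use_norm) {
    ln <- layer_norm_fw(z2, p$ln_g, p$ln_b)
    z2n <- ln$out
  } else {
    ln <- NULL
    z2n <- z2
  }
  if (!all(mask)) z2n[!mask, ] <- 0
  sp <- spatial_fw(z2n, p$W, L)
  tok <- rep_len(seq_len(L), n)
  gate <- sp$out + p$b[tok]
  list(out = z1 * gate,
       cache = list(z1 = z1, gate = gate, ln = if (use_norm) ln$cache, sp = sp$cache,
                    mask = mask, tok = tok, use_norm = use_norm, h = h))
}

sgu_bw <- function(dY, cache) {
  z1 <- cache$z1
  dz1 <- dY * cache$gate
  dgate <- dY * z1
  db <- rowSums(rowsum(dgate, cache$tok))
  spb <- spatial_bw(dgate, cache$sp)
  dz2n <- spb$dX
  if (!all(cache$mask)) dz2n[!cache$mask, ] <- 0
  if (cache$use_norm) {
    lnb <- layer_norm_bw(dz2n, cache$ln)
    dz2 <- lnb$dX
    dln_g <- lnb$dg
    dln_b <- lnb$db
  } else {
    dz2 <- dz2n
    # zero placeholders keep gradient/parameter trees structurally identical
    dln_g <- rep(0, cache$h)
    dln_b <- rep(0, cache$h)
  }
  list(dZ = cbind(dz1, dz2), dW = spb$dW, db = db,
       dln_g = dln_g, dln_b = dln_b)
}

# One gMLP block: Y = X + V(SGU(GELU(LN(X) U))). All projections carry biases;
# the residual path leaves padded rows untouched (they are never read
# downstream except as masked attention keys).
gmlp_block_fw <- function(X, p, mask, L, use_sgu_norm = TRUE) {
  ln <- layer_norm_fw(X, p$ln_g, p$ln_b)
  u <- dense_fw(ln$out, p$U, p$bu)
  g <- gelu_fw(u$out)
  s <- sgu_fw(g$out, p$sgu, mask, L, use_sgu_norm)
  v <- dense_fw(s$out, p$V, p$bv)
  list(out = X + v$out,
       cache = list(ln = ln$cache, u = u$cache, g = g$cache, s = s$cache,
                    v = v$cache))
}

gmlp_block_bw <- function(dY, cache) {
  vb <- dense_bw(dY, cache$v)
  sb <- sgu_bw(vb$dX, cache$s)
  dg <- gelu_bw(sb$dZ, cache$g)
  ub <- dense_bw(dg, cache$u)
  lnb <- layer_norm_bw(ub$dX, cache$ln)
  list(dX = dY + lnb$dX,
       grads = list(ln_g = lnb$dg, ln_b = lnb$db,
                    U = ub$dW, bu = ub$db,
                    sgu = list(W = sb$dW, b = sb$db,
                               ln_g = sb$dln_g, ln_b = sb$dln_b),
                    V = vb$dW, bv = vb$db))
}

# Scaled dot-product attention with either full-key softmax ("global") or
# block softmax over consecutive non-overlapping key windows ("local").
# Summing the per-window attention outputs is algebraically identical to a
# single weighted sum under block-normalized weights, which is how the local
# variant is computed here. Fully masked windows contribute nothing.
#
# Qp, Kp, Vp: projected queries/keys/values, (B*Lq) x H and (B*Lk) x H with
# H = n_heads * head_dim. key_mask: B x Lk logical. Scores are assembled per
# example (tiny BLAS calls); the softmax runs vectorized on the stacked
# (B*Lq) x Lk score matrix. Returns concatenated head outputs plus the
# per-head attention weights needed for the backward pass.
attention_core_fw <- function(Qp, Kp, Vp, key_mask, B, Lq, Lk,
                              n_heads, head_dim, mode = c("global", "local"),
                              window = 2L) {
  mode <- match.arg(mode)
  idxq <- rep(seq_len(B), each = Lq)
  Me <- key_mask[idxq, , drop = FALSE]
  if (mode == "global" && any(rowSums(Me) == 0L)) {
    stop("degenerate attention: an example has all keys masked")
  }
  groups <- if (mode == "global") list(seq_len(Lk)) else
    split(seq_len(Lk), ceiling(seq_len(Lk) / window))
  O <- matrix(0, nrow = B * Lq, ncol = n_heads * head_dim)
  heads <- vector("list", n_heads)
  scale <- 1 / sqrt(head_dim)
  qrows <- function(b) (b - 1L) * Lq + seq_len(Lq)
  krows <- function(b) (b - 1L) * Lk + seq_len(Lk)
  for (hh in seq_len(n_heads)) {
    cols <- (hh - 1L) * head_dim + seq_len(head_dim)
    Qh <- Qp[, cols, drop = FALSE]
    Kh <- Kp[, cols, drop = FALSE]
    Vh <- Vp[, cols, drop = FALSE]
    S <- matrix(0, nrow = B * Lq, ncol = Lk)
    for (b in seq_len(B)) {
      S[qrows(b), ] <- tcrossprod(Qh[qrows(b), , drop = FALSE],
                                  Kh[krows(b), , drop = FALSE])
    }
    S <- S * scale
    S[!Me] <- -Inf
    A <- matrix(0, nrow = B * Lq, ncol = Lk)
    for (gr in groups) {
      m <- S[, gr[1]]
      for (j in gr[-1]) m <- pmax(m, S[, j])
      P <- exp(S[, gr, drop = FALSE] - ifelse(is.finite(m), m, 0))
      P[!Me[, gr, drop = FALSE]] <- 0
      rs <- rowSums(P)
      rs[rs == 0] <- 1
      A[, gr] <- P / rs
    }
    Oh <- matrix(0, nrow = B * Lq, ncol = head_dim)
    for (b in seq_len(B)) {
      Oh[qrows(b), ] <- A[qrows(b), , drop = FALSE] %*% Vh[krows(b), , drop = FALSE]
    }
    O[, cols] <- Oh
    heads[[hh]] <- list(A = A, Qh = Qh, Kh = Kh, Vh = Vh)
  }
  list(out = O,
       cache = list(heads = heads, B = B, Lq = Lq, Lk = Lk,
                    n_heads = n_heads, head_dim = head_dim, groups = groups,
                    scale = scale))
}

attention_core_bw <- function(dO, cache) {
  B <- cache$B; Lq <- cache$Lq; Lk <- cache$Lk
  hd <- cache$head_dim
  dQp <- matrix(0, nrow = B * Lq, ncol = cache$n_heads * hd)
  dKp <- matrix(0, nrow = B * Lk, ncol = cache$n_heads * hd)
  dVp <- matrix(0, nrow = B * Lk, ncol = cache$n_heads * hd)
  qrows <- function(b) (b - 1L) * Lq + seq_len(Lq)
  krows <- function(b) (b - 1L) * Lk + seq_len(Lk)
  for (hh in seq_len(cache$n_heads)) {
    cols <- (hh - 1L) * hd + seq_len(hd)
    hc <- cache$heads[[hh]]
    dOh <- dO[, cols, drop = FALSE]
    A <- hc$A
    dA <- matrix(0, nrow = B * Lq, ncol = Lk)
    for (b in seq_len(B)) {
      qr <- qrows(b); kr <- krows(b)
      dA[qr, ] <- tcrossprod(dOh[qr, , drop = FALSE], hc$Vh[kr, , drop = FALSE])
      dVp[kr, cols] <- crossprod(A[qr, , drop = FALSE], dOh[qr, , drop = FALSE])
    }
    dAA <- dA * A
    dS <- matrix(0, nrow = B * Lq, ncol = Lk)
    for (gr in cache$groups) {
      r <- rowSums(dAA[, gr, drop = FALSE])
      dS[, gr] <- A[, gr, drop = FALSE] * (dA[, gr, drop = FALSE] - r)
    }
    dS <- dS * cache$scale
    for (b in seq_len(B)) {
      qr <- qrows(b); kr <- krows(b)
      dQp[qr, cols] <- dS[qr, , drop = FALSE] %*% hc$Kh[kr, , drop = FALSE]
      dKp[kr, cols] <- crossprod(dS[qr, , drop = FALSE], hc$Qh[qr, , drop = FALSE])
    }
  }
  list(dQp = dQp, dKp = dKp, dVp = dVp)
}

# Full attention layer: q/k/v input projections, core, output projection.
attention_fw <- function(Q_in, KV_in, p, key_mask, B, Lq, Lk,
                         n_heads, head_dim, mode, window = 2L) {
  q <- dense_fw(Q_in, p$Wq, p$bq)
  k <- dense_fw(KV_in, p$Wk, p$bk)
  v <- dense_fw(KV_in, p$Wv, p$bv)
  core <- attention_core_fw(q$out, k$out, v$out, key_mask, B, Lq, Lk,
                            n_heads, head_dim, mode, window)
  o <- dense_fw(core$out, p$Wo, p$bo)
  list(out = o$out,
       cache = list(q = q$cache, k = k$cache, v = v$cache,
                    core = core$cache, o = o$cache))
}

attention_bw <- function(dY, cache) {
  ob <- dense_bw(dY, cache$o)
  cb <- attention_core_bw(ob$dX, cache$core)
  qb <- dense_bw(cb$dQp, cache$q)
  kb <- dense_bw(cb$dKp, cache$k)
  vb <- dense_bw(cb$dVp, cache$v)
  list(dQ_in = qb$dX, dKV_in = kb$dX + vb$dX,
       grads = list(Wq = qb$dW, bq = qb$db, Wk = kb$dW, bk = kb$db,
                    Wv = vb$dW, bv = vb$db, Wo = ob$dW, bo = ob$db))
}
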