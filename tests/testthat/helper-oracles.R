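# Brute-force reference implementations, coded independently of the package's
# batched/vectorized paths: scalar loops, one example at a time, no layout
# tricks. Used to pin down the numerical semantics of every layer.

o_layer_norm <- function(X, g, b, eps = 1e-5) {
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    mu <- mean(x)
    sd_ <- sqrt(mean((x - mu)^2) + eps)
    out[i, ] <- g * (x - mu) / sd_ + b
  }
  out
}

o_gelu <- function(x) x * pnorm(x)

# SGU for one example: Z is L x f. Explicit elementwise arithmetic.
o_sgu <- function(Z, W, b, ln_g, ln_b, mask, use_norm = TRUE) {
  L <- nrow(Z)
  h <- ncol(Z) / 2
  z1 <- Z[, 1:h, drop = FALSE]
  z2 <- Z[, (h + 1):(2 * h), drop = FALSE]
  if (use_norm) z2 <- o_layer_norm(z2, ln_g, ln_b)
  z2[!mask, ] <- 0
  out <- matrix(0, L, h)
  for (l in seq_len(L)) {
    for (c in seq_len(h)) {
      gate <- b[l]
      for (t in seq_len(L)) gate <- gate + W[l, t] * z2[t, c]
      out[l, c] <- z1[l, c] * gate
    }
  }
  out
}

# one gMLP block for one example, composed from the scalar oracles
o_gmlp_block <- function(X, p, mask, use_norm = TRUE) {
  Xn <- o_layer_norm(X, p$ln_g, p$ln_b)
  Z <- Xn %*% p$U
  for (i in seq_len(nrow(Z))) Z[i, ] <- Z[i, ] + p$bu
  Z <- o_gelu(Z)
  S <- o_sgu(Z, p$sgu$W, p$sgu$b, p$sgu$ln_g, p$sgu$ln_b, mask, use_norm)
  Y <- S %*% p$V
  for (i in seq_len(nrow(Y))) Y[i, ] <- Y[i, ] + p$bv
  X + Y
}

# multi-head / local attention for one example: explicit softmax per query
# (and per window in local mode), summing window outputs.
o_attention <- function(Q, K, V, p, n_heads, head_dim, key_mask,
                        mode = "global", window = 2L) {
  addb <- function(M, b) {
    for (i in seq_len(nrow(M))) M[i, ] <- M[i, ] + b
    M
  }
  Qp <- addb(Q %*% p$Wq, p$bq)
  Kp <- addb(K %*% p$Wk, p$bk)
  Vp <- addb(V %*% p$Wv, p$bv)
  Lq <- nrow(Q)
  Lk <- nrow(K)
  O <- matrix(0, Lq, n_heads * head_dim)
  wins <- if (mode == "global") list(seq_len(Lk)) else
    split(seq_len(Lk), ceiling(seq_len(Lk) / window))
  for (hh in seq_len(n_heads)) {
    cols <- (hh - 1) * head_dim + seq_len(head_dim)
    for (i in seq_len(Lq)) {
      acc <- numeric(head_dim)
      for (win in wins) {
        keys <- win[key_mask[win]]
        if (!length(keys)) next
        s <- vapply(keys, function(j) {
          sum(Qp[i, cols] * Kp[j, cols]) / sqrt(head_dim)
        }, numeric(1))
        w <- exp(s - max(s))
        w <- w / sum(w)
        for (jj in seq_along(keys)) {
          acc <- acc + w[jj] * Vp[keys[jj], cols]
        }
      }
      O[i, cols] <- acc
    }
  }
  addb(O %*% p$Wo, p$bo)
}

# pair-counting AUC: P(score_pos > score_neg) + 0.5 P(tie)
o_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Gotoh global alignment with affine gaps (open + len * extend), BLOSUM50.
# Returns the optimal score and the identity (matches / alignment length) of
# one optimal alignment recovered by traceback.
o_align_identity <- function(a, b, open = 10, extend = 1) {
  sm <- load_blosum50()
  ai <- strsplit(a, "")[[1]]
  bi <- strsplit(b, "")[[1]]
  n <- length(ai)
  m <- length(bi)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 1) * extend
  for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 1) * extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sm$scores[ai[i - 1], bi[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
    }
  }
  score <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  # traceback one optimal path
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  matches <- 0L; cols <- 0L
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (state == 1) {
      s <- sm$scores[ai[i - 1], bi[j - 1]]
      matches <- matches + (ai[i - 1] == bi[j - 1])
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      if (isTRUE(all.equal(Ix[i, j], M[i - 1, j] - open - extend))) state <- 1
      i <- i - 1
    } else {
      if (isTRUE(all.equal(Iy[i, j], M[i, j - 1] - open - extend))) state <- 1
      j <- j - 1
    }
  }
  list(score = score, identity = matches / cols)
}

# normalized BLOSUM50 odds k-mer kernel by exhaustive double loop
o_kernel <- function(a, b, k = 3) {
  sm <- load_blosum50()
  odds <- 2^(sm$scores / 2)
  raw <- function(x, y) {
    xs <- strsplit(x, "")[[1]]
    ys <- strsplit(y, "")[[1]]
    tot <- 0
    for (u in seq_len(length(xs) - k + 1)) {
      for (v in seq_len(length(ys) - k + 1)) {
        term <- 1
        for (i in 0:(k - 1)) term <- term * odds[xs[u + i], ys[v + i]]
        tot <- tot + term
      }
    }
    tot
  }
  raw(a, b) / sqrt(raw(a, a) * raw(b, b))
}

# transitive closure of an adjacency matrix by repeated boolean products
o_closure_clusters <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  ids <- integer(n)
  nextid <- 0L
  for (i in seq_len(n)) {
    if (ids[i] == 0L) {
      nextid <- nextid + 1L
      ids[reach[i, ]] <- nextid
    }
  }
  ids
}
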