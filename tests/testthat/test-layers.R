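# Unit checks of the layer primitives against naive computations; the larger
# randomized oracle sweeps live in the acceptance suite.

ns <- asNamespace("tcrgmlp")

test_that("layer norm and GELU match their scalar definitions", {
  set.seed(11)
  X <- matrix(rnorm(60), 10, 6)
  g <- runif(6, 0.5, 1.5)
  b <- rnorm(6)
  expect_equal(ns$layer_norm_fw(X, g, b)$out, o_layer_norm(X, g, b),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ns$gelu_fw(X)$out, o_gelu(X), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("SGU gates exactly z1 at the identity initialization (W = 0, b = 1)", {
  set.seed(3)
  L <- 5L; f <- 8L; B <- 2L
  Z <- matrix(rnorm(B * L * f), B * L, f)
  p <- list(W = matrix(0, L, L), b = rep(1, L),
            ln_g = rep(1, f / 2), ln_b = rep(0, f / 2))
  out <- ns$sgu_fw(Z, p, rep(TRUE, B * L), L, use_norm = TRUE)$out
  expect_identical(out, Z[, 1:(f / 2)])
  # zero input stays zero regardless of gate
  p$W <- matrix(rnorm(L * L), L, L)
  expect_identical(ns$sgu_fw(Z * 0, p, rep(TRUE, B * L), L, TRUE)$out,
                   matrix(0, B * L, f / 2))
})

test_that("attention weight rows are normalized and respect masks", {
  set.seed(5)
  B <- 3L; Lq <- 2L; Lk <- 6L; hd <- 4L
  Qp <- matrix(rnorm(B * Lq * hd), B * Lq, hd)
  Kp <- matrix(rnorm(B * Lk * hd), B * Lk, hd)
  Vp <- matrix(rnorm(B * Lk * hd), B * Lk, hd)
  km <- matrix(TRUE, B, Lk)
  km[2, 4:6] <- FALSE
  fw <- ns$attention_core_fw(Qp, Kp, Vp, km, B, Lq, Lk, 1L, hd, "global")
  A <- fw$cache$heads[[1]]$A
  expect_equal(rowSums(A), rep(1, B * Lq), tolerance = 1e-6)
  expect_true(all(A[3:4, 4:6] == 0))  # masked keys of example 2
  # local block softmax: each fully unmasked window sums to 1
  fl <- ns$attention_core_fw(Qp, Kp, Vp, km, B, Lq, Lk, 1L, hd, "local", 2L)
  Al <- fl$cache$heads[[1]]$A
  expect_equal(rowSums(Al[1:2, 1:2, drop = FALSE]), rep(1, 2), tolerance = 1e-6)
  expect_equal(rowSums(Al[1:2, 3:4, drop = FALSE]), rep(1, 2), tolerance = 1e-6)
  # fully masked window contributes nothing
  expect_true(all(Al[3:4, 5:6] == 0))
  # all keys masked is degenerate
  km2 <- km; km2[1, ] <- FALSE
  expect_error(ns$attention_core_fw(Qp, Kp, Vp, km2, B, Lq, Lk, 1L, hd,
                                    "global"),
               "degenerate")
})

test_that("singleton and duplicated keys give the closed-form weights", {
  set.seed(6)
  d <- 4L
  p <- c(ns$init_attention(model_config(d_model = d, head_dim = d,
                                        n_heads = 1L, d_ffn = 8L)))
  Q <- matrix(rnorm(2 * d), 2, d)
  K1 <- matrix(rnorm(d), 1, d)
  V1 <- matrix(rnorm(d), 1, d)
  # one key: softmax weight is 1 regardless of the query, so the output is
  # just the projected value of that key
  out <- ns$attention_fw(Q, V1, p, matrix(TRUE, 1, 1), 1L, 2L, 1L, 1L, d,
                         "global")$out
  expected <- matrix(rep((V1 %*% p$Wv + p$bv) %*% p$Wo + p$bo, 2),
                     2, d, byrow = TRUE)
  expect_equal(out, expected, tolerance = 1e-10, ignore_attr = TRUE)
  # two identical keys: both weights 0.5
  K2 <- rbind(K1, K1)
  V2 <- rbind(V1, V1)
  fw <- ns$attention_core_fw(Q %*% p$Wq, K2 %*% p$Wk, V2 %*% p$Wv,
                             matrix(TRUE, 1, 2), 1L, 2L, 2L, 1L, d, "global")
  expect_equal(unname(fw$cache$heads[[1]]$A),
               matrix(0.5, 2, 2), tolerance = 1e-10)
})

test_that("local attention with identical chain tokens superimposes identical windows", {
  set.seed(8)
  d <- 4L
  cfgp <- ns$init_attention(model_config(d_model = d, head_dim = d,
                                         n_heads = 1L, d_ffn = 8L))
  Lk <- 4L; win <- 2L
  Q <- matrix(rnorm(3 * d), 3, d)
  token <- rnorm(d)
  K <- matrix(rep(token, Lk), Lk, d, byrow = TRUE)
  # core output with n windows of identical keys = n * single-window output
  full <- ns$attention_core_fw(Q %*% cfgp$Wq, K %*% cfgp$Wk, K %*% cfgp$Wv,
                               matrix(TRUE, 1, Lk), 1L, 3L, Lk, 1L, d,
                               "local", win)$out
  single <- ns$attention_core_fw(Q %*% cfgp$Wq,
                                 K[1:win, ] %*% cfgp$Wk, K[1:win, ] %*% cfgp$Wv,
                                 matrix(TRUE, 1, win), 1L, 3L, win, 1L, d,
                                 "local", win)$out
  expect_equal(full, (Lk / win) * single, tolerance = 1e-10)
})

test_that("analytic model gradient matches directional finite differences", {
  cfg <- tiny_cfg()
  rec <- tiny_records(4, seed = 21)
  mb <- ns$encode_records_batch(rec, cfg)
  # soften the raw substitution-score input scale so the loss surface is
  # smooth enough for finite differences at t = 1e-6
  for (s in c("alpha", "beta", "pep")) mb[[s]]$x <- mb[[s]]$x * 0.05
  params <- init_params(cfg, 9)
  skel <- params
  theta <- ns$flatten_params(params)
  y <- rec$label
  lossfn <- function(th) {
    p <- ns$unflatten_params(th, skel)
    binary_cross_entropy(ns$model_forward_batch(mb, p, cfg)$prob, y)
  }
  fw <- ns$model_forward_batch(mb, params, cfg)
  g <- ns$flatten_params(ns$model_backward_batch((fw$prob - y) / length(y),
                                                 fw$cache, params, cfg))
  set.seed(31)
  for (r in 1:5) {
    v <- rnorm(length(theta))
    v <- v / sqrt(sum(v^2))
    t <- 1e-6
    num <- (lossfn(theta + t * v) - lossfn(theta - t * v)) / (2 * t)
    ana <- sum(g * v)
    expect_equal(num, ana, tolerance = 5e-3)
  }
})
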