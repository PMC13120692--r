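# Transformer components: projections, masks, encoder/decoder properties,
# the prediction head, full-forward contracts and the gradient engine.

tiny_cfg <- function(...) {
  transformer_config(d = 16, n_heads = 2, n_enc = 1, n_dec = 1,
                     d_ff = 24, d_head = 12, ...)
}

rand_inputs <- function(L = 7, Tn = 5, d_seq = 6, d_go = 4, seed = 1) {
  set.seed(seed)
  list(X = matrix(rnorm(L * d_seq), L, d_seq),
       E = matrix(rnorm(Tn * d_go), Tn, d_go))
}

test_that("project_residues is the affine projection", {
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(project_residues(X, diag(3), rep(0, 3)), X)
  b <- c(1, -2, 0.5)
  Z <- project_residues(matrix(0, 2, 3), diag(3), b)
  expect_equal(Z, rbind(b, b), ignore_attr = TRUE)
  set.seed(4)
  W <- matrix(rnorm(3 * 5), 3, 5)
  bb <- rnorm(5)
  out <- project_residues(X, W, bb)
  manual <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5) manual[i, j] <- sum(X[i, ] * W[, j]) + bb[j]
  expect_equal(out, manual)
  expect_error(project_residues(X, matrix(0, 4, 5), rep(0, 5)), "match")
})

test_that("causal mask is lower-triangular with the diagonal", {
  M <- build_causal_mask(3)
  allowed <- which(M, arr.ind = TRUE)
  expect_setequal(paste(allowed[, 1], allowed[, 2]),
                  c("1 1", "2 1", "2 2", "3 1", "3 2", "3 3"))
  expect_equal(build_causal_mask(1), matrix(TRUE, 1, 1), ignore_attr = TRUE)
  expect_equal(rowSums(build_causal_mask(6)), 1:6)
})

test_that("encoder respects padding and permutation equivariance", {
  cfg <- tiny_cfg()
  inp <- rand_inputs(L = 9, seed = 11)
  params <- init_transformer(6, 4, cfg, seed = 2)
  H0 <- project_residues(inp$X, params$W_seq, params$b_seq)
  out <- encode_protein(H0, params, cfg)$out
  expect_equal(dim(out), c(9, 16))

  # appending masked rows leaves unmasked outputs unchanged
  H0pad <- rbind(H0, matrix(5, 3, 16))
  keep <- c(rep(TRUE, 9), rep(FALSE, 3))
  outpad <- encode_protein(H0pad, params, cfg, key_keep = keep)$out
  expect_equal(outpad[1:9, ], out, tolerance = 1e-5)
  expect_error(encode_protein(H0, params, cfg,
                              key_keep = rep(FALSE, 9)), "masked")

  # no positional encoding: permuting residues permutes outputs
  perm <- c(3, 1, 2, 9, 5, 6, 7, 8, 4)
  outperm <- encode_protein(H0[perm, ], params, cfg)$out
  expect_equal(outperm, out[perm, ], tolerance = 1e-8)
})

test_that("decoder causality: later latents cannot affect earlier ranks", {
  cfg <- tiny_cfg()
  for (seed in 1:20) {
    inp <- rand_inputs(L = 8, Tn = 6, seed = seed)
    params <- init_transformer(6, 4, cfg, seed = seed)
    fwd <- hg_forward(inp$X, inp$E, params, cfg)
    k <- sample(2:6, 1)
    E2 <- inp$E
    E2[k:6, ] <- E2[k:6, ] + matrix(rnorm(length(E2[k:6, ]), sd = 2),
                                    nrow = 7 - k)
    fwd2 <- hg_forward(inp$X, E2, params, cfg)
    expect_lt(max(abs(fwd$probs[1:(k - 1)] - fwd2$probs[1:(k - 1)])), 1e-5)
    # and the perturbation genuinely changes later outputs
    expect_gt(max(abs(fwd$probs[k:6] - fwd2$probs[k:6])), 0)
  }
})

test_that("attention rows are distributions over unmasked keys", {
  cfg <- tiny_cfg()
  inp <- rand_inputs(L = 10, Tn = 5, seed = 3)
  params <- init_transformer(6, 4, cfg, seed = 3)
  keep <- c(rep(TRUE, 7), rep(FALSE, 3))
  fwd <- hg_forward(inp$X, inp$E, params, cfg, key_keep = keep)
  for (l in seq_along(fwd$attn)) {
    for (A in fwd$attn[[l]]) {
      expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)
      expect_true(all(A[, 8:10] == 0))
      expect_true(all(A >= 0))
    }
  }
})

test_that("prediction head composes gelu and sigmoid", {
  params <- list(head = list(W1 = matrix(0, 4, 3), b1 = rep(0, 3),
                             W2 = matrix(0, 3, 1), b2 = 0))
  out <- predict_head(matrix(rnorm(8), 2, 4), params)
  expect_equal(out$probs, rep(0.5, 2))

  set.seed(8)
  p2 <- list(head = list(W1 = matrix(rnorm(2 * 3), 2, 3), b1 = rnorm(3),
                         W2 = matrix(rnorm(3), 3, 1), b2 = 0.3))
  h <- matrix(rnorm(4), 2, 2)
  out2 <- predict_head(h, p2)
  gelu_ref <- function(x) x * pnorm(x)
  manual <- vapply(1:2, function(i) {
    u <- drop(h[i, ] %*% p2$head$W1) + p2$head$b1
    1 / (1 + exp(-(sum(gelu_ref(u) * p2$head$W2) + p2$head$b2)))
  }, 0)
  expect_equal(out2$probs, manual, tolerance = 1e-12)
  expect_true(all(out2$probs > 0 & out2$probs < 1))
})

test_that("full forward has the right shapes and is deterministic", {
  cfg <- transformer_config(d = 32, n_heads = 4, n_enc = 2, n_dec = 2,
                            d_ff = 48)
  inp <- rand_inputs(L = 50, Tn = 20, d_seq = 64, d_go = 12, seed = 5)
  params <- init_transformer(64, 12, cfg, seed = 5)
  fwd <- hg_forward(inp$X, inp$E, params, cfg)
  expect_length(fwd$probs, 20)
  expect_length(fwd$attn, 2)
  expect_length(fwd$attn[[1]], 4)
  expect_equal(dim(fwd$attn[[1]][[1]]), c(20, 50))
  fwd2 <- hg_forward(inp$X, inp$E, params, cfg)
  expect_identical(fwd$probs, fwd2$probs)
})

test_that("analytic gradients match finite differences everywhere", {
  cfg <- tiny_cfg()
  inp <- rand_inputs(L = 5, Tn = 4, seed = 13)
  params <- init_transformer(6, 4, cfg, seed = 13)
  y <- c(1, 0, 0, 1)
  loss_fn <- function(p) {
    bce_objective(hg_forward(inp$X, inp$E, p, cfg)$probs, y)
  }
  fwd <- hg_forward(inp$X, inp$E, params, cfg, want_grad = TRUE)
  g <- hg_backward((fwd$probs - y) / 4, fwd, params, cfg)

  flatten <- function(tree) unlist(tree, use.names = TRUE)
  gf <- flatten(g)
  pf <- flatten(params)
  set.seed(99)
  probes <- sample(length(pf), 40)
  eps <- 1e-5
  num <- vapply(probes, function(i) {
    pp <- pf
    pp[i] <- pp[i] + eps
    up <- loss_fn(utils::relist(pp, unclass(params)))
    pp[i] <- pp[i] - 2 * eps
    dn <- loss_fn(utils::relist(pp, unclass(params)))
    (up - dn) / (2 * eps)
  }, 0)
  expect_equal(unname(gf[probes]), num, tolerance = 1e-6)
})

test_that("ablation architectures run with matching contracts", {
  inp <- rand_inputs(L = 12, Tn = 6, seed = 21)

  cfg_enc <- tiny_cfg(architecture = "encoder")
  p_enc <- init_transformer(6, 4, cfg_enc, seed = 21)
  fwd_enc <- hg_forward(inp$X, inp$E, p_enc, cfg_enc)
  expect_length(fwd_enc$probs, 6)
  # bidirectional: early outputs DO depend on later latents
  E2 <- inp$E
  E2[6, ] <- E2[6, ] + 3
  fwd_enc2 <- hg_forward(inp$X, E2, p_enc, cfg_enc)
  expect_gt(max(abs(fwd_enc$probs[1:5] - fwd_enc2$probs[1:5])), 1e-6)

  cfg_mlp <- tiny_cfg(architecture = "mlp")
  p_mlp <- init_transformer(6, 4, cfg_mlp, seed = 21)
  fwd_mlp <- hg_forward(inp$X, inp$E, p_mlp, cfg_mlp)
  expect_length(fwd_mlp$probs, 6)
  expect_null(fwd_mlp$attn)
  # closed-form check of the mlp path on a single term
  pbar <- drop(colMeans(inp$X) %*% p_mlp$W_seq) + p_mlp$b_seq
  g1 <- drop(inp$E[1, ] %*% p_mlp$W_go) + p_mlp$b_go
  u <- drop(c(pbar, g1) %*% p_mlp$head$W1) + p_mlp$head$b1
  gelu_ref <- function(x) x * pnorm(x)
  z <- sum(gelu_ref(u) * p_mlp$head$W2) + p_mlp$head$b2
  expect_equal(fwd_mlp$probs[1], 1 / (1 + exp(-z)), tolerance = 1e-10)

  # mlp gradients also pass a spot finite-difference check
  y <- c(1, 0, 1, 0, 0, 1)
  fwd <- hg_forward(inp$X, inp$E, p_mlp, cfg_mlp, want_grad = TRUE)
  g <- hg_backward((fwd$probs - y) / 6, fwd, p_mlp, cfg_mlp)
  eps <- 1e-5
  for (probe in c(1, 17, 40)) {
    pp <- unlist(unclass(p_mlp))
    pp[probe] <- pp[probe] + eps
    up <- bce_objective(hg_forward(inp$X, inp$E,
                                   utils::relist(pp, unclass(p_mlp)),
                                   cfg_mlp)$probs, y)
    pp[probe] <- pp[probe] - 2 * eps
    dn <- bce_objective(hg_forward(inp$X, inp$E,
                                   utils::relist(pp, unclass(p_mlp)),
                                   cfg_mlp)$probs, y)
    expect_equal(unname(unlist(g)[probe]), (up - dn) / (2 * eps),
                 tolerance = 1e-5)
  }
})
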