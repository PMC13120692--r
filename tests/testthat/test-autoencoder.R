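# Linear projection encoder, recovery heads, the weighted loss, training
# behaviour and the zero-shot embedding path.

tiny_ae_graph <- function(n = 12, seed = 55) parse_obo(rand_dag_obo(n, seed))

test_that("encode_term is the bare linear projection", {
  p <- list(W_emb = diag(4), d_t = 4L, d_z = 4L)
  x <- c(0.5, -1, 2, 0)
  expect_equal(encode_term(x, p), x)
  expect_equal(encode_term(rep(0, 4), p), rep(0, 4))

  set.seed(2)
  W <- matrix(rnorm(3 * 5), 3, 5)
  p2 <- list(W_emb = W, d_t = 5L, d_z = 3L)
  x2 <- rnorm(5)
  manual <- vapply(1:3, function(i) sum(W[i, ] * x2), 0)
  expect_equal(encode_term(x2, p2), manual)
  expect_error(encode_term(rnorm(4), p2), "length")
})

test_that("decode_heads produces normalized probabilities", {
  n <- 6
  p <- list(d_z = 3L,
            W_anc = matrix(0, n, 3), b_anc = rep(0, n),
            W_sub = matrix(0, 3, 3), b_sub = rep(0, 3),
            W_id = matrix(0, n, 3), b_id = rep(0, n))
  out <- decode_heads(rep(0, 3), p)
  expect_equal(out$y_anc, rep(1 / n, n))
  expect_equal(out$y_sub, rep(1 / 3, 3))

  set.seed(3)
  p$W_anc <- matrix(rnorm(n * 3), n, 3)
  p$b_anc <- rnorm(n)
  out2 <- decode_heads(rnorm(3), p)
  expect_equal(sum(out2$y_anc), 1, tolerance = 1e-6)
  expect_equal(sum(out2$y_sub), 1, tolerance = 1e-6)
  expect_equal(sum(out2$y_id), 1, tolerance = 1e-6)

  # saturating logit drives that entry to 1
  p$b_anc <- c(50, rep(0, n - 1))
  p$W_anc <- matrix(0, n, 3)
  out3 <- decode_heads(rnorm(3), p)
  expect_equal(out3$y_anc[1], 1, tolerance = 1e-12)
})

test_that("autoencoder_loss matches closed forms and weighting", {
  n <- 4
  targets <- list(y_anc = c(1, 1, 0, 0), y_sub = c(1, 0, 0),
                  y_id = c(0, 1, 0, 0))
  perfect <- list(y_anc = c(1, 1, 0, 0), y_sub = c(1, 0, 0),
                  y_id = c(0, 1, 0, 0))
  expect_equal(autoencoder_loss(perfect, targets), 0, tolerance = 1e-9)

  uniform <- list(y_anc = rep(1 / n, n), y_sub = rep(1 / 3, 3),
                  y_id = rep(1 / n, n))
  single <- list(y_anc = c(0, 1, 0, 0), y_sub = c(1, 0, 0),
                 y_id = c(0, 1, 0, 0))
  # single positive per head under uniform predictions: log N per head
  l <- autoencoder_loss(list(y_anc = uniform$y_anc, y_sub = uniform$y_sub,
                             y_id = uniform$y_id),
                        single)
  expect_equal(l, log(n) + log(3) + log(n), tolerance = 1e-9)

  # alpha_anc = 2 doubles only the ancestor contribution (hand-summed)
  preds <- list(y_anc = c(0.5, 0.3, 0.1, 0.1), y_sub = c(0.6, 0.3, 0.1),
                y_id = c(0.1, 0.7, 0.1, 0.1))
  base_anc <- -(log(0.5) + log(0.3))
  base_sub <- -log(0.6)
  base_id <- -log(0.7)
  expect_equal(autoencoder_loss(preds, targets, loss_weights(2, 1, 1)),
               2 * base_anc + base_sub + base_id, tolerance = 1e-9)
  expect_error(loss_weights(0, 0, 0), "not all zero")
})

test_that("fitting reduces loss, is seed-deterministic, keeps inputs frozen", {
  g <- tiny_ae_graph(10, 56)
  X <- embed_definitions(g, text_encoder_spec(dim = 24, seed = 8))
  sum_before <- object_checksum(unclass(X))
  fit1 <- fit_autoencoder(X, g, d_z = 8, epochs = 120, lr = 1e-2, seed = 5)
  expect_lt(tail(fit1$loss_trace, 1), fit1$loss_trace[1])
  expect_identical(object_checksum(unclass(X)), sum_before)

  fit2 <- fit_autoencoder(X, g, d_z = 8, epochs = 120, lr = 1e-2, seed = 5)
  expect_identical(object_checksum(fit1$W_emb), object_checksum(fit2$W_emb))

  # overfit sanity: tiny ontology driven far below its initial loss.
  # The softmax ancestor head has a positive loss floor (k log k at k
  # positive targets), so near-zero loss is only reachable in the sigmoid
  # multi-label mode.
  fit3 <- fit_autoencoder(X, g, d_z = 8, epochs = 2000, lr = 1e-2, seed = 5,
                          anc_mode = "sigmoid")
  expect_lt(tail(fit3$loss_trace, 1), 0.01 * fit3$loss_trace[1])
})

test_that("autoencoder head gradients agree with finite differences", {
  g <- tiny_ae_graph(8, 57)
  X <- embed_definitions(g, text_encoder_spec(dim = 12, seed = 2))
  # one Adam step from a fixed init must move in the descent direction:
  # compare losses of a 2-epoch vs 1-epoch fit from identical seeds
  f1 <- fit_autoencoder(X, g, d_z = 6, epochs = 1, lr = 1e-3, seed = 9)
  f5 <- fit_autoencoder(X, g, d_z = 6, epochs = 60, lr = 1e-2, seed = 9)
  expect_identical(f1$loss_trace[1], f5$loss_trace[1])
  expect_lt(tail(f5$loss_trace, 1), f1$loss_trace[1])

  # finite-difference check of the full-batch gradient at initialization
  tg <- ae_targets(g)
  ids <- tg$term_ids
  Xm <- unclass(X)[ids, , drop = FALSE]
  n <- length(ids)
  params <- hiergo:::init_ae_params(ncol(Xm), 5L, n, seed = 4)
  loss_at <- function(params) {
    Z <- Xm %*% t(params$W_emb)
    soft <- function(O) {
      E <- exp(O - apply(O, 1, max))
      E / rowSums(E)
    }
    preds <- list(
      y_anc = soft(Z %*% t(params$W_anc) + rep(1, n) %o% params$b_anc),
      y_sub = soft(Z %*% t(params$W_sub) + rep(1, n) %o% params$b_sub),
      y_id = soft(Z %*% t(params$W_id) + rep(1, n) %o% params$b_id))
    autoencoder_loss(preds, list(y_anc = tg$Y_anc, y_sub = tg$Y_sub,
                                 y_id = tg$Y_id)) / n
  }
  # analytic gradient, recomputed the way fit_autoencoder does internally
  Z <- Xm %*% t(params$W_emb)
  soft <- function(O) {
    E <- exp(O - apply(O, 1, max))
    E / rowSums(E)
  }
  P_anc <- soft(Z %*% t(params$W_anc) + rep(1, n) %o% params$b_anc)
  dO_anc <- (rowSums(tg$Y_anc) * P_anc - tg$Y_anc) / n
  gW_anc <- t(dO_anc) %*% Z
  eps <- 1e-6
  for (probe in list(c(1, 1), c(2, 3), c(5, 2))) {
    pp <- params
    pp$W_anc[probe[1], probe[2]] <- pp$W_anc[probe[1], probe[2]] + eps
    up <- loss_at(pp)
    pp$W_anc[probe[1], probe[2]] <- pp$W_anc[probe[1], probe[2]] - 2 * eps
    dn <- loss_at(pp)
    expect_equal(gW_anc[probe[1], probe[2]], (up - dn) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("latents preserve semantic proximity of definitions", {
  cfg <- synthetic_config(terms_per_aspect = 15, n_proteins = 1, seed = 77)
  g <- generate_ontology(cfg)
  X <- embed_definitions(g, text_encoder_spec(dim = 48, seed = 3))
  fit <- fit_autoencoder(X, g, d_z = 12, epochs = 120, lr = 5e-3, seed = 2)
  cosm <- function(M) {
    Mn <- M / sqrt(rowSums(M^2))
    tcrossprod(Mn)
  }
  ct <- cosm(unclass(X)[fit$term_ids, ])
  cz <- cosm(fit$latents[fit$term_ids, ])
  up <- upper.tri(ct)
  # definition pairs in the top decile of text cosine stay closer in the
  # latent space than the median latent pair
  top <- up & ct >= stats::quantile(ct[up], 0.9)
  expect_gt(mean(cz[top]), stats::median(cz[up]))
})

test_that("unseen terms embed through the frozen projection", {
  cfg <- synthetic_config(terms_per_aspect = 12, n_proteins = 1, seed = 58)
  g <- generate_ontology(cfg)
  enc <- text_encoder_spec(dim = 48, seed = 8)
  X <- embed_definitions(g, enc)
  fit <- fit_autoencoder(X, g, d_z = 16, epochs = 50, seed = 5)
  sum_before <- object_checksum(fit$W_emb)

  # a novel term sharing a training definition lands on the same latent
  train_id <- fit$term_ids[3]
  def <- g$definitions[[train_id]]
  z <- embed_unseen_term(def, enc, fit)
  expect_equal(z, unname(fit$latents[train_id, ]), tolerance = 1e-12)
  expect_identical(object_checksum(fit$W_emb), sum_before)
  expect_error(embed_unseen_term("", enc, fit), "empty")

  # a blend of two training definitions lands cosine-closer to those two
  # terms than to at least 90% of the others
  leaves <- setdiff(fit$term_ids, unlist(g$parents))
  id_a <- leaves[1]
  id_b <- leaves[length(leaves)]
  blend <- paste(g$definitions[[id_a]], g$definitions[[id_b]])
  zb <- embed_unseen_term(blend, enc, fit)
  cos <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  sims <- vapply(fit$term_ids, function(t) cos(zb, fit$latents[t, ]), 0)
  expect_true(all(rank(-sims)[c(id_a, id_b)] <=
                    ceiling(0.1 * length(sims)) + 2))
})
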