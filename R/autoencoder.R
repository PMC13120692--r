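# Structure-recovering GO term autoencoder.
#
# A single linear projection z_t = W_emb x_t maps frozen definition-text
# embeddings into a latent space; three linear-softmax heads are trained to
# recover each term's ancestor set, its subontology and its identity. The
# weighted positive-class cross-entropy makes the latent space carry both
# the text semantics (inherited from x_t) and the DAG structure (forced by
# the recovery heads). Because the encoder needs only definition text at
# inference, novel terms embed without retraining: that is the zero-shot
# path.

#' Build autoencoder supervision targets from an ontology
#'
#' @param graph A `go_graph`.
#' @param index An [ancestor_index()]; by convention self-inclusive
#'   (`include_self = TRUE`), so every term is its own ancestor and the
#'   ancestor target of the root is non-empty.
#' @return List with `term_ids` (id-sorted), `Y_anc` (terms x terms binary),
#'   `Y_sub` (terms x 3 one-hot over MF/BP/CC) and `Y_id` (identity).
#' @export
ae_targets <- function(graph, index = ancestor_index(graph, include_self = TRUE)) {
  ids <- index$term_ids
  n <- length(ids)
  Y_anc <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    Y_anc[i, index$ancestors[[ids[i]]]] <- 1
  }
  aspects <- graph$terms$aspect[match(ids, graph$terms$id)]
  Y_sub <- matrix(0, n, 3, dimnames = list(ids, c("MF", "BP", "CC")))
  Y_sub[cbind(seq_len(n), match(aspects, colnames(Y_sub)))] <- 1
  Y_id <- diag(n)
  dimnames(Y_id) <- list(ids, ids)
  list(term_ids = ids, Y_anc = Y_anc, Y_sub = Y_sub, Y_id = Y_id)
}

#' Encode one text embedding into the GO latent space
#'
#' The encoder is a pure linear projection (no bias, no nonlinearity).
#'
#' @param x_t Numeric vector of length `d_t`.
#' @param params Trained [fit_autoencoder()] parameters.
#' @return Latent vector of length `d_z`.
#' @export
encode_term <- function(x_t, params) {
  if (length(x_t) != params$d_t) {
    stop_hiergo("text embedding has length ", length(x_t), ", expected ",
                params$d_t, class = "hiergo_validation_error")
  }
  drop(params$W_emb %*% x_t)
}

#' @noRd
row_softmax <- function(S) {
  # max.col is much faster than apply(S, 1, max) in the attention hot path
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

#' Run the three recovery heads on a latent vector
#'
#' Each head is `softmax(W z + b)` in the default mode, so each output is a
#' probability vector. The ancestor head has multiple positive targets; a
#' `multi_label` mode replaces its softmax with an element-wise sigmoid for
#' users who prefer a proper multi-label parameterization (training and the
#' retrieval metrics accept either).
#'
#' @param z_t Latent vector (length `d_z`).
#' @param params Autoencoder parameters.
#' @param anc_mode `"softmax"` (default) or `"sigmoid"`.
#' @return List `y_anc` (length `N_terms`), `y_sub` (length 3), `y_id`
#'   (length `N_terms`).
#' @export
decode_heads <- function(z_t, params, anc_mode = c("softmax", "sigmoid")) {
  anc_mode <- match.arg(anc_mode)
  if (length(z_t) != params$d_z) {
    stop_hiergo("latent has length ", length(z_t), ", expected ",
                params$d_z, class = "hiergo_validation_error")
  }
  z <- matrix(z_t, nrow = 1L)
  o_anc <- z %*% t(params$W_anc) + rep(1, 1) %o% params$b_anc
  o_sub <- z %*% t(params$W_sub) + rep(1, 1) %o% params$b_sub
  o_id  <- z %*% t(params$W_id)  + rep(1, 1) %o% params$b_id
  list(
    y_anc = drop(if (anc_mode == "softmax") row_softmax(o_anc)
                 else 1 / (1 + exp(-o_anc))),
    y_sub = drop(row_softmax(o_sub)),
    y_id = drop(row_softmax(o_id))
  )
}

#' Weighted multi-task recovery loss
#'
#' Positive-class cross-entropy summed over the three heads,
#' `-a_anc * sum(y_anc * log(p_anc)) - a_sub * sum(y_sub * log(p_sub))
#'  - a_id * sum(y_id * log(p_id))`, with log arguments clamped at `eps`.
#'
#' @param preds List with `y_anc`, `y_sub`, `y_id` probability vectors (or
#'   matrices for a batch of terms).
#' @param targets Matching binary targets (vectors or matrices).
#' @param weights List/vector with `anc`, `sub`, `id` non-negative weights.
#' @param eps Clamp for `log(0)`.
#' @return Non-negative scalar loss.
#' @export
autoencoder_loss <- function(preds, targets, weights = loss_weights(),
                             eps = 1e-12) {
  weights <- loss_weights(weights$anc %||% weights[[1]],
                          weights$sub %||% weights[[2]],
                          weights$id %||% weights[[3]])
  ce <- function(y, p) -sum(y * log(pmax(p, eps)))
  weights$anc * ce(targets$y_anc, preds$y_anc) +
    weights$sub * ce(targets$y_sub, preds$y_sub) +
    weights$id * ce(targets$y_id, preds$y_id)
}

#' Loss weights for the three recovery heads
#'
#' @param anc,sub,id Non-negative weights (defaults 1, 1, 1).
#' @return List of validated weights.
#' @export
loss_weights <- function(anc = 1, sub = 1, id = 1) {
  w <- list(anc = anc, sub = sub, id = id)
  if (any(unlist(w) < 0) || all(unlist(w) == 0)) {
    stop_hiergo("loss weights must be non-negative and not all zero",
                class = "hiergo_config_error")
  }
  w
}

#' @noRd
init_ae_params <- function(d_t, d_z, n_terms, seed) {
  with_seed(derive_seed(seed, 11L), {
    xav <- function(nr, nc) {
      matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
    }
    list(W_emb = xav(d_z, d_t),
         W_anc = xav(n_terms, d_z), b_anc = rep(0, n_terms),
         W_sub = xav(3L, d_z), b_sub = rep(0, 3L),
         W_id = xav(n_terms, d_z), b_id = rep(0, n_terms),
         d_t = d_t, d_z = d_z, n_terms = n_terms)
  })
}

#' Fit the GO term autoencoder
#'
#' Full-batch adaptive-moment gradient descent on the weighted recovery
#' loss over all non-obsolete terms. The input embedding matrix is frozen:
#' its checksum is verified unchanged after fitting.
#'
#' @param embeddings A `term_embedding` matrix (terms x `d_t`).
#' @param graph The `go_graph` the targets are built from.
#' @param d_z Latent dimension.
#' @param weights [loss_weights()].
#' @param epochs,lr Optimization schedule (full-batch steps, Adam).
#' @param anc_mode Ancestor head: `"softmax"` (as parameterized here) or
#'   `"sigmoid"` multi-label variant.
#' @param include_self Self-inclusive ancestor targets (default TRUE).
#' @param seed RNG seed for initialization.
#' @param eps Log clamp.
#' @return Object of class `go_autoencoder`: parameters plus `term_ids`,
#'   `latents` (terms x `d_z`), `loss_trace`, and the fitting config.
#' @export
fit_autoencoder <- function(embeddings, graph, d_z = 64L,
                            weights = loss_weights(), epochs = 200L,
                            lr = 1e-3, anc_mode = c("softmax", "sigmoid"),
                            include_self = TRUE, seed = 1L, eps = 1e-12) {
  anc_mode <- match.arg(anc_mode)
  stopifnot(inherits(embeddings, "term_embedding"))
  checksum_before <- object_checksum(unclass(embeddings))

  tg <- ae_targets(graph, ancestor_index(graph, include_self = include_self))
  ids <- tg$term_ids
  if (!all(ids %in% rownames(embeddings))) {
    stop_hiergo("embedding matrix missing rows for: ",
                paste(utils::head(setdiff(ids, rownames(embeddings)), 5),
                      collapse = ", "),
                class = "hiergo_validation_error")
  }
  X <- unclass(embeddings)[ids, , drop = FALSE]
  n <- length(ids)
  params <- init_ae_params(ncol(X), d_z, n, seed)
  opt <- adam_init(params[c("W_emb", "W_anc", "b_anc", "W_sub", "b_sub",
                            "W_id", "b_id")])
  w <- weights
  trace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    Z <- X %*% t(params$W_emb)                       # n x d_z
    O_anc <- Z %*% t(params$W_anc) + rep(1, n) %o% params$b_anc
    O_sub <- Z %*% t(params$W_sub) + rep(1, n) %o% params$b_sub
    O_id  <- Z %*% t(params$W_id)  + rep(1, n) %o% params$b_id
    P_sub <- row_softmax(O_sub)
    P_id <- row_softmax(O_id)
    P_anc <- if (anc_mode == "softmax") row_softmax(O_anc)
             else 1 / (1 + exp(-O_anc))

    loss <- autoencoder_loss(
      list(y_anc = P_anc, y_sub = P_sub, y_id = P_id),
      list(y_anc = tg$Y_anc, y_sub = tg$Y_sub, y_id = tg$Y_id),
      w, eps = eps) / n
    if (!is.finite(loss)) {
      stop_hiergo("autoencoder training diverged (non-finite loss at epoch ",
                  ep, ")", class = "hiergo_training_error")
    }
    trace[ep] <- loss

    # d(loss)/d(logits): softmax positive-class CE with k positives gives
    # k*p - y per row; sigmoid variant gives -y*(1-p).
    dO_anc <- if (anc_mode == "softmax") {
      (w$anc / n) * (rowSums(tg$Y_anc) * P_anc - tg$Y_anc)
    } else {
      (w$anc / n) * (-tg$Y_anc * (1 - P_anc))
    }
    dO_sub <- (w$sub / n) * (P_sub - tg$Y_sub)
    dO_id <- (w$id / n) * (P_id - tg$Y_id)

    grads <- list(
      W_anc = t(dO_anc) %*% Z, b_anc = colSums(dO_anc),
      W_sub = t(dO_sub) %*% Z, b_sub = colSums(dO_sub),
      W_id = t(dO_id) %*% Z, b_id = colSums(dO_id)
    )
    dZ <- dO_anc %*% params$W_anc + dO_sub %*% params$W_sub +
      dO_id %*% params$W_id
    grads$W_emb <- t(dZ) %*% X

    upd <- adam_step(opt, grads, lr)
    opt <- upd$state
    for (nm in names(upd$delta)) {
      params[[nm]] <- params[[nm]] + upd$delta[[nm]]
    }
  }

  if (!identical(checksum_before, object_checksum(unclass(embeddings)))) {
    stop_hiergo("frozen embedding matrix was mutated during fitting",
                class = "hiergo_training_error")
  }

  latents <- X %*% t(params$W_emb)
  rownames(latents) <- ids
  structure(
    c(params,
      list(term_ids = ids, latents = latents, loss_trace = trace,
           weights = w, anc_mode = anc_mode, include_self = include_self,
           seed = seed, input_checksum = checksum_before)),
    class = "go_autoencoder"
  )
}

#' @export
print.go_autoencoder <- function(x, ...) {
  cat("go_autoencoder:", x$n_terms, "terms, d_t =", x$d_t, ", d_z =", x$d_z,
      "\nfinal loss:", signif(utils::tail(x$loss_trace, 1), 4), "\n")
  invisible(x)
}

#' Latent embedding for a term unseen during training
#'
#' Encodes a novel definition with the frozen text encoder and projects it
#' through the trained `W_emb`. No parameter is updated, which is what makes
#' the model track ontology releases without retraining.
#'
#' @param definition Definition text of the novel term.
#' @param encoder The [text_encoder_spec()] the training matrix was built
#'   with.
#' @param params A fitted `go_autoencoder`.
#' @return Latent vector of length `d_z`.
#' @export
embed_unseen_term <- function(definition, encoder, params) {
  x <- encode_text(definition, encoder)
  encode_term(x, params)
}

#' Structure-recovery diagnostics of a fitted autoencoder
#'
#' Ancestor-retrieval AUC (per term, ranking all terms by the ancestor
#' head's score against the true ancestor set; averaged) and subontology
#' head accuracy.
#'
#' @param params A fitted `go_autoencoder`.
#' @param graph The training `go_graph`.
#' @return List with `anc_auc` and `sub_accuracy`.
#' @export
autoencoder_recovery <- function(params, graph) {
  tg <- ae_targets(graph,
                   ancestor_index(graph, include_self = params$include_self))
  Z <- params$latents[tg$term_ids, , drop = FALSE]
  n <- nrow(Z)
  O_anc <- Z %*% t(params$W_anc) + rep(1, n) %o% params$b_anc
  O_sub <- Z %*% t(params$W_sub) + rep(1, n) %o% params$b_sub
  aucs <- vapply(seq_len(n), function(i) {
    y <- tg$Y_anc[i, ]
    if (all(y == 1) || all(y == 0)) return(NA_real_)
    roc_auc(O_anc[i, ], y)
  }, 0)
  list(anc_auc = mean(aucs, na.rm = TRUE),
       sub_accuracy = mean(max.col(O_sub) == max.col(tg$Y_sub)))
}
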