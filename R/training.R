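# Supervised multi-label training of the transformer.
#
# One model per subontology; targets are true-path-propagated binary
# vectors over the aspect's terms in decoding order. The GO latents and the
# residue embeddings are frozen inputs (checksummed before and after
# fitting); only projections, transformer blocks and the prediction head
# are optimized, with adaptive-moment gradient descent and early stopping
# on validation BCE.

#' Binary cross-entropy over a prediction batch
#'
#' Mean over proteins and terms of `-(y log p + (1 - y) log(1 - p))`, with
#' probabilities clamped to `[eps, 1 - eps]`.
#'
#' @param predictions Numeric vector or matrix of probabilities in (0, 1).
#' @param targets Matching binary vector/matrix.
#' @param eps Clamp.
#' @return Non-negative scalar.
#' @export
bce_objective <- function(predictions, targets, eps = 1e-12) {
  if (any(is.na(predictions)) || any(is.na(targets))) {
    stop_hiergo("NaN in BCE inputs", class = "hiergo_training_error")
  }
  if (length(predictions) != length(targets)) {
    stop_hiergo("prediction/target shape mismatch",
                class = "hiergo_validation_error")
  }
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(targets * log(p) + (1 - targets) * log(1 - p))
}

#' Training configuration
#'
#' @param lr Learning rate (Adam).
#' @param epochs Maximum epochs.
#' @param batch_size Proteins per gradient step.
#' @param seed RNG seed controlling initialization and shuffling.
#' @param patience Early-stopping patience on validation BCE (epochs).
#' @param val_fraction Fraction of proteins held out for validation when no
#'   explicit validation set is given (0 disables early stopping).
#' @param verbose Print per-epoch losses.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-3, epochs = 30L, batch_size = 8L, seed = 1L,
                         patience = 10L, val_fraction = 0.1,
                         verbose = FALSE) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, patience >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), patience = as.integer(patience),
                 val_fraction = val_fraction, verbose = verbose),
            class = "train_config")
}

#' Train the encoder-decoder on annotated proteins
#'
#' @param proteins Named list of residue-embedding matrices (L x d_seq).
#' @param targets Binary protein x term matrix; rows named by protein,
#'   columns named by term id in decoding-rank order.
#' @param E Frozen GO latent matrix (rows = `colnames(targets)`, in the
#'   same order), or `NULL` to learn term embeddings from scratch (the
#'   "none" embedding ablation).
#' @param config A [transformer_config()].
#' @param tc A [train_config()].
#' @param val_proteins Optional character vector of protein ids used for
#'   validation (overrides `val_fraction`).
#' @param d_go Latent dimension when `E` is `NULL`.
#' @return Object of class `hiergo_model`: `params`, `config`, `term_ids`,
#'   `d_seq`, `d_go`, `trace` (per-epoch train/validation BCE), `seed`,
#'   `best_epoch`.
#' @export
train_model <- function(proteins, targets, E, config = transformer_config(),
                        tc = train_config(), val_proteins = NULL,
                        d_go = 32L) {
  if (length(proteins) == 0L) {
    stop_hiergo("empty training set", class = "hiergo_validation_error")
  }
  if (is.null(names(proteins)) || is.null(rownames(targets)) ||
      !setequal(names(proteins), rownames(targets))) {
    stop_hiergo("proteins and target rows must share names",
                class = "hiergo_validation_error")
  }
  term_ids <- colnames(targets)
  trainable_E <- is.null(E)
  if (!trainable_E) {
    if (!identical(rownames(E), term_ids)) {
      stop_hiergo("GO latent rows must equal target columns (in order)",
                  class = "hiergo_validation_error")
    }
    E <- as.matrix(E)
    d_go <- ncol(E)
    e_checksum <- object_checksum(E)
  }
  x_checksum <- object_checksum(proteins)
  d_seq <- ncol(proteins[[1]])

  params <- init_transformer(d_seq, d_go, config, seed = tc$seed,
                             n_terms = length(term_ids),
                             trainable_embeddings = trainable_E)
  opt <- adam_init(params)

  ids <- names(proteins)
  val_ids <- val_proteins %||% with_seed(derive_seed(tc$seed, 31L), {
    n_val <- floor(tc$val_fraction * length(ids))
    if (n_val > 0) sample(ids, n_val) else character()
  })
  train_ids <- setdiff(ids, val_ids)
  if (length(train_ids) == 0L) {
    stop_hiergo("no training proteins left after validation split",
                class = "hiergo_validation_error")
  }

  Tn <- length(term_ids)
  protein_loss <- function(pid, want_grad = FALSE) {
    fwd <- hg_forward(proteins[[pid]], E, params, config,
                      want_grad = want_grad)
    y <- targets[pid, ]
    loss <- bce_objective(fwd$probs, y)
    list(loss = loss, fwd = fwd,
         dlogits = if (want_grad) (fwd$probs - y) / Tn)
  }

  trace <- data.frame(epoch = integer(), train = numeric(),
                      val = numeric())
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  stall <- 0L

  for (ep in seq_len(tc$epochs)) {
    order_ids <- with_seed(derive_seed(tc$seed, 100L + ep),
                           sample(train_ids))
    batches <- split(order_ids,
                     ceiling(seq_along(order_ids) / tc$batch_size))
    ep_loss <- 0
    for (b in batches) {
      gacc <- NULL
      for (pid in b) {
        r <- protein_loss(pid, want_grad = TRUE)
        if (!is.finite(r$loss)) {
          stop_hiergo("training diverged (non-finite loss)",
                      class = "hiergo_training_error")
        }
        ep_loss <- ep_loss + r$loss
        g <- hg_backward(r$dlogits / length(b), r$fwd, params, config)
        gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
      }
      upd <- adam_step(opt, gacc, tc$lr)
      opt <- upd$state
      params <- tree_add(params, upd$delta)
      class(params) <- "hiergo_params"
    }
    ep_loss <- ep_loss / length(order_ids)

    val_loss <- if (length(val_ids)) {
      mean(vapply(val_ids, function(pid) protein_loss(pid)$loss, 0))
    } else {
      NA_real_
    }
    trace <- rbind(trace,
                   data.frame(epoch = ep, train = ep_loss, val = val_loss))
    if (tc$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, ep_loss,
                      val_loss))
    }
    if (length(val_ids)) {
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- ep
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tc$patience) break
      }
    } else {
      best_params <- params
      best_epoch <- ep
    }
  }

  if (!trainable_E && !identical(e_checksum, object_checksum(E))) {
    stop_hiergo("frozen GO latents were mutated during training",
                class = "hiergo_training_error")
  }
  if (!identical(x_checksum, object_checksum(proteins))) {
    stop_hiergo("frozen residue embeddings were mutated during training",
                class = "hiergo_training_error")
  }

  structure(list(params = best_params, config = config,
                 term_ids = term_ids, d_seq = d_seq, d_go = d_go,
                 trace = trace, seed = tc$seed, best_epoch = best_epoch),
            class = "hiergo_model")
}

#' @export
print.hiergo_model <- function(x, ...) {
  cat("hiergo_model:", x$config$architecture, "architecture,",
      length(x$term_ids), "terms, d =", x$config$d, "\n")
  if (nrow(x$trace)) {
    cat(sprintf("final train BCE %.4f (epoch %d of %d)\n",
                utils::tail(x$trace$train, 1), x$best_epoch,
                nrow(x$trace)))
  }
  invisible(x)
}

#' Predict term probabilities for proteins
#'
#' When `E` carries more terms than the model was trained with (zero-shot:
#' held-out terms inserted at their topological ranks), predictions are
#' produced for the full sequence; nothing about the decoder depends on a
#' fixed term count.
#'
#' @param model A trained `hiergo_model`.
#' @param proteins Named list of residue-embedding matrices.
#' @param E GO latent matrix (rownames = term ids in decoding order);
#'   defaults to requiring trainable embeddings in the model.
#' @param record_attention Also return cross-attention records per protein.
#' @return Protein x term probability matrix, plus attribute `attention`
#'   when requested.
#' @export
predict_proteins <- function(model, proteins, E = NULL,
                             record_attention = FALSE) {
  term_ids <- if (!is.null(E)) rownames(E) else model$term_ids
  out <- matrix(NA_real_, length(proteins), length(term_ids),
                dimnames = list(names(proteins), term_ids))
  attn <- if (record_attention) vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    fwd <- hg_forward(proteins[[i]], E, model$params, model$config)
    out[i, ] <- fwd$probs
    if (record_attention) attn[[i]] <- fwd$attn
  }
  if (record_attention) {
    names(attn) <- names(proteins)
    attr(out, "attention") <- attn
  }
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints are written as a serialized object plus a JSON metadata
#' sidecar (dimensions, architecture, ordering, seed) for inspection
#' without loading.
#'
#' @param model A `hiergo_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(d = model$config$d, n_heads = model$config$n_heads,
               n_enc = model$config$n_enc, n_dec = model$config$n_dec,
               architecture = model$config$architecture,
               ordering = model$config$ordering,
               n_terms = length(model$term_ids), d_seq = model$d_seq,
               d_go = model$d_go, seed = model$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(path)
}
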