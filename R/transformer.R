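# The hierarchical encoder-decoder.
#
# Residue embeddings from a (frozen, pluggable) protein language model are
# projected into the model width and contextualized by N_enc self-attention
# layers. GO term latents, arranged in topological order, are projected and
# decoded by N_dec layers of causal self-attention (lower-triangular mask
# over the ordering, so each term sees only more general terms) plus
# cross-attention to the residues; a two-layer GELU head emits one sigmoid
# probability per term. Post-norm layer arrangement by default; positional
# encodings are off by default (contextual residue embeddings already carry
# position, and GO order enters through the mask).

#' Transformer hyperparameter/configuration container
#'
#' @param d Model width (must be divisible by `n_heads`).
#' @param n_heads Attention heads.
#' @param n_enc,n_dec Encoder / decoder layer counts.
#' @param d_ff Feed-forward hidden width (default `2 * d`).
#' @param d_head Prediction-head hidden width (default `d`).
#' @param ordering `"hierarchical"` (topological, causal general-to-specific
#'   decoding) or `"go_id"` (flat lexicographic ablation).
#' @param architecture `"decoder"` (causal, the primary model), `"encoder"`
#'   (bidirectional attention over GO positions) or `"mlp"` (mean-pooled
#'   protein embedding concatenated with each GO latent).
#' @param positional Add sinusoidal positional encodings to the residue
#'   stream (default FALSE).
#' @param max_len Maximum residue count accepted by [hg_forward()].
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(d = 128L, n_heads = 4L, n_enc = 2L,
                               n_dec = 2L, d_ff = 2L * d, d_head = d,
                               ordering = c("hierarchical", "go_id"),
                               architecture = c("decoder", "encoder", "mlp"),
                               positional = FALSE, max_len = 1000L) {
  if (d %% n_heads != 0L) {
    stop_hiergo("model width must be divisible by head count",
                class = "hiergo_config_error")
  }
  structure(list(d = as.integer(d), n_heads = as.integer(n_heads),
                 n_enc = as.integer(n_enc), n_dec = as.integer(n_dec),
                 d_ff = as.integer(d_ff), d_head = as.integer(d_head),
                 ordering = match.arg(ordering),
                 architecture = match.arg(architecture),
                 positional = positional, max_len = as.integer(max_len)),
            class = "transformer_config")
}

#' @noRd
init_attn <- function(d, rmat) {
  list(Wq = rmat(d, d), Wk = rmat(d, d), Wv = rmat(d, d), Wo = rmat(d, d))
}

#' @noRd
init_ln <- function(d) list(g = rep(1, d), b = rep(0, d))

#' Initialize transformer parameters
#'
#' @param d_seq Residue embedding input dimension.
#' @param d_go GO latent input dimension.
#' @param config A [transformer_config()].
#' @param seed RNG seed (Xavier/Glorot normal initialization).
#' @param n_terms Required for `architecture = "mlp"`-independent setups
#'   only when `trainable_embeddings = TRUE` ("none" embedding ablation):
#'   allocates a trainable `E` matrix of `n_terms` x `d_go`.
#' @param trainable_embeddings Allocate trainable GO embeddings instead of
#'   consuming frozen ones.
#' @return Nested parameter list of class `hiergo_params`.
#' @export
init_transformer <- function(d_seq, d_go, config = transformer_config(),
                             seed = 1L, n_terms = NULL,
                             trainable_embeddings = FALSE) {
  d <- config$d
  with_seed(derive_seed(seed, 23L), {
    rmat <- function(nr, nc) {
      matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
    }
    enc_layer <- function() {
      list(attn = init_attn(d, rmat), ln1 = init_ln(d),
           ffn = list(W1 = rmat(d, config$d_ff), b1 = rep(0, config$d_ff),
                      W2 = rmat(config$d_ff, d), b2 = rep(0, d)),
           ln2 = init_ln(d))
    }
    dec_layer <- function() {
      list(self = init_attn(d, rmat), ln1 = init_ln(d),
           cross = init_attn(d, rmat), ln2 = init_ln(d),
           ffn = list(W1 = rmat(d, config$d_ff), b1 = rep(0, config$d_ff),
                      W2 = rmat(config$d_ff, d), b2 = rep(0, d)),
           ln3 = init_ln(d))
    }
    head_in <- if (config$architecture == "mlp") 2L * d else d
    params <- list(
      W_seq = rmat(d_seq, d), b_seq = rep(0, d),
      W_go = rmat(d_go, d), b_go = rep(0, d),
      enc = if (config$architecture == "mlp") list() else
        lapply(seq_len(config$n_enc), function(i) enc_layer()),
      dec = if (config$architecture == "mlp") list() else
        lapply(seq_len(config$n_dec), function(i) dec_layer()),
      head = list(W1 = rmat(head_in, config$d_head),
                  b1 = rep(0, config$d_head),
                  W2 = rmat(config$d_head, 1L), b2 = 0)
    )
    if (trainable_embeddings) {
      if (is.null(n_terms)) {
        stop_hiergo("n_terms required for trainable embeddings",
                    class = "hiergo_config_error")
      }
      params$E <- rmat(n_terms, d_go)
    }
    structure(params, class = "hiergo_params")
  })
}

#' Project residue embeddings into the model space
#'
#' `H = X W_seq + 1 b'`: the affine map from the protein language model's
#' residue space into the encoder width.
#'
#' @param X Residue embedding matrix (L x d_seq).
#' @param W_seq,b_seq Projection weight (d_seq x d) and bias (length d).
#' @return L x d matrix.
#' @export
project_residues <- function(X, W_seq, b_seq) {
  if (ncol(X) != nrow(W_seq)) {
    stop_hiergo("residue embedding dim ", ncol(X), " does not match ",
                "projection input dim ", nrow(W_seq),
                class = "hiergo_validation_error")
  }
  add_bias(X %*% W_seq, b_seq)
}

#' Lower-triangular causal mask over a term ordering
#'
#' Position `i` may attend to positions `j <= i` (diagonal included), so in
#' a topological ordering each term sees itself and all more general terms
#' decoded before it.
#'
#' @param n_terms Sequence length T.
#' @return T x T logical matrix, TRUE = allowed.
#' @export
build_causal_mask <- function(n_terms) {
  if (n_terms < 1L) {
    stop_hiergo("mask needs at least one position",
                class = "hiergo_validation_error")
  }
  outer(seq_len(n_terms), seq_len(n_terms), `>=`)
}

#' Contextualize projected residues with the encoder stack
#'
#' Standard post-norm transformer encoder: multi-head self-attention and a
#' position-wise feed-forward block, each wrapped in a residual connection
#' and layer normalization. Masked (padding) positions are never used as
#' attention keys, so they cannot influence unmasked outputs.
#'
#' @param H0 Projected residues (L x d), e.g. from [project_residues()].
#' @param params `hiergo_params`.
#' @param config [transformer_config()].
#' @param key_keep Logical length-L vector, TRUE for real residues.
#' @param want_grad Keep caches for backpropagation.
#' @return List with `out` (L x d) and (if requested) `caches`.
#' @export
encode_protein <- function(H0, params, config, key_keep = NULL,
                           want_grad = FALSE) {
  L <- nrow(H0)
  if (is.null(key_keep)) key_keep <- rep(TRUE, L)
  if (!any(key_keep)) {
    stop_hiergo("all residue positions are masked",
                class = "hiergo_validation_error")
  }
  mask <- if (all(key_keep)) NULL else
    matrix(key_keep, L, L, byrow = TRUE)
  H <- H0
  caches <- vector("list", length(params$enc))
  for (l in seq_along(params$enc)) {
    p <- params$enc[[l]]
    a <- mha_forward(H, H, p$attn, config$n_heads, mask)
    n1 <- layernorm_forward(H + a$out, p$ln1)
    f <- ffn_forward(n1$out, p$ffn)
    n2 <- layernorm_forward(n1$out + f$out, p$ln2)
    if (want_grad) {
      caches[[l]] <- list(attn = a$cache, ln1 = n1$cache, ffn = f$cache,
                          ln2 = n2$cache)
    }
    H <- n2$out
  }
  list(out = H, caches = if (want_grad) caches)
}

#' Decode GO terms against encoded residues
#'
#' Each decoder layer applies masked self-attention over GO positions (the
#' causal mask), cross-attention with queries from GO positions and
#' keys/values from residues, and a feed-forward block, all post-norm with
#' residual connections. Cross-attention weights are recorded per layer and
#' head for interpretability.
#'
#' @param G0 Projected GO latents (T x d) in ordering-rank order.
#' @param H_enc Encoder output (L x d).
#' @param mask T x T logical causal mask from [build_causal_mask()] (or an
#'   all-TRUE matrix for the bidirectional "encoder" ablation).
#' @param params,config Model parameters and configuration.
#' @param key_keep Logical length-L residue mask.
#' @param want_grad Keep caches for backpropagation.
#' @return List with `out` (T x d), `attn` (list over layers of lists over
#'   heads of T x L row-stochastic matrices), and optional `caches`.
#' @export
decode_terms <- function(G0, H_enc, mask, params, config, key_keep = NULL,
                         want_grad = FALSE) {
  T_ <- nrow(G0)
  if (!is.matrix(mask) || nrow(mask) != T_ || ncol(mask) != T_) {
    stop_hiergo("causal mask does not match term count ", T_,
                class = "hiergo_validation_error")
  }
  L <- nrow(H_enc)
  if (is.null(key_keep)) key_keep <- rep(TRUE, L)
  cross_mask <- if (all(key_keep)) NULL else
    matrix(key_keep, T_, L, byrow = TRUE)
  G <- G0
  attn <- vector("list", length(params$dec))
  caches <- vector("list", length(params$dec))
  for (l in seq_along(params$dec)) {
    p <- params$dec[[l]]
    s <- mha_forward(G, G, p$self, config$n_heads, mask)
    n1 <- layernorm_forward(G + s$out, p$ln1)
    x <- mha_forward(n1$out, H_enc, p$cross, config$n_heads, cross_mask)
    n2 <- layernorm_forward(n1$out + x$out, p$ln2)
    f <- ffn_forward(n2$out, p$ffn)
    n3 <- layernorm_forward(n2$out + f$out, p$ln3)
    attn[[l]] <- x$attn
    if (want_grad) {
      caches[[l]] <- list(self = s$cache, ln1 = n1$cache, cross = x$cache,
                          ln2 = n2$cache, ffn = f$cache, ln3 = n3$cache)
    }
    G <- n3$out
  }
  list(out = G, attn = attn, caches = if (want_grad) caches)
}

#' Per-term probabilities from decoder states
#'
#' Two-layer feed-forward head with GELU activation and a sigmoid output:
#' `sigmoid(W2' gelu(W1' h + b1) + b2)` per GO position.
#'
#' @param H_dec Decoder output (T x d).
#' @param params `hiergo_params` (uses `params$head`).
#' @param want_grad Keep the cache.
#' @return List with `probs` (length T, in (0, 1)), `logits`, and optional
#'   `cache`.
#' @export
predict_head <- function(H_dec, params, want_grad = FALSE) {
  f <- ffn_forward(H_dec, params$head)
  logits <- drop(f$out)
  list(probs = sigmoid(logits), logits = logits,
       cache = if (want_grad) f$cache)
}

#' Full forward pass
#'
#' Composes residue projection, encoder stack, GO projection, masked
#' decoding and the prediction head. Inputs `X` and `E` are consumed
#' read-only (the frozen-embedding contract); only projections, transformer
#' blocks and the head carry gradients.
#'
#' @param X Residue embeddings (L x d_seq).
#' @param E GO latents (T x d_go) ordered by the model's term ordering.
#'   Ignored (taken from `params$E`) when the model was initialized with
#'   trainable embeddings.
#' @param params,config Parameters and configuration.
#' @param key_keep Logical residue padding mask (TRUE = real residue).
#' @param want_grad Keep caches for [hg_backward()].
#' @return List with `probs`, `logits`, `attn` (cross-attention record) and
#'   internal caches when requested.
#' @export
hg_forward <- function(X, E, params, config, key_keep = NULL,
                       want_grad = FALSE) {
  if (!is.null(params$E)) E <- params$E
  if (nrow(X) > config$max_len) {
    stop_hiergo("sequence length ", nrow(X), " exceeds max_len ",
                config$max_len, class = "hiergo_validation_error")
  }
  if (config$architecture == "mlp") {
    return(mlp_forward(X, E, params, config, key_keep, want_grad))
  }
  H0 <- project_residues(X, params$W_seq, params$b_seq)
  if (isTRUE(config$positional)) {
    H0 <- H0 + sinusoidal_encoding(nrow(H0), config$d)
  }
  enc <- encode_protein(H0, params, config, key_keep, want_grad)
  G0 <- add_bias(E %*% params$W_go, params$b_go)
  T_ <- nrow(G0)
  mask <- if (config$architecture == "encoder") {
    matrix(TRUE, T_, T_)
  } else {
    build_causal_mask(T_)
  }
  dec <- decode_terms(G0, enc$out, mask, params, config, key_keep, want_grad)
  hd <- predict_head(dec$out, params, want_grad)
  list(probs = hd$probs, logits = hd$logits, attn = dec$attn,
       cache = if (want_grad) {
         list(X = X, E = E, enc = enc, dec = dec, head = hd$cache,
              key_keep = key_keep, mask = mask, H0 = H0, G0 = G0)
       })
}

# MLP ablation: mean-pooled projected protein embedding concatenated with
# each projected GO latent, then the two-layer head.
#' @noRd
mlp_forward <- function(X, E, params, config, key_keep = NULL,
                        want_grad = FALSE) {
  if (is.null(key_keep)) key_keep <- rep(TRUE, nrow(X))
  Xk <- X[key_keep, , drop = FALSE]
  pbar <- drop(colMeans(Xk) %*% params$W_seq) + params$b_seq
  Gp <- add_bias(E %*% params$W_go, params$b_go)
  T_ <- nrow(Gp)
  Hcat <- cbind(matrix(pbar, T_, length(pbar), byrow = TRUE), Gp)
  f <- ffn_forward(Hcat, params$head)
  logits <- drop(f$out)
  list(probs = sigmoid(logits), logits = logits, attn = NULL,
       cache = if (want_grad) {
         list(X = X, E = E, head = f$cache, key_keep = key_keep, Tn = T_)
       })
}
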