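# Reverse-mode gradients through the full encoder-decoder, mirroring the
# forward composition in transformer.R exactly (post-norm residual blocks).
# Gradients stop at the projection layers: frozen inputs X and E receive no
# update (E only carries a gradient in the trainable-embedding ablation).

#' Backpropagate through a cached forward pass
#'
#' @param dlogits Gradient of the loss with respect to the pre-sigmoid
#'   logits (length T).
#' @param fwd Result of [hg_forward()] with `want_grad = TRUE`.
#' @param params,config Model parameters and configuration.
#' @return Gradient tree matching `params`.
#' @export
hg_backward <- function(dlogits, fwd, params, config) {
  cache <- fwd$cache
  if (is.null(cache)) {
    stop_hiergo("forward pass was not run with want_grad = TRUE",
                class = "hiergo_validation_error")
  }
  if (config$architecture == "mlp") {
    return(mlp_backward(dlogits, cache, params, config))
  }
  T_ <- length(dlogits)

  hb <- ffn_backward(matrix(dlogits, T_, 1L), cache$head, params$head)
  dG <- hb$dX
  grads <- list(head = hb$grads)

  dec_grads <- vector("list", length(params$dec))
  dHenc <- matrix(0, nrow(cache$enc$out), ncol(cache$enc$out))
  for (l in rev(seq_along(params$dec))) {
    p <- params$dec[[l]]
    cl <- cache$dec$caches[[l]]
    b3 <- layernorm_backward(dG, cl$ln3, p$ln3)
    fb <- ffn_backward(b3$dX, cl$ffn, p$ffn)
    dN2 <- b3$dX + fb$dX
    b2 <- layernorm_backward(dN2, cl$ln2, p$ln2)
    xb <- mha_backward(b2$dX, cl$cross, p$cross)
    dHenc <- dHenc + xb$dKin
    dN1 <- b2$dX + xb$dQin
    b1 <- layernorm_backward(dN1, cl$ln1, p$ln1)
    sb <- mha_backward(b1$dX, cl$self, p$self)
    dG <- b1$dX + sb$dQin + sb$dKin
    dec_grads[[l]] <- list(self = sb$grads, ln1 = b1$grads,
                           cross = xb$grads, ln2 = b2$grads,
                           ffn = fb$grads, ln3 = b3$grads)
  }
  grads$dec <- dec_grads

  enc_grads <- vector("list", length(params$enc))
  dH <- dHenc
  for (l in rev(seq_along(params$enc))) {
    p <- params$enc[[l]]
    cl <- cache$enc$caches[[l]]
    b2 <- layernorm_backward(dH, cl$ln2, p$ln2)
    fb <- ffn_backward(b2$dX, cl$ffn, p$ffn)
    dN1 <- b2$dX + fb$dX
    b1 <- layernorm_backward(dN1, cl$ln1, p$ln1)
    ab <- mha_backward(b1$dX, cl$attn, p$attn)
    dH <- b1$dX + ab$dQin + ab$dKin
    enc_grads[[l]] <- list(attn = ab$grads, ln1 = b1$grads,
                           ffn = fb$grads, ln2 = b2$grads)
  }
  grads$enc <- enc_grads

  # input projections (positional encodings are additive constants)
  grads$W_seq <- crossprod(cache$X, dH)
  grads$b_seq <- colSums(dH)
  dG0 <- dG
  grads$W_go <- crossprod(cache$E, dG0)
  grads$b_go <- colSums(dG0)
  if (!is.null(params$E)) grads$E <- dG0 %*% t(params$W_go)

  grads[names(params)]
}

#' @noRd
mlp_backward <- function(dlogits, cache, params, config) {
  T_ <- length(dlogits)
  hb <- ffn_backward(matrix(dlogits, T_, 1L), cache$head, params$head)
  d <- config$d
  dPbar_rows <- hb$dX[, seq_len(d), drop = FALSE]
  dGp <- hb$dX[, d + seq_len(d), drop = FALSE]
  dpbar <- colSums(dPbar_rows)
  Xk <- cache$X[cache$key_keep, , drop = FALSE]
  grads <- list(
    W_seq = colMeans(Xk) %o% dpbar,
    b_seq = dpbar,
    W_go = crossprod(cache$E, dGp),
    b_go = colSums(dGp),
    enc = list(), dec = list(),
    head = hb$grads
  )
  if (!is.null(params$E)) grads$E <- dGp %*% t(params$W_go)
  grads[names(params)]
}
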