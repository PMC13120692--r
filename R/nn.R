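# Dense neural-network primitives with hand-derived reverse-mode gradients.
#
# Parameters live in nested lists of numeric arrays; the helpers below map
# over matching trees so the optimizer is agnostic to model structure. All
# gradients are verified against central finite differences in the test
# suite.

#' @noRd
tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, tree_map, f = f) else f(tree)
}

#' @noRd
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else {
    f(a, b)
  }
}

#' @noRd
tree_add <- function(a, b) tree_map2(`+`, a, b)

#' @noRd
tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

#' @noRd
adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

# Returns updated state and the additive parameter delta.
#' @noRd
adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  t <- state$t + 1L
  m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  delta <- tree_map2(function(m, v) -lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     m, v)
  list(state = list(m = m, v = v, t = t), delta = delta)
}

#' Exact Gaussian-error linear unit
#' @noRd
gelu <- function(x) x * stats::pnorm(x)

#' @noRd
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' @noRd
add_bias <- function(M, b) M + rep(b, each = nrow(M))

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---------------------------------------------------------------------------
# Layer normalization (per row, learnable gain/bias)

#' @noRd
layernorm_forward <- function(X, p, eps = 1e-5) {
  n <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  inv <- 1 / sqrt(rowMeans(Xc^2) + eps)
  Xhat <- Xc * inv
  Y <- add_bias(Xhat * rep(p$g, each = n), p$b)
  list(out = Y, cache = list(Xhat = Xhat, inv = inv))
}

#' @noRd
layernorm_backward <- function(dY, cache, p) {
  n <- nrow(dY)
  dXhat <- dY * rep(p$g, each = n)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * cache$Xhat)
  dX <- cache$inv * (dXhat - m1 - cache$Xhat * m2)
  list(dX = dX,
       grads = list(g = colSums(dY * cache$Xhat), b = colSums(dY)))
}

# ---------------------------------------------------------------------------
# Position-wise feed-forward block (two layers, GELU)

#' @noRd
ffn_forward <- function(X, p) {
  U <- add_bias(X %*% p$W1, p$b1)
  G <- gelu(U)
  Y <- add_bias(G %*% p$W2, p$b2)
  list(out = Y, cache = list(X = X, U = U, G = G))
}

#' @noRd
ffn_backward <- function(dY, cache, p) {
  dG <- tcrossprod(dY, p$W2)
  dU <- dG * gelu_grad(cache$U)
  list(dX = tcrossprod(dU, p$W1),
       grads = list(W1 = crossprod(cache$X, dU), b1 = colSums(dU),
                    W2 = crossprod(cache$G, dY), b2 = colSums(dY)))
}

# ---------------------------------------------------------------------------
# Multi-head scaled-dot-product attention.
#
# `mask` is an n_q x n_k logical matrix (TRUE = key visible to that query);
# NULL means fully visible. Masked keys receive zero attention, so appending
# masked rows can never change unmasked outputs.

#' @noRd
mha_forward <- function(Qin, Kin, p, n_heads, mask = NULL) {
  d <- ncol(p$Wq)
  dk <- d %/% n_heads
  Q <- Qin %*% p$Wq
  K <- Kin %*% p$Wk
  V <- Kin %*% p$Wv
  O <- matrix(0, nrow(Qin), d)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dk)
    if (!is.null(mask)) S[!mask] <- -Inf
    A <- row_softmax(S)
    A_list[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  list(out = O %*% p$Wo,
       attn = A_list,
       cache = list(Qin = Qin, Kin = Kin, Q = Q, K = K, V = V, O = O,
                    A = A_list, n_heads = n_heads, dk = dk))
}

#' @noRd
mha_backward <- function(dout, cache, p) {
  dO <- tcrossprod(dout, p$Wo)
  dWo <- crossprod(cache$O, dout)
  n_heads <- cache$n_heads
  dk <- cache$dk
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- dK
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    A <- cache$A[[h]]
    Vh <- cache$V[, idx, drop = FALSE]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(A * dA))
    dQ[, idx] <- (dS %*% cache$K[, idx, drop = FALSE]) / sqrt(dk)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  list(dQin = tcrossprod(dQ, p$Wq),
       dKin = tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv),
       grads = list(Wq = crossprod(cache$Qin, dQ),
                    Wk = crossprod(cache$Kin, dK),
                    Wv = crossprod(cache$Kin, dV),
                    Wo = dWo))
}

#' Sinusoidal positional encodings
#' @noRd
sinusoidal_encoding <- function(n, d) {
  pos <- seq_len(n) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 1 / 10000^((i %/% 2) * 2 / d))
  even <- (i %% 2) == 0
  out <- matrix(0, n, d)
  out[, even] <- sin(angle[, even, drop = FALSE])
  out[, !even] <- cos(angle[, !even, drop = FALSE])
  out
}
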