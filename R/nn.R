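# Reverse-mode building blocks for the Transformer stack. Tokens are matrix
# rows (n_tokens x d_model). Every *_fwd returns list(out, cache); the paired
# *_bwd consumes the upstream gradient and the cache and returns gradients for
# inputs and parameters. All gradients are exact (finite-difference tested).

linear_fwd <- function(X, W, b) {
  list(out = X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE),
       cache = list(X = X, W = W))
}

linear_bwd <- function(dY, cache) {
  list(dX = dY %*% t(cache$W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * matrix(g, nrow(X), ncol(X), byrow = TRUE) +
    matrix(b, nrow(X), ncol(X), byrow = TRUE)
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g, d = ncol(X)))
}

layernorm_bwd <- function(dY, cache) {
  d <- cache$d
  gmat <- matrix(cache$g, nrow(dY), d, byrow = TRUE)
  dxhat <- dY * gmat
  # dX = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

# parameter-free layer normalization (used for momentum-encoder targets)
layernorm_plain <- function(X, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  (xc) / sqrt(rowMeans(xc^2) + eps)
}

gelu_fwd <- function(X) {
  list(out = X * stats::pnorm(X), cache = list(X = X))
}

gelu_bwd <- function(dY, cache) {
  X <- cache$X
  dY * (stats::pnorm(X) + X * stats::dnorm(X))
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  e <- exp(S - m)
  e / rowSums(e)
}

# Multi-head scaled dot-product attention with an optional per-key-token
# multiplicative value gate (the frequency gate of the AFTA block). The gate is
# treated as a constant during backprop (stop-gradient).
mha_fwd <- function(Xq, Xkv, p, n_heads, gate = NULL) {
  dm <- ncol(Xq)
  stop_if_not(dm %% n_heads == 0, "d_model must be divisible by n_heads")
  dk <- dm %/% n_heads
  Q <- Xq %*% p$Wq + matrix(p$bq, nrow(Xq), dm, byrow = TRUE)
  K <- Xkv %*% p$Wk + matrix(p$bk, nrow(Xkv), dm, byrow = TRUE)
  V <- Xkv %*% p$Wv + matrix(p$bv, nrow(Xkv), dm, byrow = TRUE)
  Vg <- if (is.null(gate)) V else V * gate
  O <- matrix(0, nrow(Xq), dm)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dk)
    A <- softmax_rows(S)
    A_list[[h]] <- A
    O[, cols] <- A %*% Vg[, cols, drop = FALSE]
  }
  Y <- O %*% p$Wo + matrix(p$bo, nrow(Xq), dm, byrow = TRUE)
  list(out = Y,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, Vg = Vg, O = O,
                    A = A_list, gate = gate, n_heads = n_heads, dk = dk, p = p))
}

mha_bwd <- function(dY, cache) {
  p <- cache$p
  dk <- cache$dk
  dO <- dY %*% t(p$Wo)
  dWo <- crossprod(cache$O, dY)
  dbo <- colSums(dY)
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dVg <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(cache$n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dVg[, cols] <- crossprod(A, dOh)
    dA <- dOh %*% t(cache$Vg[, cols, drop = FALSE])
    # softmax backward per row: dS = A * (dA - rowSums(dA * A))
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- (dS %*% cache$K[, cols, drop = FALSE]) / sqrt(dk)
    dK[, cols] <- (crossprod(dS, cache$Q[, cols, drop = FALSE])) / sqrt(dk)
  }
  dV <- if (is.null(cache$gate)) dVg else dVg * cache$gate
  dXq <- dQ %*% t(p$Wq)
  dXkv <- dK %*% t(p$Wk) + dV %*% t(p$Wv)
  grads <- list(Wq = crossprod(cache$Xq, dQ), bq = colSums(dQ),
                Wk = crossprod(cache$Xkv, dK), bk = colSums(dK),
                Wv = crossprod(cache$Xkv, dV), bv = colSums(dV),
                Wo = dWo, bo = dbo)
  list(dXq = dXq, dXkv = dXkv, grads = grads)
}

mlp_fwd <- function(X, p, dropout = 0, train = FALSE) {
  l1 <- linear_fwd(X, p$W1, p$b1)
  g <- gelu_fwd(l1$out)
  h <- g$out
  dmask <- NULL
  if (train && dropout > 0) {
    dmask <- matrix(stats::rbinom(length(h), 1, 1 - dropout), nrow(h)) / (1 - dropout)
    h <- h * dmask
  }
  l2 <- linear_fwd(h, p$W2, p$b2)
  list(out = l2$out, cache = list(l1 = l1$cache, g = g$cache, dmask = dmask,
                                  l2 = l2$cache))
}

mlp_bwd <- function(dY, cache) {
  b2 <- linear_bwd(dY, cache$l2)
  dh <- b2$dX
  if (!is.null(cache$dmask)) dh <- dh * cache$dmask
  dg <- gelu_bwd(dh, cache$g)
  b1 <- linear_bwd(dg, cache$l1)
  list(dX = b1$dX,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}

# --- initialization ----------------------------------------------------------

init_mat <- function(n_in, n_out, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (n_in + n_out))
  matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out)
}

init_attn <- function(dm) {
  list(Wq = init_mat(dm, dm), bq = numeric(dm),
       Wk = init_mat(dm, dm), bk = numeric(dm),
       Wv = init_mat(dm, dm), bv = numeric(dm),
       Wo = init_mat(dm, dm), bo = numeric(dm))
}

init_mlp <- function(dm, hidden) {
  list(W1 = init_mat(dm, hidden), b1 = numeric(hidden),
       W2 = init_mat(hidden, dm), b2 = numeric(dm))
}

init_ln <- function(dm) list(g = rep(1, dm), b = numeric(dm))

# --- AdamW -------------------------------------------------------------------

#' Initialize AdamW optimizer state for a parameter tree
#' @param params Nested list of numeric arrays.
#' @return Optimizer state.
#' @keywords internal
adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

# One decoupled-weight-decay Adam step. Weight decay applies to matrices only
# (biases, layer-norm gains, scalars are excluded, as is standard).
adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) {
    wd <- if (is.matrix(p)) weight_decay else 0
    p - lr * (u + wd * p)
  }, params, upd)
  list(params = params, state = state)
}
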