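# Layer primitives with explicit forward/backward passes. Sequences are
# (B*T) x D matrices in batch-major row order (row = (b-1)*T + t); the
# LSTM and attention cores live in src/dcan_kernels.cpp. All backward
# functions are validated against finite differences in the test suite.

#' Gaussian error linear unit
#'
#' The exact form `x * pnorm(x)` (standard normal CDF), not the tanh
#' approximation.
#'
#' @param x Numeric vector, matrix or array.
#' @return `x * pnorm(x)`, same shape.
#' @export
gelu <- function(x) {
  stopifnot(all(is.finite(x)))
  x * pnorm(x)
}

gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

# forward with the CDF cached for reuse in the backward pass (compiled;
# semantics identical to x * pnorm(x))
gelu_fwd <- function(x) .gelu_fwd_cpp(x)
gelu_bwd <- function(dY, x, Phi) .gelu_bwd_cpp(dY, x, Phi)

add_bias <- function(X, b) X + rep.int(b, rep.int(nrow(X), length(b)))

linear_fwd <- function(X, W, b) list(Y = add_bias(X %*% W, b), X = X)
linear_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL, p = p))
  mask <- (runif(length(X)) >= p) / (1 - p)  # element order matches X
  list(Y = X * mask, mask = mask, p = p)
}
dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- add_bias(xhat * rep.int(g, rep.int(nrow(X), length(g))), b)
  list(Y = Y, xhat = xhat, inv = inv)
}
layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep.int(g, rep.int(nrow(dY), length(g)))
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
softmax_rows_bwd <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

# ---- bidirectional LSTM -------------------------------------------------

init_lstm_params <- function(D, h) {
  gl <- function(d1, d2) {
    l <- sqrt(6 / (d1 + d2))
    matrix(runif(d1 * d2, -l, l), d1, d2)
  }
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias
  list(Wx = gl(D, 4 * h), Wh = gl(h, 4 * h), b = b)
}

bilstm_fwd <- function(X, P, prefix, B, T) {
  f <- .lstm_forward_cpp(X, P[[paste0(prefix, ".f.Wx")]],
                         P[[paste0(prefix, ".f.Wh")]],
                         P[[paste0(prefix, ".f.b")]], B, T, FALSE)
  r <- .lstm_forward_cpp(X, P[[paste0(prefix, ".b.Wx")]],
                         P[[paste0(prefix, ".b.Wh")]],
                         P[[paste0(prefix, ".b.b")]], B, T, TRUE)
  list(H = cbind(f$H, r$H), X = X, f = f, r = r)
}
bilstm_bwd <- function(dH, cache, P, prefix, B, T, G) {
  h2 <- ncol(cache$f$H)
  df <- .lstm_backward_cpp(dH[, 1:h2, drop = FALSE], cache$X,
                           P[[paste0(prefix, ".f.Wx")]],
                           P[[paste0(prefix, ".f.Wh")]],
                           cache$f$Ht, cache$f$C, cache$f$G, B, T, FALSE)
  dr <- .lstm_backward_cpp(dH[, (h2 + 1):(2 * h2), drop = FALSE], cache$X,
                           P[[paste0(prefix, ".b.Wx")]],
                           P[[paste0(prefix, ".b.Wh")]],
                           cache$r$Ht, cache$r$C, cache$r$G, B, T, TRUE)
  gacc(G, paste0(prefix, ".f.Wx"), df$dWx)
  gacc(G, paste0(prefix, ".f.Wh"), df$dWh)
  gacc(G, paste0(prefix, ".f.b"), as.numeric(df$db))
  gacc(G, paste0(prefix, ".b.Wx"), dr$dWx)
  gacc(G, paste0(prefix, ".b.Wh"), dr$dWh)
  gacc(G, paste0(prefix, ".b.b"), as.numeric(dr$db))
  df$dX + dr$dX
}

# ---- multi-head attention block (projections + core) --------------------

init_mha_params <- function(h) {
  gl <- function(d1, d2) {
    l <- sqrt(6 / (d1 + d2))
    matrix(runif(d1 * d2, -l, l), d1, d2)
  }
  # the output projection starts small so residual attention blocks begin
  # near the identity path, which stabilises the first training epochs
  list(Wq = gl(h, h), Wk = gl(h, h), Wv = gl(h, h), Wo = 0.1 * gl(h, h),
       bq = numeric(h), bk = numeric(h), bv = numeric(h), bo = numeric(h))
}

mha_fwd <- function(H, P, prefix, B, T, nh, causal, mask) {
  Q <- add_bias(H %*% P[[paste0(prefix, ".Wq")]], P[[paste0(prefix, ".bq")]])
  K <- add_bias(H %*% P[[paste0(prefix, ".Wk")]], P[[paste0(prefix, ".bk")]])
  V <- add_bias(H %*% P[[paste0(prefix, ".Wv")]], P[[paste0(prefix, ".bv")]])
  core <- .mha_forward_cpp(Q, K, V, B, T, nh, causal, mask)
  out <- add_bias(core$O %*% P[[paste0(prefix, ".Wo")]],
                  P[[paste0(prefix, ".bo")]])
  list(out = out, H = H, Q = Q, K = K, V = V, O = core$O, A = core$A,
       nh = nh)
}
mha_bwd <- function(dOut, cache, P, prefix, B, T, G) {
  dO <- dOut %*% t(P[[paste0(prefix, ".Wo")]])
  gacc(G, paste0(prefix, ".Wo"), crossprod(cache$O, dOut))
  gacc(G, paste0(prefix, ".bo"), colSums(dOut))
  core <- .mha_backward_cpp(dO, cache$Q, cache$K, cache$V, cache$A,
                            B, T, cache$nh)
  dH <- core$dQ %*% t(P[[paste0(prefix, ".Wq")]]) +
    core$dK %*% t(P[[paste0(prefix, ".Wk")]]) +
    core$dV %*% t(P[[paste0(prefix, ".Wv")]])
  gacc(G, paste0(prefix, ".Wq"), crossprod(cache$H, core$dQ))
  gacc(G, paste0(prefix, ".Wk"), crossprod(cache$H, core$dK))
  gacc(G, paste0(prefix, ".Wv"), crossprod(cache$H, core$dV))
  gacc(G, paste0(prefix, ".bq"), colSums(core$dQ))
  gacc(G, paste0(prefix, ".bk"), colSums(core$dK))
  gacc(G, paste0(prefix, ".bv"), colSums(core$dV))
  dH
}

# gradient accumulator: G is an environment holding a named list `g`
gacc <- function(G, name, val) {
  if (is.null(G$g[[name]])) G$g[[name]] <- val else
    G$g[[name]] <- G$g[[name]] + val
  invisible(NULL)
}

#' Scaled dot-product attention (reference implementation)
#'
#' `softmax(Q K' / sqrt(d_k)) V` computed row-wise, with an optional
#' boolean mask (`TRUE` = position may be attended to); masked logits
#' receive `-Inf` before the softmax, and a fully masked row yields a zero
#' output row. This single-head reference defines the semantics the
#' compiled multi-head kernel must reproduce, and the two are compared in
#' the test suite.
#'
#' @param Q,K,V Conforming `T x d` matrices.
#' @param mask Optional boolean `T x T` matrix, e.g. [causal_mask()].
#' @return `T x d` matrix of attended values.
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  d <- ncol(Q)
  S <- Q %*% t(K) / sqrt(d)
  if (!is.null(mask)) S[!mask] <- -Inf
  A <- matrix(0, nrow(S), ncol(S))
  for (i in seq_len(nrow(S))) {
    row <- S[i, ]
    if (all(!is.finite(row))) next
    e <- exp(row - max(row[is.finite(row)]))
    e[!is.finite(row)] <- 0
    A[i, ] <- e / sum(e)
  }
  A %*% V
}

#' Causal attention mask
#'
#' Boolean `T x T` matrix allowing position i to attend to positions
#' `j <= i` only, so no timestep can see its future.
#'
#' @param T Sequence length, >= 1.
#' @return Boolean matrix; `TRUE` = allowed.
#' @export
causal_mask <- function(T) {
  stopifnot(T >= 1)
  outer(seq_len(T), seq_len(T), `>=`)
}
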