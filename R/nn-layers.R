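# Neural-network primitives with hand-written backward passes. Activations
# for a batch are stored as a single (B*L) x d matrix, sequences stacked in
# row blocks; attention slices per-sequence blocks internally. Every *_fwd
# returns its output plus the cache its *_bwd needs.

LN_EPS <- 1e-5

linear_fwd <- function(X, W, b) {
  list(Y = sweep(X %*% W, 2, b, "+"), X = X)
}

linear_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W),
       dW = t(cache$X) %*% dY,
       db = colSums(dY))
}

relu_fwd <- function(X) list(Y = pmax(X, 0), mask = X > 0)
relu_bwd <- function(dY, cache) dY * cache$mask

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * invstd
  list(Y = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"),
       xhat = xhat, invstd = invstd)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  d <- ncol(xhat)
  dxhat <- sweep(dY, 2, g, "*")
  # per-row: dX = invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat*xhat))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$invstd * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, "first"))]
  mx[!is.finite(mx)] <- 0        # fully masked row: uniform, unused anyway
  E <- exp(S - mx)
  E[!is.finite(E)] <- 0
  rs <- rowSums(E)
  rs[rs == 0] <- 1
  E / rs
}

# Multi-head attention over a batch.
#   Xq: (B*Lq) x d queries input, Xkv: (B*Lk) x d keys/values input.
#   key_mask: B x Lk logical, TRUE where the key position is attendable.
#   causal: queries may not attend to later key positions (Lq == Lk).
mha_fwd <- function(Xq, Xkv, p, prefix, n_heads, B, Lq, Lk,
                    key_mask = NULL, causal = FALSE) {
  d <- ncol(Xq)
  dh <- d %/% n_heads
  Wq <- p[[paste0(prefix, "_Wq")]]; bq <- p[[paste0(prefix, "_bq")]]
  Wk <- p[[paste0(prefix, "_Wk")]]; bk <- p[[paste0(prefix, "_bk")]]
  Wv <- p[[paste0(prefix, "_Wv")]]; bv <- p[[paste0(prefix, "_bv")]]
  Wo <- p[[paste0(prefix, "_Wo")]]; bo <- p[[paste0(prefix, "_bo")]]
  Q <- sweep(Xq %*% Wq, 2, bq, "+")
  K <- sweep(Xkv %*% Wk, 2, bk, "+")
  V <- sweep(Xkv %*% Wv, 2, bv, "+")
  O <- matrix(0, nrow(Q), d)
  A_list <- vector("list", B * n_heads)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    qi <- ((b - 1) * Lq + 1):(b * Lq)
    ki <- ((b - 1) * Lk + 1):(b * Lk)
    for (h in seq_len(n_heads)) {
      hc <- ((h - 1) * dh + 1):(h * dh)
      S <- (Q[qi, hc, drop = FALSE] %*% t(K[ki, hc, drop = FALSE])) * scale
      if (!is.null(key_mask)) S[, !key_mask[b, ]] <- -Inf
      if (causal) S[upper.tri(S)] <- -Inf
      A <- softmax_rows(S)
      A_list[[(b - 1) * n_heads + h]] <- A
      O[qi, hc] <- A %*% V[ki, hc, drop = FALSE]
    }
  }
  out <- sweep(O %*% Wo, 2, bo, "+")
  list(Y = out, Q = Q, K = K, V = V, O = O, A = A_list,
       Xq = Xq, Xkv = Xkv, B = B, Lq = Lq, Lk = Lk, n_heads = n_heads)
}

mha_bwd <- function(dY, cache, p, prefix) {
  B <- cache$B; Lq <- cache$Lq; Lk <- cache$Lk; H <- cache$n_heads
  d <- ncol(cache$Xq); dh <- d %/% H
  Wq <- p[[paste0(prefix, "_Wq")]]
  Wk <- p[[paste0(prefix, "_Wk")]]
  Wv <- p[[paste0(prefix, "_Wv")]]
  Wo <- p[[paste0(prefix, "_Wo")]]
  grads <- list()
  grads[[paste0(prefix, "_Wo")]] <- t(cache$O) %*% dY
  grads[[paste0(prefix, "_bo")]] <- colSums(dY)
  dO <- dY %*% t(Wo)
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    qi <- ((b - 1) * Lq + 1):(b * Lq)
    ki <- ((b - 1) * Lk + 1):(b * Lk)
    for (h in seq_len(H)) {
      hc <- ((h - 1) * dh + 1):(h * dh)
      A <- cache$A[[(b - 1) * H + h]]
      dOb <- dO[qi, hc, drop = FALSE]
      Vb <- cache$V[ki, hc, drop = FALSE]
      dA <- dOb %*% t(Vb)
      dV[ki, hc] <- dV[ki, hc] + t(A) %*% dOb
      # softmax backward per row
      dS <- A * (dA - rowSums(dA * A))
      dQ[qi, hc] <- (dS %*% cache$K[ki, hc, drop = FALSE]) * scale
      dK[ki, hc] <- dK[ki, hc] +
        (t(dS) %*% cache$Q[qi, hc, drop = FALSE]) * scale
    }
  }
  grads[[paste0(prefix, "_Wq")]] <- t(cache$Xq) %*% dQ
  grads[[paste0(prefix, "_bq")]] <- colSums(dQ)
  grads[[paste0(prefix, "_Wk")]] <- t(cache$Xkv) %*% dK
  grads[[paste0(prefix, "_bk")]] <- colSums(dK)
  grads[[paste0(prefix, "_Wv")]] <- t(cache$Xkv) %*% dV
  grads[[paste0(prefix, "_bv")]] <- colSums(dV)
  list(dXq = dQ %*% t(Wq),
       dXkv = dK %*% t(Wk) + dV %*% t(Wv),
       grads = grads)
}

# sinusoidal positional encoding table, rows = positions
positional_encoding <- function(max_len, d) {
  pos <- seq_len(max_len) - 1
  pe <- matrix(0, max_len, d)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pe[, 2 * i - 1] <- sin(pos * freq)
    if (2 * i <= d) pe[, 2 * i] <- cos(pos * freq)
  }
  pe
}
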