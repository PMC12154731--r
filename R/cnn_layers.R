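## Vectorized neural-network layers for the contour-image classifier.
##
## A batch is a plain matrix, one image per row, flattened column-major per
## channel (pixel index fastest, channels outer). Convolutions are valid
## (no padding), computed by im2col + one BLAS matrix product; the im2col
## gather indices and the col2im scatter matrix (sparse 0/1) are
## precomputed once per layer. Max-pooling uses stride = window, so the
## four window slots are disjoint index sets and the backward pass is a
## masked assignment. Everything is deterministic given the RNG seed.

conv_setup <- function(H, W, Cin, K, Cout) {
  H_out <- H - K + 1L
  W_out <- W - K + 1L
  if (H_out < 1L || W_out < 1L)
    stop_lapnet("convolution kernel larger than its input (", H, "x", W, ")",
                class = "lapnet_validation")
  P <- H_out * W_out
  ro <- rep(seq_len(H_out), times = W_out)
  co <- rep(seq_len(W_out), each = H_out)
  Q <- K * K * Cin
  idx <- matrix(0L, P, Q)
  q <- 0L
  for (ch in seq_len(Cin)) for (kc in seq_len(K)) for (kr in seq_len(K)) {
    q <- q + 1L
    idx[, q] <- (ch - 1L) * H * W + (co + kc - 2L) * H + (ro + kr - 1L)
  }
  scatter <- Matrix::sparseMatrix(i = seq_len(P * Q), j = as.vector(idx),
                                  x = 1, dims = c(P * Q, H * W * Cin))
  list(H = H, W = W, Cin = Cin, K = K, Cout = Cout,
       H_out = H_out, W_out = W_out, P = P, Q = Q,
       gather = as.vector(idx), scatter = scatter)
}

conv_forward <- function(layer, X, Wmat, bias) {
  N <- nrow(X)
  B <- X[, layer$gather, drop = FALSE]
  dim(B) <- c(N * layer$P, layer$Q)
  Z <- B %*% Wmat
  Z <- sweep(Z, 2, bias, "+")
  dim(Z) <- c(N, layer$P * layer$Cout)
  list(out = Z, patches = B)
}

conv_backward <- function(layer, cache, dOut, Wmat) {
  N <- nrow(dOut)
  dZ <- dOut
  dim(dZ) <- c(N * layer$P, layer$Cout)
  dW <- crossprod(cache$patches, dZ)
  db <- colSums(dZ)
  dB <- tcrossprod(dZ, Wmat)            # (N*P) x Q
  dim(dB) <- c(N, layer$P * layer$Q)
  dX <- as.matrix(dB %*% layer$scatter)
  list(dX = dX, dW = dW, db = db)
}

pool_setup <- function(H, W, C) {
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  r <- rep(seq_len(H2), times = W2 * C)
  c <- rep(rep(seq_len(W2), each = H2), times = C)
  ch <- rep(seq_len(C), each = H2 * W2)
  base <- (ch - 1L) * H * W
  flat <- function(rr, cc) base + (cc - 1L) * H + rr
  list(H = H, W = W, C = C, H2 = H2, W2 = W2,
       slots = list(flat(2L * r - 1L, 2L * c - 1L),
                    flat(2L * r, 2L * c - 1L),
                    flat(2L * r - 1L, 2L * c),
                    flat(2L * r, 2L * c)))
}

pool_forward <- function(layer, X) {
  s <- layer$slots
  a1 <- X[, s[[1]], drop = FALSE]; a2 <- X[, s[[2]], drop = FALSE]
  a3 <- X[, s[[3]], drop = FALSE]; a4 <- X[, s[[4]], drop = FALSE]
  out <- pmax(a1, a2, a3, a4)
  sel <- 1L + (a2 == out & a1 < out) * 1L +
    (a3 == out & a1 < out & a2 < out) * 2L +
    (a4 == out & a1 < out & a2 < out & a3 < out) * 3L
  list(out = out, sel = sel)
}

pool_backward <- function(layer, cache, dOut, n_in_cols) {
  dX <- matrix(0, nrow(dOut), n_in_cols)
  for (k in 1:4)
    dX[, layer$slots[[k]]] <- dOut * (cache$sel == k)
  dX
}

relu_forward <- function(X) pmax(X, 0)
relu_backward <- function(X_pre, dOut) dOut * (X_pre > 0)

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable binary cross-entropy on logits
bce_loss <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
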