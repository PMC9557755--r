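# Neural-network primitives used by the CLAPA and encoder stacks: batched
# LSTM layers, per-sequence multi-head self-attention, layer normalization,
# softmax cross-entropy and Adam.  Forward passes cache what the matching
# backward pass needs; parameters and gradients live in flat named lists of
# numeric arrays so one Adam routine serves every model.
#
# All of this is plain R over BLAS-backed matrix products; determinism
# given a seed is part of the contract (no dropout anywhere).

sigmoid <- function(x) 1 / (1 + exp(-x))

# Xavier-uniform init using the caller's RNG state.
xavier <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

addbias <- function(Z, b) Z + matrix(b, nrow(Z), length(b), byrow = TRUE)

row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

## ---- LSTM ------------------------------------------------------------
# One layer over a batch: X is a list of T matrices [B, d_in]; weights
# W [(d_in + h), 4h] with gate column order input, forget, candidate,
# output; hidden and cell states start at zero.

lstm_init <- function(d_in, h) {
  W <- xavier(d_in + h, 4L * h)
  b <- numeric(4L * h)
  # forget-gate bias 1: standard stabilization for short-sequence training
  b[(h + 1L):(2L * h)] <- 1
  list(W = W, b = b)
}

lstm_forward <- function(X, W, b) {
  Tn <- length(X); B <- nrow(X[[1L]]); h <- ncol(W) / 4L
  hs <- vector("list", Tn); cache <- vector("list", Tn)
  h_prev <- matrix(0, B, h); c_prev <- matrix(0, B, h)
  idx_i <- 1:h; idx_f <- (h + 1L):(2L * h)
  idx_g <- (2L * h + 1L):(3L * h); idx_o <- (3L * h + 1L):(4L * h)
  for (t in seq_len(Tn)) {
    inp <- cbind(X[[t]], h_prev)
    Z <- addbias(inp %*% W, b)
    i <- sigmoid(Z[, idx_i, drop = FALSE])
    f <- sigmoid(Z[, idx_f, drop = FALSE])
    g <- tanh(Z[, idx_g, drop = FALSE])
    o <- sigmoid(Z[, idx_o, drop = FALSE])
    c_t <- f * c_prev + i * g
    tc <- tanh(c_t)
    h_t <- o * tc
    cache[[t]] <- list(inp = inp, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, tc = tc)
    hs[[t]] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  list(h = hs, cache = cache)
}

lstm_backward <- function(dH, cache, W) {
  Tn <- length(dH); h <- ncol(W) / 4L
  d_in <- nrow(W) - h
  B <- nrow(dH[[1L]])
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(ncol(W))
  dX <- vector("list", Tn)
  dh_next <- matrix(0, B, h); dc_next <- matrix(0, B, h)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- dH[[t]] + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$inp, dZ)
    db <- db + colSums(dZ)
    dInp <- tcrossprod(dZ, W)
    dX[[t]] <- dInp[, seq_len(d_in), drop = FALSE]
    dh_next <- dInp[, (d_in + 1L):(d_in + h), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- Multi-head self-attention (per sequence) ------------------------
# X is [n, d]; heads partition the d columns into d/heads slices.

mha_init <- function(d) {
  list(Wq = xavier(d, d), bq = numeric(d),
       Wk = xavier(d, d), bk = numeric(d),
       Wv = xavier(d, d), bv = numeric(d),
       Wo = xavier(d, d), bo = numeric(d))
}

mha_forward <- function(X, p, heads) {
  d <- ncol(X); dk <- d %/% heads
  Q <- addbias(X %*% p$Wq, p$bq)
  K <- addbias(X %*% p$Wk, p$bk)
  V <- addbias(X %*% p$Wv, p$bv)
  O <- matrix(0, nrow(X), d)
  A <- vector("list", heads)
  for (hh in seq_len(heads)) {
    cols <- ((hh - 1L) * dk + 1L):(hh * dk)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dk)
    A[[hh]] <- row_softmax(S)
    O[, cols] <- A[[hh]] %*% V[, cols, drop = FALSE]
  }
  out <- addbias(O %*% p$Wo, p$bo)
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, A = A, O = O))
}

mha_backward <- function(dout, cache, p, heads) {
  X <- cache$X; d <- ncol(X); dk <- d %/% heads
  g <- list(Wo = crossprod(cache$O, dout), bo = colSums(dout))
  dO <- tcrossprod(dout, p$Wo)
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (hh in seq_len(heads)) {
    cols <- ((hh - 1L) * dk + 1L):(hh * dk)
    A <- cache$A[[hh]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dk)
  }
  g$Wq <- crossprod(X, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(X, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(X, dV); g$bv <- colSums(dV)
  dX <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  list(dX = dX, grads = g)
}

## ---- Layer norm (per row) --------------------------------------------

ln_init <- function(d) list(g = rep(1, d), b = numeric(d))

ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- addbias(xhat * matrix(g, nrow(X), ncol(X), byrow = TRUE), b)
  list(out = Y, cache = list(xhat = xhat, inv = inv))
}

ln_backward <- function(dY, cache, g) {
  n <- nrow(dY); d <- ncol(dY)
  xhat <- cache$xhat
  dxhat <- dY * matrix(g, n, d, byrow = TRUE)
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

## ---- Softmax cross-entropy -------------------------------------------
# logits [B, 2], labels in {0, 1}; returns mean loss and dlogits.

softmax_probs <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, 1L)
  row_softmax(logits)
}

ce_loss_grad <- function(logits, labels) {
  B <- nrow(logits)
  P <- row_softmax(logits)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dP <- P
  dP[idx] <- dP[idx] - 1
  list(loss = loss, dlogits = dP / B)
}

## ---- Adam -------------------------------------------------------------
# params/grads: flat named lists of numeric arrays of matching shapes.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Accumulate grads b into a (element-wise), creating entries as needed.
acc_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}
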