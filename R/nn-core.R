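# Minimal neural-network core: dense / 2-D and 1-D convolution / max-pool /
# LSTM layers with explicit forward and backward passes, and an Adam
# optimizer. The 2-D convolution hot path (patch extraction, scatter-add,
# pooling) runs in compiled code; all matrix products go through BLAS.
#
# Map batches are stored one column per map with linear index
# h + H*w + H*W*c; convolution weights are [filters x 9*C] with column
# c*9 + kernel_offset, matching the compiled im2col layout.

glorot <- function(nin, nout, dims = c(nin, nout)) {
  s <- sqrt(6 / (nin + nout))
  array(runif(prod(dims), -s, s), dim = dims)
}

nn_relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}
nn_relu_bwd <- function(d, cache) d * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- 2-D convolution (3x3, same padding) ---------------------------------

# X: [H*W*C, N]; W: [F, 9C]; returns out [H*W*F, N]. The input is kept in
# the cache; the backward pass recomputes the per-map patch buffers.
conv2_fwd <- function(X, W, b, H, Wd, C) {
  list(out = cpp_conv3_fwd(X, W, as.numeric(b), H, Wd, C), X = X)
}

conv2_bwd <- function(dOut, cache, W, H, Wd, C, N) {
  r <- cpp_conv3_bwd(cache$X, dOut, W, H, Wd, C)
  list(dX = r$dX, dW = r$dW, db = as.numeric(r$db))
}

# --- 1-D convolution (same padding, odd kernel) --------------------------

# X: [T*C, N] with linear index t + T*c; W: [F, k*C]
conv1_fwd <- function(X, W, b, T_, C, k) {
  N <- ncol(X)
  half <- (k - 1) %/% 2
  # padded index matrix: rows k*C, cols T*N
  Xp <- rbind(X)  # no-op; padding handled via index clamping + zero mask
  P <- matrix(0, k * C, T_ * N)
  for (ko in seq_len(k)) {
    off <- ko - 1 - half
    src <- (1:T_) + off
    ok <- src >= 1 & src <= T_
    for (c in seq_len(C)) {
      row <- (c - 1) * k + ko
      block <- matrix(0, T_, N)
      block[ok, ] <- X[src[ok] + T_ * (c - 1), , drop = FALSE]
      P[row, ] <- as.vector(block)
    }
  }
  Y <- W %*% P + b                      # [F, T*N]
  Fn <- nrow(W)
  dim(Y) <- c(Fn, T_, N)
  Y <- aperm(Y, c(2, 1, 3))
  dim(Y) <- c(T_ * Fn, N)
  list(out = Y, P = P)
}

conv1_bwd <- function(dOut, cache, W, T_, C, k, N) {
  Fn <- nrow(W); half <- (k - 1) %/% 2
  dY <- dOut
  dim(dY) <- c(T_, Fn, N)
  dY <- aperm(dY, c(2, 1, 3))
  dim(dY) <- c(Fn, T_ * N)
  dW <- tcrossprod(dY, cache$P)
  db <- rowSums(dY)
  dP <- crossprod(W, dY)                # [k*C, T*N]
  dX <- matrix(0, T_ * C, N)
  for (ko in seq_len(k)) {
    off <- ko - 1 - half
    src <- (1:T_) + off
    ok <- src >= 1 & src <= T_
    for (c in seq_len(C)) {
      row <- (c - 1) * k + ko
      block <- matrix(dP[row, ], T_, N)
      tgt <- src[ok] + T_ * (c - 1)
      dX[tgt, ] <- dX[tgt, ] + block[ok, , drop = FALSE]
    }
  }
  list(dX = dX, dW = dW, db = db)
}

# 1-D max pooling by factor p over the time axis; X [T*C, N]
pool1_fwd <- function(X, T_, C, p) {
  N <- ncol(X)
  To <- T_ %/% p
  dim(X) <- c(p, To, C, N)
  out <- X[1, , , , drop = FALSE]
  arg <- array(1L, dim = c(1, To, C, N))
  for (j in 2:p) {
    upd <- X[j, , , , drop = FALSE] > out
    out[upd] <- X[j, , , , drop = FALSE][upd]
    arg[upd] <- j
  }
  dim(out) <- c(To * C, N)
  list(out = out, arg = arg, p = p, T_ = T_, C = C)
}

pool1_bwd <- function(dOut, cache) {
  p <- cache$p; T_ <- cache$T_; C <- cache$C
  N <- ncol(dOut); To <- T_ %/% p
  dX <- array(0, dim = c(p, To, C, N))
  dim(dOut) <- c(1, To, C, N)
  for (j in seq_len(p)) {
    sel <- cache$arg == j
    tmp <- array(0, dim = c(1, To, C, N))
    tmp[sel] <- dOut[sel]
    dX[j, , , ] <- tmp
  }
  dim(dX) <- c(T_ * C, N)
  dX
}

# --- LSTM ----------------------------------------------------------------

lstm_init <- function(d_in, h) {
  list(Wx = glorot(d_in, 4 * h), Wh = glorot(h, 4 * h, c(h, 4 * h)),
       b = {b <- numeric(4 * h); b[(h + 1):(2 * h)] <- 1; b})  # forget bias 1
}

# X: list of K matrices [N, d_in]; returns last hidden state [N, h].
# The input projection for all K steps is batched into one gemm.
lstm_fwd <- function(X, par) {
  h <- ncol(par$Wh) / 4
  K <- length(X)
  N <- nrow(X[[1]])
  Xall <- do.call(rbind, X)               # [K*N, d_in]
  XW <- Xall %*% par$Wx                   # [K*N, 4h]
  B <- matrix(par$b, N, 4 * h, byrow = TRUE)
  H <- matrix(0, N, h); Cc <- matrix(0, N, h)
  caches <- vector("list", K)
  for (k in seq_len(K)) {
    Z <- XW[((k - 1) * N + 1):(k * N), , drop = FALSE] + H %*% par$Wh + B
    i <- sigmoid(Z[, 1:h, drop = FALSE])
    f <- sigmoid(Z[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(Z[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(Z[, (3 * h + 1):(4 * h), drop = FALSE])
    C_new <- f * Cc + i * g
    tc <- tanh(C_new)
    H_new <- o * tc
    caches[[k]] <- list(i = i, f = f, g = g, o = o, C_prev = Cc, H_prev = H,
                        tc = tc)
    H <- H_new; Cc <- C_new
  }
  list(out = H, caches = caches, Xall = Xall)
}

# dH: gradient wrt last hidden state
lstm_bwd <- function(dH, fw, par) {
  h <- ncol(dH); K <- length(fw$caches); N <- nrow(dH)
  db <- numeric(4 * h)
  dZall <- matrix(0, K * N, 4 * h)
  tWh <- t(par$Wh)
  dC <- matrix(0, N, h)
  for (k in K:1) {
    ca <- fw$caches[[k]]
    dO <- dH * ca$tc
    dC <- dC + dH * ca$o * (1 - ca$tc^2)
    dI <- dC * ca$g
    dF <- dC * ca$C_prev
    dG <- dC * ca$i
    dZ <- cbind(dI * ca$i * (1 - ca$i),
                dF * ca$f * (1 - ca$f),
                dG * (1 - ca$g^2),
                dO * ca$o * (1 - ca$o))
    dZall[((k - 1) * N + 1):(k * N), ] <- dZ
    dWh_k <- crossprod(ca$H_prev, dZ)
    if (k == K) dWh <- dWh_k else dWh <- dWh + dWh_k
    db <- db + colSums(dZ)
    dH <- dZ %*% tWh
    dC <- dC * ca$f
  }
  dWx <- crossprod(fw$Xall, dZall)
  dXall <- tcrossprod(dZall, par$Wx)      # [K*N, d_in]
  dX <- lapply(seq_len(K), function(k) dXall[((k - 1) * N + 1):(k * N), , drop = FALSE])
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# --- heads and losses ----------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    new <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (is.null(dim(params[[nm]]))) new <- as.numeric(new)  # keep plain vectors
    params[[nm]] <- new
  }
  list(params = params, state = state)
}
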