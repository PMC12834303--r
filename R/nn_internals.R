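# Internal layer math for the next-base network. All forward passes cache
# what their backward passes need; batches are dense arrays (B, T, C) and the
# heavy lifting is BLAS matrix products. Nothing here is exported.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- 1-D convolution over time (input channels = 4) -------------------------

# X: array (B, L, Cin). Returns list(out = (B*Lout x Cout) matrix, Xcol, Lout).
.conv1d_forward <- function(X, W, b, kernel, stride, padding) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; Cin <- d[3L]
  Lout <- (L + 2L * padding - kernel) %/% stride + 1L
  if (Lout < 1L) stop("convolution output length < 1", call. = FALSE)
  Z <- array(0, dim = c(B, Lout, kernel * Cin))
  t_out <- seq_len(Lout)
  for (k in seq_len(kernel)) {
    pos <- (t_out - 1L) * stride + (k - 1L) - padding + 1L  # 1-based input pos
    ok <- pos >= 1L & pos <= L
    cols <- (k - 1L) * Cin + seq_len(Cin)
    if (any(ok)) Z[, t_out[ok], cols] <- X[, pos[ok], , drop = FALSE]
  }
  Zmat <- matrix(Z, nrow = B * Lout)     # row (b,t) pairing preserved
  out <- Zmat %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = out, Xcol = Zmat, Lout = Lout, B = B)
}

# dOut: (B*Lout x Cout). Input gradient not needed (conv is the first layer).
.conv1d_backward <- function(cache, dOut) {
  list(dW = crossprod(cache$Xcol, dOut), db = colSums(dOut))
}

# ---- batch normalisation over channels (rows = B*T observations) ------------

.bn_forward <- function(X, gamma, beta, eps, training, run_mean, run_var,
                        momentum = 0.1) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu, "-")
    v <- colMeans(xc * xc)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- sweep(X, 2L, mu, "-")
    new_mean <- run_mean; new_var <- run_var
  }
  sd_inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, sd_inv, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, xhat = xhat, sd_inv = sd_inv, gamma = gamma,
       run_mean = new_mean, run_var = new_var, training = training)
}

.bn_backward <- function(cache, dY) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  if (cache$training) {
    t1 <- sweep(dY, 2L, colSums(dY) / n, "-")
    t2 <- sweep(cache$xhat, 2L, colSums(dY * cache$xhat) / n, "*")
    dX <- sweep(t1 - t2, 2L, cache$gamma * cache$sd_inv, "*")
  } else {
    dX <- sweep(dY, 2L, cache$gamma * cache$sd_inv, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- max pooling over time, non-overlapping windows -------------------------

# X: array (B, L, C); returns (B, T, C) with T = floor(L / pool).
.maxpool_forward <- function(X, pool) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; C <- d[3L]
  T <- L %/% pool
  if (T < 1L) stop("pool window larger than sequence", call. = FALSE)
  out <- X[, seq(1L, by = pool, length.out = T), , drop = FALSE]
  arg <- array(1L, dim = c(B, T, C))
  if (pool > 1L) {
    for (k in 2:pool) {
      cand <- X[, seq(k, by = pool, length.out = T), , drop = FALSE]
      upd <- cand > out
      out[upd] <- cand[upd]
      arg[upd] <- k
    }
  }
  list(out = out, arg = arg, pool = pool, L = L)
}

.maxpool_backward <- function(cache, dOut) {
  d <- dim(dOut); B <- d[1L]; T <- d[2L]; C <- d[3L]
  dX <- array(0, dim = c(B, cache$L, C))
  for (k in seq_len(cache$pool)) {
    mask <- cache$arg == k
    slice <- array(0, dim = dim(dOut))
    slice[mask] <- dOut[mask]
    dX[, seq(k, by = cache$pool, length.out = T), ] <- slice
  }
  dX
}

# ---- LSTM (one direction) ---------------------------------------------------

# Xs: list over t of (B x D) matrices. W: (D + H) x 4H, gate order i,f,g,o.
.lstm_forward <- function(Xs, W, b, H, reverse = FALSE) {
  T <- length(Xs); B <- nrow(Xs[[1L]])
  order_t <- if (reverse) rev(seq_len(T)) else seq_len(T)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", T); cache <- vector("list", T)
  bmat <- matrix(b, B, length(b), byrow = TRUE)
  for (t in order_t) {
    Zin <- cbind(Xs[[t]], h)
    A <- Zin %*% W + bmat
    i <- .sigmoid(A[, 1:H, drop = FALSE])
    f <- .sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(A[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    hs[[t]] <- h
    cache[[t]] <- list(Zin = Zin, i = i, f = f, g = g, o = o,
                       c = cc, c_prev = c_prev, tc = tc)
  }
  list(hs = hs, cache = cache, order_t = order_t, H = H, D = ncol(Xs[[1L]]))
}

# dHs: list over t of (B x H) gradients on the hidden outputs.
.lstm_backward <- function(fwd, W, dHs) {
  T <- length(dHs); H <- fwd$H; D <- fwd$D
  B <- nrow(dHs[[1L]])
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(ncol(W))
  dXs <- vector("list", T)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(fwd$order_t)) {
    cc <- fwd$cache[[t]]
    dh <- dHs[[t]] + dh_next
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    do <- dh * cc$tc * cc$o * (1 - cc$o)
    di <- dc * cc$g * cc$i * (1 - cc$i)
    df <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dg <- dc * cc$i * (1 - cc$g^2)
    dA <- cbind(di, df, dg, do)
    dW <- dW + crossprod(cc$Zin, dA)
    db <- db + colSums(dA)
    dZin <- dA %*% t(W)
    dXs[[t]] <- dZin[, seq_len(D), drop = FALSE]
    dh_next <- dZin[, D + seq_len(H), drop = FALSE]
    dc_next <- dc * cc$f
  }
  list(dW = dW, db = db, dXs = dXs)
}

# Bidirectional layer: separate weight sets per direction, outputs concatenated.
.bilstm_forward <- function(Xs, Wf, bf, Wb, bb, H) {
  fwd <- .lstm_forward(Xs, Wf, bf, H, reverse = FALSE)
  bwd <- .lstm_forward(Xs, Wb, bb, H, reverse = TRUE)
  hs <- lapply(seq_along(Xs), function(t) cbind(fwd$hs[[t]], bwd$hs[[t]]))
  list(hs = hs, fwd = fwd, bwd = bwd, H = H)
}

.bilstm_backward <- function(cache, Wf, Wb, dHs) {
  H <- cache$H
  dfwd <- lapply(dHs, function(m) m[, seq_len(H), drop = FALSE])
  dbwd <- lapply(dHs, function(m) m[, H + seq_len(H), drop = FALSE])
  gf <- .lstm_backward(cache$fwd, Wf, dfwd)
  gb <- .lstm_backward(cache$bwd, Wb, dbwd)
  dXs <- lapply(seq_along(dHs), function(t) gf$dXs[[t]] + gb$dXs[[t]])
  list(dWf = gf$dW, dbf = gf$db, dWb = gb$dW, dbb = gb$db, dXs = dXs)
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

.adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
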