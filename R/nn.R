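# Internal neural-network primitives. Activations are arrays of dimension
# (side, side, channels, batch); convolutions are evaluated as matrix products
# via im2col so the heavy lifting happens in BLAS. Everything here is
# deterministic given the R RNG state.

# im2col index matrix for one (side x side) padded plane: rows are output
# positions in column-major order, columns are the f*f kernel offsets.
.im2col_plane_index <- function(side, f, pad) {
  sp <- side + 2L * pad
  oi <- rep(seq_len(side), times = side)
  oj <- rep(seq_len(side), each = side)
  idx <- matrix(0L, nrow = side * side, ncol = f * f)
  q <- 0L
  for (dj in 0:(f - 1L)) for (di in 0:(f - 1L)) {
    q <- q + 1L
    idx[, q] <- (oj + dj - 1L) * sp + (oi + di)
  }
  idx
}

# Full im2col index for an array (sp, sp, C, B) flattened: rows ordered as
# B blocks of side*side output positions, columns as C blocks of f*f offsets.
.im2col_index <- function(side, f, pad, C, B) {
  sp <- side + 2L * pad
  plane <- .im2col_plane_index(side, f, pad)
  n <- nrow(plane)
  rows <- plane[rep(seq_len(n), times = B), rep(seq_len(f * f), times = C)]
  boff <- rep.int((seq_len(B) - 1L) * C * sp * sp, rep.int(n, B))
  coff <- rep.int((seq_len(C) - 1L) * sp * sp, rep.int(f * f, C))
  rows + outer(boff, coff, `+`)
}

.pad_input <- function(A, pad) {
  d <- dim(A)
  sp <- d[1] + 2L * pad
  P <- array(0, dim = c(sp, sp, d[3], d[4]))
  P[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- A
  P
}

# Convolution forward: A (s,s,Cin,B), W (f*f*Cin, Cout), b (Cout).
# Returns list(out = (s,s,Cout,B), cache for backward).
conv_forward <- function(A, W, b, f = 5L, pad = 2L) {
  d <- dim(A)
  s <- d[1]; Cin <- d[3]; B <- d[4]
  P <- .pad_input(A, pad)
  I <- .im2col_index(s, f, pad, Cin, B)
  Xc <- matrix(P[I], nrow = nrow(I))
  Y <- Xc %*% W
  Y <- sweep(Y, 2L, b, `+`)
  out <- aperm(array(Y, dim = c(s, s, B, ncol(W))), c(1, 2, 4, 3))
  list(out = out, Xc = Xc, I = I, dimA = d, f = f, pad = pad)
}

conv_backward <- function(dOut, W, cache) {
  d <- cache$dimA
  s <- d[1]; Cin <- d[3]; B <- d[4]
  f <- cache$f; pad <- cache$pad
  Cout <- ncol(W)
  dY <- matrix(aperm(dOut, c(1, 2, 4, 3)), nrow = s * s * B, ncol = Cout)
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- tcrossprod(dY, W)
  sp <- s + 2L * pad
  dP <- numeric(sp * sp * Cin * B)
  I <- cache$I
  for (q in seq_len(ncol(I))) {       # per column, target indices are distinct
    ii <- I[, q]
    dP[ii] <- dP[ii] + dXc[, q]
  }
  dP <- array(dP, dim = c(sp, sp, Cin, B))
  dA <- dP[pad + seq_len(s), pad + seq_len(s), , , drop = FALSE]
  list(dA = dA, dW = dW, db = db)
}

relu_forward <- function(A) list(out = pmax(A, 0), mask = A > 0)
relu_backward <- function(dOut, cache) dOut * cache$mask

# 2x2 max pooling, stride 2. Ties route the gradient to the first of the four
# candidates in the fixed order (1,1), (2,1), (1,2), (2,2).
pool_forward <- function(A) {
  s <- dim(A)[1]
  o <- seq(1L, s, by = 2L); e <- o + 1L
  a11 <- A[o, o, , , drop = FALSE]; a21 <- A[e, o, , , drop = FALSE]
  a12 <- A[o, e, , , drop = FALSE]; a22 <- A[e, e, , , drop = FALSE]
  M <- pmax(a11, a21, a12, a22)
  m11 <- a11 == M
  m21 <- (a21 == M) & !m11
  m12 <- (a12 == M) & !(m11 | m21)
  m22 <- !(m11 | m21 | m12)
  list(out = M, masks = list(m11, m21, m12, m22), dimA = dim(A))
}

pool_backward <- function(dOut, cache) {
  d <- cache$dimA
  s <- d[1]
  o <- seq(1L, s, by = 2L); e <- o + 1L
  dA <- array(0, dim = d)
  m <- cache$masks
  dA[o, o, , ] <- dOut * m[[1]]
  dA[e, o, , ] <- dOut * m[[2]]
  dA[o, e, , ] <- dOut * m[[3]]
  dA[e, e, , ] <- dOut * m[[4]]
  dA
}

# Dense layer on (B x Din) matrices.
fc_forward <- function(X, W, b) {
  Y <- X %*% W
  list(out = sweep(Y, 2L, b, `+`), X = X)
}
fc_backward <- function(dOut, W, cache) {
  list(dX = tcrossprod(dOut, W),
       dW = crossprod(cache$X, dOut),
       db = colSums(dOut))
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean categorical cross-entropy over the batch; y is 1-based class index.
cross_entropy <- function(P, y) {
  p <- P[cbind(seq_len(nrow(P)), y)]
  -mean(log(pmax(p, 1e-12)))
}

# He-initialized parameters for the configured network.
nn_init_params <- function(config) {
  f <- config$kernel
  side <- 2L^config$k
  chans <- c(3L, config$conv_channels)
  params <- list()
  for (i in seq_along(config$conv_channels)) {
    fan_in <- f * f * chans[i]
    params[[paste0("Wc", i)]] <-
      matrix(stats::rnorm(fan_in * chans[i + 1], sd = sqrt(2 / fan_in)),
             nrow = fan_in)
    params[[paste0("bc", i)]] <- numeric(chans[i + 1])
    side <- side %/% 2L
  }
  flat <- side * side * chans[length(chans)]
  params$Wf1 <- matrix(stats::rnorm(flat * config$fc_units,
                                    sd = sqrt(2 / flat)), nrow = flat)
  params$bf1 <- numeric(config$fc_units)
  params$Wf2 <- matrix(stats::rnorm(config$fc_units * config$n_classes,
                                    sd = sqrt(2 / config$fc_units)),
                       nrow = config$fc_units)
  params$bf2 <- numeric(config$n_classes)
  params
}

# Forward pass. X: (side, side, 3, B). Returns class probabilities and, when
# `keep` is TRUE, the caches needed for backprop and the per-layer shapes.
nn_forward <- function(params, X, config, keep = FALSE) {
  nb <- length(config$conv_channels)
  caches <- list(); shapes <- list(input = dim(X)[1:3])
  A <- X
  for (i in seq_len(nb)) {
    cv <- conv_forward(A, params[[paste0("Wc", i)]], params[[paste0("bc", i)]],
                       f = config$kernel, pad = config$pad)
    rl <- relu_forward(cv$out)
    pl <- pool_forward(rl$out)
    shapes[[paste0("conv", i)]] <- dim(cv$out)[1:3]
    shapes[[paste0("pool", i)]] <- dim(pl$out)[1:3]
    if (keep) caches[[i]] <- list(conv = cv, relu = rl, pool = pl)
    A <- pl$out
  }
  dflat <- prod(dim(A)[1:3])
  B <- dim(A)[4]
  Xf <- t(matrix(A, nrow = dflat, ncol = B))
  f1 <- fc_forward(Xf, params$Wf1, params$bf1)
  r1 <- relu_forward(f1$out)
  f2 <- fc_forward(r1$out, params$Wf2, params$bf2)
  P <- softmax(f2$out)
  list(probs = P,
       caches = if (keep) list(blocks = caches, f1 = f1, r1 = r1, f2 = f2,
                               dimA = dim(A)) else NULL,
       shapes = shapes)
}

# Backward pass from softmax + cross-entropy; y is 1-based class index.
nn_backward <- function(params, fw, y, config) {
  P <- fw$probs
  B <- nrow(P)
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ / B
  grads <- list()
  g2 <- fc_backward(dZ, params$Wf2, fw$caches$f2)
  grads$Wf2 <- g2$dW; grads$bf2 <- g2$db
  dH <- relu_backward(g2$dX, fw$caches$r1)
  g1 <- fc_backward(dH, params$Wf1, fw$caches$f1)
  grads$Wf1 <- g1$dW; grads$bf1 <- g1$db
  dA <- array(t(g1$dX), dim = fw$caches$dimA)
  for (i in rev(seq_along(config$conv_channels))) {
    blk <- fw$caches$blocks[[i]]
    dA <- pool_backward(dA, blk$pool)
    dA <- relu_backward(dA, blk$relu)
    gc_ <- conv_backward(dA, params[[paste0("Wc", i)]], blk$conv)
    grads[[paste0("Wc", i)]] <- gc_$dW
    grads[[paste0("bc", i)]] <- gc_$db
    dA <- gc_$dA
  }
  grads
}

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
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
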