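# Internal neural-network primitives. All activations use the
# (channels, length, batch) array layout; the depthwise convolution kernels
# live in src/dwconv.cpp. Backward passes are hand derived and checked
# against finite differences in the test suite.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

same_pad <- function(k) (k - 1L) %/% 2L

conv_out_len <- function(L, k, stride, pad = same_pad(k)) {
  (L + 2L * pad - k) %/% stride + 1L
}

# pointwise (1x1) convolution: channel mixing, shared across positions
pw_fw <- function(X, W, b) {
  d <- dim(X)
  Y <- W %*% matrix(X, d[1], d[2] * d[3]) + b
  array(Y, c(nrow(W), d[2], d[3]))
}

pw_bw <- function(X, W, G) {
  d <- dim(X)
  Gm <- matrix(G, nrow(W), d[2] * d[3])
  Xm <- matrix(X, d[1], d[2] * d[3])
  list(dX = array(crossprod(W, Gm), d),
       dW = tcrossprod(Gm, Xm),
       db = rowSums(Gm))
}

# adaptive average pooling matrix (P x L); row i averages the window
# [floor((i-1)L/P) + 1, ceiling(iL/P)], the standard adaptive scheme
pool_matrix <- function(L, P) {
  A <- matrix(0, P, L)
  for (i in seq_len(P)) {
    s <- floor((i - 1) * L / P) + 1L
    e <- ceiling(i * L / P)
    A[i, s:e] <- 1 / (e - s + 1L)
  }
  A
}

pool_fw <- function(X, A) {
  d <- dim(X)
  Y <- array(0, c(d[1], nrow(A), d[3]))
  for (n in seq_len(d[3])) Y[, , n] <- X[, , n, drop = FALSE][, , 1] %*% t(A)
  Y
}

pool_bw <- function(G, A, L) {
  d <- dim(G)
  dX <- array(0, c(d[1], L, d[3]))
  for (n in seq_len(d[3])) dX[, , n] <- G[, , n, drop = FALSE][, , 1] %*% A
  dX
}

# sum over the length (middle) dimension of a (C, L, N) array -> (C, N)
sum_mid <- function(X) {
  d <- dim(X)
  matrix(colSums(matrix(aperm(X, c(2L, 1L, 3L)), d[2])), d[1], d[3])
}

# expand a (C, N) matrix to (C, L, N) by repeating along the length axis
expand_mid <- function(M, L) {
  aperm(array(M, c(nrow(M), ncol(M), L)), c(1L, 3L, 2L))
}

# squeeze-and-excitation: global average pool -> FC bottleneck (ReLU) ->
# FC expand (sigmoid) -> channel-wise rescale
se_fw <- function(X, p) {
  d <- dim(X)
  s <- sum_mid(X) / d[2]
  a1 <- p$W1 %*% s + p$b1
  z1 <- relu(a1)
  g <- sigmoid(p$W2 %*% z1 + p$b2)
  garr <- expand_mid(g, d[2])
  list(Y = X * garr, s = s, a1 = a1, z1 = z1, g = g, garr = garr)
}

se_bw <- function(X, p, cache, G) {
  d <- dim(X)
  dX <- G * cache$garr
  dg <- sum_mid(G * X)
  dpre2 <- dg * cache$g * (1 - cache$g)
  dW2 <- tcrossprod(dpre2, cache$z1)
  db2 <- rowSums(dpre2)
  dz1 <- crossprod(p$W2, dpre2)
  dz1[cache$a1 <= 0] <- 0
  dW1 <- tcrossprod(dz1, cache$s)
  db1 <- rowSums(dz1)
  ds <- crossprod(p$W1, dz1)
  dX <- dX + expand_mid(ds / d[2], d[2])
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# standard (full) 1-D convolution, used by the stem (in_c = 1, via channel
# tiling + depthwise) and by the plain-CNN ablation blocks. W is an array
# (C_out, C_in, k).
fullconv_fw <- function(X, W, b, stride) {
  d <- dim(X)
  k <- dim(W)[3]
  pad <- same_pad(k)
  Lo <- conv_out_len(d[2], k, stride, pad)
  Xp <- array(0, c(d[1], d[2] + 2 * pad, d[3]))
  Xp[, pad + seq_len(d[2]), ] <- X
  Y <- array(rep(b, Lo * d[3]), c(dim(W)[1], Lo, d[3]))
  for (j in seq_len(k)) {
    idx <- seq.int(j, by = stride, length.out = Lo)
    Xs <- matrix(Xp[, idx, , drop = FALSE], d[1], Lo * d[3])
    Wj <- matrix(W[, , j], dim(W)[1], d[1])
    Y <- Y + array(Wj %*% Xs, c(dim(W)[1], Lo, d[3]))
  }
  Y
}

fullconv_bw <- function(X, W, G, stride) {
  d <- dim(X)
  k <- dim(W)[3]
  pad <- same_pad(k)
  Lo <- dim(G)[2]
  Xp <- array(0, c(d[1], d[2] + 2 * pad, d[3]))
  Xp[, pad + seq_len(d[2]), ] <- X
  dXp <- array(0, dim(Xp))
  dW <- array(0, dim(W))
  Gm <- matrix(G, dim(W)[1], Lo * d[3])
  for (j in seq_len(k)) {
    idx <- seq.int(j, by = stride, length.out = Lo)
    Xs <- matrix(Xp[, idx, , drop = FALSE], d[1], Lo * d[3])
    dW[, , j] <- tcrossprod(Gm, Xs)
    dXs <- array(crossprod(matrix(W[, , j], dim(W)[1], d[1]), Gm),
                 c(d[1], Lo, d[3]))
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + dXs
  }
  list(dX = dXp[, pad + seq_len(d[2]), , drop = FALSE],
       dW = dW, db = rowSums(Gm))
}

# ---- parameter-tree helpers -------------------------------------------------

ps_flatten <- function(x) {
  if (is.null(x)) return(numeric(0))
  if (is.numeric(x)) return(as.numeric(x))
  unlist(lapply(x, ps_flatten), use.names = FALSE)
}

ps_unflatten <- function(template, v) {
  pos <- 0L
  fill <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.numeric(x)) {
      n <- length(x)
      out <- v[pos + seq_len(n)]
      pos <<- pos + n
      dim(out) <- dim(x)
      return(out)
    }
    lapply(x, fill)
  }
  out <- fill(template)
  stopifnot(pos == length(v))
  out
}

ps_count <- function(x) length(ps_flatten(x))

# elementwise a + s * b over a parameter tree (b may contain NULLs matching a)
ps_axpy <- function(a, b, s = 1) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) {
    if (is.null(b)) return(a)
    return(a + s * b)
  }
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- ps_axpy(a[[nm]], b[[nm]], s)
  out
}

# ---- Adam optimizer ---------------------------------------------------------
# Moment buffers mirror the parameter tree and are updated in place by the
# fused C++ kernel; parameters come back as fresh tensors.

ps_zeros_like <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) {
    z <- numeric(length(x))
    dim(z) <- dim(x)
    return(z)
  }
  lapply(x, ps_zeros_like)
}

adam_walk <- function(p, g, m, v, t, lr) {
  if (is.null(p)) return(NULL)
  if (is.numeric(p))
    return(.adam_tensor(p, g, m, v, t, lr, 0.9, 0.999, 1e-8))
  out <- p
  for (i in seq_along(p)) out[[i]] <- adam_walk(p[[i]], g[[i]], m[[i]],
                                                v[[i]], t, lr)
  out
}
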