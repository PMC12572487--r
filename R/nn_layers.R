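# Low-level differentiable layers (forward + hand-written backward).
#
# Parameters are plain numeric arrays in nested lists; every *_bwd returns
# gradient structures mirroring the parameter structure plus the gradient
# with respect to the layer input. Dropout uses the current R RNG (seeded
# once per training run).

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(out = x * mask, mask = mask)
}

dropout_vec_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  list(out = x * mask, mask = mask)
}

# Batch normalization over the node dimension, per feature, within one graph
# (instance-norm style: deterministic at eval time, no running statistics).
bn_fwd <- function(X, gamma, beta, eps = 1e-5) {
  n <- nrow(X)
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  v <- colMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, `*`)
  out <- sweep(xhat, 2, gamma, `*`)
  out <- sweep(out, 2, beta, `+`)
  list(out = out, xhat = xhat, inv_sd = inv_sd, xc = xc, n = n)
}

bn_bwd <- function(dout, cache, gamma) {
  n <- cache$n
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, `*`)
  # dX = inv_sd/n * (n*dxhat - colSums(dxhat) - xhat * colSums(dxhat * xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- n * dxhat
  dX <- sweep(dX, 2, s1)
  dX <- dX - sweep(cache$xhat, 2, s2, `*`)
  dX <- sweep(dX, 2, cache$inv_sd / n, `*`)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Dense layer on a row vector: out = x %*% W + b  (x length d_in, W d_in x d_out)
dense_fwd <- function(x, W, b) {
  list(out = as.vector(x %*% W) + b, x = x)
}

dense_bwd <- function(dout, cache, W) {
  list(dW = outer(cache$x, dout), db = dout, dx = as.vector(W %*% dout))
}

# Two-layer MLP with ReLU hidden, used for GHOP/HOP heads and the ESFE stem.
mlp2_init <- function(d_in, d_hidden, d_out) {
  list(W1 = glorot(d_in, d_hidden), b1 = numeric(d_hidden),
       W2 = glorot(d_hidden, d_out), b2 = numeric(d_out))
}

mlp2_fwd <- function(x, p) {
  a1 <- dense_fwd(x, p$W1, p$b1)
  r1 <- relu_fwd(a1$out)
  a2 <- dense_fwd(r1$out, p$W2, p$b2)
  list(out = a2$out, a1 = a1, r1 = r1, a2 = a2)
}

# With defer_w1 = TRUE the rank-one W1 gradient (the large input layer) is
# not materialized per call; its factors (x, d) are returned instead so a
# batch accumulator can form sum_i outer(x_i, d_i) with one crossprod.
mlp2_bwd <- function(dout, cache, p, defer_w1 = FALSE) {
  g2 <- dense_bwd(dout, cache$a2, p$W2)
  dr1 <- g2$dx * cache$r1$mask
  if (defer_w1) {
    list(grads = list(W1 = NULL, b1 = dr1, W2 = g2$dW, b2 = g2$db),
         dx = as.vector(p$W1 %*% dr1),
         xd = list(x = cache$a1$x, d = dr1))
  } else {
    g1 <- dense_bwd(dr1, cache$a1, p$W1)
    list(grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db),
         dx = g1$dx, xd = NULL)
  }
}

# Defer threshold: W1 gradients at or above this size are batched.
DEFER_MIN_LEN <- 32768L

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# ---- 1D convolution -------------------------------------------------------

# Precomputed patch plan: idx[(c,j), t] = linear index into the (in_ch x L_in)
# input matrix of channel c, input position (t-1)*stride + j. Memoized: plans
# are reused thousands of times per training run.
.plan_cache <- new.env(parent = emptyenv())
conv1d_plan <- function(n_in, in_ch, kernel, stride) {
  key <- paste(n_in, in_ch, kernel, stride, sep = "_")
  hit <- .plan_cache[[key]]
  if (!is.null(hit)) return(hit)
  plan <- conv1d_plan_build(n_in, in_ch, kernel, stride)
  .plan_cache[[key]] <- plan
  plan
}

conv1d_plan_build <- function(n_in, in_ch, kernel, stride) {
  if (n_in < kernel) {
    abort_mhnet(sprintf("input length %d shorter than kernel %d", n_in, kernel),
                "mhnet_shape_error")
  }
  L_out <- (n_in - kernel) %/% stride + 1L
  pos <- outer(seq_len(kernel), (seq_len(L_out) - 1L) * stride, `+`)  # kernel x L_out
  idx <- matrix(0L, in_ch * kernel, L_out)
  for (j in seq_len(kernel)) {
    rows <- (j - 1L) * in_ch + seq_len(in_ch)
    idx[rows, ] <- rep((pos[j, ] - 1L) * in_ch, each = in_ch) + seq_len(in_ch)
  }
  list(L_out = L_out, idx = idx, pos = pos, n_in = n_in, in_ch = in_ch,
       kernel = kernel, stride = stride)
}

# X: in_ch x L_in matrix; W: out_ch x (in_ch*kernel); b: out_ch.
# (idx is flattened before subsetting: a 2-column index matrix would
# otherwise be taken as coordinate pairs.)
conv1d_fwd <- function(X, W, b, plan) {
  P <- matrix(X[as.vector(plan$idx)], nrow(plan$idx), plan$L_out)
  out <- W %*% P + b
  list(out = out, P = P)
}

conv1d_bwd <- function(dout, cache, W, plan) {
  dW <- tcrossprod(dout, cache$P)
  db <- rowSums(dout)
  dP <- crossprod(W, dout)
  dX <- matrix(0, plan$in_ch, plan$n_in)
  # scatter-add by kernel offset: for fixed offset j the input positions of
  # successive windows are distinct, so each pass is a plain vectorized add
  for (j in seq_len(plan$kernel)) {
    rows <- (j - 1L) * plan$in_ch + seq_len(plan$in_ch)
    cols <- plan$pos[j, ]
    dX[, cols] <- dX[, cols] + dP[rows, , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

#' Valid-padding 1D convolution (cross-correlation)
#'
#' Computes `y[o, i] = sum_{c,j} w[o, c, j] x[c, i*stride + j] + b[o]` with no
#' padding and no kernel flip, so output length is
#' `floor((len - kernel)/stride) + 1`.
#'
#' @param x Numeric vector (single channel) or channels-by-length matrix.
#' @param params List with `weights` (array `out_ch x in_ch x kernel` or an
#'   `out_ch x (in_ch*kernel)` matrix), `bias` (length `out_ch`), and `stride`
#'   (default 1).
#' @return Matrix `out_ch x L_out`.
#' @export
conv1d <- function(x, params) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  w <- params$weights
  stride <- params$stride %||% 1L
  if (length(dim(w)) == 3) {
    out_ch <- dim(w)[1]; in_ch <- dim(w)[2]; kernel <- dim(w)[3]
    W <- matrix(0, out_ch, in_ch * kernel)
    for (j in seq_len(kernel)) W[, (j - 1) * in_ch + seq_len(in_ch)] <- w[, , j]
  } else {
    W <- w
    in_ch <- nrow(X)
    kernel <- ncol(W) / in_ch
    out_ch <- nrow(W)
  }
  if (nrow(X) != in_ch) {
    abort_mhnet("input channel count does not match kernel", "mhnet_shape_error")
  }
  plan <- conv1d_plan(ncol(X), in_ch, kernel, stride)
  conv1d_fwd(X, W, params$bias %||% numeric(out_ch), plan)$out
}

# ---- symmetric-matrix flatten helpers -------------------------------------

#' Row-major strict upper-triangle vectorization
#'
#' Flattens a symmetric matrix to `(C12, ..., C1N, C23, ..., C2N, ..., C_{N-1,N})`,
#' length `N(N-1)/2`.
#'
#' @param C Square matrix, symmetric within `tol`.
#' @param tol Symmetry tolerance.
#' @return Numeric vector of length `N(N-1)/2`.
#' @export
upper_tri_vector <- function(C, tol = 1e-8) {
  check_square_symmetric(C, "C", tol = tol)
  idx <- ut_pairs(nrow(C))
  C[idx]
}

#' Scatter an upper-triangle vector back into a symmetric matrix
#'
#' Inverse of [upper_tri_vector()] (diagonal set to `diag_value`).
#'
#' @param v Vector of length `N(N-1)/2`.
#' @param n Matrix size N.
#' @param diag_value Diagonal fill (default 1).
#' @return Symmetric `n x n` matrix.
#' @export
upper_tri_scatter <- function(v, n, diag_value = 1) {
  M <- diag(diag_value, n)
  idx <- ut_pairs(n)
  M[idx] <- v
  M[idx[, 2:1, drop = FALSE]] <- v
  M
}

# Flatten including the diagonal (for Gram matrices), row-major.
ut_diag_vector <- function(G) {
  G[ut_pairs(nrow(G), diag = TRUE)]
}

# Backward of ut_diag_vector: dv -> dG contribution M0 (upper incl diag).
ut_diag_scatter_grad <- function(dv, n) {
  M0 <- matrix(0, n, n)
  M0[ut_pairs(n, diag = TRUE)] <- dv
  M0
}
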