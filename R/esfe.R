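# Euclidean branch: FC vectorization, two-layer 1D convolution stack, MLP
# stem, high-order pooling (HOP) and fused Euclidean features.

#' Outer-product high-order pooling of a feature vector
#'
#' @param z Numeric vector of length d.
#' @return `z %o% z`: symmetric, PSD, rank <= 1 d x d matrix.
#' @export
hop <- function(z) {
  z <- as.numeric(z)
  outer(z, z)
}

glorot_conv <- function(out_ch, in_ch, kernel) {
  lim <- sqrt(6 / (in_ch * kernel + out_ch))
  matrix(stats::runif(out_ch * in_ch * kernel, -lim, lim), out_ch, in_ch * kernel)
}

esfe_init <- function(fc_dim, config) {
  ch <- config$conv_channels
  ks <- config$conv_kernels
  st <- config$conv_strides
  plan1 <- conv1d_plan(fc_dim, 1L, ks[1], st[1])
  plan2 <- conv1d_plan(plan1$L_out, ch[1], ks[2], st[2])
  flat_dim <- ch[2] * plan2$L_out
  d <- config$d
  tri <- if ((config$hop_mode %||% "outer") == "channel_gram") {
    ch[2] * (ch[2] + 1) / 2
  } else {
    d * (d + 1) / 2
  }
  params <- list(
    conv1 = list(W = glorot_conv(ch[1], 1L, ks[1]), b = numeric(ch[1])),
    conv2 = list(W = glorot_conv(ch[2], ch[1], ks[2]), b = numeric(ch[2])),
    fc = mlp2_init(flat_dim, config$fc_hidden, d),
    hop_mlp = mlp2_init(tri, d, d))
  list(params = params, plans = list(plan1, plan2), flat_dim = flat_dim)
}

# Forward. x: FC upper-triangle vector; plans precomputed at init.
esfe_fwd <- function(x, p, plans, config, training, high_order = TRUE) {
  c1 <- conv1d_fwd(matrix(x, 1), p$conv1$W, p$conv1$b, plans[[1]])
  r1 <- relu_fwd(c1$out)
  c2 <- conv1d_fwd(r1$out, p$conv2$W, p$conv2$b, plans[[2]])
  r2 <- relu_fwd(c2$out)
  flat <- as.vector(r2$out)
  fc <- mlp2_fwd(flat, p$fc)
  z <- fc$out
  mode <- config$hop_mode %||% "outer"
  if (high_order) {
    v <- if (mode == "channel_gram") {
      ut_diag_vector(tcrossprod(r2$out))
    } else {
      ut_diag_vector(outer(z, z))
    }
    hm <- mlp2_fwd(v, p$hop_mlp)
    out <- c(z, hm$out)
  } else {
    hm <- NULL
    out <- z
  }
  list(out = out, c1 = c1, r1 = r1, c2 = c2, r2 = r2, fc = fc, z = z, hm = hm,
       high_order = high_order, mode = mode)
}

esfe_bwd <- function(dout, cache, p, plans, want_input_grad = FALSE,
                     defer = FALSE) {
  d <- length(cache$z)
  dz <- dout[seq_len(d)]
  dr2_extra <- NULL
  xd <- list()
  if (cache$high_order) {
    dg <- dout[(d + 1):length(dout)]
    hb <- mlp2_bwd(dg, cache$hm, p$hop_mlp,
                   defer_w1 = defer && length(p$hop_mlp$W1) >= DEFER_MIN_LEN)
    xd$hop <- hb$xd
    if (cache$mode == "channel_gram") {
      M0 <- ut_diag_scatter_grad(hb$dx, nrow(cache$r2$out))
      dr2_extra <- (M0 + t(M0)) %*% cache$r2$out
    } else {
      M0 <- ut_diag_scatter_grad(hb$dx, d)
      dz <- dz + as.vector((M0 + t(M0)) %*% cache$z)
    }
    hop_grads <- hb$grads
  } else {
    hop_grads <- tree_zeros_like(p$hop_mlp)
  }
  fb <- mlp2_bwd(dz, cache$fc, p$fc,
                 defer_w1 = defer && length(p$fc$W1) >= DEFER_MIN_LEN)
  xd$fc <- fb$xd
  dflat <- matrix(fb$dx, nrow(cache$r2$out))
  if (!is.null(dr2_extra)) dflat <- dflat + dr2_extra
  dr2 <- dflat * cache$r2$mask
  g2 <- conv1d_bwd(dr2, cache$c2, p$conv2$W, plans[[2]])
  dr1 <- g2$dX * cache$r1$mask
  g1 <- conv1d_bwd(dr1, cache$c1, p$conv1$W, plans[[1]])
  list(grads = list(conv1 = list(W = g1$dW, b = g1$db),
                    conv2 = list(W = g2$dW, b = g2$db),
                    fc = fb$grads, hop_mlp = hop_grads),
       dx = if (want_input_grad) as.vector(g1$dX) else NULL,
       dr1 = if (want_input_grad) dr1 else NULL,
       xd = xd)
}

#' Forward pass of the Euclidean (ESFE) branch
#'
#' Vectorizes the strict upper triangle of the FC matrix, applies two valid
#' 1D convolutions with ReLU, an MLP stem producing first-order features
#' `Z_fc` of length d, then HOP and the HOP MLP head:
#' `concat(Z_fc, MLP(uppertri(hop(Z_fc))))`, length `2 d`. With
#' `config$hop_mode = "channel_gram"` the Gram matrix over conv-channel
#' feature maps feeds the MLP instead of the outer product of `Z_fc`.
#'
#' @param C Symmetric FC matrix (N x N).
#' @param params ESFE parameter subtree (see [mhnet_init()]).
#' @param config A [mhnet_config()]; its conv settings must match the ones the
#'   parameters were initialized with.
#' @param training Logical mode flag (the branch has no dropout; kept for
#'   interface symmetry).
#' @return Numeric vector of length `2 * config$d`.
#' @export
esfe_forward <- function(C, params, config, training = FALSE) {
  x <- upper_tri_vector(C)
  plan1 <- conv1d_plan(length(x), 1L, config$conv_kernels[1], config$conv_strides[1])
  plan2 <- conv1d_plan(plan1$L_out, config$conv_channels[1], config$conv_kernels[2],
                       config$conv_strides[2])
  esfe_fwd(x, params, list(plan1, plan2), config, training, high_order = TRUE)$out
}
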