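# Non-Euclidean branch: residual ChebConv blocks, adaptive feature maps (AFM),
# graph high-order pooling (GHOP), per-level and fused graph embeddings.

#' Symmetric normalized and rescaled graph Laplacian
#'
#' `L = I - D^{-1/2} A D^{-1/2}` with `D` the row-sum degree (self-loops
#' included), and `L_tilde = 2 L / lambda_max - I` whose spectrum lies in
#' \[-1, 1\].
#'
#' @param A Symmetric non-negative adjacency with unit diagonal.
#' @return List of class `graph_laplacian`: `L`, `L_tilde`, `lambda_max`.
#' @export
scaled_laplacian <- function(A) {
  check_square_symmetric(A, "A")
  if (any(A < 0)) abort_mhnet("adjacency must be non-negative", "mhnet_validation_error")
  d <- rowSums(A)
  ds <- 1 / sqrt(d)
  L <- diag(nrow(A)) - (ds * A) %*% diag(ds, nrow(A))
  L <- (L + t(L)) / 2
  lambda_max <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_max <= 0) lambda_max <- 2  # edgeless graph: L = 0, fall back
  Lt <- 2 * L / lambda_max - diag(nrow(A))
  structure(list(L = L, L_tilde = Lt, lambda_max = lambda_max),
            class = "graph_laplacian")
}

# Chebyshev polynomial matrices T_0..T_{K-1} of L_tilde (recurrence
# T_k = 2 L_tilde T_{k-1} - T_{k-2}, T_0 = I, T_1 = L_tilde).
cheb_polynomials <- function(L_tilde, K) {
  n <- nrow(L_tilde)
  Tk <- vector("list", K)
  Tk[[1]] <- diag(n)
  if (K >= 2) Tk[[2]] <- L_tilde
  if (K >= 3) {
    for (k in 3:K) Tk[[k]] <- 2 * L_tilde %*% Tk[[k - 1]] - Tk[[k - 2]]
  }
  Tk
}

#' K-order Chebyshev spectral graph convolution
#'
#' `sum_{k=0}^{K-1} T_k(L_tilde) H theta_k` with the standard recurrence
#' `T_0 = I`, `T_1 = L_tilde`, `T_k = 2 L_tilde T_{k-1} - T_{k-2}`.
#'
#' @param H Node-feature matrix (n x d_in).
#' @param lap A [scaled_laplacian()] (or list with `L_tilde`).
#' @param theta List of K coefficient matrices (d_in x d_out).
#' @param K Chebyshev order; defaults to `length(theta)`.
#' @return Matrix n x d_out.
#' @export
cheb_conv <- function(H, lap, theta, K = length(theta)) {
  if (K < 1) abort_mhnet("K must be >= 1", "mhnet_config_error")
  Tk <- cheb_polynomials(lap$L_tilde, K)
  d_out <- ncol(theta[[1]])
  out <- matrix(0, nrow(H), d_out)
  for (k in seq_len(K)) {
    if (nrow(theta[[k]]) != ncol(H)) {
      abort_mhnet("theta dimensions do not match feature dimension", "mhnet_shape_error")
    }
    out <- out + (Tk[[k]] %*% H) %*% theta[[k]]
  }
  out
}

cheb_block_init <- function(d_in, d_out, K) {
  list(theta = lapply(seq_len(K), function(k) glorot(d_in, d_out)),
       bn_gamma = rep(1, d_out), bn_beta = numeric(d_out),
       proj = if (d_in != d_out) glorot(d_in, d_out) else NULL)
}

# Forward through one residual ChebConv block.
# Tk: precomputed polynomial matrices for this graph.
cheb_block_fwd <- function(H, Tk, p, dropout, training, use_bn = TRUE) {
  K <- length(p$theta)
  TH <- vector("list", K)
  C <- matrix(0, nrow(H), ncol(p$theta[[1]]))
  for (k in seq_len(K)) {
    TH[[k]] <- Tk[[k]] %*% H
    C <- C + TH[[k]] %*% p$theta[[k]]
  }
  if (use_bn) {
    bn <- bn_fwd(C, p$bn_gamma, p$bn_beta)
    act_in <- bn$out
  } else {
    bn <- NULL
    act_in <- C
  }
  r <- relu_fwd(act_in)
  dr <- dropout_fwd(r$out, dropout, training)
  res <- if (is.null(p$proj)) H else H %*% p$proj
  list(out = dr$out + res, TH = TH, bn = bn, r = r, dr = dr, H = H,
       use_bn = use_bn)
}

cheb_block_bwd <- function(dout, cache, Tk, p) {
  K <- length(p$theta)
  # residual path
  if (is.null(p$proj)) {
    dH <- dout
    dproj <- NULL
  } else {
    dH <- dout %*% t(p$proj)
    dproj <- crossprod(cache$H, dout)
  }
  dr <- if (is.null(cache$dr$mask)) dout else dout * cache$dr$mask
  dact <- dr * cache$r$mask
  if (cache$use_bn) {
    bnb <- bn_bwd(dact, cache$bn, p$bn_gamma)
    dC <- bnb$dX
    dgamma <- bnb$dgamma; dbeta <- bnb$dbeta
  } else {
    dC <- dact
    dgamma <- numeric(length(p$bn_gamma)); dbeta <- numeric(length(p$bn_beta))
  }
  dtheta <- vector("list", K)
  for (k in seq_len(K)) {
    dtheta[[k]] <- crossprod(cache$TH[[k]], dC)
    dH <- dH + Tk[[k]] %*% (dC %*% t(p$theta[[k]]))
  }
  list(grads = list(theta = dtheta, bn_gamma = dgamma, bn_beta = dbeta,
                    proj = dproj),
       dH = dH)
}

#' Residual ChebConv block
#'
#' `H' = Dropout(ReLU(BN(cheb_conv(H)))) + P(H)` where `P` is the identity
#' when input and output widths match, else a learned linear projection.
#'
#' @param H Node features (n x d_in).
#' @param lap A [scaled_laplacian()].
#' @param params Block parameters from the model initializer: `theta` (list of
#'   K matrices), `bn_gamma`, `bn_beta`, optional `proj`.
#' @param dropout Dropout rate (active only when `training = TRUE`).
#' @param training Logical mode flag.
#' @param use_bn Apply the per-graph batch normalization (default `TRUE`).
#' @return Matrix n x d_out.
#' @export
cheb_block <- function(H, lap, params, dropout = 0, training = FALSE,
                       use_bn = TRUE) {
  Tk <- cheb_polynomials(lap$L_tilde, length(params$theta))
  cheb_block_fwd(H, Tk, params, dropout, training, use_bn)$out
}

#' Adaptive feature maps: softmax-weighted block aggregation
#'
#' `Z = sum_l softmax(r)[l] * H^(l)`; the weights always form a probability
#' vector, whatever the logits.
#'
#' @param H_list List of equally shaped node-embedding matrices.
#' @param r Numeric logits, one per matrix.
#' @return List with `Z` and the softmax `weights`.
#' @export
afm_aggregate <- function(H_list, r) {
  if (length(H_list) != length(r)) {
    abort_mhnet("need one logit per feature map", "mhnet_shape_error")
  }
  dims <- vapply(H_list, dim, integer(2))
  if (any(dims != dims[, 1])) {
    abort_mhnet("all feature maps must share the same shape", "mhnet_shape_error")
  }
  s <- softmax_vec(r)
  Z <- Reduce(`+`, Map(function(w, H) w * H, s, H_list))
  list(Z = Z, weights = s)
}

#' Graph high-order pooling (Gram matrix of node embeddings)
#'
#' @param Z Node-embedding matrix (n x d_h).
#' @return `t(Z) %*% Z`, a symmetric PSD d_h x d_h matrix.
#' @export
ghop <- function(Z) crossprod(as.matrix(Z))

hgnn_level_init <- function(d_in, d_h, K, n_blocks) {
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    blocks[[b]] <- cheb_block_init(if (b == 1) d_in else d_h, d_h, K)
  }
  tri <- d_h * (d_h + 1) / 2
  list(blocks = blocks,
       afm_r = stats::rnorm(n_blocks, 0, 0.01),
       ghop_mlp = mlp2_init(tri, d_h, d_h))
}

# Full forward for one level. inputs: list(H0, Tk).
level_fwd <- function(inputs, p, config, training, high_order = TRUE) {
  H <- inputs$H0
  caches <- vector("list", length(p$blocks))
  H_list <- vector("list", length(p$blocks))
  for (b in seq_along(p$blocks)) {
    caches[[b]] <- cheb_block_fwd(H, inputs$Tk, p$blocks[[b]], config$dropout,
                                  training, config$use_bn %||% TRUE)
    H <- caches[[b]]$out
    H_list[[b]] <- H
  }
  afm <- afm_aggregate(H_list, p$afm_r)
  Z <- afm$Z
  readout <- colMeans(Z)
  if (high_order) {
    G <- crossprod(Z)
    v <- ut_diag_vector(G)
    mlp <- mlp2_fwd(v, p$ghop_mlp)
    fused <- c(readout, mlp$out)
  } else {
    mlp <- NULL
    fused <- readout
  }
  list(out = fused, caches = caches, H_list = H_list, afm = afm, Z = Z,
       mlp = mlp, high_order = high_order)
}

level_bwd <- function(dout, cache, inputs, p, want_input_grad = FALSE,
                      defer = FALSE) {
  n <- nrow(cache$Z)
  d_h <- ncol(cache$Z)
  dreadout <- dout[seq_len(d_h)]
  dZ <- matrix(dreadout / n, n, d_h, byrow = TRUE)
  xd <- NULL
  if (cache$high_order) {
    dg <- dout[(d_h + 1):length(dout)]
    mb <- mlp2_bwd(dg, cache$mlp, p$ghop_mlp,
                   defer_w1 = defer && length(p$ghop_mlp$W1) >= DEFER_MIN_LEN)
    M0 <- ut_diag_scatter_grad(mb$dx, d_h)
    dZ <- dZ + cache$Z %*% (M0 + t(M0))
    ghop_grads <- mb$grads
    xd <- mb$xd
  } else {
    ghop_grads <- tree_zeros_like(p$ghop_mlp)
  }
  # AFM backward
  s <- cache$afm$weights
  nb <- length(p$blocks)
  ds <- vapply(seq_len(nb), function(l) sum(cache$H_list[[l]] * dZ), numeric(1))
  dr_afm <- s * (ds - sum(s * ds))
  dH_next <- s[nb] * dZ
  block_grads <- vector("list", nb)
  for (b in rev(seq_len(nb))) {
    bb <- cheb_block_bwd(dH_next, cache$caches[[b]], inputs$Tk, p$blocks[[b]])
    block_grads[[b]] <- bb$grads
    dH_next <- bb$dH
    if (b > 1) dH_next <- dH_next + s[b - 1] * dZ
  }
  list(grads = list(blocks = block_grads, afm_r = dr_afm, ghop_mlp = ghop_grads),
       dH0 = if (want_input_grad) dH_next else NULL,
       ghop_xd = xd)
}

#' Forward pass of one graph level
#'
#' Runs the residual ChebConv stack, AFM aggregation, mean-node readout, GHOP
#' and the GHOP MLP head, returning the fused level embedding
#' `concat(readout, MLP(uppertri(ghop(Z))))` of length `2 d_h`.
#'
#' @param level A `brain_graph_level`.
#' @param params Level parameter subtree (see [mhnet_init()]).
#' @param config A [mhnet_config()].
#' @param training Logical mode flag.
#' @return List of class `level_embedding`: `Z` (node embeddings), `readout`,
#'   `ghop` (Gram matrix), `fused`.
#' @export
level_forward <- function(level, params, config, training = FALSE) {
  lap <- scaled_laplacian(level$adjacency)
  inputs <- list(H0 = level$node_features,
                 Tk = cheb_polynomials(lap$L_tilde, config$K))
  fw <- level_fwd(inputs, params, config, training, high_order = TRUE)
  structure(list(Z = fw$Z, readout = colMeans(fw$Z), ghop = crossprod(fw$Z),
                 fused = fw$out),
            class = "level_embedding")
}

#' Forward pass of the full HGNN branch
#'
#' Concatenates the fused embeddings of the WAN, MAN and LAN level networks
#' (separate parameters per level), length `6 d_h`.
#'
#' @param views A `multiview_graph_set`.
#' @param params HGNN parameter subtree (see [mhnet_init()]).
#' @param config A [mhnet_config()].
#' @param training Logical mode flag.
#' @return Numeric vector of length `6 * config$d_h`.
#' @export
hgnn_forward <- function(views, params, config, training = FALSE) {
  unlist(lapply(c("wan", "man", "lan"), function(lv) {
    level_forward(views[[lv]], params[[lv]], config, training)$fused
  }), use.names = FALSE)
}
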