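# Independent oracles used across test files.

# RV coefficient straight from the trace formula, forming AA' and BB'
# explicitly (quadratic in the series length, unlike the implementation).
rv_brute <- function(A, B, center = TRUE) {
  if (center) {
    A <- sweep(A, 2, colMeans(A))
    B <- sweep(B, 2, colMeans(B))
  }
  AA <- A %*% t(A)
  BB <- B %*% t(B)
  sum(diag(AA %*% BB)) / sqrt(sum(diag(AA %*% AA)) * sum(diag(BB %*% BB)))
}

# Spectral-domain Chebyshev filtering via explicit eigendecomposition:
# out = sum_k U T_k(Lambda_tilde) U' H theta_k.
cheb_spectral_oracle <- function(H, L_tilde, theta) {
  eg <- eigen((L_tilde + t(L_tilde)) / 2, symmetric = TRUE)
  U <- eg$vectors
  lam <- eg$values
  K <- length(theta)
  Tl <- vector("list", K)
  Tl[[1]] <- rep(1, length(lam))
  if (K >= 2) Tl[[2]] <- lam
  if (K >= 3) for (k in 3:K) Tl[[k]] <- 2 * lam * Tl[[k - 1]] - Tl[[k - 2]]
  out <- 0
  for (k in seq_len(K)) {
    out <- out + (U %*% (Tl[[k]] * t(U))) %*% H %*% theta[[k]]
  }
  out
}

# Plain double-loop valid cross-correlation (Eq.-style indexing).
conv1d_loop_oracle <- function(x, w, b, stride) {
  n <- length(w)
  L_out <- (length(x) - n) %/% stride + 1
  vapply(seq_len(L_out), function(i) {
    s <- (i - 1) * stride
    sum(w * x[s + seq_len(n)]) + b
  }, numeric(1))
}

# Random symmetric "RV-like" matrix with unit diagonal, entries in [0, 1].
random_rv_matrix <- function(n) {
  R <- matrix(runif(n * n), n, n)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

# Random connected-ish adjacency with unit diagonal for Laplacian tests.
random_adjacency <- function(n, p_edge = 0.5) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- ifelse(runif(sum(up)) < p_edge, runif(sum(up)), 0)
  A <- A + t(A)
  diag(A) <- 1
  A
}

# Analytic maximum-curvature location of the min-max-normalized exponential
# f(g) = exp(-g / s) sampled on [0, g_max]: curvature of
# y(x) = (exp(-a x) - m) / (1 - m), a = g_max/s, maximized over a fine grid
# of the exact expression.
exp_knee_analytic <- function(s = 0.1, g_max = 0.99) {
  a <- g_max / s
  m <- exp(-a)
  xs <- seq(0, 1, length.out = 200001)
  yp <- -a * exp(-a * xs) / (1 - m)
  ypp <- a^2 * exp(-a * xs) / (1 - m)
  kappa <- abs(ypp) / (1 + yp^2)^1.5
  xs[which.max(kappa)] * g_max
}

# Tiny hierarchy data frame builder.
tiny_hierarchy_df <- function() {
  data.frame(
    region_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    cluster_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
    network_id = c("A", "A", "A", "A", "B", "B"),
    stringsAsFactors = FALSE)
}

# Small random subject for a given hierarchy.
random_subject <- function(hierarchy, n_time = 30, voxels = 3, id = "s1") {
  sig <- lapply(hierarchy$regions, function(r) matrix(rnorm(n_time * voxels), n_time))
  names(sig) <- hierarchy$regions
  region_voxel_signals(id, sig)
}
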