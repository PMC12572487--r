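# Connectivity statistics: RV coefficient, Pearson FC, adjacency thresholding
# and the retained-edge-curve knee selection of the sparsification cutoff.

#' RV coefficient between two multivariate signals
#'
#' The RV coefficient generalizes squared correlation to matrices sharing
#' rows (time points): `RV(A, B) = Tr(AA'BB') / sqrt(Tr[(AA')^2] Tr[(BB')^2])`.
#' It is computed on column-centered inputs by default (the classical
#' definition; uncentered signals with a common nonzero mean saturate toward
#' 1). Evaluated through cross-products, `Tr(AA'BB') = ||B'A||_F^2`, so cost
#' scales with voxel counts rather than the squared series length.
#'
#' @param A,B Numeric matrices (time x voxels) with the same row count.
#' @param center Column-center the inputs first (default `TRUE`).
#' @return A scalar in \[0, 1\] (up to floating-point spill, clipped).
#' @export
rv_coefficient <- function(A, B, center = TRUE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) {
    abort_mhnet("A and B must share the same number of time points", "mhnet_shape_error")
  }
  if (nrow(A) < 3) abort_mhnet("need at least 3 time points", "mhnet_validation_error")
  check_finite(A, "A"); check_finite(B, "B")
  if (center) {
    A <- sweep(A, 2, colMeans(A))
    B <- sweep(B, 2, colMeans(B))
  }
  den_a <- sum(crossprod(A)^2)
  den_b <- sum(crossprod(B)^2)
  if (den_a == 0 || den_b == 0) {
    abort_mhnet("degenerate input: all-constant matrix gives a zero denominator",
                "mhnet_degenerate_error")
  }
  num <- sum(crossprod(B, A)^2)
  min(1, max(0, num / sqrt(den_a * den_b)))
}

#' RV coefficient matrix over a list of signal matrices
#'
#' @param signals Named list of (time x voxels) matrices sharing row count.
#' @param center Passed to [rv_coefficient()].
#' @return Symmetric matrix with unit diagonal, dimnames from `signals`.
#' @export
rv_matrix <- function(signals, center = TRUE) {
  n <- length(signals)
  ids <- names(signals) %||% sprintf("n%d", seq_len(n))
  if (center) {
    signals <- lapply(signals, function(m) sweep(as.matrix(m), 2, colMeans(m)))
  }
  cp <- lapply(signals, function(m) as.matrix(m))
  dens <- vapply(cp, function(m) sum(crossprod(m)^2), numeric(1))
  if (any(dens == 0)) {
    abort_mhnet(sprintf("degenerate (all-constant) signal for node '%s'",
                        ids[dens == 0][1]), "mhnet_degenerate_error")
  }
  R <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        num <- sum(crossprod(cp[[j]], cp[[i]])^2)
        R[i, j] <- R[j, i] <- min(1, max(0, num / sqrt(dens[i] * dens[j])))
      }
    }
  }
  dimnames(R) <- list(ids, ids)
  R
}

#' Pearson functional-connectivity matrix
#'
#' @param series A `region_mean_series` or a numeric matrix (time x regions).
#' @return Symmetric correlation matrix with exact unit diagonal, entries
#'   clipped to \[-1, 1\].
#' @export
pearson_fc <- function(series) {
  if (inherits(series, "region_mean_series")) {
    M <- series$series
  } else {
    M <- as.matrix(series)
  }
  check_finite(M, "series")
  v <- apply(M, 2, stats::var)
  if (any(v == 0)) {
    nm <- (colnames(M) %||% as.character(seq_len(ncol(M))))[v == 0][1]
    abort_mhnet(sprintf("zero-variance series for region '%s'", nm),
                "mhnet_degenerate_error")
  }
  C <- stats::cor(M)
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  C
}

#' Threshold a connectivity matrix into a sparse adjacency
#'
#' Keeps `R[i,j]` where it strictly exceeds `gamma`, sets the diagonal to 1
#' and everything else to 0.
#'
#' @param R Symmetric matrix with entries in \[0, 1\].
#' @param gamma Sparsity cutoff in \[0, 1).
#' @return Symmetric adjacency matrix with unit diagonal.
#' @export
threshold_adjacency <- function(R, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0 || gamma >= 1) {
    abort_mhnet("gamma must be a single value in [0, 1)", "mhnet_config_error")
  }
  check_square_symmetric(R, "R")
  A <- ifelse(R > gamma, R, 0)
  diag(A) <- 1
  A
}

#' Retained-edge curve over a cutoff grid
#'
#' For each candidate cutoff, the fraction of strictly-upper-triangle entries
#' of `R` that survive thresholding (strict `>`). Non-increasing in gamma by
#' construction.
#'
#' @param R Symmetric matrix with entries in \[0, 1\].
#' @param grid Strictly increasing cutoff candidates (default 0 to 0.99 by
#'   0.01).
#' @return An object of class `retained_edge_curve` (also a data frame with
#'   columns `gamma` and `retained_fraction`).
#' @export
retained_edge_curve <- function(R, grid = default_gamma_grid()) {
  check_square_symmetric(R, "R")
  if (length(grid) < 1 || any(diff(grid) <= 0)) {
    abort_mhnet("grid must be strictly increasing", "mhnet_config_error")
  }
  up <- R[upper.tri(R)]
  frac <- vapply(grid, function(g) mean(up > g), numeric(1))
  structure(data.frame(gamma = grid, retained_fraction = frac),
            class = c("retained_edge_curve", "data.frame"))
}

#' Default cutoff grid (0.00 to 0.99, step 0.01)
#' @return Numeric vector of 100 candidate cutoffs.
#' @export
default_gamma_grid <- function() seq(0, 0.99, by = 0.01)

#' Select the sparsification cutoff at the knee of the retained-edge curve
#'
#' Kneedle-style: both axes are min-max normalized and the grid point of
#' maximum discrete curvature `|y''| / (1 + y'^2)^(3/2)` (central differences,
#' interior points) is returned; ties break to the smallest gamma. A constant
#' or strictly linear curve has no knee and raises an error, in which case the
#' caller must supply gamma explicitly.
#'
#' @param curve A [retained_edge_curve()] (or data frame with `gamma`,
#'   `retained_fraction`).
#' @return The selected gamma (scalar).
#' @export
select_cutoff <- function(curve) {
  g <- curve$gamma
  y <- curve$retained_fraction
  if (length(g) < 5) abort_mhnet("need at least 5 grid points", "mhnet_validation_error")
  if (max(y) == min(y)) {
    abort_mhnet("retained-edge curve is constant: no knee", "mhnet_no_knee_error")
  }
  x <- (g - min(g)) / (max(g) - min(g))
  yn <- (y - min(y)) / (max(y) - min(y))
  n <- length(x)
  i <- 2:(n - 1)
  h <- diff(x)[1]
  d1 <- (yn[i + 1] - yn[i - 1]) / (2 * h)
  d2 <- (yn[i + 1] - 2 * yn[i] + yn[i - 1]) / h^2
  kappa <- abs(d2) / (1 + d1^2)^1.5
  if (max(kappa) < 1e-8) {
    abort_mhnet("retained-edge curve is linear: no knee", "mhnet_no_knee_error")
  }
  g[i[which.max(kappa)]]
}

#' @rdname select_cutoff
#' @param R Symmetric connectivity matrix; convenience wrapper computing the
#'   curve on `grid` first.
#' @param grid Cutoff grid.
#' @export
select_cutoff_from_matrix <- function(R, grid = default_gamma_grid()) {
  select_cutoff(retained_edge_curve(R, grid))
}
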