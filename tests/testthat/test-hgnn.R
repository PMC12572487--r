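test_that("scaled_laplacian matches closed forms on tiny graphs", {
  # identity adjacency: D = I, L = 0, L_tilde = -I (lambda_max fallback 2)
  lap <- scaled_laplacian(diag(3))
  expect_equal(lap$L, matrix(0, 3, 3))
  expect_equal(lap$L_tilde, -diag(3))

  # fully coupled 2-node graph with self-loops
  A <- matrix(1, 2, 2)
  lap2 <- scaled_laplacian(A)
  expect_equal(lap2$L, diag(2) - A / 2)
  ev <- eigen(lap2$L, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(0, 1))
  evt <- eigen(lap2$L_tilde, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(evt), c(-1, 1))

  expect_error(scaled_laplacian(matrix(c(1, 0.5, 0.2, 1), 2)),
               class = "mhnet_shape_error")
})

test_that("rescaled Laplacian spectrum lies in [-1, 1] on random graphs", {
  set.seed(31)
  for (i in 1:20) {
    A <- random_adjacency(8)
    ev <- eigen(scaled_laplacian(A)$L_tilde, symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-8 & ev <= 1 + 1e-8))
  }
})

test_that("cheb_conv equals spectral filtering and its polynomial identities", {
  set.seed(32)
  # K = 1 ignores the graph
  A <- random_adjacency(5)
  lap <- scaled_laplacian(A)
  H <- matrix(rnorm(15), 5, 3)
  th <- list(matrix(rnorm(6), 3, 2))
  expect_equal(cheb_conv(H, lap, th), H %*% th[[1]])

  # K = 3 vs eigendecomposition oracle
  th3 <- lapply(1:3, function(k) matrix(rnorm(6), 3, 2))
  expect_lt(max(abs(cheb_conv(H, lap, th3) -
                      cheb_spectral_oracle(H, lap$L_tilde, th3))), 1e-6)

  # T_2 recurrence identity
  Tk <- mhnet:::cheb_polynomials(lap$L_tilde, 3)
  expect_lt(max(abs(Tk[[3]] - (2 * lap$L_tilde %*% lap$L_tilde - diag(5)))), 1e-10)

  expect_error(cheb_conv(H, lap, list(matrix(rnorm(8), 4, 2))),
               class = "mhnet_shape_error")
})

test_that("cheb_conv matches the spectral oracle over graphs <= 10 nodes, K <= 4", {
  set.seed(33)
  worst <- 0
  for (i in 1:20) {
    n <- sample(3:10, 1)
    A <- random_adjacency(n)
    lap <- scaled_laplacian(A)
    H <- matrix(rnorm(n * 4), n, 4)
    for (K in 1:4) {
      th <- lapply(seq_len(K), function(k) matrix(rnorm(4 * 3), 4, 3))
      worst <- max(worst, max(abs(cheb_conv(H, lap, th, K) -
                                    cheb_spectral_oracle(H, lap$L_tilde, th))))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("cheb_block residual behaviour: constructed identity doubles, zero theta projects", {
  set.seed(34)
  A <- random_adjacency(4)
  lap <- scaled_laplacian(A)
  H <- abs(matrix(rnorm(12), 4, 3))  # non-negative so ReLU passes
  # theta_0 = I, K = 1, BN off: cheb_conv is the identity, residual doubles
  p <- list(theta = list(diag(3)), bn_gamma = rep(1, 3), bn_beta = numeric(3),
            proj = NULL)
  expect_equal(cheb_block(H, lap, p, dropout = 0, training = FALSE, use_bn = FALSE),
               2 * H)
  # dropout rate 0: train equals eval
  expect_equal(cheb_block(H, lap, p, dropout = 0, training = TRUE, use_bn = FALSE),
               cheb_block(H, lap, p, dropout = 0, training = FALSE, use_bn = FALSE))
  # zeroing theta leaves exactly the (projected) residual
  pz <- list(theta = list(matrix(0, 3, 2), matrix(0, 3, 2)),
             bn_gamma = rep(1, 2), bn_beta = numeric(2),
             proj = matrix(rnorm(6), 3, 2))
  expect_equal(cheb_block(H, lap, pz, dropout = 0.3, training = FALSE), H %*% pz$proj)
})

test_that("afm_aggregate weights are a probability vector and act as expected", {
  set.seed(35)
  Hs <- lapply(1:3, function(i) matrix(rnorm(12), 4, 3))
  # equal logits: plain mean
  out <- afm_aggregate(Hs, c(2, 2, 2))
  expect_equal(out$Z, (Hs[[1]] + Hs[[2]] + Hs[[3]]) / 3)
  # saturated softmax picks one map
  out2 <- afm_aggregate(Hs, c(20, -20, -20))
  expect_lt(max(abs(out2$Z - Hs[[1]])), 1e-8)
  # random logits: sums to one, matches a hand-rolled weighted sum
  for (i in 1:20) {
    r <- rnorm(3, sd = 5)
    o <- afm_aggregate(Hs, r)
    expect_lt(abs(sum(o$weights) - 1), 1e-12)
    s <- exp(r - max(r)); s <- s / sum(s)
    expect_equal(o$Z, s[1] * Hs[[1]] + s[2] * Hs[[2]] + s[3] * Hs[[3]])
  }
  expect_error(afm_aggregate(Hs[1:2], c(1, 2, 3)), class = "mhnet_shape_error")
})

test_that("ghop is a symmetric PSD Gram matrix", {
  Z <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:3]
  expect_equal(ghop(Z), diag(3), tolerance = 1e-12)
  expect_equal(ghop(matrix(0, 4, 2)), matrix(0, 2, 2))
  set.seed(36)
  for (i in 1:20) {
    Z <- matrix(rnorm(24), 6, 4)
    G <- ghop(Z)
    expect_equal(G, t(G))
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    oracle <- matrix(0, 4, 4)
    for (a in 1:6) oracle <- oracle + outer(Z[a, ], Z[a, ])
    expect_equal(G, oracle, tolerance = 1e-12)
  }
})

test_that("level_forward contracts: fused length, single node, permutation invariance", {
  cfg <- mhnet_config(d_h = 6, K = 2, n_blocks = 2, dropout = 0, seed = 1)
  set.seed(37)
  # single-node graph: readout equals the node's embedding row
  lev1 <- mhnet:::new_brain_graph_level("n1", matrix(1, 1, 1),
                                        matrix(0.5, 1, 1), "WAN", "b")
  p1 <- mhnet:::hgnn_level_init(1, cfg$d_h, cfg$K, cfg$n_blocks)
  emb1 <- level_forward(lev1, p1, cfg, training = FALSE)
  expect_equal(emb1$readout, as.vector(emb1$Z))
  expect_length(emb1$fused, 2 * cfg$d_h)

  # permutation of nodes (adjacency, features and node-indexed input weights)
  n <- 5
  A <- random_adjacency(n)
  R <- random_rv_matrix(n)
  lev <- mhnet:::new_brain_graph_level(sprintf("n%d", 1:n), A, R, "LAN", rep("b", n))
  p <- mhnet:::hgnn_level_init(n, cfg$d_h, cfg$K, cfg$n_blocks)
  emb <- level_forward(lev, p, cfg, training = FALSE)

  perm <- sample(n)
  levp <- mhnet:::new_brain_graph_level(lev$node_ids[perm], A[perm, perm],
                                        R[perm, perm], "LAN", rep("b", n))
  pp <- p
  pp$blocks[[1]]$theta <- lapply(p$blocks[[1]]$theta, function(th) th[perm, , drop = FALSE])
  pp$blocks[[1]]$proj <- p$blocks[[1]]$proj[perm, , drop = FALSE]
  embp <- level_forward(levp, pp, cfg, training = FALSE)
  expect_lt(max(abs(embp$readout - emb$readout)), 1e-8)
  expect_lt(max(abs(embp$ghop - emb$ghop)), 1e-8)
})

test_that("hgnn_forward concatenates per-level embeddings with block isolation", {
  h <- read_hierarchy(tiny_hierarchy_df())
  set.seed(38)
  subj <- random_subject(h, n_time = 30)
  views <- build_multiview(subj, h, gammas = 0.05)
  cfg <- mhnet_config(d_h = 8, K = 2, n_blocks = 2, dropout = 0, seed = 2)
  set.seed(2)
  params <- list(
    wan = mhnet:::hgnn_level_init(2, 8, 2, 2),
    man = mhnet:::hgnn_level_init(3, 8, 2, 2),
    lan = mhnet:::hgnn_level_init(6, 8, 2, 2))
  out <- hgnn_forward(views, params, cfg, training = FALSE)
  expect_length(out, 6 * cfg$d_h)
  # eval-mode determinism
  expect_identical(out, hgnn_forward(views, params, cfg, training = FALSE))
  # zeroing LAN parameters changes only the last third
  params_z <- params
  params_z$lan <- mhnet:::tree_map(function(x) x * 0, params$lan)
  out_z <- hgnn_forward(views, params_z, cfg, training = FALSE)
  expect_identical(out_z[1:(4 * cfg$d_h)], out[1:(4 * cfg$d_h)])
  expect_false(identical(out_z[(4 * cfg$d_h + 1):(6 * cfg$d_h)],
                         out[(4 * cfg$d_h + 1):(6 * cfg$d_h)]))
})

test_that("residual blocks keep node-feature variance where plain propagation collapses it", {
  set.seed(39)
  collapse_ratios <- ours <- numeric(5)
  cfg <- mhnet_config(d_h = 6, K = 2, n_blocks = 3, dropout = 0, seed = 1)
  for (i in 1:5) {
    n <- 8
    A <- random_adjacency(n, p_edge = 0.9)
    H <- matrix(rnorm(n * 6), n, 6)
    # row-stochastic propagation (no residuals): three smoothing steps
    P <- A / rowSums(A)
    H3 <- P %*% P %*% P %*% H
    collapse_ratios[i] <- mean(apply(H, 2, var)) / mean(apply(H3, 2, var))
    # our residual stack on the same graph
    lap <- scaled_laplacian(A)
    p <- mhnet:::hgnn_level_init(6, 6, cfg$K, cfg$n_blocks)
    Hc <- H
    for (b in 1:3) {
      Hc <- cheb_block(Hc, lap, p$blocks[[b]], dropout = 0, training = FALSE)
    }
    ours[i] <- mean(apply(Hc, 2, var))
  }
  expect_true(all(collapse_ratios >= 10))
  expect_true(all(ours > 0))
})
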