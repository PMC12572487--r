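# Analytic backpropagation is verified against central finite differences on
# a miniature configuration of the full model (both branches, residual
# projections, batch norm, AFM, GHOP/HOP heads, fusion MLP).

pluck_path <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

poke_path <- function(x, path, val) {
  if (length(path) == 1) {
    x[[path[[1]]]] <- val
    return(x)
  }
  x[[path[[1]]]] <- poke_path(x[[path[[1]]]], path[-1], val)
  x
}

test_that("hand-written gradients match finite differences across every module", {
  set.seed(51)
  sc <- sim_config(n_per_class = 4, n_networks = 2, clusters_per_network = 2,
                   regions_per_cluster = 2, voxels_per_region = 4, n_time = 40,
                   effects = list(list(pair = c(1, 2), delta = 0.4)), seed = 3)
  co <- generate_cohort(sc)
  gcoh <- build_cohort_graphs(co, gamma = 0.05)
  cfg <- mhnet_config(d_h = 7, d = 6, K = 3, n_blocks = 3, dropout = 0,
                      learning_rate = 1e-3, conv_channels = c(2, 3),
                      conv_kernels = c(3, 3), conv_strides = c(1, 2),
                      fc_hidden = 9, fusion_hidden = c(8, 4), seed = 5)
  inputs <- mhnet:::prepare_cohort_inputs(gcoh, cfg)
  set.seed(5)
  params <- mhnet_init(cfg, mhnet:::cohort_dims(gcoh))
  # jitter every parameter so no pre-activation sits exactly on a ReLU kink
  # (zero-initialized biases put entire all-zero windows exactly at zero,
  # where the one-sided subgradient and the central difference must differ)
  params <- mhnet:::tree_map(function(x) x + rnorm(length(x), 0, 0.02), params)
  fw <- mhnet:::model_fwd(inputs[[1]], params, cfg, training = FALSE)
  bw <- mhnet:::model_bwd(mhnet:::dlogits_for(fw$prob, 1L), fw, inputs[[1]],
                          params, cfg)
  loss_fn <- function(p) {
    mhnet:::subject_loss(mhnet:::model_fwd(inputs[[1]], p, cfg, FALSE)$prob, 1L)
  }
  paths <- list(
    list("fusion", "W1"), list("fusion", "b2"), list("fusion", "W3"),
    list("hgnn", "lan", "blocks", 1L, "theta", 1L),
    list("hgnn", "lan", "blocks", 3L, "theta", 3L),
    list("hgnn", "wan", "blocks", 2L, "theta", 2L),
    list("hgnn", "man", "afm_r"),
    list("hgnn", "lan", "ghop_mlp", "W1"), list("hgnn", "wan", "ghop_mlp", "b2"),
    list("hgnn", "wan", "blocks", 1L, "bn_gamma"),
    list("hgnn", "man", "blocks", 2L, "bn_beta"),
    list("hgnn", "man", "blocks", 1L, "proj"),
    list("esfe", "conv1", "W"), list("esfe", "conv2", "b"),
    list("esfe", "fc", "W1"), list("esfe", "fc", "W2"),
    list("esfe", "hop_mlp", "W1"))
  # Central differences at two step sizes: a coordinate whose two estimates
  # disagree sits on a ReLU kink (where the finite difference itself is
  # invalid) and is skipped; everything else must match the analytic value.
  central <- function(path, leaf, k, eps) {
    up <- leaf; up[k] <- up[k] + eps
    dn <- leaf; dn[k] <- dn[k] - eps
    (loss_fn(poke_path(params, path, up)) -
       loss_fn(poke_path(params, path, dn))) / (2 * eps)
  }
  checked <- 0
  for (path in paths) {
    leaf <- pluck_path(params, path)
    g <- pluck_path(bw$grads, path)
    ks <- sample(length(leaf), min(4, length(leaf)))
    for (k in ks) {
      n1 <- central(path, leaf, k, 1e-5)
      n2 <- central(path, leaf, k, 5e-6)
      if (abs(n1 - n2) > 1e-7) next  # kink: finite difference unreliable
      checked <- checked + 1
      expect_lt(abs(n2 - g[k]), 1e-6)
    }
  }
  expect_gt(checked, 40)  # the vast majority of coordinates are smooth
})

test_that("input gradients used for saliency match finite differences", {
  set.seed(52)
  sc <- sim_config(n_per_class = 4, n_networks = 2, clusters_per_network = 2,
                   regions_per_cluster = 2, voxels_per_region = 4, n_time = 40,
                   effects = list(list(pair = c(1, 2), delta = 0.4)), seed = 4)
  co <- generate_cohort(sc)
  gcoh <- build_cohort_graphs(co, gamma = 0.05)
  cfg <- mhnet_config(d_h = 6, d = 5, K = 2, n_blocks = 2, dropout = 0,
                      conv_channels = c(2, 2), conv_kernels = c(3, 3),
                      conv_strides = c(1, 2), fc_hidden = 8,
                      fusion_hidden = c(6, 4), seed = 6)
  inputs <- mhnet:::prepare_cohort_inputs(gcoh, cfg)
  set.seed(6)
  params <- mhnet_init(cfg, mhnet:::cohort_dims(gcoh))
  logit_fn <- function(inp) {
    mhnet:::model_fwd(inp, params, cfg, training = FALSE)$logits[2]
  }
  fw <- mhnet:::model_fwd(inputs[[1]], params, cfg, training = FALSE)
  bw <- mhnet:::model_bwd(c(0, 1), fw, inputs[[1]], params, cfg,
                          want_input_grads = TRUE)
  eps <- 1e-5
  # LAN node-feature gradient
  H0 <- inputs[[1]]$levels$lan$H0
  for (k in sample(length(H0), 5)) {
    inp2 <- inputs[[1]]; inp2$levels$lan$H0[k] <- inp2$levels$lan$H0[k] + eps
    inp3 <- inputs[[1]]; inp3$levels$lan$H0[k] <- inp3$levels$lan$H0[k] - eps
    num <- (logit_fn(inp2) - logit_fn(inp3)) / (2 * eps)
    expect_lt(abs(num - bw$input_grads$dH0_lan[k]), 1e-6)
  }
  # FC-vector gradient
  for (k in sample(length(inputs[[1]]$x_fc), 5)) {
    inp2 <- inputs[[1]]; inp2$x_fc[k] <- inp2$x_fc[k] + eps
    inp3 <- inputs[[1]]; inp3$x_fc[k] <- inp3$x_fc[k] - eps
    num <- (logit_fn(inp2) - logit_fn(inp3)) / (2 * eps)
    expect_lt(abs(num - bw$input_grads$dx_fc[k]), 1e-6)
  }
})

test_that("batch-deferred weight gradients equal the direct per-subject ones", {
  set.seed(53)
  sc <- sim_config(n_per_class = 3, n_networks = 2, clusters_per_network = 2,
                   regions_per_cluster = 2, voxels_per_region = 4, n_time = 40,
                   seed = 8)
  co <- generate_cohort(sc)
  gcoh <- build_cohort_graphs(co, gamma = 0.05)
  cfg <- mhnet_config(dropout = 0, seed = 2)  # full-size widths: defer active
  inputs <- mhnet:::prepare_cohort_inputs(gcoh, cfg)
  set.seed(2)
  params <- mhnet_init(cfg, mhnet:::cohort_dims(gcoh))
  offsets <- mhnet:::leaf_offsets(params)
  n_par <- length(mhnet:::flatten_like(params, params))
  probe <- mhnet:::model_fwd(inputs[[1]], params, cfg, FALSE)
  pbw <- mhnet:::model_bwd(c(0, 0), probe, inputs[[1]], params, cfg, defer = TRUE)
  keys <- names(pbw$deferred)
  expect_true(length(keys) >= 5)
  skel_small <- mhnet:::prune_leaves(params, keys)
  B <- 3
  stacks <- lapply(pbw$deferred, function(z) {
    list(X = matrix(0, B, length(z$x)), D = matrix(0, B, length(z$d)))
  })
  gsmall <- NULL
  gdirect <- numeric(n_par)
  for (bi in 1:B) {
    fw <- mhnet:::model_fwd(inputs[[bi]], params, cfg, FALSE)
    dl <- mhnet:::dlogits_for(fw$prob, gcoh$labels[bi])
    bd <- mhnet:::model_bwd(dl, fw, inputs[[bi]], params, cfg, defer = FALSE)
    gdirect <- gdirect + mhnet:::flatten_like(params, bd$grads)
    bq <- mhnet:::model_bwd(dl, fw, inputs[[bi]], params, cfg, defer = TRUE)
    gs <- mhnet:::flatten_like(skel_small, bq$grads)
    gsmall <- if (is.null(gsmall)) gs else gsmall + gs
    for (k in keys) {
      stacks[[k]]$X[bi, ] <- bq$deferred[[k]]$x
      stacks[[k]]$D[bi, ] <- bq$deferred[[k]]$d
    }
  }
  pos <- unlist(lapply(keys, function(k) {
    o <- offsets[[k]]
    o[["start"]]:(o[["start"]] + o[["len"]] - 1L)
  }))
  gdefer <- numeric(n_par)
  gdefer[seq_len(n_par)[-pos]] <- gsmall
  for (k in keys) {
    o <- offsets[[k]]
    gdefer[o[["start"]]:(o[["start"]] + o[["len"]] - 1L)] <-
      crossprod(stacks[[k]]$X, stacks[[k]]$D)
  }
  expect_lt(max(abs(gdefer - gdirect)), 1e-10)
})
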