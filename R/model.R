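# Model configuration, parameter initialization, and the end-to-end
# forward/backward pass fusing both branches.

#' Model configuration
#'
#' Defaults follow the published settings where stated (dropout 0.3, learning
#' rate 1e-4, Adam, K = 3 Chebyshev order, 3 ChebConv blocks per level,
#' cross-entropy loss, batch training); widths and the convolution stack are
#' package defaults (never printed in the source work).
#'
#' @param d_h Hidden width of every graph level (node-embedding dimension).
#' @param d Width of the Euclidean first-order feature `Z_fc`.
#' @param K Chebyshev polynomial order.
#' @param n_blocks ChebConv blocks per level.
#' @param dropout Dropout rate in ChebConv blocks and the fusion MLP.
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Seed for initialization, shuffling and dropout.
#' @param patience Early-stopping patience on validation loss (0 = train the
#'   full `max_epochs`; the best-validation-loss checkpoint is returned either
#'   way when validation data are supplied).
#' @param variant Ablation variant, one of
#'   `"gnn-lan", "gnn", "cnn", "hgnn", "hcnn", "hcnn+gnn", "hgnn+cnn",
#'   "hgnn+hcnn"` (full model).
#' @param conv_channels,conv_kernels,conv_strides Euclidean conv stack.
#' @param fc_hidden Hidden width of the ESFE MLP stem.
#' @param fusion_hidden Hidden widths of the fusion classifier MLP.
#' @param hop_mode `"outer"` (outer product of `Z_fc`) or `"channel_gram"`.
#' @param use_bn Batch normalization in ChebConv blocks.
#' @param gamma Graph sparsification cutoff (`NULL` = knee selection).
#' @return A `mhnet_config` list.
#' @export
mhnet_config <- function(d_h = 64, d = 64, K = 3, n_blocks = 3,
                         dropout = 0.3, learning_rate = 1e-4,
                         max_epochs = 240, batch_size = 16, seed = 1,
                         patience = 0, variant = "hgnn+hcnn",
                         conv_channels = c(8, 16), conv_kernels = c(7, 5),
                         conv_strides = c(2, 2), fc_hidden = 128,
                         fusion_hidden = c(128, 32), hop_mode = "outer",
                         use_bn = TRUE, gamma = NULL) {
  if (dropout < 0 || dropout >= 1) abort_mhnet("dropout must be in [0, 1)", "mhnet_config_error")
  if (learning_rate <= 0) abort_mhnet("learning_rate must be > 0", "mhnet_config_error")
  if (!variant %in% names(mhnet_variants())) {
    abort_mhnet(sprintf("unknown variant '%s'", variant), "mhnet_config_error")
  }
  structure(as.list(environment()), class = "mhnet_config")
}

#' Ablation variant lattice
#'
#' Maps variant names to branch switches: which branch(es) are used, whether
#' the graph branch sees all three levels or only LAN, and whether each
#' branch's high-order (GHOP/HOP) head is active.
#'
#' @return Named list of variant specs.
#' @export
mhnet_variants <- function() {
  v <- function(gnn, lan_only, gnn_ho, cnn, cnn_ho)
    list(use_gnn = gnn, lan_only = lan_only, gnn_ho = gnn_ho,
         use_cnn = cnn, cnn_ho = cnn_ho)
  list(
    "gnn-lan"   = v(TRUE,  TRUE,  FALSE, FALSE, FALSE),
    "gnn"       = v(TRUE,  FALSE, FALSE, FALSE, FALSE),
    "cnn"       = v(FALSE, FALSE, FALSE, TRUE,  FALSE),
    "hgnn"      = v(TRUE,  FALSE, TRUE,  FALSE, FALSE),
    "hcnn"      = v(FALSE, FALSE, FALSE, TRUE,  TRUE),
    "hcnn+gnn"  = v(TRUE,  FALSE, FALSE, TRUE,  TRUE),
    "hgnn+cnn"  = v(TRUE,  FALSE, TRUE,  TRUE,  FALSE),
    "hgnn+hcnn" = v(TRUE,  FALSE, TRUE,  TRUE,  TRUE))
}

active_levels <- function(vs) {
  if (!vs$use_gnn) character(0) else if (vs$lan_only) "lan" else c("wan", "man", "lan")
}

fusion_input_dim <- function(config, vs) {
  per_level <- if (vs$gnn_ho) 2 * config$d_h else config$d_h
  cnn_dim <- if (vs$use_cnn) (if (vs$cnn_ho) 2 * config$d else config$d) else 0
  length(active_levels(vs)) * per_level + cnn_dim
}

# Static per-subject model inputs: per-level H0 + Chebyshev polynomial
# matrices, and the FC upper-triangle vector. Graphs are fixed during
# training, so this is computed once per cohort.
prepare_inputs <- function(views, config) {
  levels <- lapply(c(wan = "wan", man = "man", lan = "lan"), function(lv) {
    g <- views[[lv]]
    lap <- scaled_laplacian(g$adjacency)
    list(H0 = unname(g$node_features),
         Tk = cheb_polynomials(lap$L_tilde, config$K))
  })
  list(levels = levels, x_fc = upper_tri_vector(views$fc_matrix))
}

prepare_cohort_inputs <- function(graph_cohort, config) {
  lapply(graph_cohort$views, prepare_inputs, config = config)
}

cohort_dims <- function(graph_cohort) {
  v <- graph_cohort$views[[1]]
  list(n_wan = length(v$wan$node_ids), n_man = length(v$man$node_ids),
       n_lan = length(v$lan$node_ids), n_regions = nrow(v$fc_matrix))
}

#' Initialize all trainable parameters
#'
#' Glorot-uniform weight matrices, zero biases, unit batch-norm scales, AFM
#' logits from Normal(0, 0.01). Uses the current RNG state; callers seed it.
#'
#' @param config A [mhnet_config()].
#' @param dims Level dimensions: list with `n_wan`, `n_man`, `n_lan`,
#'   `n_regions` (from a prepared cohort).
#' @return Nested parameter list with subtrees `hgnn` (per level), `esfe`,
#'   `fusion`.
#' @export
mhnet_init <- function(config, dims) {
  vs <- mhnet_variants()[[config$variant]]
  params <- list()
  if (vs$use_gnn) {
    params$hgnn <- lapply(
      c(wan = dims$n_wan, man = dims$n_man, lan = dims$n_lan)[active_levels(vs)],
      function(n) hgnn_level_init(n, config$d_h, config$K, config$n_blocks))
  }
  if (vs$use_cnn) {
    fc_dim <- dims$n_regions * (dims$n_regions - 1) / 2
    params$esfe <- esfe_init(fc_dim, config)$params
  }
  d_in <- fusion_input_dim(config, vs)
  h <- config$fusion_hidden
  params$fusion <- list(
    W1 = glorot(d_in, h[1]), b1 = numeric(h[1]),
    W2 = glorot(h[1], h[2]), b2 = numeric(h[2]),
    W3 = glorot(h[2], 2), b3 = numeric(2))
  params
}

fusion_fwd <- function(z, p, dropout, training) {
  a1 <- dense_fwd(z, p$W1, p$b1)
  r1 <- relu_fwd(a1$out)
  d1 <- dropout_vec_fwd(r1$out, dropout, training)
  a2 <- dense_fwd(d1$out, p$W2, p$b2)
  r2 <- relu_fwd(a2$out)
  d2 <- dropout_vec_fwd(r2$out, dropout, training)
  a3 <- dense_fwd(d2$out, p$W3, p$b3)
  prob <- softmax_vec(a3$out)
  list(prob = prob, logits = a3$out, a1 = a1, r1 = r1, d1 = d1,
       a2 = a2, r2 = r2, d2 = d2, a3 = a3)
}

fusion_bwd <- function(dlogits, cache, p, defer = FALSE) {
  g3 <- dense_bwd(dlogits, cache$a3, p$W3)
  dd2 <- if (is.null(cache$d2$mask)) g3$dx else g3$dx * cache$d2$mask
  dr2 <- dd2 * cache$r2$mask
  g2 <- dense_bwd(dr2, cache$a2, p$W2)
  dd1 <- if (is.null(cache$d1$mask)) g2$dx else g2$dx * cache$d1$mask
  dr1 <- dd1 * cache$r1$mask
  if (defer && length(p$W1) >= DEFER_MIN_LEN) {
    list(grads = list(W1 = NULL, b1 = dr1, W2 = g2$dW, b2 = g2$db,
                      W3 = g3$dW, b3 = g3$db),
         dz = as.vector(p$W1 %*% dr1),
         xd = list(x = cache$a1$x, d = dr1))
  } else {
    g1 <- dense_bwd(dr1, cache$a1, p$W1)
    list(grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                      W3 = g3$dW, b3 = g3$db),
         dz = g1$dx, xd = NULL)
  }
}

# Full forward for one subject's prepared inputs.
model_fwd <- function(inputs, params, config, training = FALSE) {
  vs <- mhnet_variants()[[config$variant]]
  parts <- list()
  level_caches <- list()
  for (lv in active_levels(vs)) {
    fw <- level_fwd(inputs$levels[[lv]], params$hgnn[[lv]], config, training,
                    high_order = vs$gnn_ho)
    level_caches[[lv]] <- fw
    parts[[lv]] <- fw$out
  }
  esfe_cache <- NULL
  if (vs$use_cnn) {
    plans <- esfe_plans_for(length(inputs$x_fc), config)
    esfe_cache <- esfe_fwd(inputs$x_fc, params$esfe, plans, config, training,
                           high_order = vs$cnn_ho)
    parts$esfe <- esfe_cache$out
  }
  z <- unlist(parts, use.names = FALSE)
  fus <- fusion_fwd(z, params$fusion, config$dropout, training)
  list(prob = fus$prob, logits = fus$logits,
       cache = list(levels = level_caches, esfe = esfe_cache, fusion = fus,
                    part_lens = vapply(parts, length, integer(1)), vs = vs))
}

esfe_plans_for <- function(fc_len, config) {
  plan1 <- conv1d_plan(fc_len, 1L, config$conv_kernels[1], config$conv_strides[1])
  plan2 <- conv1d_plan(plan1$L_out, config$conv_channels[1],
                       config$conv_kernels[2], config$conv_strides[2])
  list(plan1, plan2)
}

# Backward from d(logits); returns parameter gradients (same structure as
# params), optionally input gradients for saliency, and — when defer = TRUE —
# the rank-one factors of the large dense-layer weight gradients keyed by
# their parameter paths (batch accumulators turn them into one crossprod).
model_bwd <- function(dlogits, fwd, inputs, params, config,
                      want_input_grads = FALSE, defer = FALSE) {
  cache <- fwd$cache
  vs <- cache$vs
  fb <- fusion_bwd(dlogits, cache$fusion, params$fusion, defer = defer)
  grads <- list(fusion = fb$grads)
  deferred <- list()
  if (!is.null(fb$xd)) deferred[["fusion/W1"]] <- fb$xd
  lens <- cache$part_lens
  offs <- c(0, cumsum(lens))
  input_grads <- list()
  i <- 1
  if (vs$use_gnn) {
    grads$hgnn <- list()
    for (lv in active_levels(vs)) {
      dpart <- fb$dz[(offs[i] + 1):offs[i + 1]]
      lb <- level_bwd(dpart, cache$levels[[lv]], inputs$levels[[lv]],
                      params$hgnn[[lv]],
                      want_input_grad = want_input_grads && lv == "lan",
                      defer = defer)
      grads$hgnn[[lv]] <- lb$grads
      if (!is.null(lb$dH0)) input_grads$dH0_lan <- lb$dH0
      if (!is.null(lb$ghop_xd)) {
        deferred[[sprintf("hgnn/%s/ghop_mlp/W1", lv)]] <- lb$ghop_xd
      }
      i <- i + 1
    }
  }
  if (vs$use_cnn) {
    dpart <- fb$dz[(offs[i] + 1):offs[i + 1]]
    plans <- esfe_plans_for(length(inputs$x_fc), config)
    eb <- esfe_bwd(dpart, cache$esfe, params$esfe, plans,
                   want_input_grad = want_input_grads, defer = defer)
    grads$esfe <- eb$grads
    if (!is.null(eb$xd$fc)) deferred[["esfe/fc/W1"]] <- eb$xd$fc
    if (!is.null(eb$xd$hop)) deferred[["esfe/hop_mlp/W1"]] <- eb$xd$hop
    if (want_input_grads) {
      input_grads$dx_fc <- eb$dx
      input_grads$dr1 <- eb$dr1
    }
  }
  list(grads = grads, input_grads = input_grads, deferred = deferred)
}

#' Fusion classifier head
#'
#' Concatenates the two branches' high-order feature vectors and applies the
#' fusion MLP with a softmax, returning the two-class probability vector.
#'
#' @param z_ghop Graph-branch feature vector (may be `numeric(0)`).
#' @param z_hop Euclidean-branch feature vector (may be `numeric(0)`).
#' @param params Fusion parameter subtree (`W1,b1,W2,b2,W3,b3`).
#' @param dropout Dropout rate (training only).
#' @param training Logical mode flag.
#' @return Probability pair summing to 1; element 2 is the patient class.
#' @export
ffc_forward <- function(z_ghop, z_hop, params, dropout = 0, training = FALSE) {
  z <- c(z_ghop, z_hop)
  check_finite(z, "fused feature vector")
  out <- fusion_fwd(z, params, dropout, training)
  if (!all(is.finite(out$prob))) {
    abort_mhnet("non-finite activations in the fusion MLP", "mhnet_numeric_error")
  }
  out$prob
}

#' Binary cross-entropy loss
#'
#' `-(1/N) sum[y log p + (1-y) log(1-p)]` with probabilities clamped to
#' `[eps, 1-eps]`, `eps = 1e-7`.
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities of the positive class.
#' @param eps Clamp value.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p)) {
    abort_mhnet("labels and probabilities must have equal length", "mhnet_shape_error")
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
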