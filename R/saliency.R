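# Node-saliency ranking: which atlas regions distinguish patients from
# controls, according to a trained model.
#
# Construction, per subject: gradient x input of the patient-class logit,
# aggregated per region on two channels —
#  - graph channel: |d logit / d H0_LAN * H0_LAN| summed over each LAN
#    node's RV-profile features;
#  - Euclidean channel: |d logit / d x_FC * x_FC| at the FC-vector entries
#    (backpropagated through the full convolution stack), each position
#    split evenly between its two regions.
# Per region and channel, the class contrast of these per-subject scores is
# a Welch |t| statistic: raw magnitudes are label-independent (high-variance
# regions score high under any labels), whereas the t ranking is pivotal
# under label permutation — shuffled labels give chance-level rankings.
# Channels are fused by a weighted mean of min-max-normalized |t| scores,
# each channel weighted by its maximum |t| (its strength of class evidence),
# so a channel the model does not use for discrimination is down-weighted.

#' Rank regions by saliency for the patient class
#'
#' @param fit A trained `mhnet_fit`; each branch contributes a channel only
#'   when the fitted variant includes it.
#' @param graph_cohort Labeled cohort providing the subjects (and labels for
#'   the class contrast).
#' @param idx Subject indices (default: all subjects; both classes must be
#'   present among them).
#' @param top_k Number of top regions to flag (default 10).
#' @param inputs Optional precomputed inputs.
#' @return Tibble with `region_id`, `score`, `score_graph`, `score_fc`
#'   (per-channel normalized |t|), `rank`, `top`, sorted by decreasing score.
#' @export
node_saliency <- function(fit, graph_cohort, idx = seq_along(graph_cohort$views),
                          top_k = 10, inputs = NULL) {
  config <- fit$config
  vs <- mhnet_variants()[[config$variant]]
  if (nrow(fit$trace) == 0) warning("model appears untrained")
  labels <- graph_cohort$labels[idx]
  if (length(unique(labels)) < 2) {
    abort_mhnet("saliency contrast needs both classes among the subjects",
                "mhnet_validation_error")
  }
  if (is.null(inputs)) inputs <- prepare_cohort_inputs(graph_cohort, config)
  region_ids <- graph_cohort$views[[1]]$lan$node_ids
  n_regions <- length(region_ids)
  pairs <- ut_pairs(n_regions)
  S_graph <- matrix(0, length(idx), n_regions)
  S_fc <- matrix(0, length(idx), n_regions)
  for (j in seq_along(idx)) {
    i <- idx[j]
    fw <- model_fwd(inputs[[i]], fit$params, config, training = FALSE)
    bw <- model_bwd(c(0, 1), fw, inputs[[i]], fit$params, config,
                    want_input_grads = TRUE)
    if (!is.null(bw$input_grads$dH0_lan)) {
      S_graph[j, ] <- rowSums(abs(bw$input_grads$dH0_lan *
                                    inputs[[i]]$levels$lan$H0))
    }
    if (!is.null(bw$input_grads$dx_fc)) {
      w <- abs(bw$input_grads$dx_fc * inputs[[i]]$x_fc)
      half <- w / 2
      S_fc[j, ] <- unname(tapply(c(half, half), c(pairs[, 1], pairs[, 2]), sum))
    }
  }
  welch_t <- function(M) {
    m1 <- colMeans(M[labels == 1, , drop = FALSE])
    m0 <- colMeans(M[labels == 0, , drop = FALSE])
    v1 <- apply(M[labels == 1, , drop = FALSE], 2, stats::var)
    v0 <- apply(M[labels == 0, , drop = FALSE], 2, stats::var)
    abs(m1 - m0) / sqrt(v1 / sum(labels == 1) + v0 / sum(labels == 0) + 1e-12)
  }
  norm01 <- function(x) {
    if (max(x) == min(x)) rep(0, length(x)) else (x - min(x)) / (max(x) - min(x))
  }
  t_graph <- if (vs$use_gnn) welch_t(S_graph) else numeric(n_regions)
  t_fc <- if (vs$use_cnn) welch_t(S_fc) else numeric(n_regions)
  w_graph <- max(t_graph)
  w_fc <- max(t_fc)
  if (w_graph + w_fc == 0) {
    combined <- numeric(n_regions)
  } else {
    combined <- (w_graph * norm01(t_graph) + w_fc * norm01(t_fc)) /
      (w_graph + w_fc)
  }
  out <- tibble::tibble(region_id = region_ids, score = combined,
                        score_graph = norm01(t_graph),
                        score_fc = norm01(t_fc))
  out <- out[order(-out$score), ]
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top_k
  out
}
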