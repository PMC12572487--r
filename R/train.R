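# Training loop (Adam), metrics, repeated stratified-split cross-validation,
# and the paired permutation test used for internal model comparisons.

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map_n(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map_n(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map_n(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                       params, state$m, state$v)
  list(params = params, state = state)
}

# Gradient of mean cross-entropy w.r.t. logits for one subject: softmax - onehot.
dlogits_for <- function(prob, y) {
  d <- prob
  d[y + 1] <- d[y + 1] - 1
  d
}

subject_loss <- function(prob, y, eps = 1e-7) {
  p <- min(max(prob[2], eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the classifier on a graph cohort
#'
#' Adam at the configured learning rate, mini-batches, cross-entropy loss.
#' With validation indices the epoch with the lowest validation loss is
#' checkpointed and (if `config$patience > 0`) training stops early after
#' that many non-improving epochs. Fixing `config$seed` makes runs bitwise
#' reproducible.
#'
#' @param graph_cohort A `graph_cohort` from [build_cohort_graphs()].
#' @param config A [mhnet_config()].
#' @param train_idx,val_idx Subject indices; default trains on everything
#'   with no validation.
#' @param inputs Optional precomputed [prepare_cohort_inputs()] result (reused
#'   across calls on the same cohort).
#' @return An object of class `mhnet_fit`: `params`, `config`, `trace`
#'   (tibble of per-epoch losses), `best_epoch`, `dims`.
#' @export
train_mhnet <- function(graph_cohort, config,
                        train_idx = seq_along(graph_cohort$views),
                        val_idx = integer(0), inputs = NULL) {
  labels <- graph_cohort$labels
  if (length(unique(labels[train_idx])) < 2) {
    abort_mhnet("training split must contain both classes", "mhnet_validation_error")
  }
  set.seed(config$seed)
  if (is.null(inputs)) inputs <- prepare_cohort_inputs(graph_cohort, config)
  dims <- cohort_dims(graph_cohort)
  params <- mhnet_init(config, dims)
  # Optimizer state lives in flat vectors (one Adam moment pair); the
  # parameter tree is rebuilt once per update. Weight gradients of the large
  # dense layers are rank-one per subject and are accumulated per batch with
  # a single crossprod; a dropout-free probe backward identifies them.
  pvec <- flatten_like(params, params)
  n_par <- length(pvec)
  probe <- model_fwd(inputs[[train_idx[1]]], params, config, training = FALSE)
  probe_bw <- model_bwd(c(0, 0), probe, inputs[[train_idx[1]]], params, config,
                        defer = TRUE)
  defer_keys <- names(probe_bw$deferred)
  skel_small <- prune_leaves(params, defer_keys)
  offsets <- leaf_offsets(params)
  defer_pos <- unlist(lapply(defer_keys, function(k) {
    o <- offsets[[k]]
    o[["start"]]:(o[["start"]] + o[["len"]] - 1L)
  }))
  small_pos <- if (length(defer_pos)) seq_len(n_par)[-defer_pos] else seq_len(n_par)
  m <- v <- numeric(n_par)
  t_step <- 0
  lr <- config$learning_rate
  n_train <- length(train_idx)
  best <- list(loss = Inf, params = params, epoch = 0L)
  since_best <- 0L
  trace <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- train_idx[sample.int(n_train)]
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      B <- length(batch)
      gsmall <- numeric(length(small_pos))
      stacks <- lapply(probe_bw$deferred, function(z) {
        list(X = matrix(0, B, length(z$x)), D = matrix(0, B, length(z$d)))
      })
      bloss <- 0
      bi <- 0L
      for (i in batch) {
        bi <- bi + 1L
        fw <- model_fwd(inputs[[i]], params, config, training = TRUE)
        if (!all(is.finite(fw$logits))) {
          abort_mhnet(sprintf(
            "training diverged (non-finite logits) at epoch %d, subject %d", epoch, i),
            "mhnet_numeric_error")
        }
        bloss <- bloss + subject_loss(fw$prob, labels[i])
        bw <- model_bwd(dlogits_for(fw$prob, labels[i]), fw, inputs[[i]],
                        params, config, defer = TRUE)
        gsmall <- gsmall + flatten_like(skel_small, bw$grads)
        for (k in defer_keys) {
          stacks[[k]]$X[bi, ] <- bw$deferred[[k]]$x
          stacks[[k]]$D[bi, ] <- bw$deferred[[k]]$d
        }
      }
      gvec <- numeric(n_par)
      gvec[small_pos] <- gsmall
      for (k in defer_keys) {
        o <- offsets[[k]]
        gvec[o[["start"]]:(o[["start"]] + o[["len"]] - 1L)] <-
          crossprod(stacks[[k]]$X, stacks[[k]]$D)
      }
      gvec <- gvec / B
      t_step <- t_step + 1
      m <- 0.9 * m + 0.1 * gvec
      v <- 0.999 * v + 0.001 * gvec^2
      pvec <- pvec - lr * (m / (1 - 0.9^t_step)) /
        (sqrt(v / (1 - 0.999^t_step)) + 1e-8)
      params <- unflatten_like(params, pvec)
      ep_loss <- ep_loss + bloss
    }
    ep_loss <- ep_loss / n_train
    val_loss <- NA_real_
    if (length(val_idx)) {
      vl <- 0
      for (i in val_idx) {
        fw <- model_fwd(inputs[[i]], params, config, training = FALSE)
        vl <- vl + subject_loss(fw$prob, labels[i])
      }
      val_loss <- vl / length(val_idx)
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
    }
    trace[[epoch]] <- c(epoch = epoch, train_loss = ep_loss, val_loss = val_loss)
    if (length(val_idx) && config$patience > 0 && since_best >= config$patience) break
  }
  trace <- tibble::as_tibble(do.call(rbind, trace[!vapply(trace, is.null, logical(1))]))
  final_params <- if (length(val_idx)) best$params else params
  structure(list(params = final_params, config = config, trace = trace,
                 best_epoch = if (length(val_idx)) best$epoch else nrow(trace),
                 dims = dims, label_names = graph_cohort$label_names),
            class = "mhnet_fit")
}

#' @export
print.mhnet_fit <- function(x, ...) {
  cat(sprintf("<mhnet_fit> variant '%s', %d parameters, %d epochs (best %d)\n",
              x$config$variant, tree_n_params(x$params), nrow(x$trace), x$best_epoch))
  invisible(x)
}

#' Predict class probabilities for cohort subjects
#'
#' @param object An `mhnet_fit`.
#' @param graph_cohort Cohort to score.
#' @param idx Subject indices (default all).
#' @param inputs Optional precomputed inputs.
#' @param ... Unused.
#' @return Tibble with `subject`, `prob` (patient-class probability), `pred`.
#' @export
predict.mhnet_fit <- function(object, graph_cohort, idx = seq_along(graph_cohort$views),
                              inputs = NULL, ...) {
  if (is.null(inputs)) inputs <- prepare_cohort_inputs(graph_cohort, object$config)
  prob <- vapply(idx, function(i) {
    model_fwd(inputs[[i]], object$params, object$config, training = FALSE)$prob[2]
  }, numeric(1))
  tibble::tibble(subject = idx, prob = prob, pred = as.integer(prob > 0.5))
}

#' Classification metrics from predictions
#'
#' ACC/SEN/SPEC from the 0.5-threshold confusion matrix (positive class =
#' patient), AUC by the rank statistic over predicted probabilities, and AVG
#' their arithmetic mean. A single-class test set yields `NA` for the
#' undefined entries with a warning.
#'
#' @param preds Predicted patient-class probabilities.
#' @param labels True 0/1 labels.
#' @return A `metrics_report` tibble row with `acc`, `sen`, `spec`, `auc`,
#'   `avg`.
#' @export
evaluate_predictions <- function(preds, labels) {
  if (length(preds) != length(labels)) {
    abort_mhnet("predictions and labels must have equal length", "mhnet_shape_error")
  }
  pred <- as.integer(preds > 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  acc <- (tp + tn) / length(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class test set: SEN/SPEC/AUC undefined")
    sen <- if (n1) tp / n1 else NA_real_
    spec <- if (n0) tn / n0 else NA_real_
    auc <- NA_real_
  } else {
    sen <- tp / n1
    spec <- tn / n0
    r <- rank(preds)
    auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out <- tibble::tibble(acc = acc, sen = sen, spec = spec, auc = auc,
                        avg = mean(c(acc, sen, spec, auc)))
  class(out) <- c("metrics_report", class(out))
  out
}

#' Confusion-matrix metrics from counts
#'
#' @param tp,fn,tn,fp Confusion-matrix counts.
#' @return Tibble with `acc`, `sen`, `spec`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  tibble::tibble(acc = (tp + tn) / (tp + fn + tn + fp),
                 sen = tp / (tp + fn), spec = tn / (tn + fp))
}

#' Stratified train/validation/test split
#'
#' 70/10/20 by default, class ratios preserved within each part (70% and 10%
#' are rounded per class; the test part takes the remainder).
#'
#' @param labels 0/1 labels.
#' @param frac Train/validation fractions (test = remainder).
#' @return List with `train`, `val`, `test` index vectors (disjoint, covering
#'   all subjects). Uses the current RNG state.
#' @export
stratified_split <- function(labels, frac = c(train = 0.7, val = 0.1)) {
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_tr <- round(frac[["train"]] * n)
    n_va <- round(frac[["val"]] * n)
    if (n_tr + n_va >= n) {
      abort_mhnet("stratified split impossible: class too small", "mhnet_validation_error")
    }
    train <- c(train, idx[seq_len(n_tr)])
    val <- c(val, idx[n_tr + seq_len(n_va)])
    test <- c(test, idx[(n_tr + n_va + 1):n])
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Repeated stratified-split cross-validation
#'
#' `n_repeats` random stratified 70/10/20 splits; per split the model is
#' trained on the 70%, checkpointed on validation loss, and scored on the
#' held-out 20%. Metrics are aggregated as mean and standard deviation.
#'
#' @param graph_cohort A `graph_cohort` (at least 20 subjects).
#' @param config A [mhnet_config()]; repeat r trains with seed
#'   `config$seed + r - 1`.
#' @param n_repeats Number of random splits.
#' @return An object of class `mhnet_cv`: `per_fold` tibble, `summary`
#'   (mean/sd per metric), `fits` not retained.
#' @export
cross_validate_mhnet <- function(graph_cohort, config, n_repeats = 10) {
  if (length(graph_cohort$views) < 20) {
    abort_mhnet("cross-validation needs at least 20 subjects", "mhnet_validation_error")
  }
  inputs <- prepare_cohort_inputs(graph_cohort, config)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1
    set.seed(cfg$seed)
    sp <- stratified_split(graph_cohort$labels)
    fit <- train_mhnet(graph_cohort, cfg, train_idx = sp$train,
                       val_idx = sp$val, inputs = inputs)
    pr <- predict(fit, graph_cohort, idx = sp$test, inputs = inputs)
    m <- evaluate_predictions(pr$prob, graph_cohort$labels[sp$test])
    rows[[r]] <- tibble::tibble(repeat_id = r, m)
  }
  per_fold <- do.call(rbind, rows)
  met <- c("acc", "sen", "spec", "auc", "avg")
  summary <- tibble::tibble(
    metric = met,
    mean = vapply(met, function(k) mean(per_fold[[k]]), numeric(1)),
    sd = vapply(met, function(k) stats::sd(per_fold[[k]]), numeric(1)))
  structure(list(per_fold = per_fold, summary = summary, config = config),
            class = "mhnet_cv")
}

#' @export
print.mhnet_cv <- function(x, ...) {
  cat(sprintf("<mhnet_cv> %d repeats, variant '%s'\n", nrow(x$per_fold),
              x$config$variant))
  print(x$summary)
  invisible(x)
}

#' Paired permutation test (sign-flip) for metric differences
#'
#' Used for internal comparisons between ablation variants in place of a
#' stochastic-order test: the observed mean difference of paired scores is
#' compared with its sign-flip permutation distribution.
#'
#' @param x,y Paired scores (e.g. per-seed accuracies of two variants).
#' @param n_perm Number of sign-flip draws.
#' @param alternative "greater" (x > y), "less" or "two.sided".
#' @return List with `estimate` (mean difference) and `p_value`.
#' @export
paired_permutation_test <- function(x, y, n_perm = 10000,
                                    alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- x - y
  obs <- mean(d)
  n <- length(d)
  perm <- vapply(seq_len(n_perm), function(i) {
    mean(d * sample(c(-1, 1), n, replace = TRUE))
  }, numeric(1))
  p <- switch(alternative,
    greater = (sum(perm >= obs) + 1) / (n_perm + 1),
    less = (sum(perm <= obs) + 1) / (n_perm + 1),
    two.sided = (sum(abs(perm) >= abs(obs)) + 1) / (n_perm + 1))
  list(estimate = obs, p_value = p)
}

#' Run the ablation lattice on one cohort
#'
#' Trains each requested variant over `seeds` single stratified splits and
#' collects held-out accuracies (one split per seed).
#'
#' @param graph_cohort A `graph_cohort`.
#' @param config Base [mhnet_config()].
#' @param variants Variant names (default: the full lattice).
#' @param seeds Seeds, one training run per seed per variant.
#' @return Tibble with `variant`, `seed`, `acc`, `auc`.
#' @export
run_ablation <- function(graph_cohort, config,
                         variants = names(mhnet_variants()),
                         seeds = 1:5) {
  rows <- list()
  for (vn in variants) {
    cfg <- config
    cfg$variant <- vn
    inputs <- prepare_cohort_inputs(graph_cohort, cfg)
    for (s in seeds) {
      cfg$seed <- s
      set.seed(s)
      sp <- stratified_split(graph_cohort$labels)
      fit <- train_mhnet(graph_cohort, cfg, train_idx = sp$train,
                         val_idx = sp$val, inputs = inputs)
      pr <- predict(fit, graph_cohort, idx = sp$test, inputs = inputs)
      m <- evaluate_predictions(pr$prob, graph_cohort$labels[sp$test])
      rows[[length(rows) + 1]] <- tibble::tibble(variant = vn, seed = s,
                                                 acc = m$acc, auc = m$auc)
    }
  }
  do.call(rbind, rows)
}
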