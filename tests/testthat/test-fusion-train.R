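test_that("ffc_forward yields a proper probability pair with monotone sharpening", {
  set.seed(61)
  p <- list(W1 = mhnet:::glorot(10, 8), b1 = numeric(8),
            W2 = mhnet:::glorot(8, 4), b2 = numeric(4),
            W3 = mhnet:::glorot(4, 2), b3 = numeric(2))
  for (i in 1:20) {
    pr <- ffc_forward(rnorm(6), rnorm(4), p)
    expect_lt(abs(sum(pr) - 1), 1e-12)
    expect_true(all(pr > 0))
  }
  # zeroed final layer: equal logits
  pz <- p; pz$W3[] <- 0; pz$b3[] <- 0
  expect_equal(ffc_forward(rnorm(6), rnorm(4), pz), c(0.5, 0.5))
  # doubling final-layer weights sharpens the larger probability
  z <- rnorm(10)
  pr1 <- ffc_forward(z[1:6], z[7:10], p)
  p2 <- p; p2$W3 <- 2 * p$W3; p2$b3 <- 2 * p$b3
  pr2 <- ffc_forward(z[1:6], z[7:10], p2)
  expect_gte(max(pr2), max(pr1))
})

test_that("cross_entropy matches closed forms and clamps", {
  expect_equal(cross_entropy(1, 0.5), log(2), tolerance = 1e-9)
  expect_lte(cross_entropy(c(1, 0), c(1, 0)), 1.2e-7)
  expect_equal(cross_entropy(c(1, 0), c(0.8, 0.4)),
               -(log(0.8) + log(0.6)) / 2, tolerance = 1e-12)
  expect_error(cross_entropy(c(1, 0), 0.5), class = "mhnet_shape_error")
})

test_that("evaluate_predictions reproduces the hand confusion matrix and AUC null", {
  # TP=3, FN=1, TN=4, FP=2 (positive probabilities placed accordingly)
  labels <- c(rep(1, 4), rep(0, 6))
  preds <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.15, 0.05, 0.3, 0.9, 0.6)
  m <- evaluate_predictions(preds, labels)
  expect_equal(m$acc, 0.7, tolerance = 1e-9)
  expect_equal(m$sen, 0.75, tolerance = 1e-9)
  expect_equal(m$spec, 2 / 3, tolerance = 1e-9)
  expect_equal(m$avg, mean(c(m$acc, m$sen, m$spec, m$auc)))

  expect_equal(confusion_metrics(3, 1, 4, 2),
               tibble::tibble(acc = 0.7, sen = 0.75, spec = 2 / 3),
               tolerance = 1e-9)

  # perfect predictions
  mp <- evaluate_predictions(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(unlist(mp), c(acc = 1, sen = 1, spec = 1, auc = 1, avg = 1))

  # AUC of uninformative scores is ~0.5
  set.seed(62)
  labels2 <- rep(0:1, each = 500)
  m2 <- evaluate_predictions(runif(1000), labels2)
  expect_lt(abs(m2$auc - 0.5), 0.05)

  expect_warning(ms <- evaluate_predictions(c(0.6, 0.7), c(1, 1)), "single-class")
  expect_true(is.na(ms$auc))
})

test_that("stratified splits have the documented sizes and are disjoint", {
  labels <- rep(0:1, each = 50)
  set.seed(63)
  for (r in 1:5) {
    sp <- stratified_split(labels)
    expect_length(sp$train, 70)
    expect_length(sp$val, 10)
    expect_length(sp$test, 20)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$train, sp$val), 0)
    expect_length(intersect(sp$val, sp$test), 0)
    expect_setequal(c(sp$train, sp$val, sp$test), seq_along(labels))
    # class balance preserved within one subject
    expect_lte(abs(sum(labels[sp$test]) - 10), 1)
  }
  expect_error(stratified_split(c(0, 1)), class = "mhnet_validation_error")
})

test_that("training is deterministic, monotone on a separable cohort, frozen at lr 0", {
  set.seed(64)
  sc <- sim_config(n_per_class = 8, n_networks = 2, clusters_per_network = 2,
                   regions_per_cluster = 2, voxels_per_region = 6, n_time = 60,
                   effects = list(list(pair = c(1, 2), delta = 0.5)), seed = 9)
  co <- generate_cohort(sc)
  gcoh <- build_cohort_graphs(co, gamma = 0.05)
  cfg <- mhnet_config(d_h = 8, d = 8, K = 2, n_blocks = 2, dropout = 0.1,
                      learning_rate = 5e-3, max_epochs = 12, batch_size = 8,
                      conv_channels = c(2, 3), conv_kernels = c(3, 3),
                      conv_strides = c(1, 2), fc_hidden = 10,
                      fusion_hidden = c(8, 4), seed = 11)
  fit1 <- train_mhnet(gcoh, cfg)
  fit2 <- train_mhnet(gcoh, cfg)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$params, fit2$params)
  expect_lt(tail(fit1$trace$train_loss, 1), fit1$trace$train_loss[1])

  cfg0 <- cfg
  cfg0$learning_rate <- 1e-30  # an exact 0 is rejected by the config contract
  cfg0$dropout <- 0            # keep the per-epoch loss free of dropout noise
  fit0 <- train_mhnet(gcoh, cfg0)
  expect_lt(diff(range(fit0$trace$train_loss)), 1e-6)

  # single-class training split is refused
  expect_error(train_mhnet(gcoh, cfg, train_idx = which(gcoh$labels == 1)),
               class = "mhnet_validation_error")
})

test_that("cross-validation aggregates per-repeat metrics with positive spread", {
  set.seed(65)
  sc <- sim_config(n_per_class = 12, n_networks = 2, clusters_per_network = 2,
                   regions_per_cluster = 2, voxels_per_region = 6, n_time = 50,
                   effects = list(list(pair = c(1, 2), delta = 0.45)), seed = 10)
  co <- generate_cohort(sc)
  gcoh <- build_cohort_graphs(co, gamma = 0.05)
  cfg <- mhnet_config(d_h = 8, d = 8, K = 2, n_blocks = 2, dropout = 0.1,
                      learning_rate = 2e-3, max_epochs = 8, batch_size = 8,
                      conv_channels = c(2, 3), conv_kernels = c(3, 3),
                      conv_strides = c(1, 2), fc_hidden = 10,
                      fusion_hidden = c(8, 4), seed = 1, patience = 0)
  cv <- cross_validate_mhnet(gcoh, cfg, n_repeats = 3)
  expect_equal(nrow(cv$per_fold), 3)
  expect_true(all(c("acc", "sen", "spec", "auc", "avg") %in% names(cv$per_fold)))
  expect_true(any(cv$summary$sd > 0))
  expect_error(cross_validate_mhnet(
    structure(list(views = gcoh$views[1:10], labels = gcoh$labels[1:10]),
              class = "graph_cohort"), cfg), class = "mhnet_validation_error")
})

test_that("paired permutation test separates a clear shift from a null", {
  set.seed(66)
  x <- rnorm(12, 1.1, 0.3)
  y <- rnorm(12, 0.4, 0.3)
  res <- paired_permutation_test(x, y, n_perm = 2000)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$estimate, 0)
  # calibration under the null: the rejection rate at alpha = 0.05 stays
  # near its nominal level over repeated exchangeable pairs
  rejections <- vapply(1:60, function(i) {
    a <- rnorm(10); b <- rnorm(10)
    paired_permutation_test(a, b, n_perm = 400)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.15)
})

test_that("tidy and glance accessors expose fit and CV summaries", {
  set.seed(67)
  sc <- sim_config(n_per_class = 6, n_networks = 2, clusters_per_network = 2,
                   regions_per_cluster = 2, voxels_per_region = 5, n_time = 40,
                   seed = 12)
  co <- generate_cohort(sc)
  gcoh <- build_cohort_graphs(co, gamma = 0.05)
  cfg <- mhnet_config(d_h = 6, d = 6, K = 2, n_blocks = 2, dropout = 0,
                      learning_rate = 1e-3, max_epochs = 3, batch_size = 6,
                      conv_channels = c(2, 2), conv_kernels = c(3, 3),
                      conv_strides = c(1, 2), fc_hidden = 8,
                      fusion_hidden = c(6, 4), seed = 2)
  fit <- train_mhnet(gcoh, cfg)
  expect_identical(tidy(fit), fit$trace)
  gl <- glance(fit)
  expect_equal(gl$epochs, 3)
  expect_gt(gl$n_params, 0)
  pl <- ggplot2::autoplot(fit)
  expect_s3_class(pl, "ggplot")
})
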