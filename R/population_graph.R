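# Population-graph extension: subjects become nodes; edges combine embedding
# similarity with phenotype agreement; a one-layer graph convolution plus MLP
# classifies nodes transductively.

#' Embedding-similarity kernel
#'
#' `rho(Y_i, Y_j) = 1 - Pearson(Y_i, Y_j)` (correlation distance between
#' embedding rows); `M1(i,j) = exp(-rho^2 / (2 sigma^2))` with `sigma` the
#' mean of the squared distances over distinct pairs.
#'
#' @param Y Embedding matrix, one row per subject (>= 2 columns).
#' @return Symmetric matrix with unit diagonal, entries in (0, 1\].
#' @export
embedding_similarity <- function(Y) {
  Y <- as.matrix(Y)
  m <- nrow(Y)
  if (m < 2) abort_mhnet("need at least 2 subjects", "mhnet_validation_error")
  v <- apply(Y, 1, stats::var)
  if (any(v == 0)) {
    abort_mhnet(sprintf("constant embedding row (subject %d)", which(v == 0)[1]),
                "mhnet_degenerate_error")
  }
  rho <- 1 - stats::cor(t(Y))
  diag(rho) <- 0
  sigma <- mean(rho[upper.tri(rho)]^2)
  M1 <- exp(-rho^2 / (2 * sigma^2))
  diag(M1) <- 1
  M1
}

#' One-hot / z-score phenotype encoding
#'
#' Categorical channels (sex, site) are one-hot encoded; age is z-scored.
#' Missing channels are skipped with a message.
#'
#' @param phenotypes Data frame with `subject_id` and any of `sex`, `age`,
#'   `site`.
#' @return Numeric matrix (subjects x encoded dims) with a `channels`
#'   attribute naming the channels used.
#' @export
phenotype_encode <- function(phenotypes) {
  blocks <- list()
  used <- character(0)
  one_hot <- function(x) {
    lv <- sort(unique(x))
    out <- vapply(lv, function(l) as.numeric(x == l), numeric(length(x)))
    matrix(out, ncol = length(lv), dimnames = list(NULL, lv))
  }
  for (ch in c("sex", "site")) {
    if (ch %in% names(phenotypes)) {
      blocks[[ch]] <- one_hot(phenotypes[[ch]])
      used <- c(used, ch)
    } else message(sprintf("phenotype channel '%s' missing: skipped", ch))
  }
  if ("age" %in% names(phenotypes)) {
    a <- phenotypes$age
    s <- stats::sd(a)
    blocks$age <- matrix(if (s > 0) (a - mean(a)) / s else a * 0, ncol = 1)
    used <- c(used, "age")
  } else message("phenotype channel 'age' missing: skipped")
  eta <- do.call(cbind, blocks)
  attr(eta, "channels") <- used
  eta
}

#' Default phenotype-projection parameters
#'
#' A fixed, seeded random one-hidden-layer MLP shared by all subjects
#' (Eq.-level weight sharing makes `W` symmetric by construction).
#'
#' @param d_in Encoded phenotype dimension.
#' @param d_hidden Hidden width (default 16).
#' @param seed RNG seed.
#' @return `mlp2` parameter list.
#' @export
phenotype_mlp_init <- function(d_in, d_hidden = 16, seed = 1) {
  set.seed(seed)
  mlp2_init(d_in, d_hidden, d_hidden)
}

#' Phenotype-similarity weight between two subjects
#'
#' `W_ij = (cos(MLP(eta_i), MLP(eta_j)) + 1) / 2`; a zero-norm MLP output is
#' treated as orthogonal (0.5) with a warning.
#'
#' @param eta_i,eta_j Encoded phenotype vectors.
#' @param mlp_params Shared MLP parameters (e.g. [phenotype_mlp_init()]).
#' @return Scalar in \[0, 1\].
#' @export
phenotype_weight <- function(eta_i, eta_j, mlp_params) {
  u <- mlp2_fwd(as.numeric(eta_i), mlp_params)$out
  v <- mlp2_fwd(as.numeric(eta_j), mlp_params)$out
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("zero-norm phenotype projection: weight set to 0.5")
    return(0.5)
  }
  (sum(u * v) / (nu * nv) + 1) / 2
}

#' Build the population graph
#'
#' Combines the embedding kernel `M1`, the phenotype indicator kernel `M2`
#' (mean of sex match, site match, and `|age_i - age_j| <= age_window`), the
#' binarization `C = 1{M1 * M2 >= mean off-diagonal}` and the phenotype MLP
#' weights `W` into the weighted adjacency `A' = C * W` (self-edges included
#' with weight 1).
#'
#' @param Y Embedding matrix (subjects x e), e.g. fused feature vectors of a
#'   trained model.
#' @param phenotypes Data frame with `subject_id`, `sex`, `age`, `site` (any
#'   subset; missing channels are skipped).
#' @param age_window Age-match window tau in years (default 2).
#' @param mlp_params Optional shared phenotype MLP (default seeded init).
#' @param use_phenotypes `FALSE` degrades to the embedding-similarity-only
#'   graph (`M2 = W = 1`).
#' @return An object of class `population_graph` with `M1`, `M2`, `W`,
#'   `C_prime`, `C`, `A_prime`, `Y`, `eta`.
#' @export
build_population_graph <- function(Y, phenotypes = NULL, age_window = 2,
                                   mlp_params = NULL, use_phenotypes = TRUE) {
  Y <- as.matrix(Y)
  m <- nrow(Y)
  M1 <- embedding_similarity(Y)
  if (use_phenotypes && !is.null(phenotypes)) {
    chans <- list()
    if ("sex" %in% names(phenotypes)) {
      chans$sex <- outer(phenotypes$sex, phenotypes$sex, `==`) * 1
    }
    if ("site" %in% names(phenotypes)) {
      chans$site <- outer(phenotypes$site, phenotypes$site, `==`) * 1
    }
    if ("age" %in% names(phenotypes)) {
      chans$age <- (abs(outer(phenotypes$age, phenotypes$age, `-`)) <= age_window) * 1
    }
    if (length(chans) == 0) {
      M2 <- matrix(1, m, m)
    } else {
      M2 <- Reduce(`+`, chans) / length(chans)
    }
    eta <- phenotype_encode(phenotypes)
    if (is.null(mlp_params)) mlp_params <- phenotype_mlp_init(ncol(eta))
    proj <- t(apply(eta, 1, function(e) mlp2_fwd(e, mlp_params)$out))
    nrm <- sqrt(rowSums(proj^2))
    if (any(nrm == 0)) {
      warning("zero-norm phenotype projection: weight set to 0.5")
      nrm[nrm == 0] <- 1
      proj[rowSums(abs(proj)) == 0, ] <- 0
    }
    cosm <- (proj / nrm) %*% t(proj / nrm)
    W <- (cosm + 1) / 2
    W[rowSums(abs(proj)) == 0, ] <- 0.5
    W[, rowSums(abs(proj)) == 0] <- 0.5
  } else {
    M2 <- matrix(1, m, m)
    W <- matrix(1, m, m)
    eta <- NULL
  }
  C_prime <- M1 * M2
  thr <- mean(C_prime[upper.tri(C_prime) | lower.tri(C_prime)])
  C <- (C_prime >= thr) * 1
  diag(C) <- 1
  A_prime <- C * W
  diag(A_prime) <- 1
  structure(list(M1 = M1, M2 = M2, W = W, C_prime = C_prime, C = C,
                 A_prime = A_prime, Y = Y, eta = eta),
            class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  m <- nrow(x$A_prime)
  dens <- mean(x$C[upper.tri(x$C)])
  cat(sprintf("<population_graph> %d subjects, edge density %.2f\n", m, dens))
  invisible(x)
}

#' Transductive node classification on a population graph
#'
#' One-layer first-order graph convolution with symmetric normalization of
#' `A'` (self-loops already present), followed by an MLP and softmax per
#' node; trained with Adam on the labeled nodes only, evaluated on the
#' held-out nodes.
#'
#' @param graph A `population_graph`.
#' @param labels 0/1 labels for all nodes (only `train_idx` are used for
#'   fitting).
#' @param train_idx Indices of labeled nodes.
#' @param d_hidden GCN output width (default 16).
#' @param epochs,learning_rate Optimization settings.
#' @param weight_decay L2 penalty on the weights; with few labeled nodes it
#'   steers the interpolating solution toward the large-margin one.
#' @param seed RNG seed.
#' @return List with `prob` (per-node patient probability), `pred`, and
#'   `metrics` on the held-out nodes.
#' @export
population_classify <- function(graph, labels, train_idx, d_hidden = 16,
                                epochs = 300, learning_rate = 0.01,
                                weight_decay = 1e-3, seed = 1) {
  if (length(unique(labels[train_idx])) < 2) {
    abort_mhnet("need at least one labeled subject per class", "mhnet_validation_error")
  }
  set.seed(seed)
  A <- graph$A_prime
  dg <- rowSums(A)
  S <- t(A / sqrt(dg)) / sqrt(dg)  # D^{-1/2} A D^{-1/2}
  Y <- scale(graph$Y)
  Y[is.nan(Y)] <- 0
  m <- nrow(Y)
  p <- list(Wg = glorot(ncol(Y), d_hidden), bg = numeric(d_hidden),
            W2 = glorot(d_hidden, 2), b2 = numeric(2))
  state <- list(t = 0, m = tree_zeros_like(p), v = tree_zeros_like(p))
  onehot <- cbind(1 - labels, labels)
  SY <- S %*% Y
  forward <- function(p) {
    A1 <- sweep(SY %*% p$Wg, 2, p$bg, `+`)
    R1 <- A1 * (A1 > 0)
    logits <- sweep(R1 %*% p$W2, 2, p$b2, `+`)
    ex <- exp(logits - apply(logits, 1, max))
    list(A1 = A1, R1 = R1, prob = ex / rowSums(ex))
  }
  for (ep in seq_len(epochs)) {
    fw <- forward(p)
    dlog <- (fw$prob - onehot)
    dlog[-train_idx, ] <- 0
    dlog <- dlog / length(train_idx)
    g <- list()
    g$W2 <- crossprod(fw$R1, dlog) + weight_decay * p$W2
    g$b2 <- colSums(dlog)
    dR1 <- dlog %*% t(p$W2) * (fw$A1 > 0)
    g$Wg <- crossprod(SY, dR1) + weight_decay * p$Wg
    g$bg <- colSums(dR1)
    g <- g[names(p)]
    upd <- adam_step(p, g, state, learning_rate)
    p <- upd$params
    state <- upd$state
  }
  prob <- forward(p)$prob[, 2]
  held <- setdiff(seq_len(m), train_idx)
  metrics <- if (length(held)) evaluate_predictions(prob[held], labels[held]) else NULL
  list(prob = prob, pred = as.integer(prob > 0.5), metrics = metrics,
       held_out = held)
}
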