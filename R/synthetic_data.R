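# Synthetic cohort generator: hierarchically correlated voxel-level signals
# with planted group differences in network coupling, plus phenotypes.
#
# Latent factor cascade (per time point, i.i.d. in time by default):
#   network factors  f_net    ~ MVN(0, Sigma_net), Sigma_net off-diagonal =
#                               rho_cross (+ delta on planted pairs, class 1)
#   cluster factors  f_clu    = sqrt(rho_network) f_net + sqrt(1-rho_network) xi
#   region factors   f_reg    = sqrt(rho_c) f_clu + sqrt(1-rho_c) xi
#   voxel signals    x        = sqrt(rho_region) f_reg + sqrt(1-rho_region) eps
#                               + noise_sd * e
# giving population voxel correlations rho_region (same region),
# rho_region*rho_cluster (same cluster), rho_region*rho_cluster*rho_network
# (same network), all divided by (1 + noise_sd^2).

#' Simulation configuration for the synthetic cohort
#'
#' Defaults are the package's planted-signal study conditions: 60 subjects per
#' class; 4 networks x 2 clusters x 3 regions x 20 voxels; 150 time points;
#' within-region / within-cluster / within-network / cross-network couplings
#' 0.85 / 0.75 / 0.6 / 0.05 (typical BOLD within-region voxel coherence and
#' within-network region-mean FC, and a cascade that transmits most of a
#' planted network-factor coupling to observable FC — see
#' [network_mean_corr_closed_form()]); one planted inter-network coupling
#' difference of +0.4 between networks 1 and 2 for class 1.
#'
#' @param n_per_class Subjects per class.
#' @param n_networks,clusters_per_network,regions_per_cluster,voxels_per_region
#'   Hierarchy dimensions.
#' @param n_time Time points per subject.
#' @param rho_region,rho_cluster,rho_network,rho_cross Latent coupling levels;
#'   must satisfy `0 <= rho_cross < rho_network < rho_cluster < rho_region <= 1`.
#' @param effects List of planted class-1 effects. Each element is
#'   `list(pair = c(i, j), delta = d)`: for `i != j` the coupling between
#'   network factors i and j is `rho_cross + d`; for `i == j` the
#'   within-cluster coupling `rho_cluster` of network i's clusters becomes
#'   `rho_cluster + d` (an effect confined to one network).
#' @param noise_sd Additive measurement-noise standard deviation on voxels.
#' @param ar_coef AR(1) coefficient for temporally autocorrelated latents
#'   (default 0 = white).
#' @param seed Cohort seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_per_class = 60,
                       n_networks = 4, clusters_per_network = 2,
                       regions_per_cluster = 3, voxels_per_region = 20,
                       n_time = 150,
                       rho_region = 0.85, rho_cluster = 0.75,
                       rho_network = 0.6, rho_cross = 0.05,
                       effects = list(list(pair = c(1, 2), delta = 0.4)),
                       noise_sd = 0.1, ar_coef = 0, seed = 1) {
  cfg <- as.list(environment())
  if (!(rho_cross >= 0 && rho_cross < rho_network && rho_network < rho_cluster &&
        rho_cluster < rho_region && rho_region <= 1)) {
    abort_mhnet("couplings must satisfy 0 <= rho_cross < rho_network < rho_cluster < rho_region <= 1",
                "mhnet_config_error")
  }
  for (cl in 0:1) {
    sn <- sigma_net_for(cfg, class_label = cl)
    ev <- eigen(sn, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      abort_mhnet("planted effects make the network covariance non-PSD",
                  "mhnet_config_error")
    }
    rc <- rho_cluster_for(cfg, class_label = cl)
    if (any(rc > 1) || any(rc <= rho_network)) {
      abort_mhnet("intra-network effect pushes rho_cluster outside (rho_network, 1]",
                  "mhnet_config_error")
    }
  }
  structure(cfg, class = "sim_config")
}

# Network-factor correlation matrix for one class.
sigma_net_for <- function(config, class_label) {
  K <- config$n_networks
  S <- matrix(config$rho_cross, K, K)
  diag(S) <- 1
  if (class_label == 1) {
    for (e in config$effects) {
      i <- e$pair[1]; j <- e$pair[2]
      if (i != j) {
        S[i, j] <- S[j, i] <- config$rho_cross + e$delta
      }
    }
  }
  S
}

# Per-network within-cluster coupling for one class (intra-network effects).
rho_cluster_for <- function(config, class_label) {
  rc <- rep(config$rho_cluster, config$n_networks)
  if (class_label == 1) {
    for (e in config$effects) {
      if (e$pair[1] == e$pair[2]) rc[e$pair[1]] <- rc[e$pair[1]] + e$delta
    }
  }
  rc
}

#' Closed-form network-mean correlation implied by the cascade
#'
#' Correlation between the voxel-mean time series of two networks, as implied
#' by the latent cascade for a given network-factor coupling `rho`. Used as
#' the oracle for planted-coupling tests: the planted delta appears in the
#' network-mean correlation attenuated by the cascade's noise shares.
#'
#' @param config A [sim_config()].
#' @param rho Coupling between the two network factors.
#' @return Scalar correlation.
#' @export
network_mean_corr_closed_form <- function(config, rho) {
  nc <- config$clusters_per_network
  nr <- config$regions_per_cluster
  nv <- config$voxels_per_region
  n_all <- nc * nr * nv
  rr <- config$rho_region; rc <- config$rho_cluster; rn <- config$rho_network
  v <- rr * rc * rn +
    rr * rc * (1 - rn) / nc +
    rr * (1 - rc) / (nc * nr) +
    (1 - rr) / n_all +
    config$noise_sd^2 / n_all
  rr * rc * rn * rho / v
}

latent_draw <- function(n_time, n_cols, ar_coef) {
  Z <- matrix(stats::rnorm(n_time * n_cols), n_time, n_cols)
  if (ar_coef > 0) {
    Z <- apply(Z, 2, function(z) {
      as.numeric(stats::filter(z, ar_coef, method = "recursive")) * sqrt(1 - ar_coef^2)
    })
  }
  Z
}

#' Deterministic hierarchy table for a simulation configuration
#'
#' Names follow `net<i>`, `net<i>.c<j>`, `net<i>.c<j>.r<k>`.
#'
#' @param config A [sim_config()].
#' @return A `hierarchy_map`.
#' @export
generate_hierarchy <- function(config) {
  rows <- list()
  for (i in seq_len(config$n_networks)) {
    for (j in seq_len(config$clusters_per_network)) {
      for (k in seq_len(config$regions_per_cluster)) {
        rows[[length(rows) + 1]] <- data.frame(
          region_id = sprintf("net%d.c%d.r%d", i, j, k),
          cluster_id = sprintf("net%d.c%d", i, j),
          network_id = sprintf("net%d", i),
          stringsAsFactors = FALSE)
      }
    }
  }
  read_hierarchy(do.call(rbind, rows))
}

#' Generate one synthetic subject
#'
#' Draws the latent factor cascade for the given class. Uses the current R
#' random-number state; seed the generator (or use [generate_cohort()]) for
#' reproducibility.
#'
#' @param config A [sim_config()].
#' @param class_label 0 (control) or 1 (patient).
#' @param subject_id Subject id string.
#' @return A [region_voxel_signals()] object.
#' @export
generate_subject <- function(config, class_label, subject_id = "sim") {
  Tn <- config$n_time
  K <- config$n_networks
  S <- sigma_net_for(config, class_label)
  rc_net <- rho_cluster_for(config, class_label)
  f_net <- latent_draw(Tn, K, config$ar_coef) %*% chol(S)
  sig <- list()
  for (i in seq_len(K)) {
    rn <- config$rho_network
    for (j in seq_len(config$clusters_per_network)) {
      f_clu <- sqrt(rn) * f_net[, i] +
        sqrt(1 - rn) * latent_draw(Tn, 1, config$ar_coef)[, 1]
      rc <- rc_net[i]
      for (k in seq_len(config$regions_per_cluster)) {
        f_reg <- sqrt(rc) * f_clu +
          sqrt(1 - rc) * latent_draw(Tn, 1, config$ar_coef)[, 1]
        rr <- config$rho_region
        V <- sqrt(rr) * matrix(f_reg, Tn, config$voxels_per_region) +
          sqrt(1 - rr) * latent_draw(Tn, config$voxels_per_region, config$ar_coef)
        if (config$noise_sd > 0) {
          V <- V + config$noise_sd *
            matrix(stats::rnorm(Tn * config$voxels_per_region), Tn)
        }
        sig[[sprintf("net%d.c%d.r%d", i, j, k)]] <- V
      }
    }
  }
  region_voxel_signals(subject_id, sig)
}

#' Generate a balanced labeled cohort with phenotypes
#'
#' Phenotypes mimic pediatric/adolescent cohort demographics: sex Bernoulli
#' (0.5), age uniform on 8-20 years, three acquisition sites.
#'
#' @param config A [sim_config()]; `config$seed` fixes the cohort.
#' @return A `subject_cohort`: `subjects` (list of [region_voxel_signals()]),
#'   `labels` (0/1), `phenotypes` (tibble), `hierarchy`, `label_names`.
#' @export
generate_cohort <- function(config) {
  set.seed(config$seed)
  n <- 2L * config$n_per_class
  labels <- rep(0:1, each = config$n_per_class)
  ids <- sprintf("sub%03d", seq_len(n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- generate_subject(config, labels[i], ids[i])
  }
  phen <- tibble::tibble(
    subject_id = ids,
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = stats::runif(n, 8, 20),
    site = sample(sprintf("site%d", 1:3), n, replace = TRUE))
  structure(list(subjects = subjects, labels = labels, phenotypes = phen,
                 hierarchy = generate_hierarchy(config),
                 label_names = c("control", "patient"),
                 config = config),
            class = "subject_cohort")
}

#' @export
print.subject_cohort <- function(x, ...) {
  cat(sprintf("<subject_cohort> %d subjects (%d per class), %d regions, %d time points\n",
              length(x$subjects), x$config$n_per_class,
              length(x$hierarchy$regions), x$config$n_time))
  invisible(x)
}

#' Label-permuted copy of a cohort (null control)
#'
#' @param cohort A `subject_cohort` or `graph_cohort`.
#' @param seed Permutation seed.
#' @return Same class of object with labels shuffled.
#' @export
permute_cohort_labels <- function(cohort, seed = 1) {
  set.seed(seed)
  cohort$labels <- sample(cohort$labels)
  cohort
}
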