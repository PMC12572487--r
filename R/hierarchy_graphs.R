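# Hierarchical multi-scale graph construction: per subject, three graph
# levels sharing one region set —
#   WAN: nodes = functional networks, one block (every network pair eligible),
#   MAN: nodes = clusters, blocks = networks,
#   LAN: nodes = regions, blocks = clusters.
# Within each block the RV coefficient is computed between pooled voxel
# signals; the adjacency is the per-block thresholded RV assembled
# block-diagonally (cross-block entries structurally zero), and node features
# are the rows of the pre-threshold block-structured RV-profile matrix.

new_brain_graph_level <- function(node_ids, adjacency, node_features, level_tag,
                                  block_ids) {
  structure(list(node_ids = node_ids, adjacency = adjacency,
                 node_features = node_features, level_tag = level_tag,
                 block_ids = block_ids),
            class = "brain_graph_level")
}

#' @export
print.brain_graph_level <- function(x, ...) {
  nz <- sum(x$adjacency[upper.tri(x$adjacency)] != 0)
  cat(sprintf("<brain_graph_level> %s: %d nodes, %d off-diagonal edges\n",
              x$level_tag, length(x$node_ids), nz))
  invisible(x)
}

#' Level specifications derived from a hierarchy map
#'
#' @param hierarchy A `hierarchy_map` from [read_hierarchy()].
#' @return Named list of three level specs (`wan`, `man`, `lan`), each with
#'   `level_tag`, `node_ids`, `grouping` (node -> member regions) and
#'   `block_of` (node -> block id).
#' @export
level_specs <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "hierarchy_map"))
  h <- hierarchy
  wan_groups <- lapply(h$networks, function(nw) h$regions[h$region_network[h$regions] == nw])
  names(wan_groups) <- h$networks
  man_groups <- lapply(h$clusters, function(cl) h$regions[h$region_cluster[h$regions] == cl])
  names(man_groups) <- h$clusters
  lan_groups <- stats::setNames(as.list(h$regions), h$regions)
  list(
    wan = list(level_tag = "WAN", node_ids = h$networks, grouping = wan_groups,
               block_of = stats::setNames(rep("brain", length(h$networks)), h$networks)),
    man = list(level_tag = "MAN", node_ids = h$clusters, grouping = man_groups,
               block_of = h$cluster_network),
    lan = list(level_tag = "LAN", node_ids = h$regions, grouping = lan_groups,
               block_of = h$region_cluster)
  )
}

#' Pool region voxel signals into level nodes
#'
#' Each node's signal matrix is the column-wise concatenation of its member
#' regions' voxel matrices (time dimension preserved), so the RV coefficient
#' applies unchanged at every level.
#'
#' @param subject A [region_voxel_signals()] object.
#' @param spec One level spec from [level_specs()].
#' @return Named list of (time x voxels) matrices, one per node.
#' @export
pool_node_signals <- function(subject, spec) {
  stopifnot(inherits(subject, "region_voxel_signals"))
  missing <- setdiff(unlist(spec$grouping), names(subject$region_signals))
  if (length(missing)) {
    abort_mhnet(sprintf("region '%s' in hierarchy is missing from subject '%s'",
                        missing[1], subject$subject_id), "mhnet_validation_error")
  }
  out <- lapply(spec$grouping, function(members) {
    do.call(cbind, unname(subject$region_signals[members]))
  })
  names(out) <- names(spec$grouping)
  out
}

#' Assemble square matrices along the diagonal of a larger matrix
#'
#' @param blocks List of square numeric matrices.
#' @return A square matrix of size `sum(sizes)`; off-block entries are exactly
#'   zero and block order follows input order.
#' @export
block_diagonal <- function(blocks) {
  sizes <- vapply(blocks, function(b) {
    b <- as.matrix(b)
    if (nrow(b) != ncol(b)) abort_mhnet("all blocks must be square", "mhnet_shape_error")
    nrow(b)
  }, integer(1))
  n <- sum(sizes)
  M <- matrix(0, n, n)
  at <- 0L
  for (b in blocks) {
    k <- nrow(as.matrix(b))
    M[at + seq_len(k), at + seq_len(k)] <- as.matrix(b)
    at <- at + k
  }
  M
}

#' Build one graph level for a subject
#'
#' RV coefficients are computed only within blocks; the adjacency is the
#' block-diagonal assembly of per-block thresholded RV matrices, and node
#' features are the rows of the pre-threshold block-structured RV matrix
#' (connectivity profiles, giving a scan-length-invariant feature dimension
#' equal to the node count).
#'
#' @param subject A [region_voxel_signals()] object.
#' @param spec A level spec from [level_specs()].
#' @param gamma Sparsity cutoff in \[0, 1).
#' @return A `brain_graph_level`.
#' @export
build_level <- function(subject, spec, gamma) {
  pooled <- pool_node_signals(subject, spec)
  node_ids <- names(pooled)
  block_ids <- spec$block_of[node_ids]
  blocks <- unique(block_ids)
  R_blocks <- vector("list", length(blocks))
  A_blocks <- vector("list", length(blocks))
  ord <- character(0)
  for (bi in seq_along(blocks)) {
    members <- node_ids[block_ids == blocks[bi]]
    ord <- c(ord, members)
    Rb <- rv_matrix(pooled[members])
    R_blocks[[bi]] <- Rb
    A_blocks[[bi]] <- threshold_adjacency(Rb, gamma)
  }
  # Node order = spec order; blocks are contiguous in first-appearance order,
  # which coincides with spec order for hierarchies read first-appearance.
  R_full <- block_diagonal(R_blocks)
  diag(R_full) <- 1
  A_full <- block_diagonal(A_blocks)
  dimnames(R_full) <- dimnames(A_full) <- list(ord, ord)
  # Reorder to the spec's node order in case blocks interleave.
  R_full <- R_full[node_ids, node_ids, drop = FALSE]
  A_full <- A_full[node_ids, node_ids, drop = FALSE]
  new_brain_graph_level(node_ids, A_full, R_full, spec$level_tag,
                        unname(block_ids))
}

#' Build the full multi-view graph set for one subject
#'
#' @param subject A [region_voxel_signals()] object.
#' @param hierarchy A `hierarchy_map`.
#' @param gammas Single cutoff shared by all levels, or a named list/vector
#'   with elements `wan`, `man`, `lan`.
#' @return A `multiview_graph_set`: `wan`, `man`, `lan` graph levels plus the
#'   Pearson `fc_matrix` over region means.
#' @export
build_multiview <- function(subject, hierarchy, gammas) {
  specs <- level_specs(hierarchy)
  if (length(gammas) == 1 && is.null(names(gammas))) {
    gammas <- list(wan = gammas, man = gammas, lan = gammas)
  }
  fc <- pearson_fc(region_mean_series(subject))
  structure(
    list(wan = build_level(subject, specs$wan, gammas[["wan"]]),
         man = build_level(subject, specs$man, gammas[["man"]]),
         lan = build_level(subject, specs$lan, gammas[["lan"]]),
         fc_matrix = fc),
    class = "multiview_graph_set")
}

#' @export
print.multiview_graph_set <- function(x, ...) {
  cat(sprintf("<multiview_graph_set> WAN %d / MAN %d / LAN %d nodes\n",
              length(x$wan$node_ids), length(x$man$node_ids), length(x$lan$node_ids)))
  invisible(x)
}

#' Build graphs for every subject of a cohort
#'
#' When `gamma` is `NULL` the cutoff is selected once by [select_cutoff()] on
#' the knee of the retained-edge curve of the LAN RV matrix averaged over
#' subjects, and shared by all three levels (one cutoff per dataset).
#'
#' @param cohort A `subject_cohort` from [generate_cohort()] (or a compatible
#'   list with `subjects`, `labels`, `hierarchy`, `phenotypes`).
#' @param gamma Cutoff, per-level named list, or `NULL` for automatic knee
#'   selection.
#' @return A `graph_cohort`: list with `views` (per-subject
#'   `multiview_graph_set`), `labels`, `phenotypes`, `gamma`, `label_names`.
#' @export
build_cohort_graphs <- function(cohort, gamma = NULL) {
  specs <- level_specs(cohort$hierarchy)
  if (is.null(gamma)) {
    Rsum <- NULL
    for (s in cohort$subjects) {
      lev <- build_level(s, specs$lan, 0)
      Rsum <- if (is.null(Rsum)) lev$node_features else Rsum + lev$node_features
    }
    Rbar <- Rsum / length(cohort$subjects)
    gamma <- select_cutoff(retained_edge_curve(Rbar))
  }
  views <- lapply(cohort$subjects, build_multiview, hierarchy = cohort$hierarchy,
                  gammas = gamma)
  structure(list(views = views, labels = cohort$labels,
                 phenotypes = cohort$phenotypes,
                 label_names = cohort$label_names %||% c("control", "patient"),
                 gamma = gamma),
            class = "graph_cohort")
}

#' @export
print.graph_cohort <- function(x, ...) {
  cat(sprintf("<graph_cohort> %d subjects (%d positive), gamma = %s\n",
              length(x$views), sum(x$labels == 1),
              paste(signif(unlist(x$gamma), 4), collapse = "/")))
  invisible(x)
}
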