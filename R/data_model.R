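# Core domain types and delimited-text readers/writers.
#
# All on-disk formats are plain text: comma- or tab-separated (auto-detected
# from the file extension: .csv is comma, anything else tab), decimal point,
# UTF-8. Numeric payloads are written with %.17g so that write/read round-trips
# are bit-exact for doubles.

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

write_numeric_table <- function(M, path, col_names = NULL, row_names = NULL) {
  sep <- delim_for(path)
  M <- as.matrix(M)
  txt <- apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  if (!is.null(row_names)) txt <- paste(row_names, txt, sep = sep)
  if (!is.null(col_names)) {
    hdr <- paste(col_names, collapse = sep)
    if (!is.null(row_names)) hdr <- paste("", hdr, sep = sep)
    txt <- c(hdr, txt)
  }
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

read_numeric_table <- function(path, header = FALSE, what = path) {
  if (!file.exists(path)) {
    abort_mhnet(sprintf("file not found: '%s'", path), "mhnet_parse_error")
  }
  sep <- delim_for(path)
  df <- tryCatch(
    utils::read.table(path, header = header, sep = sep, check.names = FALSE,
                      colClasses = "character", comment.char = ""),
    error = function(e) abort_mhnet(
      sprintf("cannot parse delimited table '%s': %s", path, conditionMessage(e)),
      "mhnet_parse_error")
  )
  M <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort_mhnet(sprintf(
        "non-numeric cell in %s at row %d, column %d: '%s'",
        what, i + as.integer(header), j, df[[j]][i]), "mhnet_parse_error")
    }
    M[, j] <- v
  }
  if (header) colnames(M) <- colnames(df)
  M
}

#' Construct a validated set of per-region voxel signals
#'
#' Bundles one subject's region-wise multivariate BOLD-like signals: for each
#' atlas region, a numeric matrix with time points in rows and voxels in
#' columns. All regions must share the same number of time points, every
#' region must have at least one voxel, and all values must be finite.
#'
#' @param subject_id Subject identifier string.
#' @param region_signals Named list of numeric matrices (time x voxels), one
#'   per region; names are region ids and their order is preserved.
#' @return An object of class `region_voxel_signals` with elements
#'   `subject_id`, `region_signals`, `n_time`.
#' @export
region_voxel_signals <- function(subject_id, region_signals) {
  if (length(region_signals) == 0) {
    abort_mhnet("region_signals must contain at least one region", "mhnet_validation_error")
  }
  if (is.null(names(region_signals)) || anyDuplicated(names(region_signals))) {
    abort_mhnet("region_signals must be a uniquely named list", "mhnet_validation_error")
  }
  region_signals <- lapply(region_signals, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n_time <- nrow(region_signals[[1]])
  for (rid in names(region_signals)) {
    m <- region_signals[[rid]]
    if (ncol(m) < 1L) {
      abort_mhnet(sprintf("region '%s' has no voxel columns", rid), "mhnet_validation_error")
    }
    if (nrow(m) != n_time) {
      abort_mhnet(sprintf(
        "region '%s' has %d time points while region '%s' has %d",
        rid, nrow(m), names(region_signals)[1], n_time), "mhnet_validation_error")
    }
    check_finite(m, sprintf("signals of region '%s'", rid))
  }
  structure(
    list(subject_id = as.character(subject_id),
         region_signals = region_signals,
         n_time = n_time),
    class = "region_voxel_signals")
}

#' @export
print.region_voxel_signals <- function(x, ...) {
  cat(sprintf("<region_voxel_signals> subject '%s': %d regions x %d time points\n",
              x$subject_id, length(x$region_signals), x$n_time))
  invisible(x)
}

#' Read per-region signal tables listed in a manifest
#'
#' The manifest maps region ids to delimited numeric tables (rows = time
#' points, columns = voxels). Region order follows manifest order.
#'
#' @param directory_path Directory containing the signal tables.
#' @param manifest Either a data frame with columns `region_id` and `path`
#'   (paths relative to `directory_path`), or the path of a manifest TSV with
#'   those two columns and a header.
#' @param header Whether the per-region tables carry a header row.
#' @param subject_id Subject id; defaults to the directory's base name.
#' @return A [region_voxel_signals()] object.
#' @export
read_region_signals <- function(directory_path, manifest = file.path(directory_path, "manifest.tsv"),
                                header = FALSE, subject_id = basename(directory_path)) {
  if (is.character(manifest)) {
    manifest <- utils::read.table(manifest, header = TRUE, sep = "\t",
                                  colClasses = "character", check.names = FALSE)
  }
  if (!all(c("region_id", "path") %in% names(manifest))) {
    abort_mhnet("manifest must have columns 'region_id' and 'path'", "mhnet_validation_error")
  }
  sig <- vector("list", nrow(manifest))
  names(sig) <- manifest$region_id
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(directory_path, manifest$path[i])
    sig[[i]] <- read_numeric_table(f, header = header,
                                   what = sprintf("region '%s' (%s)", manifest$region_id[i], f))
  }
  region_voxel_signals(subject_id, sig)
}

#' Write per-region signal tables plus a manifest
#'
#' Inverse of [read_region_signals()]; the round trip is bit-exact.
#'
#' @param x A [region_voxel_signals()] object.
#' @param directory_path Output directory (created if missing).
#' @return `directory_path`, invisibly.
#' @export
write_region_signals <- function(x, directory_path) {
  stopifnot(inherits(x, "region_voxel_signals"))
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  rel <- sprintf("%s.tsv", make.names(names(x$region_signals)))
  for (i in seq_along(x$region_signals)) {
    write_numeric_table(x$region_signals[[i]], file.path(directory_path, rel[i]))
  }
  man <- data.frame(region_id = names(x$region_signals), path = rel,
                    stringsAsFactors = FALSE)
  utils::write.table(man, file.path(directory_path, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory_path)
}

#' Region-mean time series
#'
#' Reduces each region's voxel matrix to its per-time-point arithmetic mean,
#' the standard ROI signal. Columns with zero variance are flagged with a
#' warning (they break Pearson connectivity downstream).
#'
#' @param x A [region_voxel_signals()] object, or a numeric matrix
#'   (time x regions) together with `region_ids`.
#' @param region_ids Region ids when `x` is a plain matrix.
#' @return An object of class `region_mean_series`: list with `subject_id`,
#'   `series` (time x regions matrix), `region_ids`.
#' @export
region_mean_series <- function(x, region_ids = NULL) {
  if (inherits(x, "region_voxel_signals")) {
    series <- vapply(x$region_signals, rowMeans, numeric(x$n_time))
    series <- matrix(series, nrow = x$n_time,
                     dimnames = list(NULL, names(x$region_signals)))
    out <- list(subject_id = x$subject_id, series = series,
                region_ids = names(x$region_signals))
  } else {
    series <- as.matrix(x)
    if (is.null(region_ids)) region_ids <- colnames(series) %||%
        sprintf("r%d", seq_len(ncol(series)))
    if (length(region_ids) != ncol(series)) {
      abort_mhnet("length(region_ids) must equal ncol(series)", "mhnet_validation_error")
    }
    colnames(series) <- region_ids
    out <- list(subject_id = "subject", series = series, region_ids = region_ids)
  }
  check_finite(out$series, "region-mean series")
  v <- apply(out$series, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("region(s) with zero-variance mean series: %s",
                    paste(out$region_ids[v == 0], collapse = ", ")))
  }
  structure(out, class = "region_mean_series")
}

#' Read a three-level brain hierarchy table
#'
#' The hierarchy assigns each atlas region to a mid-level cluster (e.g. a lobe
#' within a functional network) and a top-level functional network (Yeo-7
#' style). Node order at every level is first-appearance order in the table,
#' which fixes the index 0..n-1 of every graph tensor downstream.
#'
#' @param path Path to a delimited table with header
#'   `region_id,cluster_id,network_id`, or a data frame with those columns.
#' @return An object of class `hierarchy_map`: list with the `table` plus
#'   derived orderings `networks`, `clusters`, `regions`, and lookup vectors
#'   `region_cluster`, `region_network`, `cluster_network`.
#' @export
read_hierarchy <- function(path) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.table(path, header = TRUE, sep = delim_for(path),
                      colClasses = "character", check.names = FALSE)
  }
  need <- c("region_id", "cluster_id", "network_id")
  if (!all(need %in% names(df))) {
    abort_mhnet("hierarchy table must have columns region_id, cluster_id, network_id",
                "mhnet_validation_error")
  }
  df <- df[, need]
  if (anyDuplicated(df$region_id)) {
    dup <- df$region_id[duplicated(df$region_id)][1]
    abort_mhnet(sprintf("duplicate region_id '%s' in hierarchy", dup),
                "mhnet_validation_error")
  }
  cn <- unique(df[, c("cluster_id", "network_id")])
  if (anyDuplicated(cn$cluster_id)) {
    bad <- cn$cluster_id[duplicated(cn$cluster_id)][1]
    abort_mhnet(sprintf("cluster '%s' is mapped to more than one network", bad),
                "mhnet_validation_error")
  }
  networks <- unique(df$network_id)
  clusters <- unique(df$cluster_id)
  regions <- df$region_id
  if (length(networks) < 2) {
    abort_mhnet("hierarchy must contain at least 2 networks", "mhnet_validation_error")
  }
  cluster_network <- stats::setNames(cn$network_id, cn$cluster_id)[clusters]
  structure(
    list(table = df,
         networks = networks, clusters = clusters, regions = regions,
         region_cluster = stats::setNames(df$cluster_id, df$region_id),
         region_network = stats::setNames(df$network_id, df$region_id),
         cluster_network = cluster_network),
    class = "hierarchy_map")
}

#' @export
print.hierarchy_map <- function(x, ...) {
  cat(sprintf("<hierarchy_map> %d networks / %d clusters / %d regions\n",
              length(x$networks), length(x$clusters), length(x$regions)))
  invisible(x)
}

#' Write a hierarchy map back to a delimited table
#' @param x A `hierarchy_map`.
#' @param path Output path (.csv for comma, else tab).
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(x, path) {
  stopifnot(inherits(x, "hierarchy_map"))
  utils::write.table(x$table, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize one graph level (edge list + node features + JSON sidecar)
#'
#' @param level A `brain_graph_level` as returned by [build_level()].
#' @param dir Output directory; files are prefixed with the lower-cased level
#'   tag.
#' @return `dir`, invisibly.
#' @export
write_graph_level <- function(level, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- tolower(level$level_tag)
  A <- level$adjacency
  idx <- which(upper.tri(A, diag = TRUE) & A != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  el <- cbind(idx[, 1], idx[, 2], A[idx])
  writeLines(c("i\tj\tweight",
               apply(el, 1, function(r) sprintf("%d\t%d\t%.17g", r[1], r[2], r[3]))),
             file.path(dir, sprintf("%s_edges.tsv", tag)))
  write_numeric_table(level$node_features, file.path(dir, sprintf("%s_features.tsv", tag)))
  jsonlite::write_json(
    list(level_tag = level$level_tag, node_ids = level$node_ids,
         n_nodes = length(level$node_ids), block_ids = level$block_ids),
    file.path(dir, sprintf("%s_meta.json", tag)),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a serialized graph level
#' @param dir Directory written by [write_graph_level()].
#' @param tag Level tag ("WAN", "MAN" or "LAN").
#' @return A `brain_graph_level`.
#' @export
read_graph_level <- function(dir, tag) {
  ltag <- tolower(tag)
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", ltag)),
                              simplifyVector = TRUE)
  n <- meta$n_nodes
  el <- utils::read.table(file.path(dir, sprintf("%s_edges.tsv", ltag)),
                          header = TRUE, sep = "\t")
  A <- matrix(0, n, n)
  if (nrow(el)) {
    A[cbind(el$i, el$j)] <- el$weight
    A[cbind(el$j, el$i)] <- el$weight
  }
  H <- read_numeric_table(file.path(dir, sprintf("%s_features.tsv", ltag)))
  new_brain_graph_level(meta$node_ids, A, H, meta$level_tag, meta$block_ids)
}

#' Serialize a subject's multi-view graph set
#' @param views A `multiview_graph_set` from [build_multiview()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_multiview <- function(views, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lv in c("wan", "man", "lan")) write_graph_level(views[[lv]], dir)
  write_numeric_table(views$fc_matrix, file.path(dir, "fc_matrix.tsv"),
                      col_names = colnames(views$fc_matrix))
  invisible(dir)
}

#' Read back a serialized multi-view graph set
#' @param dir Directory written by [write_multiview()].
#' @return A `multiview_graph_set`.
#' @export
read_multiview <- function(dir) {
  fc <- read_numeric_table(file.path(dir, "fc_matrix.tsv"), header = TRUE)
  ids <- colnames(fc)
  fc <- unname(fc)
  dimnames(fc) <- list(ids, ids)
  structure(list(wan = read_graph_level(dir, "WAN"),
                 man = read_graph_level(dir, "MAN"),
                 lan = read_graph_level(dir, "LAN"),
                 fc_matrix = fc),
            class = "multiview_graph_set")
}
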