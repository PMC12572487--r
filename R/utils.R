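#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor rnorm runif sd var qnorm filter predict
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_mhnet <- function(msg, class) {
  stop(structure(
    class = c(class, "mhnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = is.matrix(x))
    loc <- if (is.matrix(x)) {
      sprintf("row %d, column %d", bad[1, 1], bad[1, 2])
    } else {
      sprintf("position %d", bad[[1]])
    }
    abort_mhnet(sprintf("%s contains a non-finite value (first at %s)", what, loc),
                "mhnet_nonfinite_error")
  }
  invisible(x)
}

check_square_symmetric <- function(M, what, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    abort_mhnet(sprintf("%s must be a square matrix", what), "mhnet_shape_error")
  }
  if (max(abs(M - t(M))) > tol) {
    abort_mhnet(sprintf("%s is not symmetric within tolerance %g", what, tol),
                "mhnet_shape_error")
  }
  invisible(M)
}

# Row-major strict-upper-triangle index pairs of an N x N matrix:
# (1,2),...,(1,N),(2,3),...,(N-1,N). With diag = TRUE, (1,1),(1,2),...
# Memoized: recomputed index tables dominate otherwise in inner loops.
.ut_cache <- new.env(parent = emptyenv())
ut_pairs <- function(n, diag = FALSE) {
  key <- sprintf("%d_%d", n, diag)
  hit <- .ut_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- which(if (diag) upper.tri(matrix(0, n, n), diag = TRUE) else
    upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  .ut_cache[[key]] <- idx
  idx
}

# Flatten a parameter-like tree into one numeric vector, traversing `skel`'s
# structure and pulling leaves from `tree` by name (construction order of
# `tree` need not match). NULL leaves contribute nothing. Reordering happens
# at the R level; the concatenation is a single C-level unlist.
flatten_like <- function(skel, tree) {
  reorder <- function(s, t) {
    if (is.list(s)) {
      nms <- names(s)
      out <- vector("list", length(s))
      for (i in seq_along(s)) {
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        out[[i]] <- reorder(s[[i]], t[[key]])
      }
      out
    } else if (is.null(s)) {
      NULL
    } else {
      t
    }
  }
  unlist(reorder(skel, tree), use.names = FALSE)
}

# Offsets (start, length) of every leaf in flatten_like order, keyed by the
# "/"-joined path of names (or positional indices for unnamed lists).
leaf_offsets <- function(tree) {
  out <- list()
  pos <- 0L
  walk <- function(t, path) {
    if (is.list(t)) {
      nms <- names(t)
      for (i in seq_along(t)) {
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(t[[i]], c(path, key))
      }
    } else if (!is.null(t)) {
      out[[paste(path, collapse = "/")]] <<- c(start = pos + 1L, len = length(t))
      pos <<- pos + length(t)
    }
  }
  walk(tree, character(0))
  out
}

# Replace the leaves named in `keys` ("/"-joined paths) with NULL.
prune_leaves <- function(tree, keys) {
  for (k in keys) {
    parts <- strsplit(k, "/", fixed = TRUE)[[1]]
    path <- lapply(parts, function(p) {
      if (grepl("^[0-9]+$", p)) as.integer(p) else p
    })
    tree <- prune_one(tree, path)
  }
  tree
}

prune_one <- function(tree, path) {
  if (length(path) == 1) {
    tree[path[[1]]] <- list(NULL)
    return(tree)
  }
  tree[[path[[1]]]] <- prune_one(tree[[path[[1]]]], path[-1])
  tree
}

# Inverse of flatten_like: rebuild a tree shaped like `skel` from `vec`.
unflatten_like <- function(skel, vec) {
  pos <- 0L
  fill <- function(s) {
    if (is.list(s)) {
      for (i in seq_along(s)) s[i] <- list(fill(s[[i]]))
      s
    } else if (is.null(s)) {
      NULL
    } else {
      k <- length(s)
      out <- vec[pos + seq_len(k)]
      pos <<- pos + k
      if (is.matrix(s)) dim(out) <- dim(s)
      out
    }
  }
  fill(skel)
}

# Map a (params-like) nested list of numeric arrays with f applied leaf-wise.
tree_map <- function(f, tree) {
  if (is.list(tree)) {
    lapply(tree, function(x) tree_map(f, x))
  } else if (is.null(tree)) {
    NULL
  } else {
    f(tree)
  }
}

# Leaf-wise map over several trees with identical structure (subtrees are
# matched by name where names exist, so construction order does not matter).
tree_map_n <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    nms <- names(trees[[1]])
    out <- vector("list", length(trees[[1]]))
    names(out) <- nms
    for (i in seq_along(out)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      subtrees <- lapply(trees, `[[`, key)
      out[i] <- list(if (is.null(trees[[1]][[key]])) NULL else
        do.call(tree_map_n, c(list(f), subtrees)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_sum_sq <- function(tree) {
  tot <- 0
  walk <- function(t) {
    if (is.list(t)) lapply(t, walk) else tot <<- tot + sum(t^2)
    invisible(NULL)
  }
  walk(tree)
  tot
}

tree_n_params <- function(tree) {
  tot <- 0L
  walk <- function(t) {
    if (is.list(t)) lapply(t, walk) else tot <<- tot + length(t)
    invisible(NULL)
  }
  walk(tree)
  tot
}
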