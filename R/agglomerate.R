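#' Agglomerative hierarchical clustering of embedded points
#'
#' Bottom-up clustering by repeatedly merging the closest pair of clusters
#' under the chosen linkage, with Lance-Williams distance updates. Distances
#' between points are Euclidean. Ties in the nearest-pair search are broken
#' by the smallest (left, right) cluster index pair, so the merge sequence
#' is fully deterministic.
#'
#' Ward linkage is the variance-minimising form operating on squared
#' Euclidean distances (the distance between two singletons equals their
#' Euclidean distance); recorded merge heights are on the distance scale.
#'
#' @param points a [tsne_embed()] result or a numeric matrix (rows = items).
#' @param linkage one of `"ward"` (default), `"single"`, `"complete"`,
#'   `"average"`.
#' @return An object of class `tgv_dendrogram`: list with `merge` (n-1 x 2,
#'   hclust convention: negative entries are leaves), `height`, `labels`
#'   and `linkage`.
#' @export
agglomerate <- function(points, linkage = c("ward", "single", "complete", "average")) {
  linkage <- match.arg(linkage)
  X <- if (inherits(points, "tgv_embedding")) points$coords else as.matrix(points)
  n <- nrow(X)
  if (n < 2L) stopf("agglomerate() needs at least 2 points, got %d", n)
  labels <- rownames(X)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  D <- as.matrix(stats::dist(X))
  if (linkage == "ward") D <- D^2   # Lance-Williams updates act on d^2
  diag(D) <- Inf

  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  node <- -seq_len(n)          # hclust convention: leaves are negative
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    flat <- which(sub == min(sub))
    rows <- (flat - 1L) %% length(idx) + 1L
    cols <- (flat - 1L) %/% length(idx) + 1L
    pairs <- cbind(pmin(rows, cols), pmax(rows, cols))
    pairs <- unique(pairs)
    ord <- order(pairs[, 1], pairs[, 2])
    i <- idx[pairs[ord[1], 1]]
    j <- idx[pairs[ord[1], 2]]

    d_ij <- D[i, j]
    height[step] <- if (linkage == "ward") sqrt(d_ij) else d_ij
    merge[step, ] <- sort_merge_pair(node[i], node[j])
    ni <- sizes[i]; nj <- sizes[j]

    others <- idx[idx != i & idx != j]
    if (length(others) > 0L) {
      d_i <- D[i, others]; d_j <- D[j, others]
      new_d <- switch(linkage,
        single   = pmin(d_i, d_j),
        complete = pmax(d_i, d_j),
        average  = (ni * d_i + nj * d_j) / (ni + nj),
        ward     = {
          nk <- sizes[others]
          ((ni + nk) * d_i + (nj + nk) * d_j - nk * d_ij) / (ni + nj + nk)
        }
      )
      D[i, others] <- new_d
      D[others, i] <- new_d
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    node[i] <- step
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage),
            class = "tgv_dendrogram")
}

# hclust merge-row convention: leaves (negative) before internal nodes;
# among leaves, ascending original index; among internals, ascending step.
#' @noRd
sort_merge_pair <- function(a, b) {
  key <- function(v) if (v < 0) c(0, -v) else c(1, v)
  ka <- key(a); kb <- key(b)
  if (ka[1] < kb[1] || (ka[1] == kb[1] && ka[2] <= kb[2])) c(a, b) else c(b, a)
}

#' @export
print.tgv_dendrogram <- function(x, ...) {
  cat(sprintf("<tgv_dendrogram: %d leaves, %s linkage, heights [%.4g, %.4g]>\n",
              length(x$labels), x$linkage, min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a tgv_dendrogram to an hclust object
#'
#' @param x a [agglomerate()] result.
#' @param ... unused.
#' @return A `stats::hclust` object (usable with `plot()`, `cutree()`, ...).
#' @export
as.hclust.tgv_dendrogram <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = leaf_order(x$merge),
         labels = x$labels, method = x$linkage,
         dist.method = "euclidean", call = match.call()),
    class = "hclust"
  )
}

#' @noRd
leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges: the first `n - k` merges are applied and
#' the resulting connected groups become the clusters. Clusters are numbered
#' 1..k in order of first appearance in the input.
#'
#' @param dendro a [agglomerate()] result.
#' @param k number of clusters, `1 <= k <= n`.
#' @return An object of class `tgv_clusters`: list with `labels` (named
#'   integer vector, molecule id -> cluster) and `k`.
#' @export
cut_to_k <- function(dendro, k) {
  stopifnot(inherits(dendro, "tgv_dendrogram"))
  n <- length(dendro$labels)
  if (!is_scalar_number(k) || k < 1 || k > n || k != round(k)) {
    stopf("k must be an integer in 1..%d, got %s", n, format(k))
  }
  k <- as.integer(k)
  group <- seq_len(n)            # leaf -> group id
  node_group <- integer(n - 1L)  # internal node -> group id
  n_merges <- n - k
  if (n_merges > 0L) {
    for (s in seq_len(n_merges)) {
      pair <- dendro$merge[s, ]
      g <- vapply(pair, function(nd) {
        if (nd < 0) group[-nd] else node_group[nd]
      }, 1L)
      keep <- min(g)
      group[group %in% g] <- keep
      node_group[s] <- keep
      if (s > 1L) node_group[seq_len(s - 1L)][node_group[seq_len(s - 1L)] %in% g] <- keep
    }
  }
  labs <- as.integer(factor(group, levels = unique(group)))
  names(labs) <- dendro$labels
  structure(list(labels = labs, k = k), class = "tgv_clusters")
}

#' @export
print.tgv_clusters <- function(x, ...) {
  cat(sprintf("<tgv_clusters: %d molecules in %d clusters (sizes %s)>\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from merge heights (each child branch spans
#' the height difference between its parent merge and the child's own
#' merge; leaves sit at height 0).
#'
#' @param dendro a [agglomerate()] result.
#' @param path optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "tgv_dendrogram"))
  node_str <- function(nd, parent_h) {
    if (nd < 0) {
      sprintf("%s:%.10g", gsub("[,():;\\s]", "_", dendro$labels[-nd]), parent_h)
    } else {
      h <- dendro$height[nd]
      sprintf("(%s,%s):%.10g",
              node_str(dendro$merge[nd, 1], h),
              node_str(dendro$merge[nd, 2], h),
              parent_h - h)
    }
  }
  root <- nrow(dendro$merge)
  h_root <- dendro$height[root]
  nwk <- sprintf("(%s,%s);",
                 node_str(dendro$merge[root, 1], h_root),
                 node_str(dendro$merge[root, 2], h_root))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
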