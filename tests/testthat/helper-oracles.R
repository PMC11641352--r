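# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: set arithmetic instead of bit vectors, from-scratch
# cluster distances instead of Lance-Williams updates, exhaustive
# enumeration instead of closed forms.

# Tanimoto via index-set arithmetic.
oracle_tanimoto <- function(a, b) {
  sa <- which(as.integer(a) == 1L)
  sb <- which(as.integer(b) == 1L)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# Naive O(n^3) agglomeration: every step recomputes all inter-cluster
# distances from the raw points and merges the closest pair (ties by the
# smallest pair of cluster keys, a cluster's key being its minimum member
# index). Returns merge heights and the leaf set merged at every step.
oracle_agglomerate <- function(X, linkage) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  merged_sets <- vector("list", n - 1)
  cluster_dist <- function(ci, cj) {
    sub <- D[ci, cj, drop = FALSE]
    switch(linkage,
      single   = min(sub),
      complete = max(sub),
      average  = mean(sub),
      ward     = {
        dm <- colMeans(X[ci, , drop = FALSE]) - colMeans(X[cj, , drop = FALSE])
        sqrt(2 * length(ci) * length(cj) / (length(ci) + length(cj))) *
          sqrt(sum(dm^2))
      })
  }
  for (step in seq_len(n - 1)) {
    keys <- vapply(clusters, min, 1L)
    ord <- order(keys)
    clusters <- clusters[ord]
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        d <- cluster_dist(clusters[[i]], clusters[[j]])
        if (is.null(best) || d < best$d - 1e-12) best <- list(d = d, i = i, j = j)
      }
    }
    heights[step] <- best$d
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merged_sets[[step]] <- merged
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, merged_sets = merged_sets)
}

# Leaf set under each internal node of a tgv_dendrogram, per merge step.
dendro_merge_sets <- function(dendro) {
  n <- length(dendro$labels)
  sets <- vector("list", n - 1)
  leafset <- function(nd) if (nd < 0) -nd else sets[[nd]]
  for (s in seq_len(n - 1)) {
    sets[[s]] <- sort(c(leafset(dendro$merge[s, 1]), leafset(dendro$merge[s, 2])))
  }
  sets
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws (universe 1..N, annotated genes 1..K).
oracle_hypergeom <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Adjusted Rand Index by pair counting (Hubert & Arabie), independent of
# the package's contingency-table formula.
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) n11 <- n11 + 1
      else if (!same_a && !same_b) n00 <- n00 + 1
      else if (same_a) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# Degree tally straight from an edge table.
oracle_degrees <- function(edges) {
  ends <- c(as.character(edges[[1]]), as.character(edges[[2]]))
  tab <- table(ends)
  setNames(as.integer(tab), names(tab))
}

# Exhaustive within-cluster medoid: member maximizing the mean Tanimoto
# (set arithmetic) to the other members, ties by smallest id.
oracle_medoid <- function(M) {
  ids <- rownames(M)
  m <- nrow(M)
  if (m == 1) return(list(id = ids, mean_sim = 1))
  means <- vapply(seq_len(m), function(i) {
    mean(vapply(setdiff(seq_len(m), i), function(j) {
      oracle_tanimoto(M[i, ], M[j, ])
    }, 0))
  }, 0)
  best <- order(-means, ids)[1]
  list(id = ids[best], mean_sim = means[best])
}

# Exhaustive 1-nearest-neighbour labels in an embedding.
oracle_1nn_labels <- function(coords, labels) {
  n <- nrow(coords)
  vapply(seq_len(n), function(i) {
    d <- sqrt(rowSums(sweep(coords, 2, coords[i, ])^2))
    d[i] <- Inf
    labels[which.min(d)]
  }, labels[1])
}

# Random binary fingerprint with at least one set bit.
random_fp <- function(bits = 64, p = 0.3) {
  f <- as.integer(runif(bits) < p)
  if (sum(f) == 0) f[sample.int(bits, 1)] <- 1L
  f
}
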