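#' Full fingerprint-clustering pipeline
#'
#' The complete chain: fingerprints -> 3-D t-SNE embedding -> agglomerative
#' clustering -> cut into k clusters. Accepts either a parsed SMILES
#' library (fingerprints are computed with `scheme`) or a precomputed
#' binary fingerprint matrix. Each stage's parameters are logged via
#' `message()`.
#'
#' @param library a [parse_library()] data.frame or an n x L binary
#'   fingerprint matrix (rows = molecules).
#' @param scheme fingerprint scheme (used only when `library` is a parsed
#'   SMILES library).
#' @param config a [tsne_config()]; the seed is mandatory there.
#' @param k number of clusters to cut (default 6).
#' @param linkage agglomeration linkage (default `"ward"`).
#' @return An object of class `tgv_cluster_result`: list with `assignment`
#'   ([cut_to_k()] result), `embedding`, `dendrogram`, `fingerprints` and
#'   the parameters used.
#' @examples
#' lib <- gen_fingerprint_library(k = 3, m = 8, bits = 64,
#'                                flip_prob = 0, seed = 7)
#' res <- cluster_pipeline(lib$fingerprints, config = tsne_config(seed = 7),
#'                         k = 3)
#' table(res$assignment$labels)
#' @export
cluster_pipeline <- function(library, scheme = c("maccs", "hashed"),
                             config, k = 6, linkage = "ward") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(config, "tgv_tsne_config"))
  if (is.matrix(library)) {
    fps <- library
    if (is.null(attr(fps, "scheme"))) attr(fps, "scheme") <- "precomputed"
  } else {
    message(sprintf("[fingerprints] scheme=%s on %d molecules", scheme, nrow(library)))
    fps <- library_fingerprints(library, scheme)
  }
  message(sprintf(
    "[tsne] n=%d perplexity=%.3g iterations=%d learning_rate=%.3g early_exaggeration=%.3g seed=%d metric=%s",
    nrow(fps), config$perplexity, config$iterations, config$learning_rate,
    config$early_exaggeration, config$seed, config$metric))
  emb <- tsne_embed(fps, config)
  message(sprintf("[agglomerate] linkage=%s", linkage))
  dendro <- agglomerate(emb, linkage)
  message(sprintf("[cut] k=%d", k))
  assignment <- cut_to_k(dendro, k)
  structure(
    list(assignment = assignment, embedding = emb, dendrogram = dendro,
         fingerprints = fps,
         params = list(scheme = attr(fps, "scheme"), k = as.integer(k),
                       linkage = linkage, config = config)),
    class = "tgv_cluster_result"
  )
}

#' @export
print.tgv_cluster_result <- function(x, ...) {
  print(x$assignment)
  invisible(x)
}

#' Cluster table for export
#'
#' @param result a [cluster_pipeline()] result.
#' @param library optional parsed library supplying display names.
#' @return data.frame with columns id, name, cluster, x, y, z.
#' @export
cluster_table <- function(result, library = NULL) {
  stopifnot(inherits(result, "tgv_cluster_result"))
  ids <- names(result$assignment$labels)
  nm <- if (!is.null(library)) library$name[match(ids, library$id)] else ids
  data.frame(id = ids, name = nm,
             cluster = unname(result$assignment$labels),
             result$embedding$coords[ids, , drop = FALSE],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 is the expectation under random
#' labeling.
#'
#' @param a,b label vectors of equal length (any types coercible to factor).
#'   If both are named, `b` is aligned to `a`'s names.
#' @return The ARI, a number `<= 1`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    stopifnot(setequal(names(a), names(b)))
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
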