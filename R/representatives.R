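#' Select a cluster's representative molecule (Tanimoto medoid)
#'
#' The representative is the member with the highest arithmetic mean
#' Tanimoto similarity to all other members of the cluster (self excluded).
#' A singleton cluster's sole member is its representative with
#' `mean_similarity` defined as 1. Ties are broken by the lexicographically
#' smallest molecule id.
#'
#' @param fps fingerprints of the cluster members: list of fingerprints or
#'   a binary matrix (rows = members).
#' @param ids member identifiers (defaults to rownames / list names).
#' @param cluster optional cluster index to record in the result.
#' @return A one-row data.frame with columns `cluster`, `id`,
#'   `mean_similarity`.
#' @export
select_representative <- function(fps, ids = NULL, cluster = NA_integer_) {
  M <- as_fp_matrix(fps, ids)
  m <- nrow(M)
  if (m == 0L) stopf("empty cluster has no representative")
  ids <- rownames(M)
  if (m == 1L) {
    return(data.frame(cluster = cluster, id = ids, mean_similarity = 1,
                      stringsAsFactors = FALSE))
  }
  S <- similarity_matrix(M)
  mean_sim <- (rowSums(S) - 1) / (m - 1) # drop the unit self-similarity
  best <- order(-mean_sim, ids)[1]
  data.frame(cluster = cluster, id = ids[best],
             mean_similarity = unname(mean_sim[best]),
             stringsAsFactors = FALSE)
}

#' Select a representative for every cluster
#'
#' @param assignment a [cut_to_k()] / [cluster_pipeline()]`$assignment`
#'   result, or a named integer vector of cluster labels.
#' @param fps fingerprints for all labeled molecules (binary matrix or
#'   list), rownames/names matching the assignment's molecule ids.
#' @return data.frame with one row per cluster: `cluster`, `id`,
#'   `mean_similarity`, ordered by cluster index.
#' @examples
#' lib <- gen_fingerprint_library(k = 2, m = 5, bits = 64,
#'                                flip_prob = 0, seed = 3)
#' select_all(lib$true_labels, lib$fingerprints)
#' @export
select_all <- function(assignment, fps) {
  labels <- if (inherits(assignment, "tgv_clusters")) assignment$labels else assignment
  stopifnot(!is.null(names(labels)))
  M <- as_fp_matrix(fps)
  missing_ids <- setdiff(names(labels), rownames(M))
  if (length(missing_ids) > 0L) {
    stopf("no fingerprint for molecule(s): %s", paste(missing_ids, collapse = ", "))
  }
  ks <- sort(unique(labels))
  out <- do.call(rbind, lapply(ks, function(k) {
    members <- names(labels)[labels == k]
    select_representative(M[members, , drop = FALSE], cluster = k)
  }))
  rownames(out) <- NULL
  out
}
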