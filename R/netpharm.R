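# Network-pharmacology stage: disease-gene merging, target intersection,
# molecule ranking, hub-gene ranking, and hypergeometric enrichment.

#' Normalize gene symbols into a set
#'
#' Trims whitespace, upper-cases, drops empties and duplicates. No alias
#' resolution is attempted.
#'
#' @param genes character vector of gene symbols.
#' @return A sorted character vector of unique, upper-case symbols.
#' @export
gene_set <- function(genes) {
  g <- toupper(trimws(as.character(genes)))
  sort(unique(g[nzchar(g) & !is.na(g)]))
}

#' Read a disease-gene source list (TSV: symbol [, score])
#'
#' @param path TSV file with a header; first column gene symbols, optional
#'   second column a numeric relevance score.
#' @param source label for the source (defaults to the file name).
#' @return data.frame with columns `symbol` and `score` (NA when the file
#'   carries no score column), attribute `source`.
#' @export
read_scored_gene_list <- function(path, source = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(symbol = as.character(df[[1]]),
                    score = if (ncol(df) >= 2) as.numeric(normalize_minus(as.character(df[[2]])))
                            else NA_real_,
                    stringsAsFactors = FALSE)
  if (any(!is.na(out$score) & !is.finite(out$score))) {
    stopf("non-finite relevance scores in %s", path)
  }
  attr(out, "source") <- source
  out
}

#' Merge disease-gene source lists into one target set
#'
#' Takes the union of all sources after applying the relevance-score
#' filter: scored records are kept only when the score exceeds `threshold`
#' (strictly by default, mirroring a "score of over 5" rule); unscored
#' records are always kept. Symbols are case-normalized and deduplicated.
#'
#' @param lists a list of sources; each element is either a character
#'   vector of symbols or a data.frame with columns `symbol` and
#'   (optionally) `score` (see [read_scored_gene_list()]).
#' @param threshold relevance-score cutoff (default 5).
#' @param strict if `TRUE` (default) keep scores `> threshold`; if `FALSE`
#'   keep `>= threshold`.
#' @return Character vector: the merged disease gene set. Empty union is
#'   an error.
#' @examples
#' merge_disease_genes(list(
#'   data.frame(symbol = c("g1", "g2", "g3"), score = c(4.9, 5.0, 5.1)),
#'   c("LEP", "ADIPOQ")))
#' @export
merge_disease_genes <- function(lists, threshold = 5, strict = TRUE) {
  stopifnot(is.list(lists), length(lists) >= 1L)
  parts <- lapply(lists, function(l) {
    if (is.character(l)) return(gene_set(l))
    stopifnot(is.data.frame(l), "symbol" %in% names(l))
    score <- if ("score" %in% names(l)) l$score else rep(NA_real_, nrow(l))
    keep <- is.na(score) | (if (strict) score > threshold else score >= threshold)
    gene_set(l$symbol[keep])
  })
  merged <- gene_set(unlist(parts))
  if (length(merged) == 0L) stopf("merged disease gene set is empty")
  merged
}

#' Intersect a target set with a disease gene set
#'
#' @param targets,disease character vectors of gene symbols (normalized
#'   internally).
#' @return list with `genes` (sorted intersection) and `count`.
#' @export
gene_overlap <- function(targets, disease) {
  inter <- intersect(gene_set(targets), gene_set(disease))
  list(genes = sort(inter), count = length(inter))
}

#' Rank molecules by target overlap with a disease gene set
#'
#' Molecules are ordered by the number of their predicted targets that are
#' also disease genes, descending; ties are broken by molecule id
#' ascending.
#'
#' @param target_map named list: molecule id -> character vector of target
#'   gene symbols.
#' @param disease character vector: the disease gene set.
#' @param top how many molecules to return (default all).
#' @return data.frame with columns `id` and `count`, at most `top` rows.
#' @export
rank_molecules <- function(target_map, disease, top = Inf) {
  stopifnot(is.list(target_map))
  if (length(target_map) == 0L) stopf("empty target map")
  stopifnot(!is.null(names(target_map)), top >= 1)
  dis <- gene_set(disease)
  counts <- vapply(target_map, function(g) gene_overlap(g, dis)$count, 1L)
  ord <- order(-counts, names(target_map))
  out <- data.frame(id = names(target_map)[ord], count = unname(counts[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, n = if (is.finite(top)) as.integer(top) else nrow(out))
}

#' Read a compound-target map (TSV: molecule_id, symbol)
#'
#' @param path two-column TSV with a header.
#' @return named list: molecule id -> character vector of target symbols.
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(gene_set_keep_dups(df[[2]]), df[[1]])
}

#' @noRd
gene_set_keep_dups <- function(genes) toupper(trimws(as.character(genes)))

#' Read a PPI edge list (two-column TSV)
#'
#' Builds an undirected gene-interaction network; self-loops and duplicate
#' edges are dropped.
#'
#' @param path two-column TSV with a header row.
#' @return An `igraph` graph with gene symbols as vertex names.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_gene_network(df)
}

#' Build a gene-interaction network from an edge table
#'
#' @param edges data.frame (or 2-column matrix) of gene symbol pairs.
#' @return A simplified undirected `igraph` graph.
#' @export
as_gene_network <- function(edges) {
  if (igraph::is_igraph(edges)) return(igraph::simplify(igraph::as_undirected(edges)))
  em <- cbind(gene_set_keep_dups(edges[[1]]), gene_set_keep_dups(edges[[2]]))
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  igraph::simplify(g)
}

#' Top hub genes by degree
#'
#' Ranks network nodes by degree centrality (the conventional hub notion),
#' descending; ties are broken by gene symbol ascending. Returns at most
#' `n` genes (fewer when the network is smaller).
#'
#' @param network an `igraph` graph or an edge data.frame.
#' @param n number of hubs to return (default 10).
#' @return data.frame with columns `gene` and `degree`.
#' @export
top_hubs <- function(network, n = 10) {
  g <- as_gene_network(network)
  if (igraph::vcount(g) == 0L) stopf("empty network")
  stopifnot(n >= 1)
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  out <- data.frame(gene = names(deg)[ord], degree = unname(deg[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, n = as.integer(min(n, nrow(out))))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: per line, set name, description, then member
#'   genes, tab-separated.
#' @return Named list of character vectors (normalized symbols); the
#'   descriptions are kept in attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0L) stopf("GMT line(s) with fewer than 3 fields: %s",
                              paste(bad, collapse = ", "))
  sets <- lapply(fields, function(f) gene_set(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' For each annotation term, tests over-representation of the query genes
#' with the upper-tail hypergeometric probability `P(X >= k)` of drawing
#' `k` or more annotated genes when `n` query genes are sampled without
#' replacement from a universe of `N` genes of which `K` carry the
#' annotation. P-values are adjusted across terms with Benjamini-Hochberg.
#'
#' @param query character vector of query gene symbols; must be a subset
#'   of the universe.
#' @param annotations named list of gene sets (e.g. [read_gmt()]); each
#'   set is intersected with the universe first.
#' @param universe background gene set; defaults to the union of all
#'   annotation sets.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `p_adjusted`, sorted by p-value.
#' @export
hypergeom_enrich <- function(query, annotations, universe = NULL) {
  stopifnot(is.list(annotations), length(annotations) >= 1L,
            !is.null(names(annotations)))
  query <- gene_set(query)
  universe <- if (is.null(universe)) gene_set(unlist(annotations)) else gene_set(universe)
  stray <- setdiff(query, universe)
  if (length(stray) > 0L) {
    stopf("query genes missing from the universe: %s", paste(stray, collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotations), function(term) {
    ann <- intersect(gene_set(annotations[[term]]), universe)
    K <- length(ann)
    k <- length(intersect(ann, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Union hub genes with their functional-neighbor lists
#'
#' Deduplicated union of the hub genes and every neighbor list, after
#' symbol normalization — the list-expansion arithmetic used when growing
#' a hub-centred gene database from per-hub association queries.
#'
#' @param hubs character vector of hub gene symbols.
#' @param neighbor_lists list of character vectors, one per hub.
#' @return Sorted character vector of unique symbols.
#' @examples
#' merge_neighbor_lists(c("PPARG", "PTGS2"),
#'                      list(paste0("A", 1:20), paste0("B", 1:20)))
#' @export
merge_neighbor_lists <- function(hubs, neighbor_lists = list()) {
  stopifnot(is.list(neighbor_lists))
  gene_set(c(hubs, unlist(neighbor_lists)))
}
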