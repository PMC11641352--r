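# Seeded synthetic generators emulating every input the pipeline consumes,
# each with exactly known ground truth.

#' Generate a planted-cluster fingerprint library
#'
#' Emulates a compound library with `k` chemical families. Bit positions
#' are split into `k` disjoint blocks; each family's prototype sets a
#' random 80% of its own block, so prototypes share no bits. Every member
#' copies its prototype and then loses each set bit independently with
#' probability `flip_prob` (one-sided dropout, mimicking substructure
#' variation within a family); a member that would end up all-zero keeps
#' one random prototype bit. With `flip_prob = p` the expected
#' within-family Tanimoto is `(1-p)^2 / (1-p^2)` (about 0.90 at p = 0.05)
#' while between-family similarity stays at 0.
#'
#' @param k number of planted clusters.
#' @param m members per cluster.
#' @param bits fingerprint length (default 166, MACCS-like).
#' @param flip_prob per-bit dropout probability in `[0, 0.5)`.
#' @param seed integer RNG seed (required; generation is bit-reproducible).
#' @return Object of class `tgv_planted_library`: list with `fingerprints`
#'   (k*m x bits binary matrix, rownames are molecule ids), `true_labels`
#'   (named integer vector) and `params`.
#' @examples
#' lib <- gen_fingerprint_library(k = 2, m = 4, bits = 64,
#'                                flip_prob = 0, seed = 1)
#' lib$true_labels
#' @export
gen_fingerprint_library <- function(k = 6, m = 20, bits = 166,
                                    flip_prob = 0.05, seed) {
  if (missing(seed)) stopf("gen_fingerprint_library() requires a seed")
  if (k < 1 || m < 1) stopf("k and m must be >= 1")
  if (flip_prob < 0 || flip_prob >= 0.5) stopf("flip_prob must be in [0, 0.5)")
  block <- bits %/% k
  if (block < 2L) stopf("bits = %d too small for k = %d clusters", bits, k)
  with_seed(seed, {
    n <- k * m
    M <- matrix(0L, n, bits)
    labels <- rep(seq_len(k), each = m)
    for (cl in seq_len(k)) {
      block_bits <- ((cl - 1L) * block + 1L):(cl * block)
      proto <- sort(sample(block_bits, max(2L, round(0.8 * block))))
      rows <- which(labels == cl)
      for (r in rows) {
        keep <- proto[stats::runif(length(proto)) >= flip_prob]
        if (length(keep) == 0L) keep <- sample(proto, 1L)
        M[r, keep] <- 1L
      }
    }
    ids <- sprintf("MOL%04d", seq_len(n))
    rownames(M) <- ids
    names(labels) <- ids
    structure(
      list(fingerprints = M, true_labels = labels,
           params = list(k = k, m = m, bits = bits,
                         flip_prob = flip_prob, seed = seed)),
      class = "tgv_planted_library"
    )
  })
}

#' @export
print.tgv_planted_library <- function(x, ...) {
  p <- x$params
  cat(sprintf("<tgv_planted_library: %d clusters x %d members, %d bits, flip_prob %.3g, seed %d>\n",
              p$k, p$m, p$bits, p$flip_prob, p$seed))
  invisible(x)
}

#' Generate a compound-target map with exact planted disease overlaps
#'
#' Builds a disease gene set `G0001..G<n_disease>` and, per molecule, a
#' target set whose intersection with the disease set has exactly the size
#' given in `overlap_spec`; `n_decoys` additional non-disease targets
#' (`N####` symbols) are added per molecule.
#'
#' @param overlap_spec named integer vector: molecule id -> planted
#'   overlap count (each must be `<= n_disease`).
#' @param n_disease size of the disease gene set.
#' @param seed integer RNG seed.
#' @param n_decoys non-disease targets added per molecule (default 5).
#' @return list with `target_map` (named list, see [rank_molecules()]) and
#'   `disease` (character vector).
#' @export
gen_gene_fixtures <- function(overlap_spec, n_disease, seed, n_decoys = 5) {
  if (missing(seed)) stopf("gen_gene_fixtures() requires a seed")
  stopifnot(!is.null(names(overlap_spec)), n_disease >= 1)
  spec <- as.integer(overlap_spec)
  if (any(spec < 0) || any(spec > n_disease)) {
    stopf("infeasible overlap spec: counts must be in 0..%d", n_disease)
  }
  disease <- sprintf("G%04d", seq_len(n_disease))
  with_seed(seed, {
    decoy_pool <- sprintf("N%04d", seq_len(max(1L, n_decoys * length(spec))))
    target_map <- lapply(seq_along(spec), function(i) {
      hits <- if (spec[i] > 0) sample(disease, spec[i]) else character()
      decoys <- if (n_decoys > 0) sample(decoy_pool, n_decoys) else character()
      sort(c(hits, decoys))
    })
    names(target_map) <- names(overlap_spec)
    list(target_map = target_map, disease = disease)
  })
}

#' Generate an interaction network with planted hub degrees
#'
#' Realizes a degree sequence in which the named hub genes get the given
#' (strictly decreasing) degrees and all remaining nodes get background
#' degrees drawn from `background` — kept strictly below the smallest hub
#' degree so the hub ranking is unambiguous. The sequence is realized
#' deterministically (Havel-Hakimi); a non-graphical sequence is an error.
#'
#' @param n_nodes total node count (must exceed the number of hubs).
#' @param hub_degrees named integer vector, strictly decreasing degrees.
#' @param seed integer RNG seed (background degree sampling).
#' @param background range of background degrees (default `1:3`).
#' @return An `igraph` graph whose [top_hubs()] ranking starts with the
#'   hubs in the given order.
#' @export
gen_network <- function(n_nodes, hub_degrees, seed, background = 1:3) {
  if (missing(seed)) stopf("gen_network() requires a seed")
  stopifnot(!is.null(names(hub_degrees)), n_nodes > length(hub_degrees))
  hd <- as.integer(hub_degrees)
  if (length(hd) > 1 && any(diff(hd) >= 0)) {
    stopf("hub degrees must be strictly decreasing for an unambiguous ranking")
  }
  n_bg <- n_nodes - length(hd)
  if (max(background) >= min(hd)) {
    stopf("background degrees must stay below the smallest hub degree")
  }
  with_seed(seed, {
    bg <- sample(background, n_bg, replace = TRUE)
    # parity fix: a degree sequence must have an even sum
    if ((sum(hd) + sum(bg)) %% 2 == 1) {
      adjustable <- which(bg + 1 < min(hd))
      if (length(adjustable) == 0L) adjustable <- which(bg > 1)
      if (length(adjustable) == 0L) stopf("cannot fix degree-sum parity")
      i <- adjustable[1]
      bg[i] <- if (bg[i] + 1 < min(hd)) bg[i] + 1L else bg[i] - 1L
    }
    degs <- c(hd, bg)
    names(degs) <- c(names(hub_degrees), sprintf("B%04d", seq_len(n_bg)))
    if (!igraph::is_graphical(degs)) stopf("degree sequence is not graphical")
    g <- igraph::realize_degseq(degs, method = "smallest")
    igraph::V(g)$name <- names(degs)
    g
  })
}

#' Generate Gaussian MM/PBSA snapshot samples
#'
#' Draws `n` per-snapshot component samples from independent normals with
#' the given means and standard deviations; `sds = 0` reproduces the means
#' exactly.
#'
#' @param means,sds numeric vectors with entries named `evdw`, `eele`,
#'   `gsolv` (population mean and sd per component, kcal/mol).
#' @param n number of snapshots (default 20).
#' @param seed integer RNG seed.
#' @return data.frame `snapshot`, `evdw`, `eele`, `gsolv` for
#'   [aggregate_snapshots()].
#' @export
gen_mmpbsa_snapshots <- function(means, sds, n = 20, seed) {
  if (missing(seed)) stopf("gen_mmpbsa_snapshots() requires a seed")
  comp <- c("evdw", "eele", "gsolv")
  stopifnot(all(comp %in% names(means)), all(comp %in% names(sds)), n >= 1)
  if (any(!is.finite(unlist(means[comp]))) || any(unlist(sds[comp]) < 0)) {
    stopf("means must be finite and sds non-negative")
  }
  with_seed(seed, {
    out <- data.frame(snapshot = seq_len(n))
    for (cn in comp) {
      out[[cn]] <- stats::rnorm(n, mean = means[[cn]], sd = sds[[cn]])
    }
    out
  })
}

#' Generate hydrogen-bond frame records with exact occupancies
#'
#' For each donor-acceptor pair the number of frames containing the pair
#' is fixed at `occupancy / 100 * n_frames` (which must be a whole number
#' — occupancies are hit exactly, not in expectation); the particular
#' frames are sampled with the seed. Frames left without any bond are
#' emitted as empty-marker rows so [hbond_stats()] counts them.
#'
#' @param occupancy_map named numeric vector of occupancy percentages in
#'   `[0, 100]`; names are `"donor|acceptor"` pairs.
#' @param n_frames total number of frames.
#' @param seed integer RNG seed.
#' @return data.frame `frame`, `donor`, `acceptor` (empty strings marking
#'   bond-free frames), attribute `n_frames`.
#' @examples
#' fr <- gen_hbond_frames(c("ARG81-Side|LIG1-Side" = 92.5), 1000, seed = 1)
#' hbond_stats(fr)$occupancy$occupancy_pct
#' @export
gen_hbond_frames <- function(occupancy_map, n_frames, seed) {
  if (missing(seed)) stopf("gen_hbond_frames() requires a seed")
  stopifnot(!is.null(names(occupancy_map)), n_frames >= 1)
  occ <- as.numeric(occupancy_map)
  if (any(occ < 0 | occ > 100)) stopf("occupancies must be in [0, 100]")
  counts <- occ / 100 * n_frames
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stopf("occupancies must correspond to whole frame counts at n_frames = %d",
          n_frames)
  }
  counts <- as.integer(round(counts))
  with_seed(seed, {
    rows <- lapply(seq_along(counts), function(i) {
      if (counts[i] == 0L) return(NULL)
      pair <- strsplit(names(occupancy_map)[i], "|", fixed = TRUE)[[1]]
      if (length(pair) != 2L) {
        stopf("occupancy_map names must be 'donor|acceptor', got '%s'",
              names(occupancy_map)[i])
      }
      data.frame(frame = sort(sample.int(n_frames, counts[i])),
                 donor = pair[1], acceptor = pair[2],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(frame = integer(), donor = character(),
                        acceptor = character(), stringsAsFactors = FALSE)
    }
    empty <- setdiff(seq_len(n_frames), unique(out$frame))
    if (length(empty) > 0L) {
      out <- rbind(out, data.frame(frame = empty, donor = "", acceptor = "",
                                   stringsAsFactors = FALSE))
    }
    out <- out[order(out$frame, out$donor, out$acceptor), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_frames") <- as.integer(n_frames)
    out
  })
}
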