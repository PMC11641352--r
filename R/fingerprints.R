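#' Parse a SMILES compound library
#'
#' Reads a `.smi`-style file with one record per line: a SMILES string,
#' whitespace (space or tab), an identifier, and an optional display name.
#' Blank lines and lines starting with `#` are skipped. Every SMILES is
#' validated and canonicalized through OpenBabel; the input string is kept
#' alongside the canonical form.
#'
#' @param path path to the SMILES file.
#' @return A data.frame of class `tgv_library` with columns `id`, `name`,
#'   `smiles` (as entered) and `canonical` (canonical SMILES), in file order.
#' @examples
#' smi <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene"), smi)
#' parse_library(smi)
#' @export
parse_library <- function(path) {
  if (!file.exists(path)) stopf("SMILES file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) {
    return(empty_library())
  }
  recs <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(fields) < 2L) {
      return(list(line = i, error = "expected 'SMILES id [name]'"))
    }
    can <- canonical_smiles(fields[1])
    if (is.na(can)) {
      return(list(line = i, error = sprintf("unparseable SMILES '%s'", fields[1])))
    }
    list(line = i, id = fields[2],
         name = if (length(fields) >= 3L) paste(fields[-(1:2)], collapse = " ") else fields[2],
         smiles = fields[1], canonical = can)
  })
  bad <- Filter(function(r) !is.null(r$error), recs)
  if (length(bad) > 0L) {
    msgs <- vapply(bad, function(r) sprintf("line %d: %s", r$line, r$error), "")
    stopf("invalid SMILES records:\n%s", paste(msgs, collapse = "\n"))
  }
  lib <- data.frame(
    id = vapply(recs, `[[`, "", "id"),
    name = vapply(recs, `[[`, "", "name"),
    smiles = vapply(recs, `[[`, "", "smiles"),
    canonical = vapply(recs, `[[`, "", "canonical"),
    stringsAsFactors = FALSE
  )
  dup <- unique(lib$id[duplicated(lib$id)])
  if (length(dup) > 0L) {
    stopf("duplicate molecule ids: %s", paste(dup, collapse = ", "))
  }
  class(lib) <- c("tgv_library", "data.frame")
  lib
}

#' @noRd
empty_library <- function() {
  lib <- data.frame(id = character(), name = character(),
                    smiles = character(), canonical = character(),
                    stringsAsFactors = FALSE)
  class(lib) <- c("tgv_library", "data.frame")
  lib
}

#' Canonicalize a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return The canonical SMILES, or `NA_character_` if the string is not a
#'   valid molecular graph.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, " mol\n")),
    error = function(e) ""
  )
  tok <- strsplit(trimws(out), "[ \t\n]+")[[1]]
  if (length(tok) == 0L || !nzchar(tok[1])) return(NA_character_)
  tok[1]
}

#' Compute a binary molecular fingerprint
#'
#' Two schemes are supported: `"maccs"`, the 166-key MACCS substructure
#' fingerprint (computed by OpenBabel), and `"hashed"`, a 2048-bit hashed
#' topological fingerprint that enumerates all linear atom/bond paths of up
#' to seven bonds and hashes each onto a bit position (FNV-1a). The molecule
#' is canonicalized first, so different entry forms of the same structure
#' yield identical fingerprints.
#'
#' @param mol a SMILES string, or a single-row subset of a
#'   [parse_library()] result.
#' @param scheme `"maccs"` (166 bits, default) or `"hashed"` (2048 bits).
#' @return An integer 0/1 vector of class `tgv_fp` with attribute `scheme`.
#'   An all-zero fingerprint (degenerate molecule) is an error.
#' @examples
#' fp <- compute_fingerprint("CCO", "maccs")
#' sum(fp)
#' @export
compute_fingerprint <- function(mol, scheme = c("maccs", "hashed")) {
  scheme <- match.arg(scheme)
  smiles <- if (is.data.frame(mol)) {
    stopifnot(nrow(mol) == 1L)
    mol$smiles
  } else {
    stopifnot(is.character(mol), length(mol) == 1L)
    mol
  }
  can <- canonical_smiles(smiles)
  if (is.na(can)) stopf("unparseable SMILES '%s'", smiles)
  bits <- if (scheme == "maccs") maccs_bits(can) else hashed_path_bits(can)
  if (sum(bits) == 0L) {
    stopf("all-zero %s fingerprint for '%s' (degenerate molecule)", scheme, smiles)
  }
  new_fingerprint(bits, scheme)
}

#' @noRd
new_fingerprint <- function(bits, scheme) {
  structure(as.integer(bits), scheme = scheme, class = "tgv_fp")
}

#' @export
print.tgv_fp <- function(x, ...) {
  cat(sprintf("<tgv_fp %s: %d bits, %d set>\n",
              attr(x, "scheme"), length(x), sum(x)))
  invisible(x)
}

# MACCS keys via OpenBabel: returned as a 256-slot vector whose set
# positions are the key numbers 1..166; slots past 166 are always empty.
#' @noRd
maccs_bits <- function(canonical) {
  raw <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", paste0(canonical, " mol\n"), identity),
    "MACCS"
  )
  as.integer(raw[seq_len(166)])
}

# 2048-bit hashed topological path fingerprint. All simple linear paths of
# 0..7 bonds are enumerated on the canonical structure; each path string
# (element symbols interleaved with bond orders, direction-normalised) sets
# one bit at FNV-1a(path) mod 2048.
#' @noRd
hashed_path_bits <- function(canonical, nbits = 2048L, max_len = 7L) {
  g <- mol_graph(canonical)
  paths <- enumerate_paths(g, max_len)
  bits <- integer(nbits)
  for (s in paths) bits[(fnv1a32(s) %% nbits) + 1L] <- 1L
  bits
}

# Atom/bond tables from an SDF rendering of the canonical SMILES.
#' @noRd
mol_graph <- function(canonical) {
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(canonical, " mol\n"))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf_txt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  sdf <- sdfset[[1]]
  elems <- sub("_.*$", "", rownames(ChemmineR::atomblock(sdf)))
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bonds <- matrix(integer(), ncol = 3)
  } else {
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  adj <- vector("list", length(elems))
  if (nrow(bonds) > 0L) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1]; b <- bonds[r, 2]; o <- bonds[r, 3]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  list(elems = elems, adj = adj)
}

# Depth-first enumeration of simple paths; each path is recorded once in a
# direction-normalised form so the bit set is independent of atom numbering.
#' @noRd
enumerate_paths <- function(g, max_len) {
  out <- new.env(parent = emptyenv())
  n <- length(g$elems)
  walk <- function(atom, visited, repr) {
    key <- paste(repr, collapse = "")
    rev_key <- path_reverse(repr)
    assign(min(key, rev_key), TRUE, envir = out)
    if ((length(repr) - 1L) / 2L >= max_len) return()
    nb <- g$adj[[atom]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), c(repr, as.character(nb[r, 2]), g$elems[nxt]))
    }
  }
  for (a in seq_len(n)) walk(a, a, g$elems[a])
  ls(out)
}

#' @noRd
path_reverse <- function(repr) paste(rev(repr), collapse = "")

#' Tanimoto similarity of two binary fingerprints
#'
#' The Tanimoto (Jaccard) coefficient `|a AND b| / |a OR b|` on set bits.
#'
#' @param a,b fingerprints of the same scheme and length ([compute_fingerprint()]
#'   results or plain 0/1 vectors), neither all-zero.
#' @return A similarity in `[0, 1]`; exactly 1 for identical fingerprints.
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 2 shared / 4 in union
#' @export
tanimoto <- function(a, b) {
  sa <- attr(a, "scheme"); sb <- attr(b, "scheme")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    stopf("fingerprint scheme mismatch: %s vs %s", sa, sb)
  }
  a <- as.integer(unclass(a)); b <- as.integer(unclass(b))
  if (length(a) != length(b)) {
    stopf("fingerprint length mismatch: %d vs %d", length(a), length(b))
  }
  if (any(is.na(a)) || any(is.na(b)) || any(a < 0 | a > 1) || any(b < 0 | b > 1)) {
    stopf("fingerprints must be binary 0/1 vectors")
  }
  na <- sum(a); nb <- sum(b)
  if (na == 0L || nb == 0L) stopf("all-zero fingerprint in tanimoto()")
  inter <- sum(a & b)
  inter / (na + nb - inter)
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps a list of fingerprints (uniform scheme) or an n x L binary
#'   matrix with one fingerprint per row.
#' @param ids molecule identifiers; defaults to list names / rownames.
#' @return A symmetric n x n matrix of Tanimoto coefficients with unit
#'   diagonal, `ids` as dimnames.
#' @export
similarity_matrix <- function(fps, ids = NULL) {
  M <- as_fp_matrix(fps, ids)
  n <- nrow(M)
  if (n == 0L) stopf("similarity_matrix() needs at least one fingerprint")
  on_counts <- rowSums(M)
  if (any(on_counts == 0)) {
    stopf("all-zero fingerprint(s): %s",
          paste(rownames(M)[on_counts == 0], collapse = ", "))
  }
  inter <- tcrossprod(M)
  union <- outer(on_counts, on_counts, "+") - inter
  S <- inter / union
  S <- (S + t(S)) / 2  # enforce exact symmetry against float noise
  diag(S) <- 1
  dimnames(S) <- list(rownames(M), rownames(M))
  S
}

#' Assemble fingerprints into a binary matrix
#'
#' @param fps list of `tgv_fp` objects (or 0/1 vectors) or a binary matrix.
#' @param ids optional identifiers used as rownames.
#' @return An n x L integer 0/1 matrix, one fingerprint per row.
#' @export
as_fp_matrix <- function(fps, ids = NULL) {
  if (is.matrix(fps)) {
    M <- fps
  } else if (is.list(fps)) {
    if (length(fps) == 0L) stopf("empty fingerprint list")
    lens <- vapply(fps, length, 1L)
    if (length(unique(lens)) != 1L) stopf("fingerprints differ in length")
    schemes <- unique(unlist(lapply(fps, attr, "scheme")))
    if (length(schemes) > 1L) {
      stopf("mixed fingerprint schemes: %s", paste(schemes, collapse = ", "))
    }
    M <- do.call(rbind, lapply(fps, function(f) as.integer(unclass(f))))
    if (is.null(ids)) ids <- names(fps)
  } else {
    stopf("fps must be a list of fingerprints or a binary matrix")
  }
  storage.mode(M) <- "integer"
  if (!is.null(ids)) rownames(M) <- ids
  if (is.null(rownames(M))) rownames(M) <- sprintf("M%04d", seq_len(nrow(M)))
  M
}

#' Compute fingerprints for a whole library
#'
#' @param library a [parse_library()] result.
#' @param scheme fingerprint scheme, as in [compute_fingerprint()].
#' @return An n x L binary matrix, rownames = molecule ids.
#' @export
library_fingerprints <- function(library, scheme = c("maccs", "hashed")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(library), nrow(library) >= 1L)
  fps <- lapply(seq_len(nrow(library)), function(i) {
    compute_fingerprint(library$smiles[i], scheme)
  })
  M <- as_fp_matrix(fps, ids = library$id)
  attr(M, "scheme") <- scheme
  M
}

#' Write a similarity matrix as TSV
#'
#' Square TSV with molecule ids as header row and first column.
#'
#' @param sim a [similarity_matrix()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  df <- data.frame(id = rownames(sim), sim, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
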