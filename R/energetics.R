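# Post-docking and post-MD bookkeeping: best-combination screening,
# MM/PBSA component aggregation, hydrogen-bond occupancy statistics.

#' Read a docking score table (CSV: molecule,target,energy)
#'
#' Energies are in kcal/mol; a Unicode minus in transcribed tables is
#' normalized to ASCII on read. Duplicate (molecule, target) pairs and
#' non-finite energies are rejected.
#'
#' @param path CSV file with a header row.
#' @return data.frame with columns `molecule`, `target`, `energy`.
#' @export
read_docking_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 3L)
  out <- data.frame(molecule = as.character(df[[1]]),
                    target = as.character(df[[2]]),
                    energy = as.numeric(normalize_minus(as.character(df[[3]]))),
                    stringsAsFactors = FALSE)
  validate_docking_table(out)
}

#' @noRd
validate_docking_table <- function(df) {
  stopifnot(all(c("molecule", "target", "energy") %in% names(df)))
  if (nrow(df) == 0L) stopf("empty docking score table")
  if (any(!is.finite(df$energy))) stopf("non-finite docking energies")
  key <- paste(df$molecule, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("duplicate (molecule, target) pairs: %s",
          paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }
  df
}

#' Best molecule-target combination by docking energy
#'
#' Screens a docking score table for the row with the lowest (most
#' favourable) energy, optionally restricted to one target. Ties are
#' broken by molecule id then target id, ascending.
#'
#' @param table a [read_docking_table()]-style data.frame.
#' @param target optional target id to restrict the scan to.
#' @return One-row data.frame `molecule`, `target`, `energy`.
#' @examples
#' scores <- data.frame(molecule = c("A", "B"), target = "T",
#'                      energy = c(-7.2, -8.1))
#' best_combination(scores)
#' @export
best_combination <- function(table, target = NULL) {
  df <- validate_docking_table(table)
  if (!is.null(target)) {
    if (!target %in% df$target) stopf("unknown target '%s'", target)
    df <- df[df$target == target, , drop = FALSE]
  }
  ord <- order(df$energy, df$molecule, df$target)
  out <- df[ord[1], c("molecule", "target", "energy")]
  rownames(out) <- NULL
  out
}

#' Aggregate MM/PBSA per-snapshot energy components
#'
#' From per-snapshot van der Waals (`evdw`), electrostatic (`eele`) and
#' solvation (`gsolv`) terms (kcal/mol), derives the per-snapshot gas-phase
#' sum `ggas = evdw + eele` and total `gtotal = ggas + gsolv`, then reports
#' the mean and sample (n-1) standard deviation of every column. By
#' construction the component identities hold exactly on the means.
#'
#' @param samples data.frame with numeric columns `evdw`, `eele`, `gsolv`
#'   and an optional `snapshot` index column.
#' @return Object of class `tgv_energy`: list with `summary` (data.frame
#'   component/mean/sd in the order evdw, eele, gsolv, ggas, gtotal) and
#'   `n_snapshots`.
#' @export
aggregate_snapshots <- function(samples) {
  stopifnot(is.data.frame(samples), all(c("evdw", "eele", "gsolv") %in% names(samples)))
  n <- nrow(samples)
  if (n < 1L) stopf("need at least one snapshot")
  snap <- if ("snapshot" %in% names(samples)) samples$snapshot else seq_len(n)
  for (col in c("evdw", "eele", "gsolv")) {
    bad <- which(!is.finite(samples[[col]]))
    if (length(bad) > 0L) {
      stopf("non-finite %s at snapshot(s) %s", col,
            paste(snap[bad], collapse = ", "))
    }
  }
  X <- data.frame(evdw = samples$evdw, eele = samples$eele, gsolv = samples$gsolv)
  X$ggas <- X$evdw + X$eele
  X$gtotal <- X$ggas + X$gsolv
  sds <- if (n == 1L) rep(0, 5L) else vapply(X, stats::sd, 0)
  structure(
    list(summary = data.frame(component = names(X),
                              mean = unname(vapply(X, mean, 0)),
                              sd = unname(sds),
                              stringsAsFactors = FALSE),
         n_snapshots = n),
    class = "tgv_energy"
  )
}

#' @export
print.tgv_energy <- function(x, ...) {
  cat(sprintf("MM/PBSA aggregate over %d snapshots (kcal/mol):\n", x$n_snapshots))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-7s %8.2f +/- %.2f\n", s$component[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Gas-phase and total binding energies from component means
#'
#' The MM/PBSA column identities: `ggas = evdw + eele` and
#' `gtotal = ggas + gsolv`. Either supply all three mean components, or a
#' gas-phase mean plus solvation via `ggas`.
#'
#' @param evdw,eele,gsolv mean component energies (kcal/mol).
#' @param ggas optional precomputed gas-phase mean; when given, `evdw` and
#'   `eele` are not required.
#' @param digits round the result for printed-table comparison (default
#'   `NULL` = full precision); R's `round()` is round-half-even.
#' @return Named numeric vector `c(ggas, gtotal)`.
#' @examples
#' totals_from_means(-54.88, -32.45, 47.21)  # ggas -87.33, gtotal -40.12
#' @export
totals_from_means <- function(evdw = NULL, eele = NULL, gsolv, ggas = NULL,
                              digits = NULL) {
  if (is.null(ggas)) {
    stopifnot(is_scalar_number(evdw), is_scalar_number(eele))
    ggas <- evdw + eele
  }
  stopifnot(is_scalar_number(ggas), is_scalar_number(gsolv))
  out <- c(ggas = ggas, gtotal = ggas + gsolv)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Hydrogen-bond occupancy statistics over trajectory frames
#'
#' Per donor-acceptor pair, the occupancy is the percentage of frames in
#' which that pair forms at least one hydrogen bond; repeated occurrences
#' of a pair within one frame count once for occupancy but each counts
#' toward the bonds-per-frame average.
#'
#' @param frames data.frame with columns `frame` (integer index), `donor`,
#'   `acceptor`. Rows whose donor and acceptor are both empty mark frames
#'   with no bonds (so fully-bond-free frames still enter the denominator).
#' @param n_frames total number of frames; defaults to the number of
#'   distinct frame indices present in `frames`.
#' @return Object of class `tgv_hbond_summary`: list with `occupancy`
#'   (data.frame donor/acceptor/frames_present/occupancy_pct, sorted by
#'   occupancy descending), `mean_bonds_per_frame` and `n_frames`.
#' @export
hbond_stats <- function(frames, n_frames = NULL) {
  stopifnot(is.data.frame(frames), all(c("frame", "donor", "acceptor") %in% names(frames)))
  frames$donor <- as.character(frames$donor)
  frames$acceptor <- as.character(frames$acceptor)
  frames$donor[is.na(frames$donor)] <- ""
  frames$acceptor[is.na(frames$acceptor)] <- ""
  if (is.null(n_frames)) n_frames <- length(unique(frames$frame))
  if (n_frames < 1L) stopf("need at least one frame")
  bonds <- frames[nzchar(frames$donor) | nzchar(frames$acceptor), , drop = FALSE]
  if (nrow(bonds) > 0L) {
    pair <- paste(bonds$donor, bonds$acceptor, sep = "\t")
    present <- tapply(bonds$frame, pair, function(f) length(unique(f)))
    occ <- data.frame(
      donor = sub("\t.*$", "", names(present)),
      acceptor = sub("^.*\t", "", names(present)),
      frames_present = as.integer(present),
      occupancy_pct = 100 * as.integer(present) / n_frames,
      stringsAsFactors = FALSE
    )
    occ <- occ[order(-occ$occupancy_pct, occ$donor, occ$acceptor), , drop = FALSE]
    rownames(occ) <- NULL
  } else {
    occ <- data.frame(donor = character(), acceptor = character(),
                      frames_present = integer(), occupancy_pct = numeric(),
                      stringsAsFactors = FALSE)
  }
  structure(
    list(occupancy = occ,
         mean_bonds_per_frame = nrow(bonds) / n_frames,
         n_frames = as.integer(n_frames)),
    class = "tgv_hbond_summary"
  )
}

#' @export
print.tgv_hbond_summary <- function(x, ...) {
  cat(sprintf("Hydrogen bonds over %d frames: %.3g bonds/frame on average\n",
              x$n_frames, x$mean_bonds_per_frame))
  if (nrow(x$occupancy) > 0) {
    top <- utils::head(x$occupancy, 5)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s -> %s: %.2f%%\n", top$donor[i], top$acceptor[i],
                  top$occupancy_pct[i]))
    }
  }
  invisible(x)
}

#' Read hydrogen-bond frame records (CSV: frame,donor,acceptor)
#'
#' @param path CSV file with a header row.
#' @return data.frame suitable for [hbond_stats()].
#' @export
read_hbond_frames <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "character", "character"))
  names(df)[1:3] <- c("frame", "donor", "acceptor")
  df
}

#' Read MM/PBSA per-snapshot components (CSV: snapshot,evdw,eele,gsolv)
#'
#' @param path CSV file with a header row.
#' @return data.frame suitable for [aggregate_snapshots()].
#' @export
read_snapshots <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("evdw", "eele", "gsolv")) {
    df[[col]] <- as.numeric(normalize_minus(as.character(df[[col]])))
  }
  df
}

#' Load the bundled MM/PBSA component table for a target system
#'
#' Published-style mean +/- sd component tables for the six representative
#' triterpenoid ligands against PPARG and PTGS2, shipped as plain-text CSV.
#'
#' @param target `"PPARG"` or `"PTGS2"`.
#' @return data.frame: system, then mean and sd columns for evdw, eele,
#'   gsolv, ggas, gtotal.
#' @export
mmpbsa_table <- function(target = c("PPARG", "PTGS2")) {
  target <- match.arg(target)
  path <- system.file("extdata",
                      sprintf("mmpbsa_%s.csv", tolower(target)),
                      package = "tgvscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load the bundled docking energy table
#'
#' Docking energies (kcal/mol) of the six representative ligands against
#' PPARG and PTGS2, shipped as plain-text CSV.
#'
#' @return data.frame `molecule`, `target`, `energy`.
#' @export
docking_table <- function() {
  read_docking_table(system.file("extdata", "docking_energies.csv",
                                 package = "tgvscreen", mustWork = TRUE))
}
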