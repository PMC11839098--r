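## Conformer pools: Gibbs-style sampling of suite assignments with local
## clash-rejection resampling, per-pool suite frequencies, theoretical
## profiles, and PDB/JSON persistence.

#' Sample a pool of RNA conformers from suite weights
#'
#' Each chain is grown linkage by linkage; the suite of every linkage is
#' drawn independently from `weights`, and when the newly placed residue
#' sterically clashes with the chain built so far, only that linkage is
#' resampled (up to `max_retries` draws) - a local Gibbs-with-rejection
#' scheme that keeps runtime bounded.
#'
#' @param sequence Nucleotide string (A, U, C).
#' @param weights Named probability vector over the suite library (e.g.
#'   [uniform_suite_weights()]).
#' @param n_conformers Pool size (default 2000).
#' @param seed RNG seed.
#' @param library A `suite_library`.
#' @param max_retries Resampling budget per linkage (default 500).
#' @param clash_cutoff Heavy-atom clash distance (Angstrom, default 2.0);
#'   `NULL` disables steric rejection.
#' @return A `conformer_pool`: list with `conformers`, `h_pool` (empirical
#'   suite frequencies), `sequence`, `weights` (the sampling weights),
#'   `profiles` (NULL until [pool_profiles()] is called) and
#'   `selection_weights` (uniform until an ensemble fit supplies them).
#' @export
sample_pool <- function(sequence, weights, n_conformers = 2000, seed = 1,
                        library = load_suite_library(), max_retries = 500,
                        clash_cutoff = 2.0) {
  check_weights(weights, nrow(library))
  if (n_conformers < 1) stop("n_conformers must be >= 1")
  set.seed(seed)
  bases <- strsplit(toupper(sequence), "")[[1]]
  n <- length(bases)
  libdf <- as.data.frame(library)
  counts <- stats::setNames(rep(0, nrow(library)), library$name)
  conformers <- vector("list", n_conformers)
  max_backtracks <- 500
  max_restarts <- 20
  suite_rows <- split(libdf, seq_len(nrow(libdf)))
  for (cidx in seq_len(n_conformers)) {
    restarts <- 0
    repeat {  # whole-chain restarts are a last resort
      assignment <- character(n - 1)
      first <- sample.int(nrow(library), 1, prob = weights)
      res <- list(seed_residue(bases[1], libdf$delta_prev[first],
                               libdf$chi_prev[first]))
      ## flat coordinate/label state for fast clash checks
      xyz_res <- list(do.call(rbind, res[[1]]))
      name_res <- list(names(res[[1]]))
      tries_at <- integer(n - 1)
      backtracks <- 0
      j <- 1
      stuck_at <- 0L
      while (j <= n - 1) {
        sidx <- if (j == 1 && tries_at[1] == 0 && backtracks == 0) first
                else sample.int(nrow(library), 1, prob = weights)
        cand <- extend_residue(res[[j]], bases[j + 1], suite_rows[[sidx]])
        cand_xyz <- do.call(rbind, cand)
        ok <- is.null(clash_cutoff) ||
          !clash_xyz(cand_xyz, names(cand), xyz_res, name_res, j,
                     clash_cutoff)
        if (ok) {
          assignment[j] <- libdf$name[sidx]
          res[[j + 1]] <- cand
          xyz_res[[j + 1]] <- cand_xyz
          name_res[[j + 1]] <- names(cand)
          j <- j + 1
        } else {
          tries_at[j] <- tries_at[j] + 1
          if (tries_at[j] >= max_retries) {
            ## local move set exhausted: step back one linkage and redraw
            ## it, so the sampler can escape fold-back traps
            backtracks <- backtracks + 1
            if (j == 1 || backtracks > max_backtracks) {
              stuck_at <- j
              break
            }
            tries_at[j] <- 0
            res <- res[seq_len(j)]
            xyz_res <- xyz_res[seq_len(j)]
            name_res <- name_res[seq_len(j)]
            j <- j - 1
          }
        }
      }
      if (stuck_at == 0L) break
      restarts <- restarts + 1
      if (restarts > max_restarts)
        stop("retry budget exhausted at linkage ", stuck_at,
             " of conformer ", cidx)
    }
    counts[assignment] <- counts[assignment] + 1
    conformers[[cidx]] <- assemble_conformer(res, bases, assignment)
  }
  structure(list(conformers = conformers,
                 h_pool = counts / sum(counts),
                 sequence = paste(bases, collapse = ""),
                 weights = weights, seed = seed,
                 profiles = NULL,
                 selection_weights = rep(1 / n_conformers, n_conformers)),
            class = "conformer_pool")
}

## fast clash check of a candidate residue (j+1) against residues 1..j,
## excluding the covalent phosphodiester bridge pairs to residue j
clash_xyz <- function(cand_xyz, cand_names, xyz_res, name_res, j,
                      cutoff) {
  prev <- do.call(rbind, xyz_res[seq_len(j)])
  d2 <- outer(rowSums(cand_xyz^2), rowSums(prev^2), `+`) -
    2 * cand_xyz %*% t(prev)
  ## bridge exclusion: new P/OP1/OP2/O5' vs residue j's O3'/C3'
  n_prev_j <- nrow(xyz_res[[j]])
  col_j <- (nrow(prev) - n_prev_j) + seq_len(n_prev_j)
  excl_cols <- col_j[name_res[[j]] %in% BRIDGE_PREV]
  excl_rows <- which(cand_names %in% BRIDGE_NEXT)
  d2[excl_rows, excl_cols] <- Inf
  any(d2 < cutoff^2)
}

## atoms data.frame of residues 1..upto (for incremental clash checks)
res_atoms_df <- function(res, upto) {
  do.call(rbind, lapply(seq_len(upto), function(i) {
    nm <- names(res[[i]])
    data.frame(resid = i, atom = nm,
               x = vapply(res[[i]], `[`, 0, 1),
               y = vapply(res[[i]], `[`, 0, 2),
               z = vapply(res[[i]], `[`, 0, 3),
               stringsAsFactors = FALSE)
  }))
}

assemble_conformer <- function(res, bases, assignment) {
  atoms <- do.call(rbind, lapply(seq_along(res), function(i) {
    nm <- names(res[[i]])
    data.frame(element = substr(nm, 1, 1), resid = i, atom = nm,
               x = vapply(res[[i]], `[`, 0, 1),
               y = vapply(res[[i]], `[`, 0, 2),
               z = vapply(res[[i]], `[`, 0, 3),
               stringsAsFactors = FALSE)
  }))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, sequence = paste(bases, collapse = ""),
                 suite_assignment = assignment),
            class = "conformer")
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat(sprintf("Conformer pool: %d x %d-mer (%s)%s\n",
              length(x$conformers), nchar(x$sequence), x$sequence,
              if (is.null(x$profiles)) "" else ", profiles computed"))
  invisible(x)
}

#' Compute theoretical profiles for every conformer in a pool
#'
#' @param pool A `conformer_pool`.
#' @param q_grid q grid for [debye_intensity()].
#' @return The pool with `profiles` filled (list of scattering profiles).
#' @export
pool_profiles <- function(pool, q_grid = default_q_grid()) {
  pool$profiles <- lapply(pool$conformers, debye_intensity,
                          q_grid = q_grid)
  pool
}

## -- PDB persistence -------------------------------------------------------

RESNAME <- c(A = "A", U = "U", C = "C", N = "N")

#' Write a conformer as a PDB file
#'
#' Standard RNA atom names (primes kept); pseudo-atom chains write their
#' backbone P beads.
#'
#' @param conformer A `conformer`.
#' @param path Output PDB path.
#' @export
write_conformer_pdb <- function(conformer, path) {
  at <- conformer$atoms
  bases <- strsplit(conformer$sequence, "")[[1]]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resid,
                   resid = RESNAME[bases[at$resid]],
                   elety = at$atom,
                   chain = rep("A", nrow(at)),
                   elesy = at$element)
  invisible(path)
}

#' Read a conformer from a PDB file
#'
#' @param path PDB file with standard RNA atom names.
#' @return A `conformer` (suite assignment unknown: NULL).
#' @export
read_conformer_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  seq_bases <- at$resid[!duplicated(at$resno)]
  structure(list(
    atoms = data.frame(element = substr(at$elety, 1, 1),
                       resid = match(at$resno, unique(at$resno)),
                       atom = at$elety,
                       x = at$x, y = at$y, z = at$z,
                       stringsAsFactors = FALSE),
    sequence = paste(seq_bases, collapse = ""),
    suite_assignment = NULL), class = "conformer")
}

#' Write a conformer pool as a PDB directory plus JSON manifest
#'
#' @param pool A `conformer_pool`.
#' @param dir Output directory (created if needed).
#' @return The directory path.
#' @export
write_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- max(4, nchar(length(pool$conformers)))
  files <- sprintf("conf_%0*d.pdb", nd, seq_along(pool$conformers))
  for (i in seq_along(pool$conformers))
    write_conformer_pdb(pool$conformers[[i]], file.path(dir, files[i]))
  manifest <- list(sequence = pool$sequence, seed = pool$seed,
                   weights = as.list(pool$weights),
                   h_pool = as.list(pool$h_pool),
                   selection_weights = pool$selection_weights,
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
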