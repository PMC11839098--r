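## All-atom single-stranded RNA construction from dinucleotide suites.
##
## Chains are grown atom by atom with natural-extension-reference-frame
## (NeRF) placement: every atom is positioned from three previously placed
## atoms by a bond length, a bond angle and a torsion. The suite's backbone
## torsions (alpha..zeta), sugar puckers (delta) and glycosidic angles (chi)
## enter directly as the NeRF torsions, so the built structure reproduces
## the requested suite angles exactly (up to floating point). Template bond
## lengths and angles follow standard nucleotide dictionaries; ribose ring
## torsions are interpolated from delta via the pseudorotation phase.

## -- template geometry ------------------------------------------------------

BB <- list(
  b_P_O5  = 1.593, b_O5_C5 = 1.440, b_C5_C4 = 1.510,
  b_C4_C3 = 1.524, b_C3_O3 = 1.423, b_O3_P  = 1.607,
  a_O3_P_O5 = 104.0, a_P_O5_C5 = 120.9, a_O5_C5_C4 = 111.5,
  a_C5_C4_C3 = 115.5, a_C4_C3_O3 = 110.6, a_C3_O3_P = 119.7,
  b_P_OP = 1.485, a_O3_P_OP = 108.1,
  b_C4_O4 = 1.451, a_C5_C4_O4 = 109.3,
  b_O4_C1 = 1.414, a_C4_O4_C1 = 109.9,
  b_C1_C2 = 1.526, a_O4_C1_C2 = 106.4,
  b_C2_O2 = 1.413, a_C1_C2_O2 = 110.6,
  b_C1_N  = 1.475, a_O4_C1_N  = 108.5
)

## exocyclic substituent offsets (deg) around the parent torsion axis
OFF_O4 <- -121.0   # O4' vs C3' about C5'-C4'
OFF_N  <- -119.0   # base N vs C2' about O4'-C1'
OFF_O2 <- -120.0   # O2' vs C3' about C1'-C2'
GAMMA_5PRIME <- 54 # gamma of residue 1 (not covered by any suite)

## planar base templates: each row places one atom from three earlier ones.
## torsion "chi" is replaced by the suite's glycosidic angle; "chi+180" by
## chi + 180. Reference atoms named relative to the residue being built.
BASE_TEMPLATES <- list(
  U = list(
    first = "N1",
    ring  = c("N1", "C2", "N3", "C4", "C5", "C6"),
    place = list(
      list("C2", c("O4'", "C1'", "N1"), 1.381, 117.1, "chi"),
      list("O2", c("C1'", "N1", "C2"), 1.219, 122.8, 0),
      list("N3", c("C1'", "N1", "C2"), 1.373, 114.9, 180),
      list("C4", c("N1", "C2", "N3"), 1.383, 127.2, 0),
      list("O4", c("C2", "N3", "C4"), 1.227, 119.4, 180),
      list("C5", c("C2", "N3", "C4"), 1.440, 114.6, 0),
      list("C6", c("N3", "C4", "C5"), 1.338, 119.7, 0))),
  C = list(
    first = "N1",
    ring  = c("N1", "C2", "N3", "C4", "C5", "C6"),
    place = list(
      list("C2", c("O4'", "C1'", "N1"), 1.397, 117.8, "chi"),
      list("O2", c("C1'", "N1", "C2"), 1.240, 121.9, 0),
      list("N3", c("C1'", "N1", "C2"), 1.353, 119.2, 180),
      list("C4", c("N1", "C2", "N3"), 1.335, 119.9, 0),
      list("N4", c("C2", "N3", "C4"), 1.335, 118.0, 180),
      list("C5", c("C2", "N3", "C4"), 1.425, 121.9, 0),
      list("C6", c("N3", "C4", "C5"), 1.339, 117.4, 0))),
  A = list(
    first = "N9",
    ring  = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"),
    place = list(
      list("C4", c("O4'", "C1'", "N9"), 1.374, 126.6, "chi"),
      list("C8", c("O4'", "C1'", "N9"), 1.370, 127.4, "chi+180"),
      list("C5", c("C8", "N9", "C4"), 1.382, 105.8, 0),
      list("N7", c("N9", "C4", "C5"), 1.385, 110.7, 0),
      list("N3", c("C8", "N9", "C4"), 1.344, 127.4, 180),
      list("C2", c("C5", "C4", "N3"), 1.331, 110.6, 0),
      list("N1", c("C4", "N3", "C2"), 1.339, 129.3, 0),
      list("C6", c("N3", "C2", "N1"), 1.351, 118.6, 0),
      list("N6", c("C2", "N1", "C6"), 1.335, 118.6, 180)))
)

#' Aromatic ring atom names of a nucleotide base
#' @param base One of "A", "U", "C".
#' @return Character vector of ring heavy-atom names.
#' @keywords internal
base_ring_atoms <- function(base) BASE_TEMPLATES[[base]]$ring

glycosidic_n <- function(base) BASE_TEMPLATES[[base]]$first

## ribose ring torsions nu0..nu4 interpolated from delta through the
## pseudorotation phase (C3'-endo: delta 81, P 18; C2'-endo: delta 145,
## P 162; amplitude 38 deg)
ring_torsions <- function(delta) {
  P <- 18 + (delta - 81) * (162 - 18) / (145 - 81)
  tm <- 38
  sapply(0:4, function(j) tm * cos((P + 144 * (j - 2)) * pi / 180))
}

## -- builder ---------------------------------------------------------------

#' Build an all-atom RNA conformer from a dinucleotide suite assignment
#'
#' Deterministically constructs an n-residue single-stranded RNA chain
#' (bases A, U, C) whose backbone, sugar-pucker and glycosidic torsions are
#' those of the assigned suites. Linkage j (between residues j and j+1)
#' contributes epsilon/zeta (residue j side), alpha/beta/gamma (residue j+1
#' side), delta for residue j+1 and chi for residue j+1; residue 1 takes its
#' delta and chi from the first suite's `delta_prev`/`chi_prev`.
#'
#' @param sequence Nucleotide string, e.g. `"UUUU"` (A, U, C supported).
#' @param suite_assignment Character vector of suite names, length
#'   `nchar(sequence) - 1`.
#' @param library A `suite_library` from [load_suite_library()].
#' @return A `conformer` object: list with `atoms` (data.frame: element,
#'   resid, atom, x, y, z), `sequence`, `suite_assignment`.
#' @export
#' @examples
#' lib <- load_suite_library()
#' conf <- build_chain("UUU", c("1a", "1a"), lib)
build_chain <- function(sequence, suite_assignment, library) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  n <- length(bases)
  if (n < 2) stop("sequence must have at least 2 residues")
  if (!all(bases %in% c("A", "U", "C")))
    stop("unsupported nucleotide letter(s): ",
         paste(setdiff(bases, c("A", "U", "C")), collapse = ", "))
  if (length(suite_assignment) != n - 1)
    stop("suite_assignment must have length nchar(sequence) - 1")
  idx <- match(suite_assignment, library$name)
  if (anyNA(idx))
    stop("unknown suite name(s): ",
         paste(unique(suite_assignment[is.na(idx)]), collapse = ", "))
  suites <- as.data.frame(library)[idx, , drop = FALSE]

  res <- vector("list", n)
  res[[1]] <- seed_residue(bases[1],
                           delta = suites$delta_prev[1],
                           chi = suites$chi_prev[1])
  for (j in seq_len(n - 1)) {
    res[[j + 1]] <- extend_residue(res[[j]], bases[j + 1], suites[j, ])
  }
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    nm <- names(res[[i]])
    data.frame(element = substr(nm, 1, 1), resid = i, atom = nm,
               x = vapply(res[[i]], `[`, 0, 1),
               y = vapply(res[[i]], `[`, 0, 2),
               z = vapply(res[[i]], `[`, 0, 3),
               stringsAsFactors = FALSE)
  }))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, sequence = paste(bases, collapse = ""),
                 suite_assignment = suite_assignment),
            class = "conformer")
}

## residue 1: seed frame O5'-C5'-C4', then sugar + base
seed_residue <- function(base, delta, chi) {
  r <- list()
  r[["O5'"]] <- c(0, 0, 0)
  r[["C5'"]] <- c(BB$b_O5_C5, 0, 0)
  a <- BB$a_O5_C5_C4 * pi / 180
  r[["C4'"]] <- r[["C5'"]] + BB$b_C5_C4 * c(-cos(a), sin(a), 0)
  r[["C3'"]] <- place_atom(r[["O5'"]], r[["C5'"]], r[["C4'"]],
                           BB$b_C4_C3, BB$a_C5_C4_C3, GAMMA_5PRIME)
  r[["O3'"]] <- place_atom(r[["C5'"]], r[["C4'"]], r[["C3'"]],
                           BB$b_C3_O3, BB$a_C4_C3_O3, delta)
  add_sugar_base(r, base, delta, chi, gamma = GAMMA_5PRIME)
}

## residue i+1 from residue i through suite torsions
extend_residue <- function(prev, base, s) {
  r <- list()
  r[["P"]] <- place_atom(prev[["C4'"]], prev[["C3'"]], prev[["O3'"]],
                         BB$b_O3_P, BB$a_C3_O3_P, s$epsilon)
  r[["OP1"]] <- place_atom(prev[["C3'"]], prev[["O3'"]], r[["P"]],
                           BB$b_P_OP, BB$a_O3_P_OP, s$zeta + 119)
  r[["OP2"]] <- place_atom(prev[["C3'"]], prev[["O3'"]], r[["P"]],
                           BB$b_P_OP, BB$a_O3_P_OP, s$zeta - 119)
  r[["O5'"]] <- place_atom(prev[["C3'"]], prev[["O3'"]], r[["P"]],
                           BB$b_P_O5, BB$a_O3_P_O5, s$zeta)
  r[["C5'"]] <- place_atom(prev[["O3'"]], r[["P"]], r[["O5'"]],
                           BB$b_O5_C5, BB$a_P_O5_C5, s$alpha)
  r[["C4'"]] <- place_atom(r[["P"]], r[["O5'"]], r[["C5'"]],
                           BB$b_C5_C4, BB$a_O5_C5_C4, s$beta)
  r[["C3'"]] <- place_atom(r[["O5'"]], r[["C5'"]], r[["C4'"]],
                           BB$b_C4_C3, BB$a_C5_C4_C3, s$gamma)
  r[["O3'"]] <- place_atom(r[["C5'"]], r[["C4'"]], r[["C3'"]],
                           BB$b_C3_O3, BB$a_C4_C3_O3, s$delta)
  add_sugar_base(r, base, s$delta, s$chi, gamma = s$gamma)
}

add_sugar_base <- function(r, base, delta, chi, gamma) {
  nu <- ring_torsions(delta)
  r[["O4'"]] <- place_atom(r[["O5'"]], r[["C5'"]], r[["C4'"]],
                           BB$b_C4_O4, BB$a_C5_C4_O4, gamma + OFF_O4)
  r[["C1'"]] <- place_atom(r[["C3'"]], r[["C4'"]], r[["O4'"]],
                           BB$b_O4_C1, BB$a_C4_O4_C1, nu[5])
  r[["C2'"]] <- place_atom(r[["C4'"]], r[["O4'"]], r[["C1'"]],
                           BB$b_C1_C2, BB$a_O4_C1_C2, nu[1])
  r[["O2'"]] <- place_atom(r[["O4'"]], r[["C1'"]], r[["C2'"]],
                           BB$b_C2_O2, BB$a_C1_C2_O2, nu[2] + OFF_O2)
  tpl <- BASE_TEMPLATES[[base]]
  r[[tpl$first]] <- place_atom(r[["C4'"]], r[["O4'"]], r[["C1'"]],
                               BB$b_C1_N, BB$a_O4_C1_N, nu[1] + OFF_N)
  for (p in tpl$place) {
    tor <- p[[5]]
    if (identical(tor, "chi")) tor <- chi
    else if (identical(tor, "chi+180")) tor <- chi + 180
    r[[p[[1]]]] <- place_atom(r[[p[[2]][1]]], r[[p[[2]][2]]],
                              r[[p[[2]][3]]], p[[3]], p[[4]], tor)
  }
  r
}

## -- conformer accessors ---------------------------------------------------

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("RNA conformer: %d residues (%s), %d heavy atoms\n",
              nchar(x$sequence), x$sequence, nrow(x$atoms)))
  invisible(x)
}

#' Coordinates of selected atoms of a conformer
#'
#' @param conformer A `conformer`.
#' @param atom Optional atom-name filter (e.g. `"P"` for the backbone
#'   phosphorus trace).
#' @return n x 3 coordinate matrix (Angstrom), in residue order.
#' @export
conformer_xyz <- function(conformer, atom = NULL) {
  at <- conformer$atoms
  if (!is.null(atom)) at <- at[at$atom %in% atom, , drop = FALSE]
  at <- at[order(at$resid), , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Backbone reference trace of a conformer
#'
#' Phosphorus positions where present; synthetic single-bead chains use
#' their per-residue pseudo-atoms (also labelled P). If fewer than two P
#' atoms exist (e.g. a 5'-terminal chain of length 2), C4' is used instead.
#' @param conformer A `conformer`.
#' @return m x 3 matrix of backbone reference points.
#' @export
backbone_trace <- function(conformer) {
  xyz <- conformer_xyz(conformer, "P")
  if (nrow(xyz) >= 2) return(xyz)
  conformer_xyz(conformer, "C4'")
}

atom_xyz_matrix <- function(conformer) {
  as.matrix(conformer$atoms[, c("x", "y", "z")])
}

apply_rigid <- function(conformer, R = diag(3), t = c(0, 0, 0)) {
  xyz <- atom_xyz_matrix(conformer) %*% t(R)
  xyz <- sweep(xyz, 2, t, `+`)
  conformer$atoms$x <- xyz[, 1]
  conformer$atoms$y <- xyz[, 2]
  conformer$atoms$z <- xyz[, 3]
  conformer
}

## -- torsion measurement ---------------------------------------------------

#' Measure the suite-defining torsions of a built conformer
#'
#' Computes, for every dinucleotide linkage, the nine suite-defining angles
#' from the coordinates: sugar puckers delta(i)/delta(i+1), backbone
#' epsilon, zeta, alpha, beta, gamma across the linkage, and glycosidic
#' chi(i)/chi(i+1).
#'
#' @param conformer A `conformer` with full backbone, sugar and base atoms.
#' @return data.frame with one row per linkage and columns matching the
#'   suite library angle columns.
#' @export
measure_suite_torsions <- function(conformer) {
  n <- nchar(conformer$sequence)
  bases <- strsplit(conformer$sequence, "")[[1]]
  g <- function(i, name) {
    at <- conformer$atoms
    row <- at[at$resid == i & at$atom == name, ]
    if (nrow(row) != 1) stop("missing atom ", name, " in residue ", i)
    c(row$x, row$y, row$z)
  }
  delta_i <- function(i) dihedral(g(i, "C5'"), g(i, "C4'"), g(i, "C3'"),
                                  g(i, "O3'"))
  chi_i <- function(i) {
    nat <- glycosidic_n(bases[i])
    ref <- if (bases[i] == "A") "C4" else "C2"
    dihedral(g(i, "O4'"), g(i, "C1'"), g(i, nat), g(i, ref))
  }
  out <- lapply(seq_len(n - 1), function(j) {
    i <- j; k <- j + 1
    data.frame(
      linkage = j,
      delta_prev = delta_i(i),
      epsilon = dihedral(g(i, "C4'"), g(i, "C3'"), g(i, "O3'"), g(k, "P")),
      zeta = dihedral(g(i, "C3'"), g(i, "O3'"), g(k, "P"), g(k, "O5'")),
      alpha = dihedral(g(i, "O3'"), g(k, "P"), g(k, "O5'"), g(k, "C5'")),
      beta = dihedral(g(k, "P"), g(k, "O5'"), g(k, "C5'"), g(k, "C4'")),
      gamma = dihedral(g(k, "O5'"), g(k, "C5'"), g(k, "C4'"), g(k, "C3'")),
      delta = delta_i(k),
      chi_prev = chi_i(i),
      chi = chi_i(k))
  })
  do.call(rbind, out)
}

## -- steric screening ------------------------------------------------------

## atom pairs excluded from clash detection across a phosphodiester bridge
BRIDGE_PREV <- c("O3'", "C3'")
BRIDGE_NEXT <- c("P", "OP1", "OP2", "O5'")

#' Detect steric clashes in a conformer
#'
#' A clash is any pair of non-bonded heavy atoms closer than `min_distance`.
#' Atoms of the same residue (whose geometry is fixed by the template) and
#' the covalent phosphodiester bridge atoms of adjacent residues are
#' excluded.
#'
#' @param conformer A `conformer`.
#' @param min_distance Cutoff in Angstrom (default 2.0).
#' @return List with `clash` (logical), `pair` (row indices into
#'   `conformer$atoms` of the closest offending pair, or NULL) and
#'   `min_dist` of that pair.
#' @export
has_clash <- function(conformer, min_distance = 2.0) {
  at <- conformer$atoms
  if (nrow(at) < 2) stop("need at least 2 atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  excl <- outer(at$resid, at$resid, `==`)
  adj1 <- outer(at$resid, at$resid, function(a, b) b - a == 1)
  bridge <- (at$atom %in% BRIDGE_PREV) %o% (at$atom %in% BRIDGE_NEXT)
  excl <- excl | (adj1 & bridge) | t(adj1 & bridge)
  d[excl] <- Inf
  diag(d) <- Inf
  m <- which.min(d)
  if (d[m] < min_distance) {
    ij <- arrayInd(m, dim(d))
    list(clash = TRUE, pair = as.integer(ij), min_dist = d[m])
  } else {
    list(clash = FALSE, pair = NULL, min_dist = d[m])
  }
}

## clash of candidate residue atoms against already-built atoms
clash_against <- function(new_res, new_resid, atoms, min_distance) {
  if (nrow(atoms) == 0) return(FALSE)
  new_xyz <- do.call(rbind, new_res)
  nm <- names(new_res)
  prev <- atoms[atoms$resid < new_resid, , drop = FALSE]
  if (nrow(prev) == 0) return(FALSE)
  keep_new <- rep(TRUE, length(nm))
  adj <- prev$resid == new_resid - 1
  excl_prev <- adj & prev$atom %in% BRIDGE_PREV
  d <- sqrt(outer(rowSums(new_xyz^2), rowSums(prev[, c("x", "y", "z")]^2),
                  `+`) -
            2 * new_xyz %*% t(as.matrix(prev[, c("x", "y", "z")])))
  bridge_new <- nm %in% BRIDGE_NEXT
  d[bridge_new, excl_prev] <- Inf
  any(d < min_distance)
}
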