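## Residue-level coarse-grained force field: harmonic bonds, Debye-Hueckel
## screened electrostatics, and Wang-Frenkel sticker potentials, with a
## shipped (synthetic, user-replaceable) parameter table.

COULOMB_KE <- 1389.35458  # kJ mol^-1 A e^-2 (1/(4 pi eps0))

#' Inverse Debye screening length from monovalent salt concentration
#'
#' kappa = sqrt(c_Na) / 3.06 per Angstrom, the standard-condition
#' simplification of Debye-Hueckel theory at 298 K in water.
#'
#' @param c_Na Monovalent salt concentration (mol/L, >= 0).
#' @return kappa in 1/Angstrom.
#' @export
#' @examples
#' kappa_from_salt(0.6)   # 0.253
#' kappa_from_salt(0.15)  # 0.126
kappa_from_salt <- function(c_Na) {
  if (any(c_Na < 0)) stop("salt concentration must be nonnegative")
  sqrt(c_Na) / 3.06
}

#' Wang-Frenkel pair potential
#'
#' U(r) = eps * alpha * ((sigma/r)^(2 mu) - 1) * ((rc/r)^(2 mu) - 1)^(2 nu)
#' for r < rc and exactly 0 beyond, with alpha chosen so that the minimum
#' value is exactly -eps.
#'
#' @param r Distance(s), Angstrom.
#' @param eps Well depth (kJ/mol).
#' @param sigma Size parameter (Angstrom); U crosses zero at r = sigma.
#' @param mu,nu Shape exponents.
#' @param rc Cutoff (Angstrom; default 3 sigma).
#' @return Potential energy (kJ/mol).
#' @export
wf_potential <- function(r, eps, sigma, mu = 2, nu = 1, rc = 3 * sigma) {
  rms <- (rc / sigma)^(2 * mu)
  alpha <- 2 * nu * rms *
    ((1 + 2 * nu) / (2 * nu * (rms - 1)))^(2 * nu + 1)
  out <- ifelse(r < rc,
                eps * alpha * ((sigma / r)^(2 * mu) - 1) *
                  ((rc / r)^(2 * mu) - 1)^(2 * nu),
                0)
  out
}

#' Load the coarse-grained force field
#'
#' Reads the bead and pair-potential tables (JSON) and assembles the full
#' force field: bond constant K = 9.6 kJ/(mol A^2) with reference lengths
#' 5.00 A (nucleic) and 3.81 A (amino), Debye-Hueckel electrostatics with
#' relative permittivity `epsilon_r` and screening set by the salt
#' concentration, and per-pair Wang-Frenkel sticker parameters.
#'
#' @param source `"default"` for the shipped synthetic table or a path to a
#'   JSON file of the same layout.
#' @param c_Na Monovalent salt concentration (mol/L) fixing kappa.
#' @param epsilon_r Relative permittivity (default 80).
#' @param elec_cutoff Electrostatic cutoff (Angstrom, default 35).
#' @param K Bond spring constant, kJ/(mol A^2).
#' @param rref_nucleic,rref_amino Reference bond lengths (Angstrom).
#' @return A `cg_forcefield` list with bead table and per-pair matrices.
#' @export
load_forcefield <- function(source = "default", c_Na = 0.15,
                            epsilon_r = 80, elec_cutoff = 35, K = 9.6,
                            rref_nucleic = 5.00, rref_amino = 3.81) {
  path <- if (identical(source, "default"))
    system.file("extdata", "mpipi_like_params_synthetic.json",
                package = "condensaxs") else source
  ff <- jsonlite::read_json(path, simplifyVector = TRUE)
  beads <- as.data.frame(ff$beads)
  nt <- nrow(beads)
  nm <- beads$name
  mk <- function(v) matrix(v, nt, nt, dimnames = list(nm, nm))
  eps <- mk(0); sig <- mk(0)
  for (i in seq_len(nt))
    for (j in seq_len(nt))
      sig[i, j] <- (beads$sigma[i] + beads$sigma[j]) / 2
  for (k in seq_len(nrow(ff$pairs))) {
    a <- ff$pairs$a[k]; b <- ff$pairs$b[k]
    eps[a, b] <- eps[b, a] <- ff$pairs$eps[k]
  }
  mu <- mk(ff$wf_defaults$mu); nu <- mk(ff$wf_defaults$nu)
  rc <- sig * ff$wf_defaults$rc_over_sigma
  structure(list(beads = beads, K = K, rref_nucleic = rref_nucleic,
                 rref_amino = rref_amino, epsilon_r = epsilon_r,
                 kappa = kappa_from_salt(c_Na), c_Na = c_Na,
                 elec_cutoff = elec_cutoff,
                 ke_over_eps = COULOMB_KE / epsilon_r,
                 wf = list(eps = eps, sig = sig, mu = mu, nu = nu,
                           rc = rc)),
            class = "cg_forcefield")
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat(sprintf(
    "CG force field: %d bead types; K = %.1f kJ/(mol A^2); kappa = %.4g 1/A (c = %g M); eps_r = %g\n",
    nrow(x$beads), x$K, x$kappa, x$c_Na, x$epsilon_r))
  invisible(x)
}

type_index <- function(types, ff) {
  i <- match(types, ff$beads$name)
  if (anyNA(i))
    stop("missing pair parameters for bead type(s): ",
         paste(unique(types[is.na(i)]), collapse = ", "))
  i
}

#' Harmonic bond energy
#'
#' E = sum_bonds K (r - rref)^2 with rref set by polymer class.
#'
#' @param positions n x 3 coordinate matrix (Angstrom).
#' @param system A `cg_system` (provides bonds and reference lengths), or a
#'   list with `bonds` (2-column index matrix) and `rref_bond`.
#' @param ff A `cg_forcefield`.
#' @param box Cubic box edge for minimum image (0 = open).
#' @return Energy in kJ/mol.
#' @export
bonded_energy <- function(positions, system, ff, box = 0) {
  e <- .energy_terms(as.matrix(positions), system$bonds, system$rref_bond,
                     rep(0, nrow(positions)),
                     rep(1L, nrow(positions)),
                     list(eps = matrix(0, 1, 1), sig = matrix(1, 1, 1),
                          mu = matrix(1, 1, 1), nu = matrix(1, 1, 1),
                          rc = matrix(0, 1, 1)),
                     ff$K, 0, 0, 0, box)
  unname(e["bond"])
}

#' Debye-Hueckel electrostatic energy
#'
#' E = sum_{i<j} q_i q_j exp(-kappa r_ij) / (4 pi eps0 eps_r r_ij) over
#' non-bonded pairs within the cutoff, minimum-image convention.
#'
#' @param positions n x 3 matrix (Angstrom).
#' @param charges Per-bead charges (e).
#' @param ff A `cg_forcefield` (kappa, eps_r, cutoff).
#' @param box Cubic box edge (0 = open).
#' @param bonds Optional 2-column bonded-pair matrix to exclude.
#' @return Energy in kJ/mol.
#' @export
dh_energy <- function(positions, charges, ff, box = 0,
                      bonds = matrix(0L, 0, 2)) {
  n <- nrow(positions)
  e <- .energy_terms(as.matrix(positions), bonds,
                     rep(0, nrow(bonds)), as.numeric(charges),
                     rep(1L, n),
                     list(eps = matrix(0, 1, 1), sig = matrix(1, 1, 1),
                          mu = matrix(1, 1, 1), nu = matrix(1, 1, 1),
                          rc = matrix(0, 1, 1)),
                     0, ff$kappa, ff$ke_over_eps, ff$elec_cutoff, box)
  unname(e["dh"])
}

#' Wang-Frenkel sticker energy
#'
#' Sum of per-pair Wang-Frenkel interactions over non-bonded pairs,
#' minimum-image convention; exactly zero at and beyond each pair's
#' cutoff.
#'
#' @param positions n x 3 matrix (Angstrom).
#' @param types Character bead types, matched against the force-field
#'   table.
#' @param ff A `cg_forcefield`.
#' @param box Cubic box edge (0 = open).
#' @param bonds Optional bonded pairs to exclude.
#' @return Energy in kJ/mol.
#' @export
wang_frenkel_energy <- function(positions, types, ff, box = 0,
                                bonds = matrix(0L, 0, 2)) {
  n <- nrow(positions)
  e <- .energy_terms(as.matrix(positions), bonds, rep(0, nrow(bonds)),
                     rep(0, n), as.integer(type_index(types, ff)),
                     ff$wf, 0, 0, 0, 0, box)
  unname(e["wf"])
}
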