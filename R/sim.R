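## Coarse-grained Langevin dynamics of RNA + peptide chains in a periodic
## cubic box (BAOAB integrator, seeded thermal noise).

#' Simulation configuration
#'
#' Reference-protocol defaults: 10 fs step, 298 K, 100 ps thermostat
#' relaxation (5 ps for salt-propensity runs). Desk-scale runs shrink the
#' box and step counts; the full production scale remains expressible.
#'
#' @param box Cubic box edge (Angstrom).
#' @param dt Time step (fs).
#' @param n_steps Number of integration steps.
#' @param temperature Kelvin.
#' @param relaxation_ps Langevin relaxation time tau (ps); friction is
#'   1/tau. `0` disables the thermostat (NVE integration).
#' @param c_Na Monovalent salt (mol/L), fixing the screening length.
#' @param seed RNG seed.
#' @param stride Save a frame every `stride` steps.
#' @param fmax_abort Abort when any force component exceeds this
#'   (kJ/mol/A).
#' @return A `sim_config` list.
#' @export
sim_config <- function(box = 250, dt = 10, n_steps = 10000,
                       temperature = 298, relaxation_ps = 100,
                       c_Na = 0.15, seed = 1, stride = 100,
                       fmax_abort = 1e5) {
  structure(list(box = box, dt = dt, n_steps = n_steps,
                 temperature = temperature,
                 relaxation_ps = relaxation_ps, c_Na = c_Na, seed = seed,
                 stride = stride, fmax_abort = fmax_abort),
            class = "sim_config")
}

#' Desk-scale simulation preset
#'
#' A reduced system for workstation-scale runs: 20 RNA + 20 peptide chains
#' of 30 residues in a 250 A box. The full production scale (792.7 A box,
#' microsecond trajectories) is expressible through [sim_config()] but is
#' not the default.
#'
#' @param rna_base RNA residue type ("A", "U" or "C").
#' @param c_Na Salt concentration (mol/L).
#' @param n_steps Integration steps.
#' @param seed RNG seed.
#' @param n_rna,n_peptide Chain counts.
#' @param box Box edge (Angstrom).
#' @param beads_per_chain Residues per chain.
#' @return List with `system`, `ff` and `cfg` ready for [run_langevin()].
#' @export
desk_preset <- function(rna_base = "U", c_Na = 0.15, n_steps = 20000,
                        seed = 1, n_rna = 20, n_peptide = 20, box = 250,
                        beads_per_chain = 30) {
  ff <- load_forcefield(c_Na = c_Na)
  system <- make_cg_system(n_rna = n_rna, n_peptide = n_peptide,
                           rna_base = rna_base, box = box, ff = ff,
                           beads_per_chain = beads_per_chain)
  cfg <- sim_config(box = box, n_steps = n_steps, c_Na = c_Na,
                    seed = seed)
  list(system = system, ff = ff, cfg = cfg)
}

#' Assemble an RNA + peptide bead system on a lattice
#'
#' RNA chains are homopolymers of `rna_base`; peptides are (Pro-Arg)
#' repeats (PR pattern). Chains are initialized as straight segments with
#' centers on a deterministic lattice via [init_lattice()].
#'
#' @param n_rna,n_peptide Chain counts.
#' @param rna_base "A", "U" or "C".
#' @param beads_per_chain Residues per chain (default 30 for both
#'   polymers).
#' @param box Cubic box edge (Angstrom).
#' @param ff A `cg_forcefield` (for masses/charges).
#' @return A `cg_system`: positions `x`, per-bead `mass`, `charge`,
#'   `type`, `chain`, `is_rna`, bond list with reference lengths, `box`.
#' @export
make_cg_system <- function(n_rna, n_peptide, rna_base = "U",
                           beads_per_chain = 30, box = 250,
                           ff = load_forcefield()) {
  n_chains <- n_rna + n_peptide
  if (n_chains < 1) stop("need at least one chain")
  types_per_chain <- c(
    lapply(seq_len(n_rna), function(i) rep(rna_base, beads_per_chain)),
    lapply(seq_len(n_peptide),
           function(i) rep(c("P", "R"), length.out = beads_per_chain)))
  type <- unlist(types_per_chain)
  chain <- rep(seq_len(n_chains), each = beads_per_chain)
  is_rna <- chain <= n_rna
  bead <- match(type, ff$beads$name)
  if (anyNA(bead)) stop("bead type missing from force field")
  mass <- ff$beads$mass[bead]
  charge <- ff$beads$charge[bead]
  rref <- ifelse(is_rna, ff$rref_nucleic, ff$rref_amino)
  ## bonds between consecutive beads of each chain
  first <- which(diff(chain) == 0)
  bonds <- cbind(first, first + 1L)
  rref_bond <- rref[first]
  x <- init_lattice(n_rna, n_peptide, beads_per_chain, box,
                    rref_nucleic = ff$rref_nucleic,
                    rref_amino = ff$rref_amino)
  structure(list(x = x, mass = mass, charge = charge, type = type,
                 chain = chain, is_rna = is_rna, bonds = bonds,
                 rref_bond = rref_bond, box = box, n_rna = n_rna,
                 n_peptide = n_peptide,
                 beads_per_chain = beads_per_chain),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("CG system: %d RNA + %d peptide chains (%d beads), box %.1f A\n",
              x$n_rna, x$n_peptide, length(x$mass), x$box))
  invisible(x)
}

#' Straight-chain lattice initial coordinates
#'
#' Chain centers occupy a deterministic lattice (RNA chains first, then
#' peptides); each chain is a straight segment along x with its class's
#' reference bond length. When the segments are longer than the isotropic
#' lattice spacing the lattice is made anisotropic (fewer cells along x)
#' so that no inter-chain bead pair starts closer than 2 A.
#'
#' @param n_rna,n_peptide Chain counts.
#' @param beads_per_chain Beads per chain (single count applied to both).
#' @param box Cubic box edge (Angstrom).
#' @param rref_nucleic,rref_amino Bond lengths (Angstrom).
#' @return (n_chains * beads_per_chain) x 3 coordinate matrix.
#' @export
init_lattice <- function(n_rna, n_peptide, beads_per_chain, box,
                         rref_nucleic = 5.00, rref_amino = 3.81) {
  n <- n_rna + n_peptide
  rod_len <- (beads_per_chain - 1) * max(rref_nucleic,
                                         if (n_peptide > 0) rref_amino
                                         else 0)
  side <- ceiling(n^(1 / 3))
  if (rod_len + 2 > box / side) {
    nx <- max(1, floor(box / (rod_len + 2)))
    nyz <- ceiling(sqrt(n / nx))
    dims <- c(nx, nyz, ceiling(n / (nx * nyz)))
  } else {
    dims <- rep(side, 3)
  }
  ## a chain must clear its own periodic image by more than the sticker
  ## range, or the start configuration is effectively overlapping
  if (prod(dims) < n || any(box / dims < 3) || rod_len + 20 > box)
    stop("overfilled box: ", n, " chains of length ", rod_len,
         " A do not fit in ", box, " A")
  sp <- box / dims
  cells <- as.matrix(expand.grid(x = seq_len(dims[1]),
                                 y = seq_len(dims[2]),
                                 z = seq_len(dims[3])))[seq_len(n), ,
                                                        drop = FALSE]
  centers <- sweep(cells - 0.5, 2, sp, `*`)
  out <- matrix(0, n * beads_per_chain, 3)
  for (c_i in seq_len(n)) {
    b <- if (c_i <= n_rna) rref_nucleic else rref_amino
    offs <- (seq_len(beads_per_chain) - (beads_per_chain + 1) / 2) * b
    rows <- (c_i - 1) * beads_per_chain + seq_len(beads_per_chain)
    out[rows, ] <- cbind(centers[c_i, 1] + offs, centers[c_i, 2],
                         centers[c_i, 3])
  }
  out
}

#' Run Langevin dynamics
#'
#' BAOAB integration with friction 1/tau, seeded Maxwell-Boltzmann initial
#' velocities and thermal noise, periodic wrapping, and frame saving at
#' the configured stride. Forces: harmonic bonds, Debye-Hueckel
#' electrostatics, Wang-Frenkel stickers (bonded pairs excluded from
#' non-bonded terms). Aborts with a diagnostic when any force component
#' exceeds `cfg$fmax_abort`.
#'
#' @param system A `cg_system`.
#' @param ff A `cg_forcefield`; its kappa should match `cfg$c_Na` (it is
#'   recomputed from the config's salt concentration for safety).
#' @param cfg A [sim_config()].
#' @return A `cg_trajectory` with per-frame times (fs) and an attribute
#'   `temperature` (instantaneous kinetic temperature per frame).
#' @export
run_langevin <- function(system, ff, cfg = sim_config()) {
  set.seed(cfg$seed)
  kappa <- kappa_from_salt(cfg$c_Na)
  res <- .run_langevin_cpp(
    system$x, system$mass, system$charge,
    as.integer(type_index(system$type, ff)),
    system$bonds, system$rref_bond, ff$wf, ff$K, kappa, ff$ke_over_eps,
    ff$elec_cutoff, cfg$box, cfg$dt, cfg$relaxation_ps * 1000,
    cfg$temperature, as.integer(cfg$n_steps), as.integer(cfg$stride),
    cfg$fmax_abort)
  traj <- cg_trajectory(res$frames, system$chain, cfg$box,
                        times = res$times, type = system$type)
  attr(traj, "temperature") <- res$temperature
  attr(traj, "kappa") <- kappa
  traj
}
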