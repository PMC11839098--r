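## Synthetic ground-truth generators: ideal helices and freely jointed
## coils (closed-form order-parameter oracles), noisy scattering profiles,
## and scripted bead trajectories whose cluster membership is known exactly
## at every frame, so the condensate analytics can be validated without any
## experimental data.

## -- trajectory container --------------------------------------------------

#' Bead trajectory container
#'
#' @param frames 3D array `[frame, bead, xyz]` of positions (Angstrom).
#' @param chain Integer chain id per bead (constant over frames).
#' @param box Cubic box edge (Angstrom); 0 for open boundaries.
#' @param times Optional per-frame times (fs).
#' @param type Optional character bead type per bead.
#' @return A `cg_trajectory` object.
#' @export
cg_trajectory <- function(frames, chain, box, times = NULL, type = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3,
            dim(frames)[2] == length(chain))
  if (is.null(times)) times <- seq_len(dim(frames)[1]) - 1
  structure(list(frames = frames, chain = as.integer(chain), box = box,
                 times = times, type = type),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("CG trajectory: %d frames, %d beads, %d chains, box %.1f A\n",
              dim(x$frames)[1], dim(x$frames)[2], length(unique(x$chain)),
              x$box))
  invisible(x)
}

#' Number of frames of a trajectory
#' @param trajectory A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$frames)[1]

#' Coordinates of one trajectory frame
#' @param trajectory A `cg_trajectory`.
#' @param f Frame index (1-based).
#' @return n_beads x 3 matrix.
#' @export
frame_coords <- function(trajectory, f) {
  matrix(trajectory$frames[f, , ], ncol = 3)
}

#' Write a trajectory as multi-frame XYZ text
#'
#' Standard XYZ blocks; the comment line carries the box edge and frame
#' time as `box=<edge> time=<fs>`. Bead symbols are the bead types (or the
#' chain id when types are absent).
#'
#' @param trajectory A `cg_trajectory`.
#' @param path Output file.
#' @export
write_trajectory_xyz <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nb <- dim(trajectory$frames)[2]
  sym <- if (is.null(trajectory$type)) paste0("C", trajectory$chain)
         else trajectory$type
  for (f in seq_len(n_frames(trajectory))) {
    xyz <- frame_coords(trajectory, f)
    writeLines(as.character(nb), con)
    writeLines(sprintf("box=%.6f time=%.6f", trajectory$box,
                       trajectory$times[f]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", sym, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory written by [write_trajectory_xyz()]
#'
#' @param path XYZ file.
#' @param chain Chain id per bead; recovered from `C<k>` symbols when NULL.
#' @return A `cg_trajectory`.
#' @export
read_trajectory_xyz <- function(path, chain = NULL) {
  lines <- readLines(path)
  i <- 1; frames <- list(); times <- c(); box <- 0; sym <- NULL
  while (i <= length(lines)) {
    nb <- as.integer(lines[i])
    hdr <- lines[i + 1]
    box <- as.numeric(sub(".*box=([0-9.eE+-]+).*", "\\1", hdr))
    times <- c(times, as.numeric(sub(".*time=([0-9.eE+-]+).*", "\\1", hdr)))
    block <- lines[(i + 2):(i + 1 + nb)]
    parts <- strsplit(block, "\\s+")
    sym <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + nb
  }
  arr <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  if (is.null(chain)) {
    ch <- suppressWarnings(as.integer(sub("^C", "", sym)))
    chain <- if (anyNA(ch)) rep(1L, length(sym)) else ch
  }
  cg_trajectory(arr, chain, box, times, type = sym)
}

## -- structure generators --------------------------------------------------

#' Ideal circular-helix backbone fixture
#'
#' One pseudo-atom per residue (labelled P, so order-parameter code paths
#' are shared with all-atom structures) placed exactly on a circular helix:
#' point i = (radius cos(i t), radius sin(i t), i rise) with t the twist.
#' The backbone orientation correlation function of this fixture has the
#' closed form of helix tangent correlations with period 360/twist
#' residues.
#'
#' @param n_residues Number of residues (>= 2).
#' @param rise Rise per residue (Angstrom, > 0).
#' @param twist Twist per residue (degrees).
#' @param radius Helix radius (Angstrom, >= 0).
#' @return A `conformer` with one P pseudo-atom per residue.
#' @export
gen_ideal_helix <- function(n_residues, rise = 2.81, twist = 32.7,
                            radius = 9.4) {
  if (n_residues < 2) stop("n_residues must be >= 2")
  if (rise <= 0) stop("rise must be positive")
  if (radius < 0) stop("radius must be nonnegative")
  i <- seq_len(n_residues) - 1
  t <- twist * pi / 180
  xyz <- cbind(radius * cos(i * t), radius * sin(i * t), i * rise)
  pseudo_conformer(xyz, paste(rep("N", n_residues), collapse = ""))
}

#' Freely jointed chain fixture
#'
#' Seeded random walk of fixed bond length: the null model for a fully
#' disordered backbone (mean squared end-to-end distance n b^2).
#'
#' @param n_residues Number of residues (>= 2).
#' @param bond_length Bond length (Angstrom).
#' @param seed RNG seed.
#' @return A `conformer` with one P pseudo-atom per residue.
#' @export
gen_random_coil <- function(n_residues, bond_length = 5.9, seed = 1) {
  if (n_residues < 2) stop("n_residues must be >= 2")
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * (n_residues - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  xyz <- rbind(c(0, 0, 0), apply(dirs * bond_length, 2, cumsum))
  pseudo_conformer(xyz, paste(rep("N", n_residues), collapse = ""))
}

pseudo_conformer <- function(xyz, sequence) {
  n <- nrow(xyz)
  structure(list(
    atoms = data.frame(element = "P", resid = seq_len(n), atom = "P",
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
    sequence = sequence, suite_assignment = NULL),
    class = "conformer")
}

## -- noisy profiles --------------------------------------------------------

#' Measurement-noise model for synthetic profiles
#'
#' @param kind `"gaussian-proportional"` (sigma is a relative fraction of
#'   I(q); the synchrotron-like default) or `"gaussian-constant"` (sigma in
#'   intensity units).
#' @param sigma Noise level (>= 0); default 0.02 (2% relative).
#' @param seed RNG seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(kind = c("gaussian-proportional",
                                 "gaussian-constant"),
                        sigma = 0.02, seed = 1) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be nonnegative")
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "noise_model")
}

#' Add synthetic Gaussian noise to a scattering profile
#'
#' Perturbs intensities according to the noise model and fills the sigma
#' column with the model's (absolute) sigma. Identical seeds reproduce
#' identical draws.
#'
#' @param true_profile A [scattering_profile()] with positive intensities.
#' @param noise A [noise_model()].
#' @return A noisy [scattering_profile()].
#' @export
gen_noisy_profile <- function(true_profile, noise = noise_model()) {
  if (any(true_profile$I <= 0))
    stop("true profile must have positive intensities")
  set.seed(noise$seed)
  eps <- stats::rnorm(nrow(true_profile))
  if (noise$kind == "gaussian-proportional") {
    s <- noise$sigma * true_profile$I
  } else {
    s <- rep(noise$sigma, nrow(true_profile))
  }
  scattering_profile(true_profile$q, true_profile$I + s * eps, s)
}

## -- scripted trajectories -------------------------------------------------

#' Cluster-membership script for a synthetic trajectory
#'
#' Defines, with full ground truth, which cluster every chain occupies at
#' every frame: an initial assignment plus move events. Cluster ids are
#' positive integers; id 0 means free solution.
#'
#' @param n_chains Number of chains.
#' @param initial Integer vector (length n_chains) of initial cluster ids
#'   (0 = solution).
#' @param events data.frame with columns `frame`, `chain`, `from`, `to`:
#'   at frame `frame` the chain moves from cluster `from` to `to` (the
#'   membership differs between frames `frame - 1` and `frame`).
#' @param n_frames Trajectory length (frames).
#' @param box_edge Cubic box edge (Angstrom).
#' @return A `trajectory_script`.
#' @export
trajectory_script <- function(n_chains, initial, events =
                                data.frame(frame = integer(),
                                           chain = integer(),
                                           from = integer(),
                                           to = integer()),
                              n_frames = 10, box_edge = 500) {
  if (length(initial) != n_chains)
    stop("initial must assign every chain")
  events <- as.data.frame(events)
  if (nrow(events)) {
    if (any(events$frame < 2 | events$frame > n_frames))
      stop("event frames must lie strictly within the trajectory (2..n_frames)")
    events <- events[order(events$frame), , drop = FALSE]
  }
  ## replay the events to check occupancy consistency
  memb <- as.integer(initial)
  for (e in seq_len(nrow(events))) {
    ch <- events$chain[e]
    if (memb[ch] != events$from[e])
      stop(sprintf("event %d: chain %d is in cluster %d, not %d", e, ch,
                   memb[ch], events$from[e]))
    if (events$from[e] == events$to[e])
      stop("event source and destination coincide")
    memb[ch] <- events$to[e]
  }
  structure(list(n_chains = as.integer(n_chains),
                 initial = as.integer(initial), events = events,
                 n_frames = as.integer(n_frames), box_edge = box_edge),
            class = "trajectory_script")
}

#' Per-frame cluster membership implied by a script
#' @param script A [trajectory_script()].
#' @return n_frames x n_chains integer matrix of cluster ids (0 = solution).
#' @export
script_membership <- function(script) {
  m <- matrix(0L, script$n_frames, script$n_chains)
  memb <- script$initial
  ev <- script$events
  k <- 1
  for (f in seq_len(script$n_frames)) {
    while (k <= nrow(ev) && ev$frame[k] == f) {
      memb[ev$chain[k]] <- ev$to[k]
      k <- k + 1
    }
    m[f, ] <- memb
  }
  m
}

#' Ground-truth arrival/departure totals of a script
#'
#' Counts events with adjacency-matrix semantics: a move only registers as
#' an arrival when the destination cluster holds at least one other chain
#' (otherwise no same-cluster partnership is created), and as a departure
#' when the source cluster held at least one other chain. Moves to or from
#' free solution count on the occupied side only.
#'
#' @param script A [trajectory_script()].
#' @return List with `arrivals` and `departures`.
#' @export
script_totals <- function(script) {
  memb <- script$initial
  ev <- script$events
  arr <- 0L; dep <- 0L
  for (e in seq_len(nrow(ev))) {
    ch <- ev$chain[e]; from <- ev$from[e]; to <- ev$to[e]
    others_src <- sum(memb == from) - 1L
    others_dst <- sum(memb[-ch] == to)
    if (from != 0 && others_src >= 1) dep <- dep + 1L
    if (to != 0 && others_dst >= 1) arr <- arr + 1L
    memb[ch] <- to
  }
  list(arrivals = arr, departures = dep)
}

#' Random move script with one event per frame
#'
#' Draws `n_events` moves at distinct frames: each moves a random chain
#' from its current location to a different cluster or to solution.
#'
#' @param n_chains Number of chains.
#' @param n_clusters Number of cluster ids in play.
#' @param n_events Number of move events.
#' @param n_frames Trajectory length (must exceed n_events + 1).
#' @param seed RNG seed.
#' @param box_edge Box edge (Angstrom).
#' @param p_solution Probability that a move targets free solution.
#' @return A [trajectory_script()].
#' @export
random_trajectory_script <- function(n_chains = 12, n_clusters = 3,
                                     n_events = 20, n_frames = n_events + 2,
                                     seed = 1, box_edge = 600,
                                     p_solution = 0.25) {
  if (n_frames < n_events + 2) stop("need n_frames >= n_events + 2")
  set.seed(seed)
  initial <- sample(0:n_clusters, n_chains, replace = TRUE)
  memb <- initial
  frames <- sort(sample(2:n_frames, n_events))
  ev <- data.frame(frame = frames, chain = 0L, from = 0L, to = 0L)
  for (e in seq_len(n_events)) {
    ch <- sample(n_chains, 1)
    from <- memb[ch]
    pick <- setdiff(seq_len(n_clusters), from)
    to <- if (stats::runif(1) < p_solution && from != 0) 0L
          else pick[sample.int(length(pick), 1)]
    ev$chain[e] <- ch; ev$from[e] <- from; ev$to[e] <- to
    memb[ch] <- to
  }
  trajectory_script(n_chains, initial, ev, n_frames, box_edge)
}

#' Realize a scripted trajectory as bead coordinates
#'
#' Generates frame-wise coordinates such that chain-level clustering with
#' the given cutoff reproduces the scripted membership exactly: every
#' occupancy group (each cluster id, and each chain while in solution) owns
#' a cell on a deterministic cubic grid of spacing `cluster_spacing`;
#' chains inside a cluster sit on a sub-grid of spacing 0.8 x cutoff, and
#' each chain is a compact bead blob of ~2 A extent.
#'
#' @param script A [trajectory_script()].
#' @param beads_per_chain Beads per chain (default 30).
#' @param cluster_spacing Distance between cluster-cell origins (Angstrom).
#' @param cutoff Clustering cutoff the geometry must honor (default 7.5).
#' @return A `cg_trajectory` with attribute `script`.
#' @export
gen_scripted_trajectory <- function(script, beads_per_chain = 30,
                                    cluster_spacing = 80, cutoff = 7.5) {
  nc <- script$n_chains
  memb <- script_membership(script)
  sub <- 0.8 * cutoff
  ## chain blob template: compact grid, spacing 1.2 A
  k <- ceiling(beads_per_chain^(1/3))
  g <- as.matrix(expand.grid(x = 1:k, y = 1:k, z = 1:k))[
    seq_len(beads_per_chain), , drop = FALSE] * 1.2
  blob <- sweep(g, 2, colMeans(g))
  blob_r <- max(sqrt(rowSums(blob^2)))
  ## occupancy groups: positive cluster ids + one per chain for solution
  cl_ids <- sort(unique(c(memb[memb > 0])))
  groups <- c(paste0("cl", cl_ids), paste0("sol", seq_len(nc)))
  gdim <- ceiling(length(groups)^(1/3))
  cells <- as.matrix(expand.grid(0:(gdim - 1), 0:(gdim - 1),
                                 0:(gdim - 1)))[seq_along(groups), ,
                                                drop = FALSE]
  origin <- cluster_spacing / 2
  cell_xyz <- cells * cluster_spacing + origin
  rownames(cell_xyz) <- groups
  ## feasibility: max sub-grid extent + blob must leave > cutoff gaps and
  ## fit in the box
  max_occ <- max(table(factor(memb[memb > 0],
                              levels = cl_ids)) |> as.integer(), 1)
  sdim <- ceiling(max_occ^(1/3))
  extent <- (sdim - 1) * sub + 2 * blob_r
  if (cluster_spacing - extent <= cutoff)
    stop("infeasible geometry: cluster_spacing ", cluster_spacing,
         " A leaves gaps <= cutoff for up to ", max_occ,
         " chains per cluster")
  if (2 * blob_r >= sub)
    stop("infeasible geometry: bead blob wider than intra-cluster spacing")
  if ((gdim - 1) * cluster_spacing + origin + extent > script$box_edge)
    stop("infeasible geometry: groups do not fit in the box")
  subcells <- as.matrix(expand.grid(0:(sdim - 1), 0:(sdim - 1),
                                    0:(sdim - 1))) * sub
  arr <- array(0, c(script$n_frames, nc * beads_per_chain, 3))
  chain <- rep(seq_len(nc), each = beads_per_chain)
  for (f in seq_len(script$n_frames)) {
    for (cid in cl_ids) {
      members <- which(memb[f, ] == cid)
      if (!length(members)) next
      base <- cell_xyz[paste0("cl", cid), ]
      for (s in seq_along(members)) {
        ch <- members[s]
        pos <- sweep(blob, 2, base + subcells[s, ], `+`)
        arr[f, chain == ch, ] <- pos
      }
    }
    for (ch in which(memb[f, ] == 0)) {
      base <- cell_xyz[paste0("sol", ch), ]
      arr[f, chain == ch, ] <- sweep(blob, 2, base, `+`)
    }
  }
  traj <- cg_trajectory(arr, chain, script$box_edge)
  attr(traj, "script") <- script
  traj
}

#' Write a trajectory script as JSON
#' @param script A [trajectory_script()].
#' @param path Output JSON file.
#' @export
write_trajectory_script <- function(script, path) {
  jsonlite::write_json(unclass(script), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory script from JSON
#' @param path JSON file written by [write_trajectory_script()].
#' @return A [trajectory_script()].
#' @export
read_trajectory_script <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trajectory_script(x$n_chains, x$initial, as.data.frame(x$events),
                    x$n_frames, x$box_edge)
}
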