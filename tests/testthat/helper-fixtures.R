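# Shared fixtures (built in code; nothing is read from disk except the
# package's own data files).

suite_lib <- load_suite_library()

# analytic OCF of a discrete circular helix: chord vectors have
# cos theta(s) = (a cos(s t) + h^2) / (a + h^2), a = (2 R sin(t/2))^2
helix_ocf_analytic <- function(s, rise, twist, radius) {
  t <- twist * pi / 180
  a <- (2 * radius * sin(t / 2))^2
  (a * cos(s * t) + rise^2) / (a + rise^2)
}

# pseudo-atom conformer from an explicit backbone coordinate matrix
points_conformer <- function(xyz) {
  n <- nrow(xyz)
  structure(list(
    atoms = data.frame(element = "P", resid = seq_len(n), atom = "P",
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
    sequence = paste(rep("N", n), collapse = ""),
    suite_assignment = NULL), class = "conformer")
}

# planar hexagon ("base ring") with a given normal, centered at `center`;
# returns 6 x 3 ring coordinates using uracil ring atom names
hexagon_ring <- function(center, normal, radius = 1.39, phase = 0) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ang <- phase + (0:5) * pi / 3
  t(sapply(ang, function(a) center + radius * (cos(a) * e1 + sin(a) * e2)))
}

# conformer whose "bases" are explicit hexagons (sequence of U's)
hexagon_conformer <- function(centers, normals) {
  n <- nrow(centers)
  rows <- lapply(seq_len(n), function(i) {
    ring <- hexagon_ring(centers[i, ], normals[i, ])
    data.frame(element = c("N", "C", "N", "C", "C", "C"), resid = i,
               atom = c("N1", "C2", "N3", "C4", "C5", "C6"),
               x = ring[, 1], y = ring[, 2], z = ring[, 3],
               stringsAsFactors = FALSE)
  })
  structure(list(atoms = do.call(rbind, rows),
                 sequence = paste(rep("U", n), collapse = ""),
                 suite_assignment = NULL), class = "conformer")
}

# independent union-find clustering oracle (no igraph, no kernel code)
brute_force_clusters <- function(x, chain, box, cutoff) {
  chains <- sort(unique(chain))
  parent <- seq_along(chains)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mi <- function(d) if (box > 0) d - box * round(d / box) else d
  for (ai in seq_along(chains)) for (bi in seq_along(chains)) {
    if (bi <= ai) next
    xa <- x[chain == chains[ai], , drop = FALSE]
    xb <- x[chain == chains[bi], , drop = FALSE]
    linked <- FALSE
    for (i in seq_len(nrow(xa))) {
      d <- sweep(xb, 2, xa[i, ], `-`)
      d <- cbind(mi(d[, 1]), mi(d[, 2]), mi(d[, 3]))
      if (any(rowSums(d^2) <= cutoff^2)) { linked <- TRUE; break }
    }
    if (linked) {
      ra <- find(ai); rb <- find(bi)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(chains), find, 0L)
  match(roots, unique(roots))
}

# partitions equal up to relabeling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    nrow(unique(cbind(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# minimal hand-rolled cg system for bespoke bead layouts
bead_system <- function(x, type, charge, mass, chain,
                        bonds = matrix(0L, 0, 2), rref_bond = numeric(0),
                        box = 0) {
  list(x = x, mass = mass, charge = charge, type = type, chain = chain,
       bonds = bonds, rref_bond = rref_bond, box = box)
}
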