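## Internal 3D geometry helpers shared by the chain builder and the
## structural order parameters.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle defined by four points
#'
#' Signed torsion angle (IUPAC convention) of the bond b-c viewed from a to d.
#'
#' @param a,b,c,d Numeric xyz vectors of length 3 (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @keywords internal
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(a, b, c) {
  v1 <- unit(a - b)
  v2 <- unit(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three previously placed atoms a-b-c, returns the position of atom d
#' such that |c-d| = `length`, angle(b,c,d) = `angle` and the torsion
#' a-b-c-d equals `torsion`.
#'
#' @param a,b,c xyz of the three reference atoms.
#' @param length Bond length c-d (Angstrom).
#' @param angle Bond angle b-c-d (degrees).
#' @param torsion Dihedral a-b-c-d (degrees).
#' @return xyz of the new atom.
#' @keywords internal
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Random rigid-body transform, used by rotation-invariance property tests.
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Radius of gyration of a set of points
#'
#' @param xyz n x 3 coordinate matrix.
#' @param mass Optional per-point masses (defaults to equal weights).
#' @return Rg in the units of `xyz`.
#' @export
radius_of_gyration <- function(xyz, mass = NULL) {
  xyz <- as.matrix(xyz)
  if (is.null(mass)) mass <- rep(1, nrow(xyz))
  mass <- mass / sum(mass)
  com <- colSums(xyz * mass)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(mass * d2))
}

#' Gyration tensor of a set of points
#'
#' @param xyz n x 3 coordinate matrix (unwrapped coordinates).
#' @return 3 x 3 gyration tensor.
#' @keywords internal
gyration_tensor <- function(xyz) {
  xyz <- as.matrix(xyz)
  com <- colMeans(xyz)
  d <- sweep(xyz, 2, com)
  crossprod(d) / nrow(xyz)
}
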