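## 3D convex hulls and Monte-Carlo volume-overlap (Jaccard) estimation for
## condensate shape-fluctuation analysis. The hull is built with an
## incremental (quickhull-style) algorithm; overlap volumes are estimated
## by seeded uniform sampling with half-space point-in-hull tests.

#' Convex hull of a 3D point cloud
#'
#' Incremental construction: start from a tetrahedron of extreme points,
#' then add every outside point, replacing its visible faces by a fan over
#' the horizon edges.
#'
#' @param points n x 3 coordinate matrix with >= 4 non-coplanar points.
#' @return A `hull3d`: `vertices` (indices into `points`), `faces`
#'   (triangles, outward oriented), `normals`, `offsets` (face plane
#'   d = n . x), `volume`, and the input `points`.
#' @export
convex_hull_3d <- function(points) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < 4) stop("degenerate hull: need at least 4 points")
  diam <- max(apply(P, 2, function(v) diff(range(v))))
  if (diam <= 0) stop("degenerate hull: all points coincide")
  eps <- 1e-9 * diam
  ## initial tetrahedron from extreme points
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (i1 == i2) i2 <- which.max(rowSums(sweep(P, 2, P[i1, ])^2))
  d12 <- P[i2, ] - P[i1, ]
  perp <- sweep(P, 2, P[i1, ])
  cr <- t(apply(perp, 1, function(v) cross3(d12, v)))
  i3 <- which.max(rowSums(cr^2))
  nrm <- cross3(d12, P[i3, ] - P[i1, ])
  h <- abs(as.numeric(sweep(P, 2, P[i1, ]) %*% nrm))
  i4 <- which.max(h)
  if (h[i4] < eps * sqrt(sum(nrm^2)) || length(unique(c(i1,i2,i3,i4))) < 4)
    stop("degenerate hull: points are (nearly) coplanar")
  interior <- colMeans(P[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4),
                 c(i2, i3, i4))
  orient <- function(f) {
    nv <- cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    if (sum(nv * (interior - P[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  face_normal <- function(f) {
    nv <- cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    list(n = nv, d = sum(nv * P[f[1], ]))
  }
  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- logical(nrow(faces))
    for (k in seq_len(nrow(faces))) {
      fn <- face_normal(faces[k, ])
      vis[k] <- sum(fn$n * P[p, ]) - fn$d >
        eps * sqrt(sum(fn$n^2))
    }
    if (!any(vis)) next
    ## horizon: directed edges of visible faces whose reverse lies in a
    ## non-visible face
    edges <- NULL
    for (k in which(vis)) {
      f <- faces[k, ]
      edges <- rbind(edges, c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[1]))
    }
    keep_edge <- vapply(seq_len(nrow(edges)), function(e) {
      rev_in_vis <- FALSE
      for (k in which(vis)) {
        f <- faces[k, ]
        fe <- rbind(c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[1]))
        if (any(fe[, 1] == edges[e, 2] & fe[, 2] == edges[e, 1]))
          rev_in_vis <- TRUE
      }
      !rev_in_vis
    }, TRUE)
    horizon <- edges[keep_edge, , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    newf <- cbind(horizon, p)
    faces <- rbind(faces, t(apply(newf, 1, orient)))
  }
  normals <- matrix(0, nrow(faces), 3)
  offsets <- numeric(nrow(faces))
  vol <- 0
  cen <- interior
  for (k in seq_len(nrow(faces))) {
    fn <- face_normal(faces[k, ])
    nv <- fn$n / sqrt(sum(fn$n^2))
    normals[k, ] <- nv
    offsets[k] <- sum(nv * P[faces[k, 1], ])
    a <- P[faces[k, 1], ] - cen
    b <- P[faces[k, 2], ] - cen
    cc <- P[faces[k, 3], ] - cen
    vol <- vol + abs(sum(a * cross3(b, cc))) / 6
  }
  structure(list(points = P, vertices = sort(unique(as.integer(faces))),
                 faces = faces, normals = normals, offsets = offsets,
                 volume = vol),
            class = "hull3d")
}

#' @export
print.hull3d <- function(x, ...) {
  cat(sprintf("Convex hull: %d vertices, %d faces, volume %.4g A^3\n",
              length(x$vertices), nrow(x$faces), x$volume))
  invisible(x)
}

#' Test points against a convex hull
#'
#' @param hull A `hull3d`.
#' @param pts m x 3 matrix.
#' @param tol Half-space tolerance.
#' @return Logical vector: inside (or on) the hull.
#' @export
in_hull <- function(hull, pts, tol = 1e-9) {
  pts <- matrix(pts, ncol = 3)
  s <- pts %*% t(hull$normals)
  apply(sweep(s, 2, hull$offsets, `-`) <= tol *
          max(1, max(abs(hull$offsets))), 1, all)
}

#' Jaccard index of two convex hulls
#'
#' Volume overlap |H1 intersect H2| / |H1 union H2| of the convex hulls of
#' two point clouds, estimated by seeded uniform Monte-Carlo sampling over
#' the union's bounding box. Optionally aligns both clouds to a common
#' center of mass before comparing (shape-only comparison).
#'
#' @param points1,points2 Point clouds (n x 3, >= 4 non-coplanar points,
#'   unwrapped coordinates).
#' @param n_samples Monte-Carlo samples (default 1e5).
#' @param seed RNG seed.
#' @param align_com Translate both clouds to a common centroid first
#'   (default FALSE: compare in place).
#' @return List with `jaccard`, the two hull volumes, and the estimator's
#'   binomial standard error.
#' @export
hull_jaccard <- function(points1, points2, n_samples = 1e5, seed = 1,
                         align_com = FALSE) {
  P1 <- as.matrix(points1); P2 <- as.matrix(points2)
  if (align_com) {
    P1 <- sweep(P1, 2, colMeans(P1))
    P2 <- sweep(P2, 2, colMeans(P2))
  }
  h1 <- convex_hull_3d(P1)
  h2 <- convex_hull_3d(P2)
  lo <- pmin(apply(P1, 2, min), apply(P2, 2, min))
  hi <- pmax(apply(P1, 2, max), apply(P2, 2, max))
  set.seed(seed)
  S <- cbind(stats::runif(n_samples, lo[1], hi[1]),
             stats::runif(n_samples, lo[2], hi[2]),
             stats::runif(n_samples, lo[3], hi[3]))
  in1 <- in_hull(h1, S)
  in2 <- in_hull(h2, S)
  n_union <- sum(in1 | in2)
  if (n_union == 0)
    return(list(jaccard = 0, volume1 = h1$volume, volume2 = h2$volume,
                se = 0))
  jac <- sum(in1 & in2) / n_union
  list(jaccard = jac, volume1 = h1$volume, volume2 = h2$volume,
       se = sqrt(jac * (1 - jac) / n_union))
}
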