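## Structural order parameters of RNA chains: orientation correlation
## function (OCF) of the backbone bond vectors, the summed correlation
## length l_OCF, and the base-stacking fraction from fitted base planes.

#' Orientation correlation function of a backbone
#'
#' Bond vectors between consecutive backbone reference points (phosphorus
#' atoms, or the per-residue pseudo-atoms of synthetic chains) are
#' normalized, and the mean dot product <cos theta_ij> is reported as a
#' function of the separation |i - j| over all bond pairs.
#'
#' @param conformer A `conformer` (all-atom or pseudo-atom backbone), or an
#'   n x 3 matrix of backbone points.
#' @return An `ocf_result`: list with `separation` (0..n_bonds-1), `ocf`
#'   (mean cos theta per separation), `b` (mean bond length, Angstrom) and
#'   `n_bonds`.
#' @export
ocf <- function(conformer) {
  pts <- if (is.matrix(conformer)) conformer else backbone_trace(conformer)
  if (nrow(pts) < 3)
    stop("need at least 3 backbone points (2 bond vectors)")
  bonds <- diff(pts)
  blen <- sqrt(rowSums(bonds^2))
  if (any(blen < 1e-9)) stop("coincident consecutive backbone points")
  u <- bonds / blen
  nb <- nrow(u)
  C <- u %*% t(u)   # cos theta_ij
  sep <- abs(outer(seq_len(nb), seq_len(nb), `-`))
  vals <- tapply(C, sep, mean)
  structure(list(separation = as.integer(names(vals)),
                 ocf = as.numeric(vals), b = mean(blen), n_bonds = nb),
            class = "ocf_result")
}

#' @export
print.ocf_result <- function(x, ...) {
  cat(sprintf("OCF over %d bonds (b = %.2f A); ocf(1) = %.3f\n",
              x$n_bonds, x$b, x$ocf[2]))
  invisible(x)
}

#' Correlation length from an orientation correlation function
#'
#' l_OCF = b * sum_s ocf(s), summing the per-separation means over
#' s = 0..n_bonds-1 (the s = 0 term is included, so a delta-correlated
#' chain gives l_OCF = b). A stiffness/order proxy: a rigid rod of n bonds
#' gives n * b.
#'
#' @param ocf_result An `ocf_result` from [ocf()].
#' @return Correlation length in Angstrom.
#' @export
locf <- function(ocf_result) {
  ocf_result$b * sum(ocf_result$ocf)
}

#' Base-stacking fraction of an RNA conformer
#'
#' Fits a plane to the aromatic ring heavy atoms of every base by total
#' least squares (the plane normal is the smallest-eigenvalue eigenvector
#' of the ring-atom covariance, which makes the fit rotation invariant).
#' Two bases are stacked when their plane centroids are within
#' `dist_cutoff` and their normals within `angle_cutoff` (acute angle).
#' A base counts as stacked if it has at least one qualifying partner.
#'
#' @param conformer A `conformer` with base ring atoms.
#' @param dist_cutoff Centroid distance threshold (Angstrom, default 5).
#' @param angle_cutoff Normal angle threshold (degrees, default 45).
#' @param adjacent_only Restrict partners to sequence-adjacent bases.
#' @return A `stacking_result`: percent_stacked, pairs (2-column matrix of
#'   stacked residue pairs), centroids, normals, thresholds.
#' @export
stacking_fraction <- function(conformer, dist_cutoff = 5,
                              angle_cutoff = 45, adjacent_only = FALSE) {
  bases <- strsplit(conformer$sequence, "")[[1]]
  n <- length(bases)
  cent <- matrix(NA_real_, n, 3)
  norm <- matrix(NA_real_, n, 3)
  at <- conformer$atoms
  for (i in seq_len(n)) {
    ring <- base_ring_atoms(bases[i])
    xyz <- as.matrix(at[at$resid == i & at$atom %in% ring,
                        c("x", "y", "z")])
    if (nrow(xyz) < 3) stop("residue ", i, " lacks ring atoms")
    cent[i, ] <- colMeans(xyz)
    cv <- stats::cov(xyz)
    ev <- eigen(cv, symmetric = TRUE)
    if (ev$values[2] < 1e-8)
      stop("degenerate (collinear) ring coordinates in residue ", i)
    norm[i, ] <- ev$vectors[, 3]
  }
  pairs <- NULL
  stacked <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    js <- if (adjacent_only) i + 1 else (i + 1):n
    for (j in js) {
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (d > dist_cutoff) next
      ca <- abs(sum(norm[i, ] * norm[j, ]))
      ang <- acos(min(1, ca)) * 180 / pi
      if (ang <= angle_cutoff) {
        pairs <- rbind(pairs, c(i, j))
        stacked[i] <- stacked[j] <- TRUE
      }
    }
  }
  structure(list(percent_stacked = 100 * mean(stacked),
                 stacked = stacked, pairs = pairs,
                 centroids = cent, normals = norm,
                 dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "stacking_result")
}

#' @export
print.stacking_result <- function(x, ...) {
  cat(sprintf("Base stacking: %.1f%% of bases stacked (%d pairs)\n",
              x$percent_stacked,
              if (is.null(x$pairs)) 0 else nrow(x$pairs)))
  invisible(x)
}

#' Ensemble-weighted mean and spread of a per-conformer metric
#'
#' Weighted mean and weighted standard deviation, with weights typically
#' the per-conformer selection frequencies from the ensemble optimization.
#'
#' @param values Per-conformer metric values.
#' @param weights Nonnegative weights (normalized internally).
#' @return List with `mean` and `sd`.
#' @export
ensemble_weighted_metric <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values and weights must be parallel")
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("all weights are zero")
  w <- weights / s
  m <- sum(w * values)
  list(mean = m, sd = sqrt(sum(w * (values - m)^2)))
}
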