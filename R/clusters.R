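## Condensate analytics: chain-level clustering, periodic unwrapping,
## migration (arrival/departure) events from adjacency differences,
## cluster growth tracking and per-chain shape metrics.

#' Chain-level clusters in one frame
#'
#' Two chains are linked when any inter-chain bead pair is within `cutoff`
#' under the minimum-image convention; clusters are the connected
#' components. An optional bead mask restricts the analysis (e.g. to RNA
#' beads only); chains with no retained beads get label NA.
#'
#' @param x n_beads x 3 coordinate matrix.
#' @param chain Integer chain id per bead.
#' @param box Cubic box edge (0 = open boundaries).
#' @param cutoff Linking distance (Angstrom; default 7.5 = 1.5 x the RNA
#'   bond length).
#' @param keep Optional logical bead mask.
#' @return Integer cluster label per chain (named by chain id), numbered
#'   by first appearance.
#' @export
find_clusters <- function(x, chain, box = 0, cutoff = 7.5, keep = NULL) {
  chains_all <- sort(unique(chain))
  if (!is.null(keep)) {
    x <- x[keep, , drop = FALSE]
    chain <- chain[keep]
  }
  chains <- sort(unique(chain))
  ## compact chain ids for the kernel
  cid <- match(chain, chains)
  A <- .chain_adjacency_cpp(as.matrix(x), as.integer(cid), box, cutoff)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  ## renumber by first appearance
  lab <- match(comp, unique(comp))
  out <- rep(NA_integer_, length(chains_all))
  names(out) <- chains_all
  out[as.character(chains)] <- lab
  out
}

#' Cluster labels for every frame of a trajectory
#'
#' @param trajectory A `cg_trajectory`.
#' @param cutoff Linking cutoff (Angstrom).
#' @param rna_only Restrict to RNA beads (types A, U, C, G); requires bead
#'   types in the trajectory.
#' @return A `cluster_timeline`: `labels` (frames x chains matrix),
#'   `cutoff`, `sizes` (list of per-frame cluster size tables) and
#'   `n_clusters` per frame.
#' @export
cluster_timeline <- function(trajectory, cutoff = 7.5, rna_only = FALSE) {
  keep <- NULL
  if (rna_only) {
    if (is.null(trajectory$type))
      stop("rna_only requires bead types in the trajectory")
    keep <- trajectory$type %in% c("A", "U", "C", "G")
  }
  nf <- n_frames(trajectory)
  labs <- NULL
  for (f in seq_len(nf)) {
    l <- find_clusters(frame_coords(trajectory, f), trajectory$chain,
                       trajectory$box, cutoff, keep)
    if (is.null(labs)) labs <- matrix(NA_integer_, nf, length(l),
                                      dimnames = list(NULL, names(l)))
    labs[f, ] <- l
  }
  keep_chain <- !is.na(labs[1, ])
  labs <- labs[, keep_chain, drop = FALSE]
  sizes <- lapply(seq_len(nf), function(f) table(labs[f, ]))
  structure(list(labels = labs, cutoff = cutoff,
                 sizes = sizes,
                 n_clusters = vapply(sizes, length, 0L)),
            class = "cluster_timeline")
}

#' @export
print.cluster_timeline <- function(x, ...) {
  cat(sprintf("Cluster timeline: %d frames, %d chains, cutoff %.1f A\n",
              nrow(x$labels), ncol(x$labels), x$cutoff))
  cat(sprintf("  clusters per frame: %d .. %d\n", min(x$n_clusters),
              max(x$n_clusters)))
  invisible(x)
}

## same-cluster adjacency matrix (unit diagonal) from one label row
labels_to_adjacency <- function(lab) {
  outer(lab, lab, `==`) * 1L
}

#' Arrival/departure events from a cluster timeline
#'
#' For each frame pair the same-cluster adjacency matrix A (unit diagonal)
#' is differenced, M = A(f+1) - A(f); +1 entries mark arrivals, -1 mark
#' departures. To prevent overcounting, a deterministic greedy scan of the
#' upper triangle (ascending row-then-column) counts at most one arrival
#' and one departure per involved chain per frame pair.
#'
#' @param timeline A `cluster_timeline`, or a frames x chains label
#'   matrix.
#' @return A `migration_events` object: `events` data.frame (frame, chain,
#'   type, cluster), totals `arrivals`/`departures`, and the per-frame
#'   migration matrices are recomputable from the labels (kept as
#'   `labels`).
#' @export
migration_events <- function(timeline) {
  labs <- if (inherits(timeline, "cluster_timeline")) timeline$labels
          else as.matrix(timeline)
  nf <- nrow(labs)
  if (nf < 2) stop("need at least 2 frames")
  nc <- ncol(labs)
  ev <- list()
  for (f in seq_len(nf - 1)) {
    M <- labels_to_adjacency(labs[f + 1, ]) - labels_to_adjacency(labs[f, ])
    used_arr <- logical(nc); used_dep <- logical(nc)
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        m <- M[i, j]
        if (m == 0) next
        if (m > 0 && !used_arr[i] && !used_arr[j]) {
          used_arr[i] <- used_arr[j] <- TRUE
          mover <- if (labs[f + 1, i] != labs[f, i]) i else j
          ev[[length(ev) + 1]] <- data.frame(
            frame = f, chain = mover, type = "arrival",
            cluster = labs[f + 1, mover])
        } else if (m < 0 && !used_dep[i] && !used_dep[j]) {
          used_dep[i] <- used_dep[j] <- TRUE
          mover <- if (labs[f + 1, i] != labs[f, i]) i else j
          ev[[length(ev) + 1]] <- data.frame(
            frame = f, chain = mover, type = "departure",
            cluster = labs[f, mover])
        }
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(frame = integer(), chain = integer(),
                            type = character(), cluster = integer())
  structure(list(events = events,
                 arrivals = sum(events$type == "arrival"),
                 departures = sum(events$type == "departure"),
                 labels = labs),
            class = "migration_events")
}

#' @export
print.migration_events <- function(x, ...) {
  cat(sprintf("Migration events: %d arrivals, %d departures over %d frame pairs\n",
              x$arrivals, x$departures, nrow(x$labels) - 1))
  invisible(x)
}

## -- unwrapping ------------------------------------------------------------

## make each chain contiguous, then stitch chains of one cluster together
unwrap_frame <- function(x, chain, box, labels) {
  x <- as.matrix(x)
  for (c_i in unique(chain)) {
    rows <- which(chain == c_i)
    if (length(rows) < 2) next
    for (k in 2:length(rows)) {
      d <- x[rows[k], ] - x[rows[k - 1], ]
      x[rows[k], ] <- x[rows[k], ] - box * round(d / box)
    }
  }
  chains <- as.integer(names(labels))
  if (!length(chains)) chains <- seq_along(labels)
  for (cl in unique(stats::na.omit(labels))) {
    members <- chains[which(labels == cl)]
    if (length(members) < 2) next
    placed <- members[1]
    todo <- members[-1]
    while (length(todo)) {
      ## nearest (wrapped) chain pair between placed and todo
      best <- NULL
      for (a in placed) for (b in todo) {
        xa <- x[chain == a, , drop = FALSE]
        xb <- x[chain == b, , drop = FALSE]
        dmin <- Inf; shift <- c(0, 0, 0)
        for (ib in seq_len(nrow(xb))) {
          d <- sweep(xa, 2, xb[ib, ], `-`)
          dw <- d - box * round(d / box)
          r2 <- rowSums(dw^2)
          k <- which.min(r2)
          if (r2[k] < dmin) {
            dmin <- r2[k]
            shift <- box * round((xb[ib, ] - xa[k, ]) / box)
          }
        }
        if (is.null(best) || dmin < best$d)
          best <- list(a = a, b = b, d = dmin, shift = shift)
      }
      x[chain == best$b, ] <- sweep(x[chain == best$b, , drop = FALSE],
                                    2, best$shift, `-`)
      placed <- c(placed, best$b)
      todo <- setdiff(todo, best$b)
    }
  }
  x
}

#' Unwrap cluster coordinates across periodic boundaries
#'
#' Per frame, every chain is made contiguous (bond-walk with nearest-image
#' shifts) and the chains of each cluster are stitched into one contiguous
#' object. Clusters whose unwrapped extent exceeds half the box are
#' flagged as percolating with a warning.
#'
#' @param trajectory A `cg_trajectory`.
#' @param timeline A `cluster_timeline` for the same trajectory.
#' @param frames Frame indices to unwrap (default all).
#' @return List (per requested frame) of unwrapped n_beads x 3 matrices.
#' @export
unwrap_clusters <- function(trajectory, timeline,
                            frames = seq_len(n_frames(trajectory))) {
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    xu <- unwrap_frame(frame_coords(trajectory, f), trajectory$chain,
                       trajectory$box, timeline$labels[f, ])
    labs <- timeline$labels[f, ]
    chains <- as.integer(colnames(timeline$labels))
    for (cl in unique(stats::na.omit(labs))) {
      members <- chains[which(labs == cl)]
      rows <- trajectory$chain %in% members
      ext <- apply(xu[rows, , drop = FALSE], 2,
                   function(v) diff(range(v)))
      if (trajectory$box > 0 && any(ext > trajectory$box / 2 + 1e-9))
        warning(sprintf(
          "cluster %d spans more than half the box in frame %d (percolation?)",
          cl, f))
    }
    out[[k]] <- xu
  }
  names(out) <- frames
  out
}

## -- shape metrics ---------------------------------------------------------

#' Size and shape metrics of one chain
#'
#' Radius of gyration (gyration-tensor trace), end-to-end distance, and
#' relative shape anisotropy kappa^2 = 1 - 3 (l1 l2 + l2 l3 + l3 l1) /
#' (l1 + l2 + l3)^2 from the gyration-tensor eigenvalues (0 = isotropic,
#' 1 = rod).
#'
#' @param xyz n x 3 matrix of unwrapped chain coordinates (>= 2 beads).
#' @return List with Rg, REE, kappa2, and the eigenvalues.
#' @export
chain_shape <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2) stop("need at least 2 beads")
  Tg <- gyration_tensor(xyz)
  ev <- sort(eigen(Tg, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  tr <- sum(ev)
  kappa2 <- if (tr < 1e-12) 0
            else 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] +
                          ev[3] * ev[1]) / tr^2
  list(Rg = sqrt(tr), REE = sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2)),
       kappa2 = max(0, min(1, kappa2)), eigenvalues = ev)
}

## -- growth tracking -------------------------------------------------------

#' Cluster growth and count series with identity tracking
#'
#' Clusters are tracked across frames by maximal membership overlap with
#' the previous frame (ties to the lower cluster id); sizes of tracked
#' clusters and the per-frame cluster count are reported.
#'
#' @param timeline A `cluster_timeline`.
#' @return List with `sizes` (frames x tracked-cluster matrix, NA before
#'   birth), `n_clusters` per frame, and `track_labels` (frames x chains
#'   matrix of tracked ids).
#' @export
cluster_growth_series <- function(timeline) {
  labs <- timeline$labels
  nf <- nrow(labs)
  tracked <- matrix(NA_integer_, nf, ncol(labs),
                    dimnames = dimnames(labs))
  next_id <- 0L
  prev_map <- NULL
  for (f in seq_len(nf)) {
    cur <- labs[f, ]
    ids <- sort(unique(cur))
    map <- integer(0)
    for (cl in ids) {
      members <- which(cur == cl)
      if (f == 1 || is.null(prev_map)) {
        next_id <- next_id + 1L
        map[as.character(cl)] <- next_id
      } else {
        prev_tracked <- tracked[f - 1, members]
        if (all(is.na(prev_tracked))) {
          next_id <- next_id + 1L
          map[as.character(cl)] <- next_id
        } else {
          tb <- sort(table(prev_tracked), decreasing = TRUE)
          best <- as.integer(names(tb)[tb == max(tb)])
          map[as.character(cl)] <- min(best)
        }
      }
    }
    ## a tracked id may be claimed by several current clusters (splits):
    ## keep it for the largest claimant, new ids for the rest
    claimed <- split(names(map), map)
    for (tid in names(claimed)) {
      cls <- as.integer(claimed[[tid]])
      if (length(cls) > 1) {
        szs <- vapply(cls, function(cl) sum(cur == cl), 0L)
        keepcl <- cls[order(-szs, cls)][1]
        for (cl in setdiff(cls, keepcl)) {
          next_id <- next_id + 1L
          map[as.character(cl)] <- next_id
        }
      }
    }
    tracked[f, ] <- map[as.character(cur)]
    prev_map <- map
  }
  all_ids <- sort(unique(as.integer(tracked)))
  sizes <- matrix(NA_integer_, nf, length(all_ids),
                  dimnames = list(NULL, all_ids))
  for (f in seq_len(nf)) {
    tb <- table(tracked[f, ])
    sizes[f, names(tb)] <- as.integer(tb)
  }
  list(sizes = sizes, n_clusters = timeline$n_clusters,
       track_labels = tracked)
}
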