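# Condensate analytics: clustering, unwrapping, migration accounting,
# convex hulls and chain shape metrics.

test_that("chain clustering matches a union-find brute force", {
  # far-apart chains are singletons
  x <- rbind(matrix(0, 3, 3) + 0, matrix(0, 3, 3) + 50,
             matrix(0, 3, 3) + 120)
  x <- x + matrix(stats::rnorm(27, sd = 0.5), ncol = 3)
  lab <- find_clusters(x, rep(1:3, each = 3), box = 400, cutoff = 7.5)
  expect_equal(length(unique(lab)), 3)
  # threshold behavior at the exact cutoff
  two <- rbind(c(0, 0, 0), c(7.0, 0, 0))
  expect_equal(length(unique(find_clusters(two, 1:2, 0, 7.5))), 1)
  two8 <- rbind(c(0, 0, 0), c(8.0, 0, 0))
  expect_equal(length(unique(find_clusters(two8, 1:2, 0, 7.5))), 2)
  # random 30-chain periodic frame vs the independent oracle
  set.seed(14)
  box <- 80
  xr <- matrix(stats::runif(30 * 5 * 3, 0, box), ncol = 3)
  ch <- rep(1:30, each = 5)
  got <- find_clusters(xr, ch, box = box, cutoff = 7.5)
  want <- brute_force_clusters(xr, ch, box = box, cutoff = 7.5)
  expect_true(same_partition(got, want))
})

test_that("periodic unwrapping restores contiguous clusters exactly", {
  box <- 50
  # contiguous reference chain crossing one face after wrapping
  ref <- cbind(seq(44, 62, by = 2), 10, 10)  # 10 beads, extends past 50
  wrapped <- ref; wrapped[, 1] <- wrapped[, 1] %% box
  xu <- unwrap_frame(wrapped, rep(1L, 10), box,
                     stats::setNames(1L, "1"))
  bond_len <- sqrt(rowSums(diff(xu)^2))
  expect_lt(max(bond_len), 6)
  expect_lt(max(abs(diff(xu) - diff(ref))), 1e-9)
  # fully interior chain is untouched
  interior <- cbind(seq(15, 33, by = 2), 25, 25)
  xi <- unwrap_frame(interior, rep(1L, 10), box, stats::setNames(1L, "1"))
  expect_equal(xi, interior)
  # two-chain cluster split across a face is stitched back together
  chain2 <- sweep(ref, 2, c(3, 2, 0), `+`)
  truth <- rbind(ref, chain2)
  wrapped2 <- truth %% box
  xu2 <- unwrap_frame(wrapped2, rep(1:2, each = 10), box,
                      stats::setNames(c(1L, 1L), c("1", "2")))
  rel <- sweep(xu2, 2, xu2[1, ])
  rel_truth <- sweep(truth, 2, truth[1, ])
  expect_lt(max(abs(rel - rel_truth)), 1e-9)
})

test_that("migration accounting: static, single-move and event balance", {
  lab_static <- matrix(rep(c(1, 1, 2, 2), 4), nrow = 4, byrow = TRUE)
  me <- migration_events(lab_static)
  expect_equal(me$arrivals + me$departures, 0)
  lab_move <- rbind(c(1, 1, 2, 2), c(1, 2, 2, 2))
  me2 <- migration_events(lab_move)
  expect_equal(me2$arrivals, 1)
  expect_equal(me2$departures, 1)
  expect_equal(me2$events$chain, c(2, 2))
  # departure into solution only
  lab_solo <- rbind(c(1, 1, 1), c(1, 1, 9))
  me3 <- migration_events(lab_solo)
  expect_equal(me3$arrivals, 0)
  expect_equal(me3$departures, 1)
  expect_error(migration_events(lab_solo[1, , drop = FALSE]), "2 frames")
})

test_that("convex hull volumes and Jaccard overlap are correct", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  h <- convex_hull_3d(cube)
  expect_equal(h$volume, 8, tolerance = 1e-9)
  # interior points do not change the hull
  h2 <- convex_hull_3d(rbind(cube, matrix(stats::runif(30, -0.9, 0.9),
                                          ncol = 3)))
  expect_equal(h2$volume, 8, tolerance = 1e-9)
  expect_error(convex_hull_3d(cbind(1:5, 2 * (1:5), 0)), "degenerate")
  # identical / disjoint / nested overlap cases
  expect_equal(hull_jaccard(cube, cube, n_samples = 2e4)$jaccard, 1)
  expect_equal(hull_jaccard(cube, cube + 10, n_samples = 2e4)$jaccard, 0)
  nest <- hull_jaccard(cube * 2^(1 / 3), cube, n_samples = 1e5, seed = 2)
  expect_lt(abs(nest$jaccard - 0.5), 0.02)
  # center-of-mass alignment makes translated shapes identical
  shifted <- hull_jaccard(cube, cube + 5, n_samples = 2e4,
                          align_com = TRUE)
  expect_equal(shifted$jaccard, 1)
})

test_that("Jaccard estimator error shrinks like 1/sqrt(samples)", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  est <- function(n, seed) hull_jaccard(cube * 2^(1 / 3), cube,
                                        n_samples = n,
                                        seed = seed)$jaccard
  s_small <- stats::sd(vapply(1:8, function(s) est(2000, s), 0))
  s_big <- stats::sd(vapply(1:8, function(s) est(32000, 100 + s), 0))
  # 16x samples: expect ~4x smaller spread (loose band)
  expect_gt(s_small / s_big, 1.5)
})

test_that("chain shape metrics hit their geometric limits", {
  rodx <- cbind(seq(0, 18, by = 2), 0, 0)
  sh <- chain_shape(rodx)
  expect_equal(sh$kappa2, 1, tolerance = 1e-12)
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  expect_equal(chain_shape(octa)$kappa2, 0, tolerance = 1e-12)
  dimer <- rbind(c(0, 0, 0), c(0, 0, 7))
  shd <- chain_shape(dimer)
  expect_equal(shd$REE, 7)
  expect_equal(shd$Rg, 3.5)
  # bounds over random chains
  k2 <- vapply(1:10000, function(s) {
    chain_shape(conformer_xyz(gen_random_coil(10, 5, seed = s),
                              "P"))$kappa2
  }, 0)
  expect_true(all(k2 >= 0 & k2 <= 1))
})

test_that("growth series conserve chains and track merges and splits", {
  # merge-only script: tracked sizes never decrease
  ev <- data.frame(frame = c(2, 3, 4), chain = c(3, 4, 5),
                   from = c(2, 2, 3), to = c(1, 1, 1))
  sc <- trajectory_script(5, c(1, 1, 2, 2, 3), ev, n_frames = 5)
  tl <- cluster_timeline(gen_scripted_trajectory(sc, beads_per_chain = 10))
  g <- cluster_growth_series(tl)
  expect_true(all(rowSums(g$sizes, na.rm = TRUE) == 5))
  big <- g$sizes[, "1"]
  expect_true(all(diff(big) >= 0))
  # a split raises the cluster count by one at the split frame
  ev2 <- data.frame(frame = 3, chain = 2, from = 1, to = 0)
  sc2 <- trajectory_script(4, c(1, 1, 1, 2), ev2, n_frames = 4)
  tl2 <- cluster_timeline(gen_scripted_trajectory(sc2,
                                                  beads_per_chain = 10))
  expect_equal(tl2$n_clusters, c(2, 2, 3, 3))
  # random script: per-frame sizes always sum to the chain count
  sc3 <- random_trajectory_script(n_chains = 10, n_clusters = 3,
                                  n_events = 15, seed = 4)
  tl3 <- cluster_timeline(gen_scripted_trajectory(sc3,
                                                  beads_per_chain = 8))
  g3 <- cluster_growth_series(tl3)
  expect_true(all(rowSums(g3$sizes, na.rm = TRUE) == 10))
})
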