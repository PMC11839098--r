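# Orientation correlation functions, correlation lengths, base stacking,
# and ensemble weighting.

test_that("OCF normalization, bounds and limiting geometries", {
  rod <- gen_ideal_helix(10, rise = 5, twist = 0, radius = 0)
  o_rod <- ocf(rod)
  expect_equal(o_rod$ocf, rep(1, 9), tolerance = 1e-12)
  h <- gen_ideal_helix(33, rise = 2.81, twist = 360 / 11, radius = 9.4)
  o_h <- ocf(h)
  expect_equal(o_h$ocf[1], 1)
  expect_true(all(abs(o_h$ocf) <= 1 + 1e-12))
  # period 11: maxima at separations 11 and 22
  expect_gt(o_h$ocf[12], 0.999)
  expect_gt(o_h$ocf[23], 0.999)
  expect_error(ocf(points_conformer(rbind(c(0, 0, 0), c(0, 0, 0),
                                          c(1, 0, 0)))), "coincident")
})

test_that("isotropic chains decorrelate to zero mean", {
  vals <- vapply(1:10000, function(s) {
    o <- ocf(gen_random_coil(5, 5, seed = s))
    mean(o$ocf[-1])
  }, 0)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-3)
})

test_that("OCF and stacking are rigid-motion invariant", {
  cf <- build_chain(strrep("A", 12), rep("1a", 11), suite_lib)
  set.seed(9)
  cf2 <- apply_rigid(cf, random_rotation(), c(-30, 12, 99))
  expect_lt(max(abs(ocf(cf)$ocf - ocf(cf2)$ocf)), 1e-9)
  s1 <- stacking_fraction(cf); s2 <- stacking_fraction(cf2)
  expect_equal(s1$percent_stacked, s2$percent_stacked)
  expect_identical(s1$pairs, s2$pairs)
})

test_that("correlation length follows the stated summation convention", {
  # rigid rod of 9 bonds: l_ocf = n_bonds * b
  rod <- ocf(gen_ideal_helix(10, rise = 5, twist = 0, radius = 0))
  expect_equal(locf(rod), 9 * 5, tolerance = 1e-9)
  # delta-correlated chain: l_ocf = b
  delta <- structure(list(separation = 0:9,
                          ocf = c(1, rep(0, 9)), b = 5.9, n_bonds = 10),
                     class = "ocf_result")
  expect_equal(locf(delta), 5.9)
  # exponential decay: geometric series closed form
  lam <- 3; n <- 25; b <- 5.9
  expo <- structure(list(separation = 0:(n - 1),
                         ocf = exp(-(0:(n - 1)) / lam), b = b,
                         n_bonds = n), class = "ocf_result")
  closed <- b * (1 - exp(-n / lam)) / (1 - exp(-1 / lam))
  expect_lt(abs(locf(expo) / closed - 1), 0.01)
})

test_that("stacking criteria respond to distance and angle exactly", {
  z <- c(0, 0, 1)
  # parallel coplanar hexagons offset 3.4 A along the shared normal
  cf_stack <- hexagon_conformer(rbind(c(0, 0, 0), c(0, 0, 3.4)),
                                rbind(z, z))
  expect_equal(stacking_fraction(cf_stack)$percent_stacked, 100)
  # same pair at 6.0 A: distance criterion fails
  cf_far <- hexagon_conformer(rbind(c(0, 0, 0), c(0, 0, 6)), rbind(z, z))
  expect_equal(stacking_fraction(cf_far)$percent_stacked, 0)
  # 60-degree tilt fails the angle criterion; 30 degrees passes
  tilt <- function(deg) c(sin(deg * pi / 180), 0, cos(deg * pi / 180))
  cf_60 <- hexagon_conformer(rbind(c(0, 0, 0), c(0, 0, 3.4)),
                             rbind(z, tilt(60)))
  expect_equal(stacking_fraction(cf_60)$percent_stacked, 0)
  cf_30 <- hexagon_conformer(rbind(c(0, 0, 0), c(0, 0, 3.4)),
                             rbind(z, tilt(30)))
  expect_equal(stacking_fraction(cf_30)$percent_stacked, 100)
  # collinear "ring" is rejected
  cf_bad <- cf_stack
  cf_bad$atoms[cf_bad$atoms$resid == 1, c("y", "z")] <- 0
  cf_bad$atoms$x[cf_bad$atoms$resid == 1] <- 1:6
  expect_error(stacking_fraction(cf_bad), "collinear")
})

test_that("randomized base orientations on real backbones rarely stack", {
  # sampled RNA coils with every base ring re-oriented at random about
  # its own centroid: the geometry-only null for the stacking detector
  set.seed(3)
  rand_rot <- function() {
    qv <- stats::rnorm(4); qv <- qv / sqrt(sum(qv^2))
    w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x),
             1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
  }
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
  pct <- vapply(1:10, function(s) {
    p <- sample_pool(strrep("U", 15), uniform_suite_weights(suite_lib),
                     n_conformers = 1, seed = s)
    cf <- p$conformers[[1]]
    for (i in 1:15) {
      rows <- cf$atoms$resid == i & cf$atoms$atom %in% ring
      xyz <- as.matrix(cf$atoms[rows, c("x", "y", "z")])
      cen <- colMeans(xyz)
      cf$atoms[rows, c("x", "y", "z")] <-
        sweep(sweep(xyz, 2, cen) %*% t(rand_rot()), 2, cen, `+`)
    }
    stacking_fraction(cf)$percent_stacked
  }, 0)
  expect_lt(mean(pct), 15)
})

test_that("helical chains stack while adjacent-only mode is stricter", {
  cf <- build_chain(strrep("A", 20), rep("1a", 19), suite_lib)
  all_mode <- stacking_fraction(cf)
  adj_mode <- stacking_fraction(cf, adjacent_only = TRUE)
  expect_gt(all_mode$percent_stacked, 80)
  expect_lte(adj_mode$percent_stacked, all_mode$percent_stacked)
})

test_that("ensemble weighting matches the explicit weighted sums", {
  x <- c(2, 4, 6, 8)
  expect_equal(ensemble_weighted_metric(x, rep(1, 4))$mean, 5)
  one <- ensemble_weighted_metric(x, c(0, 0, 1, 0))
  expect_equal(one$mean, 6)
  expect_equal(one$sd, 0)
  set.seed(12)
  v <- stats::rnorm(50); w <- stats::runif(50)
  got <- ensemble_weighted_metric(v, w)
  m <- sum(w * v) / sum(w)
  expect_lt(abs(got$mean - m), 1e-12)
  expect_lt(abs(got$sd - sqrt(sum(w / sum(w) * (v - m)^2))), 1e-12)
  expect_error(ensemble_weighted_metric(v, rep(0, 50)), "zero")
})
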