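# Coarse-grained force field and Langevin dynamics: screening lengths,
# energy terms against brute-force oracles, lattice initialization, and
# integrator physics.

ff150 <- load_forcefield(c_Na = 0.15)

test_that("Debye screening follows kappa = sqrt(c)/3.06", {
  # agreement at the printed precision (3 decimals)
  expect_equal(kappa_from_salt(0.6), 0.253, tolerance = 1e-3)
  expect_equal(kappa_from_salt(0.15), 0.126, tolerance = 5e-3)
  expect_equal(kappa_from_salt(0), 0)
  expect_error(kappa_from_salt(-0.1), "nonnegative")
})

test_that("harmonic bond energy matches K (r - rref)^2 and a loop oracle", {
  sys <- make_cg_system(1, 0, "U", beads_per_chain = 2, box = 100,
                        ff = ff150)
  expect_equal(bonded_energy(sys$x, sys, ff150, box = 100), 0,
               tolerance = 1e-12)
  x <- sys$x; x[2, 1] <- x[1, 1] + 6.00
  expect_equal(bonded_energy(x, sys, ff150, box = 100), 9.6,
               tolerance = 1e-10)
  # 10-chain random displacement vs explicit per-bond loop
  sys10 <- make_cg_system(5, 5, "A", beads_per_chain = 8, box = 150,
                          ff = ff150)
  set.seed(3)
  xr <- sys10$x + matrix(stats::rnorm(length(sys10$x)) * 0.5,
                         ncol = 3)
  manual <- 0
  for (b in seq_len(nrow(sys10$bonds))) {
    i <- sys10$bonds[b, 1]; j <- sys10$bonds[b, 2]
    d <- xr[i, ] - xr[j, ]
    d <- d - 150 * round(d / 150)
    manual <- manual + ff150$K * (sqrt(sum(d^2)) - sys10$rref_bond[b])^2
  }
  expect_lt(abs(bonded_energy(xr, sys10, ff150, box = 150) - manual),
            1e-10)
})

test_that("Debye-Hueckel energy: limits, symmetry and brute force", {
  ff0 <- load_forcefield(c_Na = 0)
  x2 <- rbind(c(0, 0, 0), c(10, 0, 0))
  # unscreened Coulomb at eps_r = 80
  e <- dh_energy(x2, c(1, 1), ff0)
  expect_equal(e, 1389.35458 / 80 / 10, tolerance = 1e-9)
  # attraction/repulsion symmetry
  ea <- dh_energy(x2, c(1, -1), ff150)
  er <- dh_energy(x2, c(1, 1), ff150)
  expect_lt(ea, 0)
  expect_equal(abs(ea), er, tolerance = 1e-12)
  # 50-bead random periodic box vs all-pairs minimum-image sum
  set.seed(8)
  box <- 40
  x <- matrix(stats::runif(150, 0, box), ncol = 3)
  qch <- sample(c(-1, 1), 50, replace = TRUE)
  manual <- 0
  for (i in 1:49) for (j in (i + 1):50) {
    d <- x[i, ] - x[j, ]
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    if (r < ff150$elec_cutoff)
      manual <- manual + ff150$ke_over_eps * qch[i] * qch[j] *
        exp(-ff150$kappa * r) / r
  }
  expect_lt(abs(dh_energy(x, qch, ff150, box = box) - manual) /
              abs(manual), 1e-9)
  expect_error(dh_energy(rbind(c(0, 0, 0), c(1e-9, 0, 0)), c(1, 1),
                         ff150), "overlapping")
})

test_that("Wang-Frenkel wells vanish at cutoff and bottom out at -eps", {
  eps <- 5; sig <- 8
  expect_identical(wf_potential(3 * sig, eps, sig), 0)
  expect_identical(wf_potential(4 * sig, eps, sig), 0)
  opt <- stats::optimize(wf_potential, c(sig, 3 * sig), eps = eps,
                         sigma = sig, tol = 1e-12)
  expect_lt(abs(opt$objective + eps), 1e-9)
  expect_gt(wf_potential(0.8 * sig, eps, sig), 0)  # repulsive core
  # shipped table: adenine-adenine stickers outcompete uracil-uracil
  expect_gt(ff150$wf$eps["A", "A"], ff150$wf$eps["U", "U"])
  expect_gt(ff150$wf$eps["A", "A"], ff150$wf$eps["C", "C"])
  # the pairwise kernel agrees with the closed form
  x2 <- rbind(c(0, 0, 0), c(7.1, 0, 0))
  got <- wang_frenkel_energy(x2, c("U", "R"), ff150)
  want <- wf_potential(7.1, ff150$wf$eps["U", "R"],
                       ff150$wf$sig["U", "R"], rc = ff150$wf$rc["U", "R"])
  expect_lt(abs(got - want), 1e-9)
  expect_error(wang_frenkel_energy(x2, c("U", "X"), ff150), "missing")
})

test_that("lattice initialization is deterministic and collision-free", {
  x8 <- init_lattice(8, 0, 2, box = 100)
  centers <- t(vapply(1:8, function(c_i)
    colMeans(x8[(c_i - 1) * 2 + 1:2, ]), numeric(3)))
  expect_true(all(sort(unique(centers[, 1])) == c(25, 75)))
  expect_true(all(sort(unique(centers[, 3])) == c(25, 75)))
  x1 <- init_lattice(1, 0, 3, box = 80)
  expect_equal(colMeans(x1), c(40, 40, 40))
  # no inter-chain bead pair closer than 2 A at frame 0
  sys <- make_cg_system(6, 6, "U", beads_per_chain = 20, box = 160,
                        ff = ff150)
  d <- as.matrix(stats::dist(sys$x))
  same <- outer(sys$chain, sys$chain, `==`)
  d[same] <- Inf
  expect_gt(min(d), 2)
  expect_error(init_lattice(100, 0, 30, box = 100), "overfilled")
})

test_that("overdamped zero-temperature dynamics relax the bond to rref", {
  sys <- make_cg_system(1, 0, "U", beads_per_chain = 2, box = 60,
                        ff = ff150)
  sys$x[2, 1] <- sys$x[1, 1] + 6.5  # stretched start
  cfg <- sim_config(box = 60, dt = 10, n_steps = 20000, temperature = 0,
                    relaxation_ps = 1, seed = 2, stride = 1000)
  tr <- run_langevin(sys, ff150, cfg)
  xf <- frame_coords(tr, n_frames(tr))
  d <- xf[1, ] - xf[2, ]
  d <- d - 60 * round(d / 60)
  expect_lt(abs(sqrt(sum(d^2)) - 5.00), 1e-3)
})

test_that("frictionless integration conserves energy on a dimer", {
  sys <- make_cg_system(1, 0, "U", beads_per_chain = 2, box = 200,
                        ff = ff150)
  sys$x[2, 1] <- sys$x[1, 1] + 6.0
  cfg <- sim_config(box = 200, dt = 1, n_steps = 100000,
                    relaxation_ps = 0, seed = 1, stride = 1000)
  tr <- run_langevin(sys, ff150, cfg)
  kB <- 0.00831446
  etot <- vapply(seq_len(n_frames(tr)), function(f) {
    ke <- 1.5 * 2 * kB * attr(tr, "temperature")[f]
    x <- frame_coords(tr, f)
    pe <- bonded_energy(x, sys, ff150, box = 200) +
      dh_energy(x, sys$charge, ff150, box = 200, bonds = sys$bonds) +
      wang_frenkel_energy(x, sys$type, ff150, box = 200,
                          bonds = sys$bonds)
    ke + pe
  }, 0)
  expect_lt(max(abs(etot - etot[1])), 0.01 * abs(etot[1]))
})

test_that("random forcing does not impart net drift", {
  # 32 independent beads: the center of mass stays within the diffusive
  # envelope (3 sigma) rather than drifting ballistically
  sys <- make_cg_system(32, 0, "U", beads_per_chain = 1, box = 500,
                        ff = ff150)
  sys$charge[] <- 0
  cfg <- sim_config(box = 500, n_steps = 5000, relaxation_ps = 5,
                    seed = 6, stride = 100)
  tr <- run_langevin(sys, ff150, cfg)
  # per-bead displacement over the run
  x0 <- frame_coords(tr, 1); x1 <- frame_coords(tr, n_frames(tr))
  disp <- x1 - x0
  disp <- disp - 500 * round(disp / 500)
  m <- colMeans(disp)
  se <- apply(disp, 2, stats::sd) / sqrt(32)
  expect_true(all(abs(m) < 3 * se + 1e-9))
})

test_that("screening shortens the bound time of an oppositely charged pair", {
  bound_frac <- function(c_Na, seed) {
    ff <- load_forcefield(c_Na = c_Na)
    x <- rbind(c(30, 30, 30), c(37, 30, 30))
    sys <- bead_system(x, type = c("U", "R"), charge = c(-1, 1),
                       mass = c(306.2, 156.2), chain = c(1L, 2L),
                       box = 60)
    cfg <- sim_config(box = 60, n_steps = 30000, relaxation_ps = 5,
                      seed = seed, stride = 50, c_Na = c_Na)
    tr <- run_langevin(sys, ff, cfg)
    r <- vapply(seq_len(n_frames(tr)), function(f) {
      d <- frame_coords(tr, f)[1, ] - frame_coords(tr, f)[2, ]
      d <- d - 60 * round(d / 60)
      sqrt(sum(d^2))
    }, 0)
    mean(r < 12)
  }
  lo <- vapply(1:5, function(s) bound_frac(0.15, s), 0)
  hi <- vapply(1:5, function(s) bound_frac(0.90, s), 0)
  expect_gte(stats::median(lo), stats::median(hi))
})
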