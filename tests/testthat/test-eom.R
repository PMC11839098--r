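# Ensemble optimization: profile averaging, GA selection, suite
# reweighting and the Jensen-Shannon diagnostics.

make_profiles <- function(n, seed = 1) {
  lapply(seq_len(n), function(i) {
    cf <- gen_random_coil(20, 5.9, seed = seed + i)
    debye_intensity(conformer_xyz(cf, "P"), default_q_grid())
  })
}

test_that("ensemble averaging is the exact weighted pointwise sum", {
  profs <- make_profiles(10)
  one <- ensemble_average(profs, c(1, rep(0, 9)))
  expect_equal(one$I, profs[[1]]$I)
  two <- ensemble_average(profs[1:2], c(1, 1))
  expect_equal(two$I, (profs[[1]]$I + profs[[2]]$I) / 2)
  set.seed(3)
  a <- stats::runif(10)
  got <- ensemble_average(profs, a)
  manual <- 0
  for (k in 1:10) manual <- manual + a[k] / sum(a) * profs[[k]]$I
  expect_lt(max(abs(got$I - manual)), 1e-12)
  expect_error(ensemble_average(profs, a[1:3]), "one weight per profile")
})

test_that("Jensen-Shannon divergence matches its direct evaluation", {
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:20) {
    W1 <- stats::runif(34); W1 <- W1 / sum(W1)
    W2 <- stats::runif(34); W2 <- W2 / sum(W2)
    S <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    direct <- S((W1 + W2) / 2) - S(W1) / 2 - S(W2) / 2
    j <- jsd(W1, W2)
    expect_lt(abs(j - direct), 1e-12)
    expect_gte(j, 0)
    expect_lte(j, log(2) + 1e-12)
  }
  expect_error(jsd(c(0.5, 0.4), c(0.5, 0.5)), "normalized")
})

test_that("suite reweighting minimizes the frequency discrepancy", {
  w_old <- c(0.5, 0.3, 0.2)
  h_pool <- c(0.45, 0.35, 0.2)
  # fixed point at h_ens = h_pool
  r0 <- reweight_suites(h_pool, h_pool, w_old)
  expect_equal(r0$w, w_old, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r0$chi_h2, 0, tolerance = 1e-15)
  # concentration on one suite raises its weight; objective never worsens
  h_ens <- c(0.9, 0.05, 0.05)
  r1 <- reweight_suites(h_ens, h_pool, w_old)
  expect_gt(r1$w[1], w_old[1])
  expect_lte(r1$chi_h2, r1$chi_h2_old)
  # dense simplex grid oracle on the 3-suite toy
  grid <- seq(0.001, 0.998, by = 0.004)
  best <- Inf
  for (w1 in grid) for (w2 in grid[grid < 1 - w1]) {
    v <- chi_h_square(c(w1, w2, 1 - w1 - w2), w_old, h_ens, h_pool)
    if (v < best) best <- v
  }
  expect_lte(r1$chi_h2, best + 1e-6)
  # numerical polish agrees with the closed form
  r2 <- reweight_suites(h_ens, h_pool, w_old, polish = TRUE)
  expect_equal(r2$w, r1$w, tolerance = 1e-4, ignore_attr = TRUE)
  expect_error(reweight_suites(c(0.5, 0.5, 0), c(0.5, 0, 0.5), w_old),
               "positive")
})

test_that("GA selection behaves on degenerate and planted inputs", {
  q <- default_q_grid()
  base <- make_profiles(1)[[1]]
  same <- lapply(1:30, function(i) base)
  target <- scattering_profile(q, 1.3 * base$I, 0.02 * base$I)
  cfg <- ga_config(n_generations = 5, n_ensembles = 8,
                   curves_per_ensemble = 5, mutations_per_ensemble = 1,
                   inner_iterations = 1, seed = 2)
  sel <- genetic_select(same, target, cfg)
  single <- chi_square(base, target)
  expect_lt(max(abs(sel$chi2 - single$chi2)), 1e-10)
  expect_equal(sel$chi2_red, single$chi2, tolerance = 1e-10)
  # elitism makes the best fitness non-increasing across generations
  profs <- make_profiles(60, seed = 40)
  tI <- Reduce(`+`, lapply(profs[1:10], function(p) p$I)) / 10
  target2 <- scattering_profile(q, tI, 0.02 * tI)
  cfg2 <- ga_config(n_generations = 60, n_ensembles = 20,
                    curves_per_ensemble = 10, mutations_per_ensemble = 2,
                    inner_iterations = 1, seed = 3)
  sel2 <- genetic_select(profs, target2, cfg2)
  expect_true(all(diff(sel2$trace) <= 1e-12))
  # reproducibility
  sel3 <- genetic_select(profs, target2, cfg2)
  expect_identical(sel2$members, sel3$members)
  # no-repeats mode needs a large enough pool
  cfg3 <- ga_config(n_generations = 2, n_ensembles = 4,
                    curves_per_ensemble = 10, allow_repeats = FALSE,
                    inner_iterations = 1)
  expect_error(genetic_select(profs[1:5], target2, cfg3), "pool smaller")
})

test_that("a single outer iteration returns a one-entry trace", {
  red <- suite_subset(suite_lib, c("5j", "4d", "8d"))
  w <- uniform_suite_weights(red)
  pool <- sample_pool(strrep("U", 10), w, n_conformers = 15, seed = 5,
                      library = red, clash_cutoff = NULL)
  pool <- pool_profiles(pool)
  tI <- Reduce(`+`, lapply(pool$profiles, function(p) p$I)) / 15
  target <- scattering_profile(default_q_grid(), tI, 0.02 * tI)
  cfg <- ga_config(n_generations = 30, n_ensembles = 10,
                   curves_per_ensemble = 6, mutations_per_ensemble = 1,
                   inner_iterations = 1, seed = 4)
  fit <- iterate_eom(strrep("U", 10), target, library = red, cfg = cfg,
                     n_outer = 1, seed = 7, pool_size = 15,
                     clash_cutoff = NULL)
  expect_length(fit$trace$chi2_red, 1)
  expect_length(fit$trace$jsd, 0)
  expect_length(fit$trace$weights, 1)  # weights untouched after selection
  # full determinism of the outer loop
  fit2 <- iterate_eom(strrep("U", 10), target, library = red, cfg = cfg,
                      n_outer = 1, seed = 7, pool_size = 15,
                      clash_cutoff = NULL)
  expect_identical(fit$trace$chi2_red, fit2$trace$chi2_red)
  expect_identical(fit$selection$members, fit2$selection$members)
})
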