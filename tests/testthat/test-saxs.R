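# Debye scattering and the profile-level analyses: Guinier, molecular
# form factor, chi-square with fitted scale, Kratky, I(0) extrapolation,
# match point, peak lengthscale.

test_that("Debye intensity matches closed forms and a brute-force loop", {
  q <- default_q_grid()
  # single unit scatterer
  one <- debye_intensity(matrix(c(1, 2, 3), 1), q)
  expect_equal(one$I, rep(1, length(q)))
  # two unit scatterers at distance d
  d <- 8.5
  two <- debye_intensity(rbind(c(0, 0, 0), c(d, 0, 0)), q)
  expect_lt(max(abs(two$I - (2 + 2 * sin(q * d) / (q * d)))), 1e-12)
  # 50-atom random structure vs naive double loop
  set.seed(1)
  xyz <- matrix(stats::rnorm(150) * 10, ncol = 3)
  got <- debye_intensity(xyz, q)$I
  brute <- vapply(q, function(qq) {
    s <- 0
    for (i in 1:50) for (j in 1:50) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      s <- s + if (r < 1e-12) 1 else sin(qq * r) / (qq * r)
    }
    s
  }, 0)
  expect_lt(max(abs(got - brute) / brute), 1e-9)
})

test_that("Debye intensity is rigid-motion invariant with exact I(0)", {
  q <- c(1e-6, default_q_grid())
  cf <- build_chain(strrep("U", 8), rep("1a", 7), suite_lib)
  I1 <- debye_intensity(cf, q)$I
  set.seed(2)
  cf2 <- apply_rigid(cf, random_rotation(), c(10, -40, 7))
  I2 <- debye_intensity(cf2, q)$I
  expect_lt(max(abs(I1 - I2) / I1), 1e-9)
  f0 <- sum(vapply(cf$atoms$element, function(e) atomic_form_factor(e, 0),
                   0))
  expect_equal(I1[1], f0^2, tolerance = 1e-6)
})

test_that("Guinier fit recovers exact and near-exact inputs", {
  q <- default_q_grid()
  exact <- scattering_profile(q, 7 * exp(-q^2 * 23.25^2 / 3))
  g <- suppressWarnings(guinier_fit(exact))
  expect_equal(g$Rg, 23.25, tolerance = 1e-9)
  expect_equal(g$I0, 7, tolerance = 1e-9)
  # flat profile: no decaying window
  expect_error(guinier_fit(scattering_profile(q, rep(3, length(q)))),
               "window")
  # homogeneous sphere of radius R: Rg -> R sqrt(3/5); a conservative
  # window keeps the Guinier truncation bias of the sharp sphere below 1%
  R <- 25
  qs <- seq(0.001, 0.06, length.out = 120)
  qr <- qs * R
  Isph <- (3 * (sin(qr) - qr * cos(qr)) / qr^3)^2
  gs <- guinier_fit(scattering_profile(qs, Isph), qRg_limit = 0.8)
  expect_lt(abs(gs$Rg / (R * sqrt(3 / 5)) - 1), 0.01)
})

test_that("Guinier consistency: fitted Rg matches the coordinate Rg", {
  cf <- build_chain(strrep("U", 10), rep("1c", 9), suite_lib)
  qfine <- seq(0.002, 0.06, length.out = 40)
  g <- guinier_fit(debye_intensity(cf, qfine))
  expect_lt(abs(g$Rg / radius_of_gyration(conformer_xyz(cf)) - 1), 0.02)
})

test_that("molecular form factor fit recovers the Flory exponent", {
  q <- default_q_grid()
  # Gaussian-chain limit: the Debye function is the nu = 1/2 case
  x <- (q * 20)^2
  Idebye <- 5 * 2 * (exp(-x) - 1 + x) / x^2
  f <- mff_fit(scattering_profile(q, Idebye))
  expect_lt(abs(f$nu - 0.5), 0.02)
  # planted swollen-chain exponent
  Im <- mff_intensity(q, nu = 0.551, Rg = 23.25, I0 = 7)
  f2 <- mff_fit(scattering_profile(q, Im))
  expect_lt(abs(f2$nu - 0.551), 0.005)
  # rigid rod: high-q decay ~ q^-1, nu fitted near 1 over the mid-q
  # power-law region (the fit's stated operating regime)
  qr <- q * 60
  Irod <- vapply(qr, function(u) {
    2 * stats::integrate(function(t) sin(t) / t, 1e-8, u)$value / u -
      4 * sin(u / 2)^2 / u^2
  }, 0)
  mid <- q >= 0.06
  f3 <- mff_fit(scattering_profile(q[mid], Irod[mid]))
  expect_gte(f3$nu, 0.9)
})

test_that("chi-square uses the analytic optimal scale", {
  q <- default_q_grid()
  I <- 6 * exp(-q^2 * 150)
  m <- scattering_profile(q, I)
  e_same <- scattering_profile(q, I, sigma = 0.02 * I)
  r1 <- chi_square(m, e_same)
  expect_equal(r1$chi2, 0, tolerance = 1e-20)
  expect_equal(r1$mu, 1)
  e_scaled <- scattering_profile(q, 3 * I, sigma = 0.05 * I)
  r3 <- chi_square(m, e_scaled)
  expect_equal(r3$chi2, 0, tolerance = 1e-20)
  expect_equal(r3$mu, 3)
  # random pair: analytic mu minimizes Eq-style objective (1D search)
  set.seed(4)
  e_rand <- scattering_profile(q, I * (1 + 0.1 * stats::rnorm(length(q))),
                               sigma = 0.03 * I)
  r <- chi_square(m, e_rand)
  direct <- function(mu) sum(((mu * I - e_rand$I) / e_rand$sigma)^2) /
    (length(q) - 1)
  opt <- stats::optimize(direct, r$mu * c(0.5, 2), tol = 1e-14)
  expect_lt(abs(r$chi2 - opt$objective), 1e-9)
  expect_lt(abs(r$mu - opt$minimum), 1e-6)
  expect_error(chi_square(m, scattering_profile(q, I)), "sigma")
})

test_that("chi-square of truth against its own noise is ~1", {
  q <- seq(0.001, 0.3, length.out = 10000)
  I <- 5 * exp(-q^2 * 120)
  truth <- scattering_profile(q, I)
  noisy <- gen_noisy_profile(truth, noise_model(sigma = 0.02, seed = 8))
  r <- chi_square(truth, noisy)
  expect_gt(r$chi2, 0.5)
  expect_lt(r$chi2, 2)
})

test_that("Kratky transforms have the Guinier-curve analytic peak", {
  q <- seq(0.001, 0.3, length.out = 400)
  Rg <- 20; I0 <- 4
  prof <- scattering_profile(q, I0 * exp(-(q * Rg)^2 / 3))
  kt <- kratky_transforms(prof, Rg = Rg, I0 = I0)
  peak <- which.max(kt$norm_kratky$value)
  expect_equal(kt$norm_kratky$qRg[peak], sqrt(3), tolerance = 0.02)
  expect_equal(max(kt$norm_kratky$value), 3 * exp(-1), tolerance = 1e-3)
  expect_lt(kt$norm_kratky$value[1], 1e-3)  # -> 0 at qRg -> 0
  kt10 <- kratky_transforms(scattering_profile(q, 10 * prof$I),
                            Rg = Rg, I0 = 10 * I0)
  expect_equal(kt10$norm_kratky$value, kt$norm_kratky$value)
})

test_that("linear I(0) extrapolation and fold change", {
  q <- seq(0.01, 0.1, length.out = 10)
  lin <- scattering_profile(q, 5 - 2 * q)
  r <- suppressWarnings(extrapolate_I0_linear(lin, c(0, 0.1)))
  expect_equal(r$I0, 5, tolerance = 1e-12)
  r2 <- suppressWarnings(
    extrapolate_I0_linear(lin, c(0, 0.1), I0_reference = 5 / 17.4))
  expect_equal(r2$fold_change, 17.4, tolerance = 1e-9)
  expect_error(extrapolate_I0_linear(lin, c(0, 0.015)), "3 points")
})

test_that("match point extrapolates the zero crossing of I(0) vs density", {
  r <- match_point(c(4, 2, 0), c(0.334, 0.344, 0.354))
  expect_equal(r$rho_match, 0.354, tolerance = 1e-12)
  r2 <- suppressMessages(match_point(c(6, 4), c(0.334, 0.344)))
  expect_equal(r2$rho_match, 0.364, tolerance = 1e-12)
  # contrast-squared synthetic data linearized over a narrow range
  rho_p <- 0.42
  rho <- seq(0.40, 0.41, length.out = 5)
  I0 <- (rho_p - rho)^2
  r3 <- match_point(I0, rho)
  expect_lt(abs(r3$rho_match / rho_p - 1), 0.02)
  expect_warning(match_point(c(1, 3, 2), c(0.33, 0.34, 0.35)),
                 "non-monotonic")
})

test_that("peak lengthscale is 2 pi / q", {
  expect_equal(peak_lengthscale(2 * pi), 1)
  expect_equal(peak_lengthscale(0.2), 31.4159, tolerance = 1e-4)
  expect_error(peak_lengthscale(0), "positive")
})

test_that("profiles round-trip through three-column text", {
  q <- default_q_grid()
  p <- scattering_profile(q, exp(-q^2 * 90), 0.02 * exp(-q^2 * 90))
  f <- tempfile(fileext = ".dat")
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(p2$I, p$I, tolerance = 1e-8)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-8)
})
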