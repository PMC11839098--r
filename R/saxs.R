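## Solution X-ray scattering: theoretical intensities from atomic
## coordinates via the Debye formula, and the standard profile-level
## analyses (Guinier, molecular form factor / Flory exponent, chi-square
## with fitted scale, Kratky transforms, I(0) extrapolation, contrast match
## point, correlation-peak lengthscale).

## 4-Gaussian atomic X-ray form factors in vacuum (Cromer-Mann):
## f(q) = sum_k a_k exp(-b_k (q/4pi)^2) + c
CROMER_MANN <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490)
)

#' Atomic X-ray form factor
#'
#' Tabulated vacuum form factor f(q) for an element (H, C, N, O, P).
#'
#' @param element Element symbol.
#' @param q q values (1/Angstrom).
#' @return f(q), electrons.
#' @export
atomic_form_factor <- function(element, q) {
  cm <- CROMER_MANN[[element]]
  if (is.null(cm)) stop("no form factor tabulated for element ", element)
  s2 <- (q / (4 * pi))^2
  sapply(s2, function(x) sum(cm$a * exp(-cm$b * x))) + cm$c
}

#' Debye-formula scattering intensity of a conformer
#'
#' I(q) = sum_ij f_i(q) f_j(q) sin(q r_ij)/(q r_ij) with tabulated vacuum
#' atomic form factors. Hydrogens (absent from built structures anyway) are
#' excluded by default; no hydration shell or excluded-volume correction is
#' applied, so profiles are self-consistent theoretical curves rather than
#' buffer-subtracted experimental ones.
#'
#' @param conformer A `conformer`, or an n x 3 coordinate matrix of unit
#'   point scatterers.
#' @param q_grid q values (1/Angstrom); see [default_q_grid()].
#' @param include_h Include hydrogens if present (default FALSE).
#' @return A [scattering_profile()] with sigma = 0.
#' @export
debye_intensity <- function(conformer, q_grid = default_q_grid(),
                            include_h = FALSE) {
  if (is.matrix(conformer)) {
    xyz <- conformer
    ff <- matrix(1, nrow(xyz), length(q_grid))
  } else {
    at <- conformer$atoms
    if (!include_h) at <- at[at$element != "H", , drop = FALSE]
    if (nrow(at) == 0) stop("conformer has no atoms to scatter from")
    xyz <- as.matrix(at[, c("x", "y", "z")])
    elements <- unique(at$element)
    ffe <- lapply(elements, atomic_form_factor, q = q_grid)
    names(ffe) <- elements
    ff <- do.call(rbind, ffe[at$element])
  }
  I <- .debye_sum(xyz, ff, q_grid)
  scattering_profile(q_grid, I)
}

#' Guinier fit
#'
#' Linear fit of log I(q) against q^2 over the largest low-q window whose
#' upper edge satisfies q_max * Rg <= `qRg_limit`, found by iterating the
#' fit-window search to self-consistency. Returns Rg = sqrt(-3 * slope) and
#' I0 = exp(intercept) with standard errors propagated from the linear fit.
#'
#' @param profile A [scattering_profile()].
#' @param qRg_limit Guinier validity limit (default 1.3).
#' @param min_points Minimum number of points in the window (default 5).
#' @return List with Rg, I0, their standard errors, the fit window, and the
#'   number of points used.
#' @export
guinier_fit <- function(profile, qRg_limit = 1.3, min_points = 5) {
  q <- profile$q; I <- profile$I
  use <- I > 0 & q > 0
  q <- q[use]; I <- I[use]
  if (length(q) < min_points)
    stop("fewer than ", min_points, " positive-intensity points")
  fit_upto <- function(k) {
    qs <- q[1:k]
    stats::lm(log(I[1:k]) ~ I(qs^2))
  }
  k <- length(q)
  for (iter in 1:3) {
    f <- fit_upto(k)
    sl <- stats::coef(f)[2]
    if (sl >= -1e-12)
      stop("no self-consistent Guinier window (non-decaying profile)")
    Rg <- sqrt(-3 * sl)
    k_new <- max(min_points, sum(q * Rg <= qRg_limit))
    if (k_new == k) break
    k <- k_new
  }
  f <- fit_upto(k)
  sm <- summary(f)$coefficients
  sl <- sm[2, 1]
  if (sl >= 0) stop("no self-consistent Guinier window")
  Rg <- sqrt(-3 * sl)
  Rg_se <- 3 * sm[2, 2] / (2 * Rg)
  I0 <- exp(sm[1, 1])
  if (q[k] * Rg > qRg_limit * 1.5)
    warning("Guinier window exceeds qRg limit; profile may be too coarse")
  list(Rg = Rg, I0 = I0, Rg_se = Rg_se, I0_se = I0 * sm[1, 2],
       q_window = c(q[1], q[k]), n_points = k)
}

#' Excluded-volume polymer form factor (molecular form factor)
#'
#' Closed-form form factor of a swollen polymer chain with Flory exponent
#' nu and radius of gyration Rg (lower-incomplete-gamma form):
#' with U = (2nu+1)(2nu+2) (qRg)^2 / 6,
#' P(q) = gammainc(1/(2nu), U) / (nu U^(1/(2nu)))
#'      - gammainc(1/nu, U) / (nu U^(1/nu)).
#' Reduces to the Debye function at nu = 1/2; the high-q decay tends to
#' q^(-1/nu).
#'
#' @param q q values (1/Angstrom).
#' @param nu Flory exponent.
#' @param Rg Radius of gyration (Angstrom).
#' @param I0 Forward intensity scale.
#' @return I(q) = I0 * P(q).
#' @export
mff_intensity <- function(q, nu, Rg, I0 = 1) {
  U <- (2 * nu + 1) * (2 * nu + 2) * (q * Rg)^2 / 6
  low_inc_gamma <- function(a, x) stats::pgamma(x, a) * gamma(a)
  P <- ifelse(U < 1e-10, 1,
              low_inc_gamma(1 / (2 * nu), U) / (nu * U^(1 / (2 * nu))) -
              low_inc_gamma(1 / nu, U) / (nu * U^(1 / nu)))
  I0 * P
}

#' Fit the molecular form factor to a scattering profile
#'
#' Nonlinear least squares of [mff_intensity()] (parameters nu, Rg, I0)
#' against the profile, weighted by 1/sigma^2 where sigma > 0. Initial
#' values come from a Guinier fit and nu = 0.55.
#'
#' @param profile A [scattering_profile()].
#' @param nu_start Starting Flory exponent.
#' @return List with nu, Rg, I0, standard errors, and reduced chi2 of the
#'   fit (1 where sigma is all zero, in which case chi2 is the residual
#'   sum of squares).
#' @export
mff_fit <- function(profile, nu_start = 0.55) {
  q <- profile$q; I <- profile$I; s <- profile$sigma
  g <- tryCatch(guinier_fit(profile), error = function(e) NULL)
  Rg0 <- if (is.null(g)) 1 / max(q) * 3 else g$Rg
  I00 <- if (is.null(g)) max(I) else g$I0
  w <- if (any(s > 0)) 1 / pmax(s, max(s[s > 0]) * 1e-3)^2 else rep(1, length(q))
  fit <- minpack.lm::nlsLM(
    I ~ mff_intensity(q, nu, Rg, I0),
    start = list(nu = nu_start, Rg = Rg0, I0 = I00),
    weights = w,
    lower = c(0.2, 0.1, 0), upper = c(1.2, 1e4, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  res <- stats::resid(fit)
  chi2 <- if (any(s > 0)) sum(w * res^2) / (length(q) - 3) else sum(res^2)
  list(nu = co["nu", 1], Rg = co["Rg", 1], I0 = co["I0", 1],
       nu_se = co["nu", 2], Rg_se = co["Rg", 2], chi2 = chi2,
       converged = fit$convInfo$isConv)
}

#' Reduced chi-square between a model and an experimental profile
#'
#' chi2 = 1/(Q-1) sum_i ((mu I_model(q_i) - I_exp(q_i)) / sigma_i)^2 with
#' the scale factor mu chosen analytically by weighted least squares. The
#' model is linearly interpolated onto the experimental grid if needed.
#'
#' @param model Theoretical [scattering_profile()].
#' @param experiment Experimental [scattering_profile()] with sigma > 0.
#' @return List with chi2, mu and Q (number of points).
#' @export
chi_square <- function(model, experiment) {
  if (any(experiment$sigma <= 0))
    stop("experimental sigma must be positive everywhere")
  if (!isTRUE(all.equal(model$q, experiment$q)))
    model <- interpolate_profile(model, experiment$q)
  w <- 1 / experiment$sigma^2
  mu <- sum(w * model$I * experiment$I) / sum(w * model$I^2)
  if (mu <= 0) stop("fitted scale factor is non-positive")
  Q <- nrow(experiment)
  chi2 <- sum(w * (mu * model$I - experiment$I)^2) / (Q - 1)
  list(chi2 = chi2, mu = mu, Q = Q)
}

#' Kratky and dimensionless Kratky transforms
#'
#' @param profile A [scattering_profile()].
#' @param Rg,I0 Size and forward intensity used for the dimensionless
#'   (normalized) transform; defaults from a Guinier fit.
#' @return List of two data.frames: `kratky` (q, q2I) and `norm_kratky`
#'   (qRg, value = (qRg)^2 I / I0).
#' @export
kratky_transforms <- function(profile, Rg = NULL, I0 = NULL) {
  if (is.null(Rg) || is.null(I0)) {
    g <- guinier_fit(profile)
    if (is.null(Rg)) Rg <- g$Rg
    if (is.null(I0)) I0 <- g$I0
  }
  if (Rg <= 0 || I0 <= 0) stop("Rg and I0 must be positive")
  list(
    kratky = data.frame(q = profile$q, q2I = profile$q^2 * profile$I),
    norm_kratky = data.frame(qRg = profile$q * Rg,
                             value = (profile$q * Rg)^2 * profile$I / I0))
}

#' Linear low-q extrapolation of I(0)
#'
#' Straight-line fit of I against q over a low-q window, evaluated at q = 0.
#' Used where a Guinier analysis is not meaningful (associating samples);
#' optionally reports the fold change against a reference I(0).
#'
#' @param profile A [scattering_profile()].
#' @param q_window Numeric c(qmin, qmax) selecting the fit window.
#' @param I0_reference Optional reference I(0) for the fold change.
#' @return List with I0, its standard error, n_points, and fold_change
#'   (NULL without a reference).
#' @export
extrapolate_I0_linear <- function(profile, q_window, I0_reference = NULL) {
  sel <- profile$q >= q_window[1] & profile$q <= q_window[2]
  if (sum(sel) < 3) stop("I(0) window must contain at least 3 points")
  q <- profile$q[sel]; I <- profile$I[sel]
  f <- stats::lm(I ~ q)
  I0 <- unname(stats::coef(f)[1])
  if (I0 < 0) warning("extrapolated I(0) is negative")
  fold <- if (!is.null(I0_reference)) I0 / I0_reference else NULL
  list(I0 = I0, I0_se = summary(f)$coefficients[1, 2],
       n_points = sum(sel), fold_change = fold)
}

#' Contrast match point from an I(0) vs buffer-density series
#'
#' Linear fit of I(0) against buffer electron density, extrapolated to the
#' density at which I(0) = 0 (the match point of the contrast-varied
#' component). The density is converted to percent w/v sucrose through a
#' linear density map rho(c) = rho0 + k c.
#'
#' @param I0_values I(0) values (intensity units).
#' @param buffer_densities Buffer electron densities (e/Angstrom^3), same
#'   length.
#' @param rho0 Buffer electron density at zero sucrose (e/Angstrom^3).
#' @param k Density increment per percent w/v sucrose (e/Angstrom^3 per %).
#' @return List with rho_match, sucrose_wv (percent w/v) and the fitted
#'   slope/intercept; warns when the trend is non-monotonic.
#' @export
match_point <- function(I0_values, buffer_densities,
                        rho0 = 0.3344, k = 6.4e-4) {
  if (length(I0_values) < 2 || length(I0_values) != length(buffer_densities))
    stop("need >= 2 paired (I0, density) values")
  if (length(I0_values) < 3)
    message("only 2 points: exact line extension, no fit uncertainty")
  d <- diff(I0_values[order(buffer_densities)])
  if (any(d > 0) && any(d < 0))
    warning("I(0) trend is non-monotonic in buffer density")
  f <- stats::lm(I0_values ~ buffer_densities)
  co <- stats::coef(f)
  if (abs(co[2]) < 1e-15) stop("flat I(0) trend: no zero crossing")
  rho_match <- unname(-co[1] / co[2])
  list(rho_match = rho_match, sucrose_wv = (rho_match - rho0) / k,
       intercept = unname(co[1]), slope = unname(co[2]))
}

#' Real-space lengthscale of a scattering correlation peak
#'
#' d = 2 pi / q_peak.
#'
#' @param q_peak Peak position (1/Angstrom), positive.
#' @return Lengthscale in Angstrom.
#' @export
peak_lengthscale <- function(q_peak) {
  if (any(q_peak <= 0)) stop("q_peak must be positive")
  2 * pi / q_peak
}
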