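#' Scattering profile container
#'
#' A small-angle scattering profile: a strictly increasing, nonnegative
#' momentum-transfer grid `q` (1/Angstrom) with intensities `I` (arbitrary
#' units) and per-point uncertainties `sigma`.
#'
#' @param q Numeric vector of q values (1/Angstrom), strictly increasing,
#'   nonnegative.
#' @param I Intensities, same length as `q`.
#' @param sigma Uncertainties, same length as `q`; may be zero for
#'   noise-free theoretical curves (chi-square evaluation then refuses them).
#' @return An object of class `scattering_profile` (a data.frame with
#'   columns q, I, sigma).
#' @export
scattering_profile <- function(q, I, sigma = rep(0, length(q))) {
  q <- as.numeric(q); I <- as.numeric(I); sigma <- as.numeric(sigma)
  if (length(q) != length(I) || length(q) != length(sigma))
    stop("q, I and sigma must have equal length")
  if (any(q < 0)) stop("q must be nonnegative")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  structure(data.frame(q = q, I = I, sigma = sigma),
            class = c("scattering_profile", "data.frame"))
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("Scattering profile: %d points, q in [%.4g, %.4g] 1/A\n",
              nrow(x), min(x$q), max(x$q)))
  invisible(x)
}

#' Default q grid for theoretical profiles
#'
#' 61 points from just above zero to 0.3 1/Angstrom, the grid used for all
#' theoretical curves in this package.
#'
#' @param qmax Maximum q (1/Angstrom).
#' @param n Number of points.
#' @return Numeric q grid starting at qmax/n.
#' @export
default_q_grid <- function(qmax = 0.3, n = 61) {
  seq(qmax / n, qmax, length.out = n)
}

#' Read a three-column scattering profile from whitespace text
#'
#' @param path File with columns q, I, sigma (sigma optional); `#` comments
#'   are skipped.
#' @return A [scattering_profile()].
#' @export
read_profile <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("profile file needs at least two columns (q, I)")
  sigma <- if (ncol(tab) >= 3) tab[[3]] else rep(0, nrow(tab))
  scattering_profile(tab[[1]], tab[[2]], sigma)
}

#' Write a scattering profile as three-column whitespace text
#'
#' @param profile A [scattering_profile()].
#' @param path Output file.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(format(as.data.frame(profile), digits = 10),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Interpolate a profile onto a new q grid
#'
#' Linear interpolation of I (and sigma) onto `q_new`; q values outside the
#' original range are refused.
#'
#' @param profile A [scattering_profile()].
#' @param q_new Target grid.
#' @return A [scattering_profile()] on `q_new`.
#' @export
interpolate_profile <- function(profile, q_new) {
  if (min(q_new) < min(profile$q) - 1e-12 ||
      max(q_new) > max(profile$q) + 1e-12)
    stop("target grid extends beyond the measured q range")
  I <- stats::approx(profile$q, profile$I, xout = q_new, rule = 2)$y
  s <- stats::approx(profile$q, profile$sigma, xout = q_new, rule = 2)$y
  scattering_profile(q_new, I, s)
}
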