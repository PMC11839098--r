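## Dinucleotide suite library: the discrete torsion-angle alphabet from
## which single-stranded RNA chains are assembled. A suite spans one
## dinucleotide step and is parameterized by the backbone torsions
## {alpha, beta, gamma, epsilon, zeta}, the sugar puckers {delta(i-1),
## delta} and the glycosidic angles {chi(i-1), chi}.

SUITE_ANGLE_COLS <- c("delta_prev", "epsilon", "zeta", "alpha", "beta",
                      "gamma", "delta", "chi_prev", "chi")
N_SUITES <- 34L

#' Load a dinucleotide suite library
#'
#' Reads and validates a 34-suite torsion-angle table. The default library
#' shipped with the package contains synthetic representative per-suite
#' means spanning the standard suite classes; it is intended to be replaced
#' with a user-supplied table when exact published consensus values are
#' required.
#'
#' @param source `"default"` for the shipped table, or a path to a CSV with
#'   columns `name, delta_prev, epsilon, zeta, alpha, beta, gamma, delta,
#'   chi_prev, chi` (angles in degrees).
#' @return A `suite_library` object (data.frame with a `provenance`
#'   attribute).
#' @export
#' @examples
#' lib <- load_suite_library()
#' nrow(lib)  # 34
load_suite_library <- function(source = "default") {
  if (identical(source, "default")) {
    path <- system.file("extdata", "suites_default_synthetic.csv",
                        package = "condensaxs")
    provenance <- "shipped synthetic representative suite means"
  } else {
    path <- source
    provenance <- paste("user table:", source)
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_suite_library(tab)
  structure(tab, class = c("suite_library", "data.frame"),
            provenance = provenance)
}

validate_suite_library <- function(tab) {
  if (!identical(names(tab), c("name", SUITE_ANGLE_COLS)))
    stop("suite table must have columns: name, ",
         paste(SUITE_ANGLE_COLS, collapse = ", "))
  if (nrow(tab) != N_SUITES)
    stop(sprintf("suite library must contain exactly %d suites, got %d",
                 N_SUITES, nrow(tab)))
  if (anyDuplicated(tab$name))
    stop("duplicate suite names: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  ang <- as.matrix(tab[SUITE_ANGLE_COLS])
  if (!all(is.finite(ang)))
    stop("non-numeric angle entries in suite table")
  if (any(ang <= -180 | ang > 180))
    stop("suite angles must lie in (-180, 180]")
  invisible(tab)
}

#' Write a suite library to CSV
#'
#' @param library A `suite_library`.
#' @param path Output CSV path.
#' @export
write_suite_library <- function(library, path) {
  utils::write.csv(as.data.frame(library), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.suite_library <- function(x, ...) {
  cat(sprintf("Suite library: %d dinucleotide suites (%s)\n", nrow(x),
              attr(x, "provenance")))
  invisible(x)
}

#' Reduced suite library
#'
#' Subsets a full library to the named suites. Full libraries carry all 34
#' suites; reduced libraries are used in synthetic-truth studies where the
#' ground-truth weights live on a few suites.
#'
#' @param library A `suite_library`.
#' @param names Suite names to keep (>= 2).
#' @return A `suite_library` restricted to those suites.
#' @export
suite_subset <- function(library, names) {
  idx <- match(names, library$name)
  if (anyNA(idx)) stop("unknown suite name(s): ",
                       paste(names[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) stop("a library needs at least 2 suites")
  structure(as.data.frame(library)[idx, , drop = FALSE],
            class = c("suite_library", "data.frame"),
            provenance = paste0(attr(library, "provenance"),
                                " (subset of ", length(idx), ")"))
}

#' Uniform suite weights
#'
#' Starting weights for pool generation: equal probability on every suite in
#' the library.
#'
#' @param library A `suite_library` (or an integer number of suites).
#' @return A named probability vector summing to 1.
#' @export
uniform_suite_weights <- function(library) {
  n <- if (is.numeric(library)) as.integer(library) else nrow(library)
  nm <- if (is.numeric(library)) paste0("s", seq_len(n)) else library$name
  stats::setNames(rep(1 / n, n), nm)
}

check_weights <- function(w, n = NULL, tol = 1e-9) {
  if (!is.null(n) && length(w) != n)
    stop(sprintf("weight vector must have length %d", n))
  if (any(w < 0)) stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > tol) stop("weights must sum to 1")
  invisible(w)
}
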