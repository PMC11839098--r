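## Ensemble optimization: genetic-algorithm selection of sub-ensembles
## whose averaged theoretical scattering fits a target profile, iterative
## reweighting of the dinucleotide suite weights, and Jensen-Shannon
## convergence diagnostics.

#' Genetic-algorithm configuration
#'
#' Defaults mirror the reference selection protocol: 1000 generations with
#' 50 ensembles of 20 curves and 10 mutations per ensemble, over 100
#' independent restarts; repeat selections allowed, no intensity offsets.
#' Desk-scale analyses pass smaller values.
#'
#' @param n_generations GA generations per restart.
#' @param n_ensembles Population size N.
#' @param curves_per_ensemble Members per ensemble M.
#' @param mutations_per_ensemble Single-member resamples applied to each
#'   offspring.
#' @param inner_iterations Independent restarts; the best population is
#'   retained.
#' @param allow_repeats Allow a conformer to appear multiple times in one
#'   ensemble.
#' @param allow_offsets Additive intensity offsets (not implemented; must
#'   be FALSE).
#' @param seed RNG seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(n_generations = 1000, n_ensembles = 50,
                      curves_per_ensemble = 20, mutations_per_ensemble = 10,
                      inner_iterations = 100, allow_repeats = TRUE,
                      allow_offsets = FALSE, seed = 1) {
  if (allow_offsets) stop("intensity offsets are not supported")
  structure(list(n_generations = n_generations, n_ensembles = n_ensembles,
                 curves_per_ensemble = curves_per_ensemble,
                 mutations_per_ensemble = mutations_per_ensemble,
                 inner_iterations = inner_iterations,
                 allow_repeats = allow_repeats,
                 allow_offsets = allow_offsets, seed = seed),
            class = "ga_config")
}

#' Weighted average of scattering profiles
#'
#' Pointwise I(q) = sum_k a_k I_k(q); weights are normalized to sum 1.
#'
#' @param profiles List of [scattering_profile()]s on a common q grid.
#' @param a Nonnegative weights, one per profile.
#' @return A [scattering_profile()].
#' @export
ensemble_average <- function(profiles, a) {
  if (length(profiles) != length(a))
    stop("one weight per profile required")
  if (any(a < 0)) stop("weights must be nonnegative")
  q <- profiles[[1]]$q
  for (p in profiles)
    if (!isTRUE(all.equal(p$q, q))) stop("profiles must share a q grid")
  a <- a / sum(a)
  I <- Reduce(`+`, Map(function(p, w) w * p$I, profiles, a))
  scattering_profile(q, I)
}

## profile matrix (Q x n_pool) on the target grid
profile_matrix <- function(pool, target) {
  if (is.null(pool$profiles))
    stop("pool has no profiles; call pool_profiles() first")
  sapply(pool$profiles, function(p) {
    if (isTRUE(all.equal(p$q, target$q))) p$I
    else interpolate_profile(p, target$q)$I
  })
}

#' Genetic-algorithm sub-ensemble selection against a target profile
#'
#' Evolves `n_ensembles` ensembles of `curves_per_ensemble` pool members to
#' minimize the reduced chi-square between the ensemble-averaged curve
#' (with analytically fitted scale factor) and the target. Tournament
#' selection (k = 2), single-point crossover of member lists, mutation by
#' uniform member resampling, and single-ensemble elitism; restarts are
#' independent and the best final population is kept.
#'
#' @param pool A `conformer_pool` with profiles (see [pool_profiles()]),
#'   or a list of profiles.
#' @param target Target [scattering_profile()] with sigma > 0.
#' @param cfg A [ga_config()].
#' @return An `ensemble_selection`: members (M x N index matrix), per-
#'   ensemble chi2, chi2_red (their mean), mu of the best ensemble,
#'   per-conformer selection `frequency`, the best ensemble's averaged
#'   `model` profile, and the best-fitness trace of the winning restart.
#' @export
genetic_select <- function(pool, target, cfg = ga_config()) {
  if (any(target$sigma <= 0)) stop("target profile needs positive sigma")
  P <- if (inherits(pool, "conformer_pool")) profile_matrix(pool, target)
       else sapply(pool, function(p) interpolate_profile(p, target$q)$I)
  n_pool <- ncol(P)
  M <- cfg$curves_per_ensemble
  N <- cfg$n_ensembles
  if (!cfg$allow_repeats && n_pool < M)
    stop("pool smaller than ensemble size with repeats disabled")
  w <- 1 / target$sigma^2
  Iexp <- target$I
  Q <- length(Iexp)
  eval_pop <- function(pop) { # pop: M x N matrix of pool indices
    Cnt <- apply(pop, 2, tabulate, nbins = n_pool) / M
    Model <- P %*% Cnt
    mu <- colSums(w * Model * Iexp) / colSums(w * Model^2)
    chi2 <- colSums(w * (sweep(Model, 2, mu, `*`) - Iexp)^2) / (Q - 1)
    list(chi2 = chi2, mu = mu)
  }
  sample_member <- function(k) sample.int(n_pool, k, replace = TRUE)
  set.seed(cfg$seed)
  best_overall <- NULL
  for (restart in seq_len(cfg$inner_iterations)) {
    pop <- matrix(sample_member(M * N), nrow = M)
    ev <- eval_pop(pop)
    trace <- numeric(cfg$n_generations)
    for (gen in seq_len(cfg$n_generations)) {
      elite <- which.min(ev$chi2)
      newpop <- matrix(0L, M, N)
      newpop[, 1] <- pop[, elite]
      for (e in 2:N) {
        t1 <- sample.int(N, 2); t2 <- sample.int(N, 2)
        p1 <- pop[, t1[which.min(ev$chi2[t1])]]
        p2 <- pop[, t2[which.min(ev$chi2[t2])]]
        cut <- sample.int(M - 1, 1)
        child <- c(p1[1:cut], p2[(cut + 1):M])
        nm <- cfg$mutations_per_ensemble
        if (nm > 0) {
          pos <- sample.int(M, min(nm, M))
          child[pos] <- sample_member(length(pos))
        }
        if (!cfg$allow_repeats) {
          while (anyDuplicated(child)) {
            dup <- which(duplicated(child))
            child[dup] <- sample_member(length(dup))
          }
        }
        newpop[, e] <- child
      }
      pop <- newpop
      ev <- eval_pop(pop)
      trace[gen] <- min(ev$chi2)
    }
    cand <- list(pop = pop, ev = ev, trace = trace,
                 best = min(ev$chi2))
    if (is.null(best_overall) || cand$best < best_overall$best)
      best_overall <- cand
  }
  pop <- best_overall$pop; ev <- best_overall$ev
  freq <- tabulate(pop, nbins = n_pool) / length(pop)
  b <- which.min(ev$chi2)
  counts <- tabulate(pop[, b], nbins = n_pool)
  model_I <- as.numeric(P %*% (counts / M)) * ev$mu[b]
  structure(list(members = pop, chi2 = ev$chi2,
                 chi2_red = mean(ev$chi2),
                 best = b, best_chi2 = ev$chi2[b], mu = ev$mu[b],
                 frequency = freq,
                 model = scattering_profile(target$q, model_I),
                 trace = best_overall$trace, cfg = cfg),
            class = "ensemble_selection")
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat(sprintf(
    "Ensemble selection: %d ensembles x %d curves; chi2_red = %.4g (best %.4g)\n",
    ncol(x$members), nrow(x$members), x$chi2_red, x$best_chi2))
  invisible(x)
}

## -- suite reweighting -----------------------------------------------------

#' Suite-frequency discrepancy of a reweighting
#'
#' chi_h^2 = sum_m (h_ens,m - h_pool,m r_m / sum_n h_pool,n r_n)^2 with
#' r = w_new / w_old: the squared distance between the observed ensemble
#' suite frequencies and those the pool would produce under the new
#' weights.
#'
#' @param w_new,w_old Suite weight vectors.
#' @param h_ens,h_pool Observed ensemble and pool suite frequencies.
#' @return chi_h^2 (scalar).
#' @export
chi_h_square <- function(w_new, w_old, h_ens, h_pool) {
  r <- ifelse(w_old > 0, w_new / w_old, 0)
  pred <- h_pool * r
  s <- sum(pred)
  if (s <= 0) return(sum(h_ens^2))
  sum((h_ens - pred / s)^2)
}

#' Reweight suite probabilities toward observed ensemble frequencies
#'
#' Minimizes [chi_h_square()] over the probability simplex. The
#' multiplicative update w_new proportional to w_old * h_ens / h_pool
#' attains chi_h^2 = 0 whenever h_pool > 0 wherever h_ens > 0; an optional
#' Nelder-Mead polish on a softmax parameterization verifies the optimum
#' numerically.
#'
#' @param h_ens Observed suite frequencies in the selected ensembles.
#' @param h_pool Suite frequencies in the full pool (positive wherever
#'   h_ens is).
#' @param w_old Current suite weights.
#' @param floor Minimum weight applied after the update (then
#'   renormalized); keeps suites resamplable across iterations. Default 0
#'   (exact fixed point at h_ens = h_pool).
#' @param polish Run the numerical minimizer from the closed-form start.
#' @return List with `w` (new weights), `chi_h2`, and `chi_h2_old` (the
#'   objective at w_old).
#' @export
reweight_suites <- function(h_ens, h_pool, w_old, floor = 0,
                            polish = FALSE) {
  k <- length(w_old)
  if (length(h_ens) != k || length(h_pool) != k)
    stop("frequency vectors must match the weight length")
  if (any(h_ens > 0 & h_pool <= 0))
    stop("h_pool must be positive wherever h_ens is positive")
  ratio <- ifelse(h_pool > 0, h_ens / h_pool, 1)
  w <- w_old * ratio
  if (sum(w) <= 0) w <- w_old
  w <- w / sum(w)
  if (floor > 0) {
    w <- pmax(w, floor)
    w <- w / sum(w)
  }
  if (polish) {
    obj <- function(theta) {
      wn <- exp(theta - max(theta)); wn <- wn / sum(wn)
      chi_h_square(wn, w_old, h_ens, h_pool)
    }
    op <- stats::optim(log(pmax(w, 1e-12)), obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    wp <- exp(op$par - max(op$par)); wp <- wp / sum(wp)
    if (chi_h_square(wp, w_old, h_ens, h_pool) <
        chi_h_square(w, w_old, h_ens, h_pool)) w <- wp
  }
  names(w) <- names(w_old)
  list(w = w, chi_h2 = chi_h_square(w, w_old, h_ens, h_pool),
       chi_h2_old = chi_h_square(w_old, w_old, h_ens, h_pool))
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' JSD = S((W1 + W2)/2) - S(W1)/2 - S(W2)/2 with S the Shannon entropy in
#' nats (0 ln 0 := 0). Bounded by ln 2.
#'
#' @param W1,W2 Probability vectors of equal length (sums within 1e-6
#'   of 1).
#' @return Divergence in nats.
#' @export
jsd <- function(W1, W2) {
  if (length(W1) != length(W2)) stop("distributions must have equal length")
  if (abs(sum(W1) - 1) > 1e-6 || abs(sum(W2) - 1) > 1e-6)
    stop("inputs must be normalized distributions")
  S <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  S((W1 + W2) / 2) - S(W1) / 2 - S(W2) / 2
}

## suite frequencies of the selected ensembles, weighted by selection
## multiplicity
selection_suite_freq <- function(pool, selection, library) {
  counts <- stats::setNames(rep(0, nrow(library)), library$name)
  tab <- tabulate(selection$members, nbins = length(pool$conformers))
  for (i in which(tab > 0)) {
    a <- pool$conformers[[i]]$suite_assignment
    t2 <- table(factor(a, levels = library$name))
    counts <- counts + tab[i] * as.numeric(t2)
  }
  counts / sum(counts)
}

#' Iterative ensemble optimization with suite reweighting
#'
#' The full dilute-phase loop: sample a conformer pool from the current
#' suite weights, compute Debye profiles, select scattering-consistent
#' sub-ensembles with the genetic algorithm, reweight the suite
#' probabilities toward the selected ensembles' suite frequencies, and
#' repeat until the Jensen-Shannon divergence between consecutive weight
#' vectors drops below `jsd_tol` or `n_outer` iterations are reached.
#'
#' @param sequence Nucleotide string.
#' @param target Target [scattering_profile()] with sigma > 0.
#' @param library A `suite_library` (any size >= 2; reduced libraries are
#'   supported for synthetic-truth studies).
#' @param cfg A [ga_config()].
#' @param n_outer Maximum outer iterations (default 10).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param pool_size Conformers sampled per iteration (default 2000).
#' @param jsd_tol Early-stopping threshold in nats (default 0.01).
#' @param weight_floor Weight floor passed to [reweight_suites()].
#' @param clash_cutoff Steric cutoff forwarded to [sample_pool()]; NULL
#'   disables rejection (useful on reduced libraries, where the steric
#'   filter badly distorts small suite alphabets).
#' @param w0 Starting weights (default uniform).
#' @return An `eom_fit`: final pool and selection, and a trace with
#'   per-iteration chi2_red, JSD and the weight history.
#' @export
iterate_eom <- function(sequence, target, library = load_suite_library(),
                        cfg = ga_config(), n_outer = 10, seed = 1,
                        pool_size = 2000, jsd_tol = 0.01,
                        weight_floor = 1e-4, clash_cutoff = 2.0,
                        w0 = NULL) {
  w <- if (is.null(w0)) uniform_suite_weights(library) else w0
  check_weights(w, nrow(library))
  chi2_trace <- numeric(0); jsd_trace <- numeric(0)
  w_hist <- list(w)
  pool <- NULL; sel <- NULL
  for (it in seq_len(n_outer)) {
    it_seed <- (seed * 1000L + it) %% .Machine$integer.max
    pool <- sample_pool(sequence, w, n_conformers = pool_size,
                        seed = it_seed, library = library,
                        clash_cutoff = clash_cutoff)
    pool <- pool_profiles(pool, q_grid = target$q)
    cfg_it <- cfg; cfg_it$seed <- it_seed + 1L
    sel <- genetic_select(pool, target, cfg_it)
    pool$selection_weights <- sel$frequency
    chi2_trace <- c(chi2_trace, sel$chi2_red)
    if (it == n_outer) break
    h_ens <- selection_suite_freq(pool, sel, library)
    rw <- reweight_suites(h_ens, pool$h_pool, w, floor = weight_floor)
    j <- jsd(w, rw$w)
    jsd_trace <- c(jsd_trace, j)
    w <- rw$w
    w_hist[[length(w_hist) + 1]] <- w
    if (j < jsd_tol) break
  }
  structure(list(pool = pool, selection = sel, weights = w,
                 trace = list(chi2_red = chi2_trace, jsd = jsd_trace,
                              weights = w_hist),
                 sequence = sequence, cfg = cfg, seed = seed),
            class = "eom_fit")
}

#' @export
print.eom_fit <- function(x, ...) {
  cat(sprintf("Ensemble-optimization fit: %s, %d outer iteration(s)\n",
              x$sequence, length(x$trace$chi2_red)))
  cat(sprintf("  final chi2_red = %.4g; final JSD = %s nats\n",
              utils::tail(x$trace$chi2_red, 1),
              if (length(x$trace$jsd))
                sprintf("%.4g", utils::tail(x$trace$jsd, 1)) else "NA"))
  invisible(x)
}

#' @export
summary.eom_fit <- function(object, ...) {
  w <- sort(object$weights, decreasing = TRUE)
  cat("Iterative ensemble optimization\n")
  cat(sprintf("  sequence: %s\n  iterations: %d\n", object$sequence,
              length(object$trace$chi2_red)))
  cat(sprintf("  chi2_red trace: %s\n",
              paste(sprintf("%.3g", object$trace$chi2_red),
                    collapse = " -> ")))
  if (length(object$trace$jsd))
    cat(sprintf("  JSD trace: %s\n",
                paste(sprintf("%.3g", object$trace$jsd),
                      collapse = " -> ")))
  cat("  top suite weights:\n")
  print(round(utils::head(w, 5), 4))
  invisible(object)
}

#' @export
coef.eom_fit <- function(object, ...) object$weights

#' @export
plot.eom_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$trace$chi2_red), x$trace$chi2_red,
                 type = "b", xlab = "outer iteration",
                 ylab = expression(chi[red]^2), main = "fit quality", ...)
  if (length(x$trace$jsd))
    graphics::plot(seq_along(x$trace$jsd), x$trace$jsd, type = "b",
                   xlab = "outer iteration", ylab = "JSD (nats)",
                   main = "weight convergence", ...)
  invisible(x)
}
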