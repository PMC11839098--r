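## End-to-end orchestration: a dilute-phase ensemble-optimization arm and
## a condensed-phase simulation arm, each run from a single seeded config
## and emitting a structured report (optionally written to disk as
## CSV/JSON).

#' Pipeline run configuration
#'
#' @param arm `"eom"`, `"simulate"` or `"both"`.
#' @param sequence RNA sequence (homopolymer string, e.g. `strrep("U", 30)`).
#' @param salt Monovalent salt (mol/L).
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it.
#' @param target Target scattering profile for the eom arm: a
#'   [scattering_profile()] or a path to a 3-column text file.
#' @param eom List of overrides for the eom arm (pool_size, n_outer,
#'   ga = [ga_config()] arguments).
#' @param sim List of overrides for the simulation arm (n_rna, n_peptide,
#'   n_steps, box, rna_base).
#' @param out_dir Optional output directory for report files.
#' @return A `run_config`.
#' @export
run_config <- function(arm = c("eom", "simulate", "both"),
                       sequence = strrep("U", 30), salt = 0.15, seed = 1,
                       target = NULL, eom = list(), sim = list(),
                       out_dir = NULL) {
  arm <- match.arg(arm)
  if (arm %in% c("eom", "both") && is.null(target))
    stop("eom arm requires a target profile")
  structure(list(arm = arm, sequence = sequence, salt = salt, seed = seed,
                 target = target, eom = eom, sim = sim,
                 out_dir = out_dir),
            class = "run_config")
}

resolve_target <- function(target) {
  if (inherits(target, "scattering_profile")) target
  else read_profile(target)
}

write_report_files <- function(report, out_dir, prefix) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$summary,
                       file.path(out_dir, paste0(prefix, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(report$tables)) {
    utils::write.csv(report$tables[[nm]],
                     file.path(out_dir, paste0(prefix, "_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' Run the dilute-phase ensemble-optimization arm
#'
#' sample pool -> Debye profiles -> genetic selection -> suite reweighting
#' (iterated), followed by ensemble-weighted structural descriptors:
#' orientation correlation function, correlation length, base-stacking
#' percentage, plus Guinier and molecular-form-factor analyses of the
#' target.
#'
#' @param cfg A [run_config()] with `arm = "eom"` (or "both").
#' @return Report list: `fit` (the `eom_fit`), `summary` (named scalars),
#'   `tables` (data.frames: traces, weighted OCF).
#' @export
run_eom_arm <- function(cfg) {
  target <- resolve_target(cfg$target)
  e <- cfg$eom
  ga_args <- e$ga %||% list()
  ga_args$seed <- cfg$seed
  ga <- do.call(ga_config, ga_args)
  library <- e$library %||% load_suite_library()
  clash <- if ("clash_cutoff" %in% names(e)) e$clash_cutoff else 2.0
  fit <- iterate_eom(cfg$sequence, target, library = library, cfg = ga,
                     n_outer = e$n_outer %||% 10, seed = cfg$seed,
                     pool_size = e$pool_size %||% 2000,
                     clash_cutoff = clash)
  pool <- fit$pool
  w <- pool$selection_weights
  ocfs <- lapply(pool$conformers, ocf)
  nsep <- min(vapply(ocfs, function(o) length(o$ocf), 0L))
  ocf_mat <- t(vapply(ocfs, function(o) o$ocf[seq_len(nsep)],
                      numeric(nsep)))
  wn <- w / sum(w)
  ocf_w <- colSums(ocf_mat * wn)
  locfs <- vapply(ocfs, locf, 0)
  stack <- vapply(pool$conformers,
                  function(cf) stacking_fraction(cf)$percent_stacked, 0)
  g <- tryCatch(guinier_fit(target), error = function(e) NULL)
  mf <- tryCatch(mff_fit(target), error = function(e) NULL)
  summary <- list(
    sequence = cfg$sequence, seed = cfg$seed,
    chi2_red_final = utils::tail(fit$trace$chi2_red, 1),
    jsd_final = if (length(fit$trace$jsd))
      utils::tail(fit$trace$jsd, 1) else NA,
    locf_weighted = ensemble_weighted_metric(locfs, w)$mean,
    stacking_pct_weighted = ensemble_weighted_metric(stack, w)$mean,
    guinier_Rg = if (is.null(g)) NA else g$Rg,
    mff_nu = if (is.null(mf)) NA else mf$nu)
  tables <- list(
    trace = data.frame(iteration = seq_along(fit$trace$chi2_red),
                       chi2_red = fit$trace$chi2_red,
                       jsd = c(fit$trace$jsd,
                               rep(NA, length(fit$trace$chi2_red) -
                                     length(fit$trace$jsd)))),
    ocf_weighted = data.frame(separation = seq_len(nsep) - 1,
                              ocf = ocf_w))
  report <- list(fit = fit, summary = summary, tables = tables)
  write_report_files(report, cfg$out_dir, "eom")
  report
}

#' Run the condensed-phase simulation arm
#'
#' Coarse-grained Langevin dynamics followed by RNA-chain cluster
#' analytics: cluster count/size series, arrival/departure totals,
#' convex-hull Jaccard indices of the largest tracked cluster, and
#' per-chain shape metrics at the start and end of the run.
#'
#' @param cfg A [run_config()] with `arm = "simulate"` (or "both").
#' @return Report list: `trajectory`, `timeline`, `summary`, `tables`.
#' @export
run_sim_arm <- function(cfg) {
  s <- cfg$sim
  preset <- desk_preset(rna_base = s$rna_base %||%
                          substr(cfg$sequence, 1, 1),
                        c_Na = cfg$salt,
                        n_steps = s$n_steps %||% 20000,
                        seed = cfg$seed,
                        n_rna = s$n_rna %||% 20,
                        n_peptide = s$n_peptide %||% 20,
                        box = s$box %||% 250,
                        beads_per_chain = s$beads_per_chain %||% 30)
  traj <- run_langevin(preset$system, preset$ff, preset$cfg)
  tl <- withCallingHandlers(
    cluster_timeline(traj, cutoff = s$cutoff %||% 7.5, rna_only = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  mig <- migration_events(tl)
  growth <- cluster_growth_series(tl)
  nf <- n_frames(traj)
  rna_rows <- traj$type %in% c("A", "U", "C", "G")
  shape_at <- function(f) {
    xu <- unwrap_frame(frame_coords(traj, f), traj$chain, traj$box,
                       tl$labels[f, ])
    sh <- lapply(unique(traj$chain[rna_rows]), function(ci)
      chain_shape(xu[traj$chain == ci & rna_rows, , drop = FALSE]))
    c(Rg = mean(vapply(sh, `[[`, 0, "Rg")),
      REE = mean(vapply(sh, `[[`, 0, "REE")),
      kappa2 = mean(vapply(sh, `[[`, 0, "kappa2")))
  }
  sh0 <- shape_at(1); sh1 <- shape_at(nf)
  ## hull Jaccard of the largest tracked cluster between two late frames
  jac <- tryCatch({
    sizes <- growth$sizes
    last <- sizes[nf, ]
    big <- as.integer(colnames(sizes)[which.max(last)])
    f1 <- max(1, nf - 2)
    members <- as.integer(colnames(tl$labels))[
      growth$track_labels[nf, ] == big]
    rows <- traj$chain %in% members & rna_rows
    x1 <- unwrap_frame(frame_coords(traj, f1), traj$chain, traj$box,
                       tl$labels[f1, ])[rows, , drop = FALSE]
    x2 <- unwrap_frame(frame_coords(traj, nf), traj$chain, traj$box,
                       tl$labels[nf, ])[rows, , drop = FALSE]
    hull_jaccard(x1, x2, n_samples = 2e4, seed = cfg$seed,
                 align_com = TRUE)$jaccard
  }, error = function(e) NA_real_)
  summary <- list(
    salt = cfg$salt, kappa = attr(traj, "kappa"), seed = cfg$seed,
    n_frames = nf,
    arrivals = mig$arrivals, departures = mig$departures,
    largest_cluster_final = max(tl$sizes[[nf]]),
    n_clusters_final = tl$n_clusters[nf],
    mean_temperature = mean(attr(traj, "temperature")[-1]),
    rna_Rg_start = unname(sh0["Rg"]), rna_Rg_end = unname(sh1["Rg"]),
    rna_REE_end = unname(sh1["REE"]),
    rna_kappa2_end = unname(sh1["kappa2"]),
    hull_jaccard_late = jac)
  tables <- list(
    clusters = data.frame(frame = seq_len(nf),
                          n_clusters = tl$n_clusters,
                          largest = vapply(tl$sizes, max, 0L)),
    events = mig$events)
  report <- list(trajectory = traj, timeline = tl, migration = mig,
                 growth = growth, summary = summary, tables = tables)
  write_report_files(report, cfg$out_dir, "sim")
  report
}

#' Run the configured pipeline arm(s)
#'
#' @param cfg A [run_config()].
#' @return List with `eom` and/or `sim` reports.
#' @export
run_pipeline <- function(cfg) {
  out <- list()
  if (cfg$arm %in% c("eom", "both")) out$eom <- run_eom_arm(cfg)
  if (cfg$arm %in% c("simulate", "both")) out$sim <- run_sim_arm(cfg)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
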