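#' Named simulation scenarios
#'
#' Pre-configured experiments covering the model's characteristic regimes:
#'
#' * `pairwise_same_class`: one obligate lytic and one temperate strain in
#'   a single immunity class.
#' * `pairwise_diff_class`: one obligate lytic and one temperate strain in
#'   different classes.
#' * `temperate_chaos_Nc3`: three classes, one temperate strain each - the
#'   minimal sustained-chaos community.
#' * `lytic_invasion`: the chaotic three-class community with an obligate
#'   lytic strain added to class 1; the matching no-lytic baseline is run
#'   alongside for comparison.
#' * `multistrain_bunching`: three classes, each with one obligate lytic
#'   and three temperate strains (f = 0, 0.1, 0.5, 0.9); the trough
#'   "bunching" regime.
#' * `temperate_Nc6`: six single-strain temperate classes; larger
#'   communities fluctuate less.
#'
#' @param name Scenario name (see above).
#' @param seeds Integer seeds, one run per seed.
#' @param duration Run length in generations.
#' @param params Model parameters.
#' @param settings Solver settings.
#' @param f Lysogeny fraction used for the temperate strains (default 0.3,
#'   a moderate lysogeny propensity).
#' @param equal_lysogens Initialize within-class lysogens equal.
#' @param log10_range Initial-density range (log10).
#' @param compute_lyapunov Attach a largest-Lyapunov estimate to each run
#'   (default: only for scenarios whose point is chaos).
#' @param extensions Optional [extensions()] applied to every run.
#' @param heterogeneity_spread If > 0, per-strain log-normal parameter
#'   jitter with this relative spread (seeded per run).
#' @param heterogeneity_params Which parameters the jitter touches. Within
#'   a multi-strain class the lysogen equations of all strains differ only
#'   through `alpha - gamma`, so growth-rate jitter there causes plain
#'   exponential competitive exclusion among the class's lysogens; jitter
#'   restricted to the phage traits (`b`, `delta`, `k`) probes robustness
#'   of the ecological mechanism instead.
#' @return An object of class `"scenario_spec"`.
#' @export
#' @examples
#' sc <- scenario("temperate_chaos_Nc3", seeds = 1:2, duration = 300)
#' sc$config
scenario <- function(name = c("pairwise_same_class", "pairwise_diff_class",
                              "temperate_chaos_Nc3", "lytic_invasion",
                              "multistrain_bunching", "temperate_Nc6"),
                     seeds = NULL, duration = NULL,
                     params = default_parameters(),
                     settings = solver_settings(),
                     f = 0.3, equal_lysogens = FALSE,
                     log10_range = c(6, 9),
                     compute_lyapunov = NULL,
                     extensions = NULL,
                     heterogeneity_spread = 0,
                     heterogeneity_params = c("alpha", "gamma", "delta",
                                              "k", "b")) {
  name <- match.arg(name)
  if (startsWith(name, "pairwise") && missing(settings)) {
    # one- and two-class competitions leave the loser collapsing and, for a
    # single class, the lysogens growing without bound: stop the solver once
    # the outcome is decided rather than integrating absurd magnitudes
    settings <- solver_settings(stop_below = 1e-40, stop_above = 1e30)
  }
  classes <- switch(name,
    pairwise_same_class = list(c(0, f)),
    pairwise_diff_class = list(0, f),
    temperate_chaos_Nc3 = rep(list(f), 3),
    lytic_invasion = c(list(c(0, f)), rep(list(f), 2)),
    multistrain_bunching = rep(list(c(0, 0.1, 0.5, 0.9)), 3),
    temperate_Nc6 = rep(list(f), 6))
  baseline <- if (name == "lytic_invasion") rep(list(f), 3) else NULL
  if (is.null(seeds))
    seeds <- switch(name,
                    pairwise_same_class = 1:10, pairwise_diff_class = 1:10,
                    temperate_chaos_Nc3 = 1:5, lytic_invasion = 1:3,
                    multistrain_bunching = 1:3, temperate_Nc6 = 1:3)
  if (is.null(duration))
    duration <- if (name == "multistrain_bunching") 2500 else 2000
  if (is.null(compute_lyapunov))
    compute_lyapunov <- name %in% c("temperate_chaos_Nc3",
                                    "multistrain_bunching", "temperate_Nc6")
  structure(list(name = name,
                 config = community_config(classes),
                 baseline_config = if (!is.null(baseline))
                   community_config(baseline),
                 params = params, settings = settings, seeds = seeds,
                 duration = duration, equal_lysogens = equal_lysogens,
                 log10_range = log10_range,
                 compute_lyapunov = compute_lyapunov,
                 extensions = normalize_extensions(extensions),
                 heterogeneity_spread = heterogeneity_spread,
                 heterogeneity_params = heterogeneity_params),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d seed(s) x %g generations\n",
              x$name, length(x$seeds), x$duration))
  print(x$config)
  invisible(x)
}

run_one <- function(config, spec, seed) {
  cfg <- config
  if (spec$heterogeneity_spread > 0) {
    ov <- jitter_parameters(spec$params, cfg, spec$heterogeneity_spread,
                            seed = seed + 7919L,
                            which = spec$heterogeneity_params)
    cfg <- community_config(cfg$classes, overrides = ov)
  }
  init <- sample_initial_state(cfg, spec$log10_range, seed = seed,
                               equal_lysogens = spec$equal_lysogens)
  extra <- if (spec$extensions$sensitive || spec$extensions$double_lysogens ||
               spec$extensions$tau > 0)
    quasi_equilibrium_extra(init, cfg, spec$params, spec$extensions,
                            S = if (spec$extensions$sensitive)
                              mean(init$P) * 1e-3 else 0)
  traj <- simulate_community(cfg, spec$params, init, spec$duration,
                   settings = spec$settings, extensions = spec$extensions,
                   extra = extra, seed = seed)
  lyap <- NULL
  if (spec$compute_lyapunov) {
    lyap <- lyapunov_exponent(cfg, spec$params, init,
                              settings = spec$settings,
                              horizon = min(500, spec$duration / 2),
                              transient = min(200, spec$duration / 5),
                              extensions = spec$extensions, extra = extra,
                              seed = seed)
  }
  stats <- summarize_trajectory(traj, lyapunov = lyap)
  stats <- classify_outcome(stats, traj)
  list(trajectory = traj, stats = stats, seed = seed)
}

#' Run a scenario over its seed list
#'
#' Runs [simulate_community()] and [summarize_trajectory()] once per seed (twice per
#' seed for `lytic_invasion`, which also runs the no-lytic baseline), and
#' collects an ensemble table with one row per strain per run.
#'
#' @param spec A [scenario()] specification.
#' @param verbose Print one progress line per run.
#' @return An object of class `"scenario_result"`: list with `spec`,
#'   `runs` (per-seed list of `trajectory`, `stats`; for `lytic_invasion`
#'   also `baseline`), and `ensemble` (data frame: `scenario`, `arm`,
#'   `seed`, `class`, `f`, `mean_P`, `min_P`, `max_P`, `mean_L`, `min_PL`,
#'   `extinct`, `lyapunov`, `outcome`).
#' @export
run_scenario <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  runs <- list()
  rows <- list()
  for (seed in spec$seeds) {
    one <- run_one(spec$config, spec, seed)
    entry <- list(trajectory = one$trajectory, stats = one$stats,
                  seed = seed)
    rows[[length(rows) + 1]] <- ensemble_rows(spec, "main", one)
    if (!is.null(spec$baseline_config)) {
      base <- run_one(spec$baseline_config, spec, seed)
      entry$baseline <- base
      rows[[length(rows) + 1]] <- ensemble_rows(spec, "baseline", base)
    }
    runs[[as.character(seed)]] <- entry
    if (verbose)
      message(sprintf("[%s] seed %d: %s", spec$name, seed,
                      one$stats$outcome))
  }
  structure(list(spec = spec, runs = runs,
                 ensemble = do.call(rbind, rows)),
            class = "scenario_result")
}

ensemble_rows <- function(spec, arm, one) {
  st <- one$stats$strains
  lam <- if (!is.null(one$stats$lyapunov))
    one$stats$lyapunov$lambda else NA_real_
  data.frame(scenario = spec$name, arm = arm, seed = one$seed,
             class = st$class, f = st$f, mean_P = st$mean_P,
             min_P = st$min_P, max_P = st$max_P, mean_L = st$mean_L,
             min_PL = st$min_PL, extinct = st$extinct,
             lyapunov = lam, outcome = one$stats$outcome)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d run(s)\n", x$spec$name, length(x$runs)))
  tab <- table(vapply(x$runs, function(r) r$stats$outcome, character(1)))
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}

# Community used for the class-number sweep: Nc-1 classes with a single
# temperate strain, plus one class holding an obligate lytic and a
# temperate strain.
nc_sweep_config <- function(nc, f = 0.3) {
  stopifnot(nc >= 2)
  community_config(c(rep(list(f), nc - 1), list(c(0, f))))
}

#' Sweep over the number of immunity classes
#'
#' For each `Nc` in `nc_range`, runs `reps` seeded simulations of the
#' community of `Nc - 1` single-temperate classes plus one two-strain
#' (obligate lytic + temperate) class, and aggregates per-strain-role
#' time-averaged and minimum phage densities. Runs at `Nc = 2` in which the
#' obligate lytic strain fluctuates below the extinction threshold are
#' excluded from the aggregates (at `Nc = 2` the lytic strain preys on a
#' single lysogen class, so its troughs are deepest; larger communities
#' buffer it).
#'
#' @param nc_range Integer vector of class numbers (each >= 2).
#' @param reps Runs per class number (>= 2).
#' @param duration Generations per run.
#' @param f Temperate lysogeny fraction.
#' @param params,settings As in [simulate_community()].
#' @param seeds Base seeds, recycled per Nc; default `1:reps`.
#' @param verbose Print one line per Nc.
#' @return An object of class `"nc_sweep"`: list with `table` (one row per
#'   strain per kept run: `nc`, `seed`, `role` in
#'   `{"single_temperate", "lytic", "paired_temperate"}`, `class`, `f`,
#'   `mean_P`, `min_P`, `excluded`), `summary` (per `nc` x `role`: mean of
#'   means, median of minima, `n_runs`, `n_excluded`, and the fixed-point
#'   prediction `P_ss`), and `excluded` counts per Nc.
#' @export
run_nc_sweep <- function(nc_range = 2:6, reps = 10, duration = 2000,
                         f = 0.3, params = default_parameters(),
                         settings = solver_settings(stop_below = 1e-40,
                                                    stop_above = 1e30),
                         seeds = NULL, verbose = FALSE) {
  if (reps < 2) stop("'reps' must be >= 2", call. = FALSE)
  if (any(nc_range < 2)) stop("every Nc must be >= 2", call. = FALSE)
  if (is.null(seeds)) seeds <- seq_len(reps)
  rows <- list()
  excl <- data.frame(nc = integer(), n_excluded = integer(),
                     n_runs = integer())
  for (nc in nc_range) {
    cfg <- nc_sweep_config(nc, f)
    threshold <- 1e-6 * steady_state_phage(params, nc, 0)
    n_excl <- 0
    for (seed in seeds) {
      init <- sample_initial_state(cfg, seed = seed + 1000L * nc)
      traj <- simulate_community(cfg, params, init, duration, settings = settings,
                       seed = seed)
      stats <- summarize_trajectory(traj, threshold = threshold)
      st <- stats$strains
      lytic <- which(st$f == 0)
      excluded <- nc == 2 && st$min_P[lytic] < threshold
      if (excluded) n_excl <- n_excl + 1
      role <- ifelse(st$class < nc, "single_temperate",
                     ifelse(st$f == 0, "lytic", "paired_temperate"))
      rows[[length(rows) + 1]] <- data.frame(
        nc = nc, seed = seed, role = role, class = st$class, f = st$f,
        mean_P = st$mean_P, min_P = st$min_P, excluded = excluded)
    }
    if (n_excl == length(seeds))
      warning(sprintf(
        "Nc = %d: the obligate lytic strain crossed the extinction threshold in all %d runs; no runs retained",
        nc, length(seeds)), call. = FALSE)
    excl <- rbind(excl, data.frame(nc = nc, n_excluded = n_excl,
                                   n_runs = length(seeds)))
    if (verbose)
      message(sprintf("Nc = %d done (%d/%d runs excluded)", nc, n_excl,
                      length(seeds)))
  }
  tab <- do.call(rbind, rows)
  kept <- tab[!tab$excluded, ]
  summ <- do.call(rbind, lapply(split(kept, list(kept$nc, kept$role),
                                      drop = TRUE), function(g) {
    data.frame(nc = g$nc[1], role = g$role[1],
               mean_of_means = mean(g$mean_P),
               median_of_mins = stats::median(g$min_P),
               n_runs = length(unique(g$seed)),
               P_ss = steady_state_phage(params, g$nc[1],
                                         if (g$role[1] == "lytic") 0
                                         else g$f[1]))
  }))
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, excluded = excl,
                 params = params, f = f, duration = duration),
            class = "nc_sweep")
}

#' @export
print.nc_sweep <- function(x, ...) {
  cat("Immunity-class sweep:\n")
  print(x$summary, digits = 3)
  invisible(x)
}
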