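#' Solver settings for community simulations
#'
#' The integrator works in log-density coordinates, which guarantees
#' positivity and resolves the many decades of dynamic range the chaotic
#' dynamics visit. Tolerances therefore apply to log densities; the default
#' `atol = 1e-10` corresponds to a relative density accuracy of about
#' 1e-10 per step. Population troughs are the scientifically relevant
#' feature, so the defaults favour accuracy over speed.
#'
#' @param method deSolve integration method; `"lsoda"` switches
#'   automatically between stiff and non-stiff steppers.
#' @param rtol,atol Relative and absolute tolerance (log-density space).
#' @param dt Output grid spacing in generations.
#' @param floor Densities of exactly zero in initial conditions are padded
#'   to this value before the log transform (densities, 1/volume).
#' @param extinction_threshold Default density threshold used by
#'   [apply_extinction()] and outcome classification, in cells (or phage)
#'   per unit volume. The default `1e-3` corresponds to less than one
#'   organism per litre when densities are per millilitre: a population
#'   this rare in any real community has gone extinct.
#' @param stop_below,stop_above Optional density bounds; when any tracked
#'   population leaves them the run is terminated early (via the solver's
#'   root finder) and the trajectory is truncated there. Communities
#'   without cross-class predation (e.g. a single immunity class) grow
#'   without bound and need these guards.
#' @param transient_frac Fraction of each run discarded as transient by
#'   analyses unless they are given an explicit window.
#' @param maxsteps Maximum internal solver steps between output times.
#' @return An object of class `"solver_settings"`.
#' @export
solver_settings <- function(method = "lsoda", rtol = 1e-8, atol = 1e-10,
                            dt = 0.1, floor = 1e-30,
                            extinction_threshold = 1e-3,
                            transient_frac = 0.2, maxsteps = 50000,
                            stop_below = NULL, stop_above = NULL) {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0", call. = FALSE)
  if (dt <= 0) stop("output spacing 'dt' must be > 0", call. = FALSE)
  if (floor <= 0) stop("'floor' must be > 0", call. = FALSE)
  if (!is.null(extinction_threshold) && extinction_threshold < 0)
    stop("'extinction_threshold' must be >= 0", call. = FALSE)
  if (transient_frac < 0 || transient_frac >= 1)
    stop("'transient_frac' must be in [0, 1)", call. = FALSE)
  if (!is.null(stop_below) && stop_below <= 0)
    stop("'stop_below' must be > 0", call. = FALSE)
  if (!is.null(stop_above) && stop_above <= 0)
    stop("'stop_above' must be > 0", call. = FALSE)
  structure(list(method = method, rtol = rtol, atol = atol, dt = dt,
                 floor = floor, extinction_threshold = extinction_threshold,
                 transient_frac = transient_frac, maxsteps = maxsteps,
                 stop_below = stop_below, stop_above = stop_above),
            class = "solver_settings")
}

#' Seeded random initial community state
#'
#' Draws every tracked density independently log-uniformly over
#' `10^log10_range`. With `equal_lysogens = TRUE`, lysogens of different
#' strains of the same immunity class are initialized with equal densities
#' (the within-class lysogen ratio is conserved by the dynamics, so this
#' convention pins it to 1 for the whole run).
#'
#' @param config A [community_config()].
#' @param log10_range Length-2 numeric: log10 of the density range.
#' @param seed Integer seed; the draw is reproducible per seed and does not
#'   disturb the caller's RNG state.
#' @param equal_lysogens Force equal within-class lysogen densities.
#' @return A [community_state()].
#' @export
sample_initial_state <- function(config, log10_range = c(6, 9), seed,
                                 equal_lysogens = FALSE) {
  stopifnot(inherits(config, "community_config"))
  if (length(log10_range) != 2 || diff(log10_range) < 0)
    stop("'log10_range' must be c(lo, hi) with lo <= hi", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  with_preserved_rng(seed, {
    P <- 10^stats::runif(config$n_strains, log10_range[1], log10_range[2])
    L <- 10^stats::runif(config$n_lysogens, log10_range[1], log10_range[2])
    if (equal_lysogens && config$n_lysogens > 0) {
      tab <- config$strains
      temperate <- !is.na(tab$lysogen_index)
      cls <- tab$class[temperate]
      first <- match(unique(cls), cls)
      L <- L[first][match(cls, unique(cls))]
    }
    community_state(P, L, config)
  })
}

# Evaluate expr with a temporary RNG seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- parameter packing for the compiled rhs ----

pack_parms <- function(config, params, extensions = NULL, pm = NULL,
                       root_lo = NULL, root_hi = NULL) {
  if (is.null(pm)) pm <- param_matrix(params, config)
  ext <- normalize_extensions(extensions)
  tab <- config$strains
  nc <- config$n_classes
  pairs <- if (ext$double_lysogens && nc >= 2) {
    m <- utils::combn(nc, 2)
    as.numeric(m)
  } else numeric(0)
  npairs <- length(pairs) / 2
  head <- c(nc, config$n_strains, config$n_lysogens,
            as.numeric(ext$sensitive), as.numeric(ext$double_lysogens),
            ext$tau, ext$kappa, npairs, params$alpha,
            if (is.null(root_lo)) -1e300 else log(root_lo),
            if (is.null(root_hi)) 1e300 else log(root_hi), 0)
  strains <- as.numeric(t(cbind(tab$class, tab$f,
                                ifelse(is.na(tab$lysogen_index), 0,
                                       tab$lysogen_index),
                                pm)))
  c(head, strains, pairs)
}

state_dim <- function(config, extensions = NULL) {
  ext <- normalize_extensions(extensions)
  nc <- config$n_classes
  npairs <- if (ext$double_lysogens && nc >= 2) choose(nc, 2) else 0
  config$n_strains + config$n_lysogens +
    as.integer(ext$sensitive) + npairs +
    if (ext$tau > 0) config$n_strains else 0
}

state_names <- function(config, extensions = NULL) {
  ext <- normalize_extensions(extensions)
  tab <- config$strains
  nm <- sprintf("P_c%d_f%g", tab$class, tab$f)
  temperate <- !is.na(tab$lysogen_index)
  nm <- c(nm, sprintf("L_c%d_f%g", tab$class[temperate], tab$f[temperate]))
  if (ext$sensitive) nm <- c(nm, "S")
  if (ext$double_lysogens && config$n_classes >= 2) {
    m <- utils::combn(config$n_classes, 2)
    nm <- c(nm, sprintf("D_c%d_c%d", m[1, ], m[2, ]))
  }
  if (ext$tau > 0)
    nm <- c(nm, sprintf("E_c%d_f%g", tab$class, tab$f))
  nm
}

# Flatten a community_state (+ optional extended compartments) to the
# log-density vector the compiled rhs expects.
pack_state <- function(state, config, extensions = NULL, extra = NULL,
                       floor = 1e-30) {
  check_state_dims(state, config)
  ext <- normalize_extensions(extensions)
  pad <- function(v) log(pmax(v, floor))
  z <- c(pad(state$P), pad(state$L))
  if (ext$sensitive) {
    S <- if (!is.null(extra$S)) extra$S else 0
    z <- c(z, pad(S))
  }
  if (ext$double_lysogens && config$n_classes >= 2) {
    npairs <- choose(config$n_classes, 2)
    D <- if (!is.null(extra$D)) extra$D else rep(0, npairs)
    if (length(D) != npairs)
      stop(sprintf("'D' must have %d entries (one per class pair)", npairs),
           call. = FALSE)
    z <- c(z, pad(D))
  }
  if (ext$tau > 0) {
    E <- if (!is.null(extra$E)) extra$E else rep(0, config$n_strains)
    if (length(E) != config$n_strains)
      stop("'E' must have one entry per strain", call. = FALSE)
    z <- c(z, pad(E))
  }
  stats::setNames(z, state_names(config, ext))
}

#' Integrate the community dynamics
#'
#' Runs the model forward from `init` for `t_end` generations, in
#' log-density coordinates, recording the state on a fixed output grid.
#' With an `extensions` object the extended mechanisms (sensitive bacteria,
#' double lysogens, finite lysis time, coinfection-induced lysogeny) are
#' simulated; with `extensions = NULL` the simplified model is used.
#'
#' @param config A [community_config()].
#' @param params A [model_parameters()] object.
#' @param init A [community_state()] with strictly positive densities
#'   (zeros are padded to `settings$floor`).
#' @param t_end Duration in generations.
#' @param settings A [solver_settings()] object.
#' @param extensions Optional [extensions()] object.
#' @param extra Optional named list of initial extended compartments:
#'   `S` (scalar), `D` (per class pair), `E` (per strain). Missing entries
#'   start at the log floor; [quasi_equilibrium_extra()] provides smoother
#'   starts.
#' @param seed Optional integer recorded in the trajectory provenance (the
#'   integration itself is deterministic).
#' @param t_start Start time (generations); output grid runs from here.
#' @return An object of class `"phage_trajectory"`: list with `times`
#'   (output grid), `log_state` (matrix, rows = times, natural-log
#'   densities), `config`, `params`, `settings`, `extensions`, `seed`,
#'   and an `events` data frame (filled by [apply_extinction()]).
#' @export
#' @examples
#' cfg <- community_config(list(0.5, 0.5, 0.5))
#' init <- sample_initial_state(cfg, seed = 1)
#' traj <- simulate_community(cfg, default_parameters(), init, t_end = 50)
#' dim(traj$log_state)
simulate_community <- function(config, params, init, t_end,
                     settings = solver_settings(), extensions = NULL,
                     extra = NULL, seed = NA_integer_, t_start = 0) {
  stopifnot(inherits(config, "community_config"),
            inherits(settings, "solver_settings"))
  ext <- normalize_extensions(extensions)
  if (ext$tau > 0 && identical(settings$method, "lsoda")) {
    # the exposed compartment adds a fast relaxation mode that lsoda's
    # stiffness switching handles poorly; fixed-order BDF is robust
    settings$method <- "vode"
  }
  z0 <- pack_state(init, config, ext, extra, settings$floor)
  times <- seq(t_start, t_start + t_end, by = settings$dt)
  out <- integrate_log(z0, times, config, params, ext, settings)
  ev <- empty_event_log()
  troot <- attr(out, "troot")
  if (!is.null(troot))
    ev <- rbind(ev, data.frame(name = "<bounds>", class = NA_integer_,
                               f = NA_real_, type = "solver_stop",
                               time = troot))
  structure(
    list(times = out[, 1], log_state = out[, -1, drop = FALSE],
         config = config, params = params, settings = settings,
         extensions = ext, seed = seed, events = ev),
    class = "phage_trajectory")
}

# Low-level integration of a packed log-state vector.
integrate_log <- function(z0, times, config, params, ext, settings,
                          pair = FALSE, events = NULL) {
  pm <- param_matrix(params, config)
  use_root <- !pair &&
    (!is.null(settings$stop_below) || !is.null(settings$stop_above))
  p <- pack_parms(config, params, ext, pm,
                  root_lo = settings$stop_below,
                  root_hi = settings$stop_above)
  .Call(C_lyso_set_parms, p)
  fn <- if (pair) "lyso_derivs_pair" else "lyso_derivs"
  if (use_root) {
    # lsodar for the plain model; radau (implicit, stiffly accurate) when
    # the exposed-compartment mode is active, which lsodar mishandles
    rooted <- if (settings$method %in% c("vode", "bdf")) deSolve::radau
      else deSolve::lsodar
    out <- rooted(y = z0, times = times, func = fn,
                  parms = NULL, dllname = "lysochaos",
                  rootfunc = "lyso_root", nroot = 2,
                  rtol = settings$rtol, atol = settings$atol,
                  maxsteps = settings$maxsteps, events = events)
  } else {
    out <- deSolve::ode(y = z0, times = times, func = fn,
                        parms = NULL, dllname = "lysochaos",
                        method = settings$method,
                        rtol = settings$rtol, atol = settings$atol,
                        maxsteps = settings$maxsteps, events = events)
  }
  troot <- attr(out, "troot")
  out <- unclass(out)
  finite <- rowSums(!is.finite(out)) == 0
  if (!all(finite)) out <- out[seq_len(which.min(finite) - 1), , drop = FALSE]
  truncated_by_root <- use_root && length(troot) > 0 && !is.na(troot[1])
  if (!truncated_by_root &&
      (nrow(out) < length(times) || any(!is.finite(out))))
    stop(sprintf(
      "integration failed at t = %.3f (solver gave up after %d of %d output times)",
      out[nrow(out), 1], nrow(out), length(times)), call. = FALSE)
  attr(out, "troot") <- if (truncated_by_root) troot[1] else NULL
  out
}

# Evaluate the compiled log-space rhs once (internal; used by tests and
# fixed-point verification).
eval_log_rhs <- function(z, config, params, extensions = NULL) {
  ext <- normalize_extensions(extensions)
  .Call(C_lyso_set_parms, pack_parms(config, params, ext))
  .Call(C_lyso_eval, as.numeric(z))
}

empty_event_log <- function() {
  data.frame(name = character(), class = integer(), f = numeric(),
             type = character(), time = numeric())
}

#' Densities stored in a trajectory
#'
#' @param traj A [simulate_community()] trajectory.
#' @param log10 Return log10 densities instead of densities.
#' @return Numeric matrix, rows = output times, columns named like the
#'   packed state (`P_c1_f0.5`, `L_c1_f0.5`, `S`, `D_c1_c2`, `E_...`).
#' @export
trajectory_densities <- function(traj, log10 = FALSE) {
  stopifnot(inherits(traj, "phage_trajectory"))
  m <- traj$log_state
  if (log10) m / log(10) else exp(m)
}

#' Tidy long-format view of a trajectory
#'
#' @param x A `phage_trajectory`.
#' @param ... Unused.
#' @return A data frame with columns `time`, `class`, `strain_f`,
#'   `population_type` (`"phage"`, `"lysogen"`, `"sensitive"`,
#'   `"double_lysogen"`, `"exposed"`) and `density`.
#' @export
as.data.frame.phage_trajectory <- function(x, ...) {
  nm <- colnames(x$log_state)
  dens <- exp(x$log_state)
  pieces <- lapply(seq_along(nm), function(j) {
    info <- parse_state_name(nm[j])
    data.frame(time = x$times, class = info$class, strain_f = info$f,
               population_type = info$type, density = dens[, j])
  })
  do.call(rbind, pieces)
}

parse_state_name <- function(nm) {
  if (nm == "S")
    return(list(class = NA_integer_, f = NA_real_, type = "sensitive"))
  if (grepl("^D_", nm))
    return(list(class = NA_integer_, f = NA_real_, type = "double_lysogen"))
  type <- c(P = "phage", L = "lysogen", E = "exposed")[substr(nm, 1, 1)]
  m <- regmatches(nm, regexec("^[PLE]_c([0-9]+)_f([0-9.eE+-]+)$", nm))[[1]]
  list(class = as.integer(m[2]), f = as.numeric(m[3]), type = unname(type))
}

#' Flag (and optionally zero) populations that cross an extinction threshold
#'
#' The model itself is a deterministic ODE and never reaches zero; an
#' extinction threshold is an analysis-layer interpretation: densities that
#' fall below a fraction of a single organism per system volume would have
#' gone extinct in any finite system. The threshold is off by default and
#' applied explicitly via this function or via outcome classification.
#'
#' @param traj A [simulate_community()] trajectory.
#' @param threshold Density threshold (> 0); default from the trajectory's
#'   solver settings ([solver_settings()]).
#' @param zero If `TRUE`, densities of a flagged population are clamped to
#'   the log floor from the first crossing onward.
#' @return The trajectory with its `events` log filled (columns: `name`,
#'   `class`, `f`, `type`, `time` of first crossing).
#' @export
apply_extinction <- function(traj, threshold = NULL, zero = FALSE) {
  stopifnot(inherits(traj, "phage_trajectory"))
  if (is.null(threshold)) threshold <- default_threshold(traj)
  if (threshold <= 0) stop("'threshold' must be > 0", call. = FALSE)
  lt <- log(threshold)
  ev <- empty_event_log()
  m <- traj$log_state
  for (j in seq_len(ncol(m))) {
    below <- which(m[, j] < lt)
    if (length(below)) {
      info <- parse_state_name(colnames(m)[j])
      ev <- rbind(ev, data.frame(name = colnames(m)[j], class = info$class,
                                 f = info$f, type = info$type,
                                 time = traj$times[below[1]]))
      if (zero) m[below[1]:nrow(m), j] <- log(traj$settings$floor)
    }
  }
  traj$log_state <- m
  traj$events <- ev
  traj
}

default_threshold <- function(traj) {
  th <- traj$settings$extinction_threshold
  if (is.null(th)) th <- 1e-3
  th
}

#' @export
print.phage_trajectory <- function(x, ...) {
  cat(sprintf(
    "Phage community trajectory: %d strains (%d classes), t in [%g, %g] generations, %d output points\n",
    x$config$n_strains, x$config$n_classes,
    min(x$times), max(x$times), length(x$times)))
  if (nrow(x$events))
    cat(sprintf("  %d extinction event(s) flagged\n", nrow(x$events)))
  invisible(x)
}
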