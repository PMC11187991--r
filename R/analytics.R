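#' Homeostatic phage-to-lysogen density ratio
#'
#' For an obligate lysogenic ("dormant") strain with `f = 1`, setting
#' `dP/dt = 0` gives the homeostatic phage density relative to its lysogen,
#' \deqn{P^*/L = b\gamma / (k L_c + \delta),}
#' where `L_c` is the lysogen density adsorbing the phage (in a multi-class
#' community, the total over all classes). When the
#' phage density dips below this ratio, induction restores it; above it,
#' phage death pushes it down. With `L_c = 0` the ratio reduces to the
#' simpler estimate `b*gamma/delta`, which predicts the troughs of
#' temperate phage-to-lysogen ratios to within a factor of about 2.
#'
#' @param params A [model_parameters()] object.
#' @param L_c Class lysogen total (>= 0), possibly a vector.
#' @return The ratio(s) `b*gamma/(k*L_c + delta)`.
#' @export
#' @examples
#' homeostatic_ratio(default_parameters(), 0)   # b*gamma/delta
homeostatic_ratio <- function(params, L_c) {
  stopifnot(is_model_parameters(params))
  if (any(L_c < 0)) stop("'L_c' must be >= 0", call. = FALSE)
  params$b * params$gamma / (params$k * L_c + params$delta)
}

#' Symmetric steady-state phage density
#'
#' The non-zero fixed point of the symmetric community (every class
#' equivalent, one strain per class with lysogeny fraction `f`) has phage
#' density
#' \deqn{P^{ss} = (\alpha - \gamma) / (k (N_c - 1)(1 - f)).}
#' It decreases with the number of immunity classes and increases with `f`.
#' Although the chaotic attractor never settles there, time-averaged phage
#' densities agree with this value to well within a factor of 2.
#'
#' @param params A [model_parameters()] object.
#' @param Nc Number of immunity classes (>= 2).
#' @param f Lysogeny fraction (< 1).
#' @return The steady-state phage density (1/volume).
#' @export
#' @examples
#' steady_state_phage(default_parameters(), Nc = 3, f = 0.5)
steady_state_phage <- function(params, Nc, f) {
  stopifnot(is_model_parameters(params))
  if (any(Nc < 2))
    stop("no such fixed point: Nc must be >= 2 (a single class has no prey)",
         call. = FALSE)
  if (any(f >= 1))
    stop("no such fixed point: f must be < 1 (an f = 1 strain never lyses)",
         call. = FALSE)
  if (any(f < 0)) stop("'f' must be in [0, 1)", call. = FALSE)
  (params$alpha - params$gamma) / (params$k * (Nc - 1) * (1 - f))
}

#' Symmetric fixed point (phage and lysogen densities)
#'
#' Solves `dP/dt = dL/dt = 0` for the symmetric community of `Nc`
#' equivalent classes, one temperate strain of fraction `f` each. The
#' lysogen equation fixes the phage density at [steady_state_phage()]; the
#' phage equation, with all class lysogen totals equal, is then linear in
#' the lysogen density:
#' `b*gamma*L - (delta + k*Nc*L) P + k*b*(1-f) P (Nc-1) L = 0`.
#'
#' @param params A [model_parameters()] object.
#' @param Nc Number of immunity classes (>= 2).
#' @param f Lysogeny fraction in (0, 1).
#' @return A list with `P_ss` and `L_ss` (densities, 1/volume).
#' @export
#' @examples
#' fp <- symmetric_fixed_point(default_parameters(), Nc = 3, f = 0.5)
#' cfg <- community_config(rep(list(0.5), 3))
#' st <- community_state(rep(fp$P_ss, 3), rep(fp$L_ss, 3), cfg)
#' unlist(rhs(st, default_parameters(), cfg))  # ~ 0
symmetric_fixed_point <- function(params, Nc, f) {
  stopifnot(is_model_parameters(params))
  if (Nc < 2)
    stop("no such fixed point: Nc must be >= 2", call. = FALSE)
  if (f <= 0 || f >= 1)
    stop("L_ss requires a temperate strain: f must be in (0, 1)",
         call. = FALSE)
  P <- steady_state_phage(params, Nc, f)
  # b g L - (delta + k Nc L) P + k b (1-f) P (Nc-1) L = 0
  denom <- params$b * params$gamma +
    params$k * P * (params$b * (1 - f) * (Nc - 1) - Nc)
  if (denom <= 0)
    stop(sprintf(
      "no positive lysogen solution: induction + lysis gain (%.3g) does not exceed adsorption loss",
      denom), call. = FALSE)
  L <- params$delta * P / denom
  list(P_ss = P, L_ss = L)
}

#' Tile the symmetric fixed point into a community state
#'
#' @param params,Nc,f As in [symmetric_fixed_point()].
#' @return A list with `config` (the symmetric [community_config()]) and
#'   `state` (the fixed-point [community_state()]).
#' @export
fixed_point_state <- function(params, Nc, f) {
  fp <- symmetric_fixed_point(params, Nc, f)
  config <- community_config(rep(list(f), Nc))
  state <- community_state(rep(fp$P_ss, Nc), rep(fp$L_ss, Nc), config)
  list(config = config, state = state, P_ss = fp$P_ss, L_ss = fp$L_ss)
}

#' Largest Lyapunov exponent of a community trajectory
#'
#' Benettin-style two-trajectory estimate in log-density space: after an
#' optional transient, a copy of the state is displaced by `delta0` (log
#' units), both copies are integrated together, and the separation is
#' renormalized back to `delta0` every `renorm_interval` generations. The
#' estimate is the mean log-divergence rate over renormalization blocks;
#' its standard error is computed across blocks (blocks are correlated, so
#' treat it as a scale, not an exact CI).
#'
#' @param config,params As in [simulate_community()].
#' @param init Initial [community_state()].
#' @param settings A [solver_settings()].
#' @param horizon Generations over which divergence is averaged (after the
#'   transient). Chaotic attractors need several hundred generations for a
#'   stable estimate; unbounded (prey-free) communities should use shorter
#'   horizons and small initial densities since their lysogen densities
#'   grow without bound.
#' @param transient Generations discarded before measuring.
#' @param renorm_interval Generations between renormalizations.
#' @param delta0 Initial separation (log-density units).
#' @param extensions Optional [extensions()] object.
#' @param extra Optional extended-compartment initial values.
#' @param seed Seed for the random perturbation direction.
#' @return A list with `lambda` (1/generation), `se`, `n_blocks`, and
#'   `rates` (per-block divergence rates).
#' @export
lyapunov_exponent <- function(config, params, init,
                              settings = solver_settings(),
                              horizon = 500, transient = 200,
                              renorm_interval = 1, delta0 = 1e-8,
                              extensions = NULL, extra = NULL, seed = 1) {
  stopifnot(inherits(config, "community_config"))
  if (horizon < 10 * renorm_interval)
    stop("'horizon' must cover at least 10 renormalization intervals",
         call. = FALSE)
  ext <- normalize_extensions(extensions)
  z0 <- pack_state(init, config, ext, extra, settings$floor)
  n <- length(z0)

  if (transient > 0) {
    run <- integrate_log(z0, c(0, transient), config, params, ext,
                         settings)
    z0 <- run[nrow(run), -1]
  }
  pert <- with_preserved_rng(seed, stats::rnorm(n))
  pert <- delta0 * pert / sqrt(sum(pert^2))

  acc <- new.env(parent = emptyenv())
  acc$rates <- numeric(0)
  renorm <- function(t, y, parms) {
    y1 <- y[1:n]; y2 <- y[(n + 1):(2 * n)]
    d <- sqrt(sum((y2 - y1)^2))
    acc$rates <- c(acc$rates, log(d / delta0) / renorm_interval)
    c(y1, y1 + (y2 - y1) * (delta0 / d))
  }
  etimes <- seq(renorm_interval, horizon, by = renorm_interval)
  zpair <- c(z0, z0 + pert)
  names(zpair) <- NULL
  integrate_log(zpair, c(0, etimes), config, params, ext, settings,
                pair = TRUE,
                events = list(func = renorm, time = etimes))
  rates <- acc$rates
  list(lambda = mean(rates),
       se = stats::sd(rates) / sqrt(length(rates)),
       n_blocks = length(rates), rates = rates)
}

#' Per-strain summary statistics of a trajectory
#'
#' Time-averaged (trapezoidal) density, minimum and maximum per strain over
#' an analysis window, the minimum phage-to-lysogen ratio for temperate
#' strains, and extinction flags against a density threshold.
#'
#' @param traj A [simulate_community()] trajectory.
#' @param window Length-2 numeric: analysis window in generations. Default:
#'   the trajectory with its configured transient fraction discarded.
#' @param threshold Extinction threshold; default from the trajectory's
#'   solver settings (see [apply_extinction()]).
#' @param lyapunov Optional result of [lyapunov_exponent()] to attach.
#' @return An object of class `"community_summary"`: list with `strains`
#'   (data frame: `class`, `f`, `mean_P`, `min_P`, `max_P`, `mean_L`,
#'   `min_L`, `max_L`, `min_PL`, `extinct`), `window`, `threshold`,
#'   `lyapunov`, and `outcome` (filled by [classify_outcome()]).
#' @export
summarize_trajectory <- function(traj, window = NULL, threshold = NULL,
                                 lyapunov = NULL) {
  stopifnot(inherits(traj, "phage_trajectory"))
  t <- traj$times
  if (is.null(window)) {
    t0 <- min(t) + traj$settings$transient_frac * (max(t) - min(t))
    window <- c(t0, max(t))
  }
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 2)
    stop("analysis window contains fewer than 2 output points", call. = FALSE)
  if (is.null(threshold)) threshold <- default_threshold(traj)

  tw <- t[keep]
  m <- traj$log_state[keep, , drop = FALSE]
  dens <- exp(m)
  tab <- traj$config$strains
  nl <- traj$config$n_lysogens
  ns <- traj$config$n_strains

  trap <- function(v) sum(diff(tw) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) /
    (tw[length(tw)] - tw[1])

  res <- data.frame(class = tab$class, f = tab$f,
                    mean_P = apply(dens[, 1:ns, drop = FALSE], 2, trap),
                    min_P = apply(dens[, 1:ns, drop = FALSE], 2, min),
                    max_P = apply(dens[, 1:ns, drop = FALSE], 2, max),
                    mean_L = NA_real_, min_L = NA_real_, max_L = NA_real_,
                    min_PL = NA_real_)
  temperate <- !is.na(tab$lysogen_index)
  if (nl > 0) {
    lm <- dens[, ns + seq_len(nl), drop = FALSE]
    res$mean_L[temperate] <- apply(lm, 2, trap)[tab$lysogen_index[temperate]]
    res$min_L[temperate] <- apply(lm, 2, min)[tab$lysogen_index[temperate]]
    res$max_L[temperate] <- apply(lm, 2, max)[tab$lysogen_index[temperate]]
    ratio <- m[, tab$phage_index[temperate], drop = FALSE] -
      m[, ns + tab$lysogen_index[temperate], drop = FALSE]
    res$min_PL[temperate] <- exp(apply(ratio, 2, min))
  }
  res$extinct <- res$min_P < threshold
  structure(list(strains = res, window = window, threshold = threshold,
                 lyapunov = lyapunov, outcome = NULL),
            class = "community_summary")
}

#' @export
print.community_summary <- function(x, ...) {
  cat(sprintf("Community summary over t in [%g, %g]:\n",
              x$window[1], x$window[2]))
  print(x$strains, digits = 3)
  if (!is.null(x$lyapunov))
    cat(sprintf("largest Lyapunov exponent: %.4f +/- %.4f per generation\n",
                x$lyapunov$lambda, x$lyapunov$se))
  if (!is.null(x$outcome)) cat("outcome:", x$outcome, "\n")
  invisible(x)
}

#' Trough analysis of phage-to-lysogen ratios
#'
#' Detects local minima ("troughs") of each temperate strain's log10(P/L)
#' ratio with a prominence of at least `prominence` decades, and quantifies
#' (i) the fold-gap between the analytic floor estimate `b*gamma/delta` and
#' each strain's global minimum ratio, and (ii) the "bunching" of ratios:
#' at each common trough of the class total, the max/min spread of P/L
#' across the temperate strains of that class.
#'
#' @param traj A [simulate_community()] trajectory.
#' @param window Analysis window (default: transient removed).
#' @param prominence Minimum trough prominence in decades of P/L.
#' @param min_troughs Required number of troughs per strain.
#' @return A list with `per_strain` (data frame: `class`, `f`, `min_PL`,
#'   `fold_gap` = (b*gamma/delta)/min_PL, `n_troughs`, `range_decades`),
#'   `bunching` (data frame per class trough: `class`, `time`, `spread` =
#'   max/min P/L across strains), and `floor_estimate`.
#' @export
trough_floor_gap <- function(traj, window = NULL, prominence = 0.5,
                             min_troughs = 10) {
  stopifnot(inherits(traj, "phage_trajectory"))
  t <- traj$times
  if (is.null(window)) {
    t0 <- min(t) + traj$settings$transient_frac * (max(t) - min(t))
    window <- c(t0, max(t))
  }
  keep <- t >= window[1] & t <= window[2]
  tw <- t[keep]
  m <- traj$log_state[keep, , drop = FALSE]
  tab <- traj$config$strains
  ns <- traj$config$n_strains
  temperate <- which(!is.na(tab$lysogen_index))
  if (!length(temperate))
    stop("community has no temperate strains", call. = FALSE)
  floor_est <- homeostatic_ratio(traj$params, 0)

  per <- do.call(rbind, lapply(temperate, function(i) {
    r <- (m[, tab$phage_index[i]] - m[, ns + tab$lysogen_index[i]]) / log(10)
    tr <- find_troughs(r, prominence)
    data.frame(class = tab$class[i], f = tab$f[i],
               min_PL = 10^min(r), fold_gap = floor_est / 10^min(r),
               n_troughs = length(tr), range_decades = diff(range(r)))
  }))
  if (any(per$n_troughs < min_troughs))
    warning(sprintf(
      "fewer than %d troughs for %d strain(s); fold-gap estimates may be unstable",
      min_troughs, sum(per$n_troughs < min_troughs)), call. = FALSE)

  bunch <- do.call(rbind, lapply(unique(tab$class[temperate]), function(cl) {
    idx <- temperate[tab$class[temperate] == cl]
    if (length(idx) < 2) return(NULL)
    rmat <- vapply(idx, function(i)
      (m[, tab$phage_index[i]] - m[, ns + tab$lysogen_index[i]]) / log(10),
      numeric(sum(keep)))
    cls_mean <- rowMeans(rmat)
    tr <- find_troughs(cls_mean, prominence)
    if (!length(tr)) return(NULL)
    data.frame(class = cl, time = tw[tr],
               spread = 10^(apply(rmat[tr, , drop = FALSE], 1, max) -
                            apply(rmat[tr, , drop = FALSE], 1, min)))
  }))
  list(per_strain = per, bunching = bunch, floor_estimate = floor_est)
}

# Local minima of `x` with prominence of at least `prom` (same units as x):
# a trough must be separated from the neighbouring troughs by rises of at
# least `prom` on both sides.
find_troughs <- function(x, prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] <= x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1
  if (!length(cand)) return(integer(0))
  # prominence from segment maxima between consecutive candidate minima
  sel <- integer(0)
  for (j in seq_along(cand)) {
    i <- cand[j]
    lo <- if (j == 1) 1 else cand[j - 1]
    hi <- if (j == length(cand)) n else cand[j + 1]
    rise_l <- max(x[lo:i]) - x[i]
    rise_r <- max(x[i:hi]) - x[i]
    if (min(rise_l, rise_r) >= prom) sel <- c(sel, i)
  }
  sel
}

#' Classify the ecological outcome of a run
#'
#' Labels a summarized run as `"extinction(...)"` if any strain's minimum
#' density fell below the threshold, `"fixed-point"` if the dynamics are
#' non-chaotic (Lyapunov estimate not positive) and densities have stopped
#' moving, and `"coexistence"` otherwise.
#'
#' @param stats A [summarize_trajectory()] result.
#' @param traj The trajectory behind `stats` (used for the convergence
#'   check; optional if a Lyapunov estimate is attached and positive).
#' @param drift_tol Relative density drift over the last 10% of the window
#'   below which a non-chaotic run counts as converged.
#' @return The input summary with `outcome` set.
#' @export
classify_outcome <- function(stats, traj = NULL, drift_tol = 1e-4) {
  stopifnot(inherits(stats, "community_summary"))
  res <- stats$strains
  if (any(res$extinct)) {
    who <- sprintf("c%d_f%g", res$class[res$extinct], res$f[res$extinct])
    stats$outcome <- sprintf("extinction(%s)", paste(who, collapse = ","))
    return(stats)
  }
  lam <- if (!is.null(stats$lyapunov)) stats$lyapunov$lambda else NA_real_
  if (!is.na(lam) && lam <= 0 && !is.null(traj)) {
    t <- traj$times
    keep <- t >= stats$window[2] - 0.1 * diff(stats$window)
    m <- traj$log_state[keep, seq_len(nrow(res)), drop = FALSE]
    drift <- max(apply(m, 2, function(v) diff(range(v))))
    if (drift < drift_tol * log(10)) {
      stats$outcome <- "fixed-point"
      return(stats)
    }
  }
  stats$outcome <- "coexistence"
  stats
}
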