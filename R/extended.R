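#' Mechanistic extensions of the simplified community model
#'
#' The simplified model tracks only phage and single lysogens: sensitive
#' (non-lysogenic) bacteria are treated as negligible and double lysogens
#' are disallowed. These switches relax those simplifications while sharing
#' the same integrator and analysis layer:
#'
#' * `sensitive`: track a sensitive bacterial population S that grows
#'   exponentially at `alpha` and is infected at rate `k` by every phage
#'   (lysogenized with probability `f`, lysed otherwise).
#' * `double_lysogens`: single lysogens of class `c` infected by a phage of
#'   class `c' != c` are lysogenized with probability `f'`, forming double
#'   lysogens `D_{cc'}` (tracked per unordered class pair) that are immune
#'   to both classes, grow at `alpha`, and induce either prophage at its
#'   strain-weighted induction rate.
#' * `tau`: finite lysis time; every lysis event (induction or lytic
#'   infection) routes through an exposed compartment `E` that matures to a
#'   burst at rate `1/tau`. `tau = 0` selects the instantaneous-lysis model.
#' * `kappa`: coinfection-induced lysogeny; the effective lysogeny fraction
#'   rises with instantaneous phage pressure (see [moi_dependent_f()]).
#'
#' With every switch off the extended right-hand side reduces exactly to
#' the simplified model.
#'
#' @param sensitive Track sensitive bacteria.
#' @param double_lysogens Track double lysogens.
#' @param tau Lysis time in generations (0 = instantaneous).
#' @param kappa Half-saturation of coinfection-induced lysogeny, in units
#'   of `k * P` (1/generation); 0 disables the mechanism.
#' @return An object of class `"lyso_extensions"`.
#' @export
#' @examples
#' extensions(sensitive = TRUE, double_lysogens = TRUE)
extensions <- function(sensitive = FALSE, double_lysogens = FALSE,
                       tau = 0, kappa = 0) {
  if (length(tau) != 1 || !is.finite(tau) || tau < 0)
    stop("'tau' must be a single finite value >= 0 (0 = instantaneous lysis)",
         call. = FALSE)
  if (length(kappa) != 1 || !is.finite(kappa) || kappa < 0)
    stop("'kappa' must be a single finite value >= 0 (0 = off)", call. = FALSE)
  structure(list(sensitive = isTRUE(sensitive),
                 double_lysogens = isTRUE(double_lysogens),
                 tau = tau, kappa = kappa),
            class = "lyso_extensions")
}

normalize_extensions <- function(ext) {
  if (is.null(ext)) return(extensions())
  if (inherits(ext, "lyso_extensions")) return(ext)
  if (is.list(ext)) return(do.call(extensions, ext))
  stop("'extensions' must be NULL or an extensions() object", call. = FALSE)
}

#' Full-model right-hand side (sensitive bacteria and double lysogens)
#'
#' Linear-space derivative of the extended model. This is the reference
#' (vectorized R) implementation; simulations use the compiled equivalent
#' via [simulate_community()] with an [extensions()] object.
#'
#' @param state A [community_state()].
#' @param params A [model_parameters()] object.
#' @param config The matching [community_config()].
#' @param S Sensitive-bacteria density (scalar >= 0).
#' @param D Double-lysogen densities, one per unordered class pair in
#'   `utils::combn(Nc, 2)` column order; `NULL` means all zero.
#' @param ext An [extensions()] object; `sensitive`/`double_lysogens`
#'   default to `TRUE` here.
#' @return A list with `dP`, `dL`, `dS`, `dD`.
#' @export
rhs_full <- function(state, params, config, S = 0, D = NULL,
                     ext = extensions(sensitive = TRUE,
                                      double_lysogens = TRUE)) {
  check_state_dims(state, config)
  ext <- normalize_extensions(ext)
  if (S < 0) stop("'S' must be >= 0", call. = FALSE)
  nc <- config$n_classes
  npairs <- if (ext$double_lysogens && nc >= 2) choose(nc, 2) else 0
  if (is.null(D)) D <- rep(0, npairs)
  if (length(D) != npairs)
    stop("'D' must have one entry per unordered class pair", call. = FALSE)
  if (any(D < 0)) stop("'D' must be >= 0", call. = FALSE)

  pm <- param_matrix(params, config)
  tab <- config$strains
  P <- state$P
  temperate <- !is.na(tab$lysogen_index)
  Lfull <- numeric(config$n_strains)
  Lfull[temperate] <- state$L[tab$lysogen_index[temperate]]
  Lc <- class_lysogen_totals(state, config)
  Ltot <- sum(Lc)

  f <- tab$f
  if (ext$kappa > 0)
    f <- moi_dependent_f(f, sum(P), params, kappa = ext$kappa,
                         k = pm[, "k"])

  by_class <- function(v) as.numeric(rowsum(v, tab$class, reorder = TRUE))
  lysP <- by_class(pm[, "k"] * (1 - f) * P)    # lytic pressure by source class
  lysoP <- by_class(pm[, "k"] * f * P)         # lysogenizing pressure
  kP <- by_class(pm[, "k"] * P)

  pairs <- if (npairs) utils::combn(nc, 2) else matrix(0, 2, 0)
  Dtot <- sum(D)
  Dwith <- numeric(nc)
  for (q in seq_len(npairs)) {
    Dwith[pairs[1, q]] <- Dwith[pairs[1, q]] + D[q]
    Dwith[pairs[2, q]] <- Dwith[pairs[2, q]] + D[q]
  }
  gsum <- numeric(nc)
  if (any(temperate)) {
    gs <- rowsum((pm[, "gamma"] * Lfull)[temperate], tab$class[temperate])
    gsum[as.integer(rownames(gs))] <- gs
  }
  gbar <- ifelse(Lc > 0, gsum / Lc, 0)

  Suse <- if (ext$sensitive) S else 0
  B <- Ltot + Suse + Dtot
  prey <- (Ltot - Lc[tab$class]) + Suse +
    if (npairs) (Dtot - Dwith[tab$class]) else 0

  ind <- pm[, "gamma"] * Lfull
  if (npairs) {
    share <- ifelse(temperate & Lc[tab$class] > 0,
                    Lfull / pmax(Lc[tab$class], .Machine$double.xmin), 0)
    ind <- ind + pm[, "gamma"] * share * Dwith[tab$class]
  }
  dP <- pm[, "b"] * ind - (pm[, "delta"] + pm[, "k"] * B) * P +
    pm[, "b"] * pm[, "k"] * (1 - f) * P * prey

  press_lyt <- sum(lysP) - lysP[tab$class]
  press_lyso <- if (npairs) sum(lysoP) - lysoP[tab$class] else 0
  dLfull <- (pm[, "alpha"] - pm[, "gamma"]) * Lfull -
    Lfull * (press_lyt + press_lyso) +
    if (ext$sensitive) pm[, "k"] * f * Suse * P else 0
  dL <- dLfull[temperate][order(tab$lysogen_index[temperate])]

  dS <- if (ext$sensitive) params$alpha * S - S * sum(pm[, "k"] * P) else NULL
  dD <- if (npairs) {
    vapply(seq_len(npairs), function(q) {
      c1 <- pairs[1, q]; c2 <- pairs[2, q]
      Lc[c1] * lysoP[c2] + Lc[c2] * lysoP[c1] +
        (params$alpha - gbar[c1] - gbar[c2]) * D[q] -
        D[q] * (sum(lysP) - lysP[c1] - lysP[c2])
    }, numeric(1))
  } else NULL
  list(dP = as.numeric(dP), dL = as.numeric(dL), dS = dS, dD = dD)
}

#' Finite-lysis-time right-hand side
#'
#' Reference (R) derivative of the exposed-compartment variant: every lysis
#' event (induction or lytic infection) enters an exposed class `E` indexed
#' by the phage strain that will burst from it, and matures at rate
#' `1/tau`. As `tau -> 0` trajectories converge to the instantaneous-lysis
#' model.
#'
#' @param state A [community_state()].
#' @param E Exposed-cell densities, one per strain.
#' @param params,config As in [rhs()].
#' @param tau Lysis time in generations, > 0.
#' @return A list with `dP`, `dL`, `dE`.
#' @export
rhs_finite_lysis <- function(state, E, params, config, tau) {
  check_state_dims(state, config)
  if (length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("'tau' must be > 0; use rhs() for the instantaneous-lysis model",
         call. = FALSE)
  if (length(E) != config$n_strains || any(E < 0))
    stop("'E' must be a nonnegative vector with one entry per strain",
         call. = FALSE)
  pm <- param_matrix(params, config)
  tab <- config$strains
  P <- state$P
  temperate <- !is.na(tab$lysogen_index)
  Lfull <- numeric(config$n_strains)
  Lfull[temperate] <- state$L[tab$lysogen_index[temperate]]
  Lc <- class_lysogen_totals(state, config)
  Ltot <- sum(Lc)
  L_other <- Ltot - Lc[tab$class]

  influx <- pm[, "gamma"] * Lfull +
    pm[, "k"] * (1 - tab$f) * P * L_other
  dE <- influx - E / tau
  dP <- pm[, "b"] * E / tau - (pm[, "delta"] + pm[, "k"] * Ltot) * P

  kfP <- pm[, "k"] * (1 - tab$f) * P
  press <- sum(kfP) - as.numeric(rowsum(kfP, tab$class, reorder = TRUE))
  dLfull <- (pm[, "alpha"] - pm[, "gamma"]) * Lfull -
    Lfull * press[tab$class]
  dL <- dLfull[temperate][order(tab$lysogen_index[temperate])]
  list(dP = as.numeric(dP), dL = dL, dE = as.numeric(dE))
}

#' Coinfection-dependent effective lysogeny fraction
#'
#' Under high phage pressure, coinfection biases the lysis-lysogeny
#' decision toward lysogeny. The effective fraction is
#' `f_eff = 1 - (1 - f) / (1 + k P / kappa)`: equal to `f` at zero phage
#' density, monotonically increasing with pressure, saturating at 1.
#'
#' @param base_f Baseline lysogeny fraction(s) in `[0, 1]`.
#' @param phage_pressure Total phage density (1/volume).
#' @param params A [model_parameters()] (supplies `k` unless given).
#' @param kappa Half-saturation in units of `k * P` (1/generation).
#' @param k Optional adsorption rate(s) overriding `params$k`.
#' @return Effective lysogeny fraction(s).
#' @export
#' @examples
#' moi_dependent_f(0.1, 0, default_parameters(), kappa = 1)       # = 0.1
#' moi_dependent_f(0.1, 1e9, default_parameters(), kappa = 1)     # -> 0.55
moi_dependent_f <- function(base_f, phage_pressure, params, kappa,
                            k = NULL) {
  if (any(base_f < 0 | base_f > 1))
    stop("'base_f' must lie in [0, 1]", call. = FALSE)
  if (any(phage_pressure < 0))
    stop("'phage_pressure' must be >= 0", call. = FALSE)
  if (kappa <= 0) stop("'kappa' must be > 0", call. = FALSE)
  if (is.null(k)) k <- params$k
  1 - (1 - base_f) / (1 + k * phage_pressure / kappa)
}

#' Per-strain parameter heterogeneity
#'
#' Multiplies the shared rate constants by strain-specific log-normal
#' factors (median 1, log-sd `log(1 + spread)`), producing an overrides
#' table for [community_config()]. `spread = 0` returns the homogeneous
#' table. Draws are seeded and leave the caller's RNG untouched.
#'
#' @param params A [model_parameters()] object.
#' @param config A [community_config()].
#' @param spread Relative spread (approximate coefficient of variation).
#' @param seed Integer seed.
#' @param which Parameters to jitter.
#' @return A data frame usable as the `overrides` argument of
#'   [community_config()]; columns `class`, `f`, and one per jittered
#'   parameter holding multiplicative factors.
#' @export
#' @examples
#' cfg <- community_config(list(0.5, 0.5, 0.5))
#' jitter_parameters(default_parameters(), cfg, spread = 0.1, seed = 1)
jitter_parameters <- function(params, config, spread, seed,
                              which = c("alpha", "gamma", "delta", "k", "b")) {
  stopifnot(inherits(config, "community_config"))
  if (spread < 0) stop("'spread' must be >= 0", call. = FALSE)
  which <- match.arg(which, several.ok = TRUE)
  tab <- config$strains
  out <- data.frame(class = tab$class, f = tab$f)
  if (spread == 0) {
    for (w in which) out[[w]] <- rep(1, nrow(tab))
    return(out)
  }
  with_preserved_rng(seed, {
    for (w in which)
      out[[w]] <- exp(stats::rnorm(nrow(tab), 0, log1p(spread)))
  })
  out
}

#' Quasi-equilibrium initial values for extended compartments
#'
#' Double lysogens and exposed cells have inflow terms independent of their
#' own density, so starting them at the log floor makes the first steps
#' needlessly stiff. This helper balances each compartment's inflow against
#' its outflow at the given initial state.
#'
#' @param state Initial [community_state()].
#' @param config,params As in [simulate_community()].
#' @param ext An [extensions()] object.
#' @param S Initial sensitive density used for the balance (default 0).
#' @return A list with entries among `S`, `D`, `E` suitable for the `extra`
#'   argument of [simulate_community()].
#' @export
quasi_equilibrium_extra <- function(state, config, params, ext, S = 0) {
  ext <- normalize_extensions(ext)
  out <- list()
  if (ext$sensitive) out$S <- S
  if (ext$double_lysogens && config$n_classes >= 2) {
    d0 <- rhs_full(state, params, config, S = S, D = NULL, ext = ext)
    # formation flux / (loss rate scale alpha) as a smooth starting point
    out$D <- pmax(d0$dD, 0) / params$alpha
  }
  if (ext$tau > 0) {
    fl <- rhs_finite_lysis(state, rep(0, config$n_strains), params, config,
                           ext$tau)
    out$E <- pmax(fl$dE, 0) * ext$tau
  }
  out
}
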