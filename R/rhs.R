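#' Right-hand side of the community dynamics
#'
#' Time derivative of the phage and lysogen densities. For a strain of
#' class `c` with lysogeny fraction `f`,
#' \deqn{dP_{cf}/dt = b \gamma L_{cf}
#'   - (\delta + k \sum_{c'} L_{c'}) P_{cf}
#'   + k b (1-f) P_{cf} \sum_{c' \ne c} L_{c'}}
#' \deqn{dL_{cf}/dt = (\alpha - \gamma) L_{cf}
#'   - k L_{cf} \sum_{c' \ne c} \sum_{f'} (1-f') P_{c'f'}}
#' where `L_c` is the class lysogen total. The three phage terms are
#' induction of the strain's own lysogens, phage death plus adsorption to
#' (immune or not) lysogens, and growth through lysis of other-class
#' lysogens; the lysogen terms are net growth and death by lytic infection
#' from other classes. Obligate lytic strains (`f = 0`) have no lysogens and
#' hence no induction term.
#'
#' With per-strain parameter overrides, each strain's own `alpha`, `gamma`,
#' `delta`, `k`, `b` govern its growth, induction, death and adsorption,
#' while the lysogen-death term uses the attacking phage strain's `k`.
#'
#' @param state A [community_state()].
#' @param params A [model_parameters()] object.
#' @param config The matching [community_config()].
#' @return A list with numeric vectors `dP` (per strain) and `dL` (per
#'   temperate strain), in flattening order.
#' @export
#' @examples
#' cfg <- community_config(list(0.5, 0.5, 0.5))
#' st <- community_state(P = c(1e8, 1e8, 1e8), L = c(1e7, 1e7, 1e7), cfg)
#' rhs(st, default_parameters(), cfg)
rhs <- function(state, params, config) {
  check_state_dims(state, config)
  pm <- param_matrix(params, config)
  tab <- config$strains
  P <- state$P
  Lfull <- numeric(config$n_strains)
  temperate <- !is.na(tab$lysogen_index)
  Lfull[temperate] <- state$L[tab$lysogen_index[temperate]]

  Lc <- class_lysogen_totals(state, config)
  Ltot <- sum(Lc)
  L_other <- Ltot - Lc[tab$class]          # per strain: lysogens of other classes

  # lytic predation pressure on each class: sum over other-class phage of
  # k_j (1 - f_j) P_j
  kfP <- pm[, "k"] * (1 - tab$f) * P
  press_per_class <- sum(kfP) - as.numeric(rowsum(kfP, tab$class,
                                                  reorder = TRUE))

  dP <- -(pm[, "delta"] + pm[, "k"] * Ltot) * P +
    pm[, "k"] * pm[, "b"] * (1 - tab$f) * P * L_other +
    pm[, "b"] * pm[, "gamma"] * Lfull
  dL <- (pm[temperate, "alpha"] - pm[temperate, "gamma"]) * state$L -
    state$L * press_per_class[tab$class[temperate]]
  list(dP = as.numeric(dP), dL = as.numeric(dL))
}
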