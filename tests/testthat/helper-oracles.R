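# Literal nested-loop oracles for the model derivatives, written term by
# term from the equations; deliberately slow and independent of the
# package's vectorized and compiled implementations.

oracle_rhs <- function(state, params, config) {
  tab <- strain_table(config)
  pm <- lysochaos:::param_matrix(params, config)
  ns <- nrow(tab)
  L <- numeric(ns)
  for (i in seq_len(ns))
    if (!is.na(tab$lysogen_index[i])) L[i] <- state$L[tab$lysogen_index[i]]
  dP <- numeric(ns)
  dL <- numeric(ns)
  for (i in seq_len(ns)) {
    ci <- tab$class[i]; fi <- tab$f[i]
    # induction
    dP[i] <- pm[i, "b"] * pm[i, "gamma"] * L[i]
    # death and adsorption: delta + k * sum over ALL classes' lysogens
    ltot <- 0
    for (j in seq_len(ns)) ltot <- ltot + L[j]
    dP[i] <- dP[i] - (pm[i, "delta"] + pm[i, "k"] * ltot) * state$P[i]
    # growth through lysis of other-class lysogens
    for (j in seq_len(ns))
      if (tab$class[j] != ci)
        dP[i] <- dP[i] + pm[i, "k"] * pm[i, "b"] * (1 - fi) * state$P[i] * L[j]
    # lysogen equation
    if (!is.na(tab$lysogen_index[i])) {
      dL[i] <- (pm[i, "alpha"] - pm[i, "gamma"]) * L[i]
      for (j in seq_len(ns))
        if (tab$class[j] != ci)
          dL[i] <- dL[i] - pm[j, "k"] * L[i] * (1 - tab$f[j]) * state$P[j]
    }
  }
  list(dP = dP,
       dL = dL[!is.na(tab$lysogen_index)][order(tab$lysogen_index[
         !is.na(tab$lysogen_index)])])
}

# Extended-model oracle: sensitive bacteria + double lysogens, literal loops.
oracle_rhs_full <- function(state, params, config, S, D) {
  tab <- strain_table(config)
  pm <- lysochaos:::param_matrix(params, config)
  ns <- nrow(tab)
  nc <- config$n_classes
  pairs <- utils::combn(nc, 2)
  np <- ncol(pairs)
  L <- numeric(ns)
  for (i in seq_len(ns))
    if (!is.na(tab$lysogen_index[i])) L[i] <- state$L[tab$lysogen_index[i]]
  Lc <- numeric(nc)
  for (i in seq_len(ns)) Lc[tab$class[i]] <- Lc[tab$class[i]] + L[i]
  Dwith <- numeric(nc)
  for (q in seq_len(np)) {
    Dwith[pairs[1, q]] <- Dwith[pairs[1, q]] + D[q]
    Dwith[pairs[2, q]] <- Dwith[pairs[2, q]] + D[q]
  }
  Dtot <- sum(D); Ltot <- sum(Lc)
  dP <- numeric(ns); dL <- numeric(ns)
  for (i in seq_len(ns)) {
    ci <- tab$class[i]; fi <- tab$f[i]
    # induction from own single lysogens and own-class doubles (share by
    # single-lysogen abundance)
    ind <- pm[i, "gamma"] * L[i]
    if (!is.na(tab$lysogen_index[i]) && Lc[ci] > 0)
      ind <- ind + pm[i, "gamma"] * (L[i] / Lc[ci]) * Dwith[ci]
    dP[i] <- pm[i, "b"] * ind
    # adsorption to every bacterial cell + decay
    dP[i] <- dP[i] - (pm[i, "delta"] + pm[i, "k"] * (Ltot + S + Dtot)) *
      state$P[i]
    # burst from lysing S, other-class singles, and doubles not
    # containing the class
    prey <- S
    for (j in seq_len(ns)) if (tab$class[j] != ci) prey <- prey + L[j]
    for (q in seq_len(np))
      if (pairs[1, q] != ci && pairs[2, q] != ci) prey <- prey + D[q]
    dP[i] <- dP[i] + pm[i, "k"] * pm[i, "b"] * (1 - fi) * state$P[i] * prey
    if (!is.na(tab$lysogen_index[i])) {
      dL[i] <- (pm[i, "alpha"] - pm[i, "gamma"]) * L[i] +
        pm[i, "k"] * fi * S * state$P[i]
      for (j in seq_len(ns))
        if (tab$class[j] != ci)
          dL[i] <- dL[i] - pm[j, "k"] * L[i] * state$P[j]  # lysis + lysogenization
    }
  }
  dS <- params$alpha * S
  for (j in seq_len(ns)) dS <- dS - pm[j, "k"] * S * state$P[j]
  dD <- numeric(np)
  for (q in seq_len(np)) {
    c1 <- pairs[1, q]; c2 <- pairs[2, q]
    gb1 <- 0; gb2 <- 0
    if (Lc[c1] > 0)
      for (i in seq_len(ns))
        if (tab$class[i] == c1) gb1 <- gb1 + pm[i, "gamma"] * L[i] / Lc[c1]
    if (Lc[c2] > 0)
      for (i in seq_len(ns))
        if (tab$class[i] == c2) gb2 <- gb2 + pm[i, "gamma"] * L[i] / Lc[c2]
    form <- 0
    for (i in seq_len(ns)) {
      if (tab$class[i] == c1)
        for (j in seq_len(ns))
          if (tab$class[j] == c2)
            form <- form + pm[j, "k"] * tab$f[j] * state$P[j] * L[i]
      if (tab$class[i] == c2)
        for (j in seq_len(ns))
          if (tab$class[j] == c1)
            form <- form + pm[j, "k"] * tab$f[j] * state$P[j] * L[i]
    }
    press <- 0
    for (j in seq_len(ns))
      if (tab$class[j] != c1 && tab$class[j] != c2)
        press <- press + pm[j, "k"] * (1 - tab$f[j]) * state$P[j]
    dD[q] <- form + (params$alpha - gb1 - gb2) * D[q] - press * D[q]
  }
  list(dP = dP,
       dL = dL[!is.na(tab$lysogen_index)][order(tab$lysogen_index[
         !is.na(tab$lysogen_index)])],
       dS = dS, dD = dD)
}

# random instances --------------------------------------------------------

random_config <- function(max_classes = 5, max_strains = 4, seed) {
  set.seed(seed)
  nc <- sample(1:max_classes, 1)
  classes <- lapply(seq_len(nc), function(i) {
    pool <- unique(c(0, round(runif(9), 3)))
    k <- sample(1:min(max_strains, length(pool)), 1)
    sort(sample(pool, k))
  })
  community_config(classes)
}

random_state <- function(config, seed, lo = 2, hi = 9) {
  set.seed(seed)
  community_state(10^runif(config$n_strains, lo, hi),
                  10^runif(config$n_lysogens, lo, hi), config)
}

random_params <- function(seed) {
  set.seed(seed)
  model_parameters(alpha = runif(1, 0.5, 2),
                   gamma = 10^runif(1, -5, -2),
                   delta = runif(1, 0.3, 3),
                   k = 10^runif(1, -10, -8),
                   b = runif(1, 5, 200))
}

expect_rel_equal <- function(a, b, tol, scale = NULL) {
  a <- unlist(a); b <- unlist(b)
  if (is.null(scale)) scale <- pmax(abs(a), abs(b), 1e-300)
  expect_lt(max(abs(a - b) / scale), tol)
}
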