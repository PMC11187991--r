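test_that("the coinfection response interpolates between f and 1", {
  p <- default_parameters()
  expect_equal(moi_dependent_f(0.1, 0, p, kappa = 1), 0.1)
  expect_equal(moi_dependent_f(c(0, 0.5), 0, p, kappa = 2), c(0, 0.5))
  # kP = kappa halves the lytic fraction
  expect_equal(1 - moi_dependent_f(0.2, 1 / p$k, p, kappa = 1),
               (1 - 0.2) / 2)
  expect_equal(moi_dependent_f(0.3, 1e30, p, kappa = 1), 1,
               tolerance = 1e-10)
  expect_error(moi_dependent_f(1.2, 0, p, kappa = 1), "\\[0, 1\\]")
})

test_that("parameter jitter is seeded, multiplicative, and off at zero spread", {
  p <- default_parameters()
  cfg <- community_config(list(c(0, 0.5), 0.9))
  z <- jitter_parameters(p, cfg, spread = 0, seed = 1)
  expect_true(all(as.matrix(z[, -(1:2)]) == 1))
  a <- jitter_parameters(p, cfg, spread = 0.1, seed = 1)
  b <- jitter_parameters(p, cfg, spread = 0.1, seed = 1)
  d <- jitter_parameters(p, cfg, spread = 0.1, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_true(all(as.matrix(a[, -(1:2)]) > 0))
  # a jittered config changes the derivative through param_matrix
  cfg2 <- community_config(list(c(0, 0.5), 0.9), overrides = a)
  st <- random_state(cfg, seed = 3)
  expect_false(identical(rhs(st, p, cfg), rhs(st, p, cfg2)))
})

test_that("the full model reduces exactly to the simplified model", {
  p <- default_parameters()
  for (s in 1:25) {
    cfg <- random_config(max_classes = 4, seed = s)
    st <- random_state(cfg, seed = s + 40)
    base <- rhs(st, p, cfg)
    red <- rhs_full(st, p, cfg, S = 0, D = NULL,
                    ext = extensions(sensitive = TRUE,
                                     double_lysogens = FALSE))
    expect_rel_equal(list(red$dP, red$dL), base, 1e-12)
  }
})

test_that("the full model matches its literal nested-loop oracle", {
  p <- default_parameters()
  for (s in 1:25) {
    cfg <- random_config(max_classes = 4, seed = s)
    if (cfg$n_classes < 2) next
    st <- random_state(cfg, seed = s + 80)
    set.seed(s + 160)
    S <- 10^runif(1, 2, 8)
    D <- 10^runif(choose(cfg$n_classes, 2), 2, 8)
    got <- rhs_full(st, p, cfg, S = S, D = D)
    want <- oracle_rhs_full(st, p, cfg, S = S, D = D)
    expect_rel_equal(got, want, 1e-12)
  }
})

test_that("the compiled extended rhs agrees with the R implementation", {
  p <- default_parameters()
  ext <- extensions(sensitive = TRUE, double_lysogens = TRUE)
  for (s in 1:10) {
    cfg <- random_config(max_classes = 4, seed = s + 7)
    if (cfg$n_classes < 2) next
    st <- random_state(cfg, seed = s + 21, lo = 4, hi = 8)
    set.seed(s + 35)
    S <- 10^runif(1, 3, 7)
    D <- 10^runif(choose(cfg$n_classes, 2), 3, 7)
    z <- log(c(st$P, st$L, S, D))
    dz <- lysochaos:::eval_log_rhs(z, cfg, p, ext)
    lin <- rhs_full(st, p, cfg, S = S, D = D, ext = ext)
    expect_rel_equal(dz * exp(z),
                     c(lin$dP, lin$dL, lin$dS, lin$dD), 1e-10,
                     scale = pmax(abs(dz * exp(z)), 1e-6 * exp(z)))
  }
})

test_that("exposed cells decay at 1/tau and tau = 0 is rejected", {
  p <- default_parameters()
  cfg <- community_config(list(0.5, 0.5))
  st <- community_state(c(0, 0), c(0, 0), cfg)
  fl <- rhs_finite_lysis(st, E = c(100, 50), p, cfg, tau = 0.2)
  expect_equal(fl$dE, -c(100, 50) / 0.2)
  expect_equal(fl$dP, p$b * c(100, 50) / 0.2)
  expect_error(rhs_finite_lysis(st, c(0, 0), p, cfg, tau = 0), "> 0")
})

test_that("finite lysis converges to instantaneous lysis as tau -> 0", {
  p <- default_parameters()
  # smoothly attracting community (dormant strain tracking its floor):
  # phase drift cannot amplify the model discrepancy here
  cfg <- community_config(list(1, 0.5))
  # start near the homeostatic ratio so the comparison tracks the smooth
  # solution rather than an O(tau) boundary layer
  init <- community_state(c(8e5, 1e6), c(1e8, 1e8), cfg)
  guard <- solver_settings(stop_above = 1e30)
  base <- simulate_community(cfg, p, init, 25, settings = guard)
  ext <- extensions(tau = 1e-3)
  extra <- quasi_equilibrium_extra(init, cfg, p, ext)
  tl <- simulate_community(cfg, p, init, 25, settings = guard,
                           extensions = ext, extra = extra)
  n <- ncol(base$log_state)
  rows <- which(base$times >= 5)     # skip the initial adjustment swing
  rows <- rows[rows <= nrow(tl$log_state)]
  disc <- max(abs(base$log_state[rows, ] - tl$log_state[rows, 1:n])) / log(10)
  expect_lt(disc, 0.01)
  # on the chaotic community the discrepancy scales linearly with tau
  cfgc <- community_config(rep(list(c(0, 0.1, 0.5, 0.9)), 3))
  initc <- sample_initial_state(cfgc, seed = 1)
  basec <- simulate_community(cfgc, p, initc, 10)
  d <- vapply(c(1e-3, 1e-4), function(tau) {
    e <- extensions(tau = tau)
    x <- quasi_equilibrium_extra(initc, cfgc, p, e)
    tr <- simulate_community(cfgc, p, initc, 10, extensions = e, extra = x)
    max(abs(basec$log_state - tr$log_state[, 1:ncol(basec$log_state)]))
  }, numeric(1))
  expect_lt(d[2], d[1] / 3)
})

test_that("quasi-equilibrium extras balance inflow and outflow at start", {
  p <- default_parameters()
  cfg <- community_config(list(c(0, 0.5), 0.5))
  init <- sample_initial_state(cfg, seed = 2)
  ext <- extensions(tau = 0.1)
  x <- quasi_equilibrium_extra(init, cfg, p, ext)
  fl <- rhs_finite_lysis(init, x$E, p, cfg, 0.1)
  expect_lt(max(abs(fl$dE) / (x$E / 0.1 + 1e-300)), 1e-10)
})
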