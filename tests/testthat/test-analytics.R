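test_that("homeostatic ratio follows its closed form", {
  p <- default_parameters()
  expect_equal(homeostatic_ratio(p, 0), p$b * p$gamma / p$delta)
  # kL = delta halves the prey-free value
  expect_equal(homeostatic_ratio(p, p$delta / p$k),
               homeostatic_ratio(p, 0) / 2)
  L <- 10^seq(0, 10, length.out = 20)
  expect_true(all(diff(homeostatic_ratio(p, L)) < 0))
  expect_error(homeostatic_ratio(p, -1), ">= 0")
})

test_that("steady-state phage density follows the fixed-point formula", {
  p <- model_parameters(1, 1e-2, 1, 1e-9, 100)
  # alpha - gamma = 0.99, Nc = 3, f = 0.5 -> 9.9e8
  expect_equal(steady_state_phage(p, 3, 0.5), 9.9e8)
  expect_equal(steady_state_phage(p, 3, 0), steady_state_phage(p, 3, 0.5) / 2)
  expect_equal(steady_state_phage(p, 5, 0.5),
               steady_state_phage(p, 3, 0.5) / 2)  # (Nc-1) doubles
  expect_error(steady_state_phage(p, 1, 0.5), "no such fixed point")
  expect_error(steady_state_phage(p, 3, 1), "no such fixed point")
  # monotonicity over randomized parameters
  for (s in 1:20) {
    pr <- random_params(s)
    f <- runif(1, 0, 0.95)
    expect_true(all(diff(steady_state_phage(pr, 2:6, f)) < 0))
    fs <- sort(runif(5, 0, 0.95))
    expect_true(all(diff(steady_state_phage(pr, 3, fs)) > 0))
  }
})

test_that("the symmetric fixed point zeroes the rhs and matches a root-search oracle", {
  p <- default_parameters()
  fp <- fixed_point_state(p, 3, 0.5)
  expect_equal(fp$P_ss, steady_state_phage(p, 3, 0.5))
  d <- rhs(fp$state, p, fp$config)
  expect_lt(max(abs(c(d$dP / fp$P_ss, d$dL / fp$L_ss))) / p$alpha, 1e-12)
  # independent bracketing root search on the scalar phage balance
  P <- fp$P_ss; Nc <- 3; fr <- 0.5
  phage_balance <- function(L)
    p$b * p$gamma * L - (p$delta + p$k * Nc * L) * P +
      p$k * p$b * (1 - fr) * P * (Nc - 1) * L
  oracle <- uniroot(phage_balance, c(1e-3, 1e15), tol = 1e-8)$root
  expect_equal(fp$L_ss, oracle, tolerance = 1e-6)
  expect_error(symmetric_fixed_point(p, 3, 1), "\\(0, 1\\)")
})

test_that("summaries reproduce closed-form integrals on synthetic trajectories", {
  p <- default_parameters()
  cfg <- community_config(list(0.5))
  # hand-built trajectory object: constant then linear segment
  times <- seq(0, 10, by = 0.5)
  const <- rep(log(5e6), length(times))
  lin <- log(1e6 + 4e5 * times)    # linear density ramp
  traj <- structure(list(
    times = times,
    log_state = cbind(P_c1_f0.5 = const, L_c1_f0.5 = lin),
    config = cfg, params = p, settings = solver_settings(dt = 0.5),
    extensions = extensions(), seed = NA,
    events = lysochaos:::empty_event_log()), class = "phage_trajectory")
  s <- summarize_trajectory(traj, window = c(0, 10))
  expect_equal(s$strains$mean_P, 5e6)
  expect_equal(s$strains$min_P, 5e6)
  expect_equal(s$strains$max_P, 5e6)
  # trapezoid of a linear function is exact: mean = value at midpoint
  expect_equal(s$strains$mean_L, 1e6 + 4e5 * 5, tolerance = 1e-12)
  expect_equal(s$strains$min_L, 1e6)
  expect_error(summarize_trajectory(traj, window = c(20, 30)), "window")
})

test_that("outcome classification applies its rules in order", {
  p <- default_parameters()
  fx <- make_fixture("tiny", seed = 2)
  traj <- simulate_community(fx$config, fx$params, fx$init, 50, fx$settings)
  st <- summarize_trajectory(traj, threshold = 1e-3)
  lam_pos <- list(lambda = 0.05, se = 0.01)
  st$lyapunov <- lam_pos
  expect_equal(classify_outcome(st, traj)$outcome, "coexistence")
  # force an extinction flag
  st2 <- st
  st2$strains$extinct[1] <- TRUE
  out <- classify_outcome(st2, traj)$outcome
  expect_match(out, "^extinction\\(")
  expect_match(out, "c1_f0.3")
  # converged fixed-point run with non-positive lyapunov
  fp <- fixed_point_state(p, 3, 0.3)
  tfp <- simulate_community(fp$config, p, fp$state, 50)
  sfp <- summarize_trajectory(tfp, threshold = 1e-3,
                              lyapunov = list(lambda = -0.01, se = 0.005))
  expect_equal(classify_outcome(sfp, tfp)$outcome, "fixed-point")
})

test_that("trough detection finds prominent minima only", {
  t <- seq(0, 40 * pi, by = 0.05)
  x <- sin(t)                       # prominence 2, minima at 3pi/2 + 2k pi
  idx <- lysochaos:::find_troughs(x, 0.5)
  expect_equal(length(idx), 20, tolerance = 1)
  expect_true(all(abs(x[idx] + 1) < 1e-3))
  # shallow ripple below the prominence cut is ignored
  y <- 0.1 * sin(5 * t)
  expect_equal(length(lysochaos:::find_troughs(y, 0.5)), 0)
})

test_that("a dormant strain's ratio settles onto the homeostatic floor", {
  p <- default_parameters()
  cfg <- community_config(list(1, 0.5))   # dormant strain plus partner class
  st <- community_state(c(1e4, 1e6), c(1e8, 1e8), cfg)
  traj <- simulate_community(cfg, p, st, 40,
    settings = solver_settings(stop_above = 1e30))
  n <- nrow(traj$log_state)
  ratio <- unname(exp(traj$log_state[n, "P_c1_f1"] -
                      traj$log_state[n, "L_c1_f1"]))
  Ltot <- sum(exp(traj$log_state[n, c("L_c1_f1", "L_c2_f0.5")]))
  expect_equal(ratio, homeostatic_ratio(p, Ltot), tolerance = 0.1)
})

test_that("the Lyapunov estimator is non-positive for regular dynamics", {
  p <- default_parameters()
  cfg <- community_config(list(1))
  init <- sample_initial_state(cfg, c(0, 2), seed = 1)
  ly <- lyapunov_exponent(cfg, p, init, horizon = 30, transient = 2)
  expect_lt(ly$lambda, 2 * ly$se)
  expect_gt(ly$n_blocks, 10)
})

test_that("the Lyapunov estimate is stable under the renormalization interval", {
  p <- default_parameters()
  cfg <- community_config(rep(list(0.3), 3))
  init <- sample_initial_state(cfg, seed = 7)
  a <- lyapunov_exponent(cfg, p, init, horizon = 400, transient = 200,
                         renorm_interval = 1, seed = 7)
  b <- lyapunov_exponent(cfg, p, init, horizon = 400, transient = 200,
                         renorm_interval = 2, seed = 7)
  expect_lt(abs(a$lambda - b$lambda), 3 * (a$se + b$se))
  expect_gt(a$lambda, 0)
})
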