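test_that("a prey-free temperate community grows exactly exponentially", {
  p <- default_parameters()
  cfg <- community_config(list(1))
  st <- community_state(10, 100, cfg)
  traj <- simulate_community(cfg, p, st, 10)
  L <- exp(traj$log_state[, "L_c1_f1"])
  want <- 100 * exp((p$alpha - p$gamma) * traj$times)
  expect_lt(max(abs(L / want - 1)), 10 * traj$settings$rtol * 10)
})

test_that("the symmetric fixed point is stationary over tens of generations", {
  p <- default_parameters()
  fp <- fixed_point_state(p, Nc = 3, f = 0.3)
  traj <- simulate_community(fp$config, p, fp$state, 20)
  drift <- apply(traj$log_state, 2, function(v) diff(range(v)))
  expect_lt(max(drift), 1e-6)
})

test_that("integration is deterministic for identical inputs", {
  fx <- make_fixture("tiny", seed = 3)
  t1 <- simulate_community(fx$config, fx$params, fx$init, 30, fx$settings)
  t2 <- simulate_community(fx$config, fx$params, fx$init, 30, fx$settings)
  expect_identical(t1$log_state, t2$log_state)
  expect_identical(t1$times, t2$times)
})

test_that("halving the tolerances barely moves short-horizon trajectories", {
  fx <- make_fixture("chaos", seed = 2)
  s1 <- solver_settings(rtol = 1e-8, atol = 1e-10)
  s2 <- solver_settings(rtol = 5e-9, atol = 5e-11)
  t1 <- simulate_community(fx$config, fx$params, fx$init, 20, s1)
  t2 <- simulate_community(fx$config, fx$params, fx$init, 20, s2)
  diff_log10 <- max(abs(t1$log_state - t2$log_state)) / log(10)
  expect_lt(diff_log10, 1e-4)
})

test_that("initial-state sampling is seeded, honours the range, and can tie lysogens", {
  cfg <- community_config(list(c(0.1, 0.5, 0.9), 0.3))
  a <- sample_initial_state(cfg, seed = 11)
  b <- sample_initial_state(cfg, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, sample_initial_state(cfg, seed = 12)))
  eq <- sample_initial_state(cfg, seed = 5, equal_lysogens = TRUE)
  expect_equal(eq$L[1], eq$L[2])
  expect_equal(eq$L[2], eq$L[3])
  expect_false(eq$L[1] == eq$L[4])   # different class drawn independently
  expect_error(sample_initial_state(cfg, c(5, 3), seed = 1), "lo <= hi")
  # sampling leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_initial_state(cfg, seed = 1))
  expect_identical(runif(1), before)
})

test_that("sampled log10 densities are uniform over the requested range", {
  cfg <- community_config(rep(list(0.5), 4))
  draws <- unlist(lapply(1:1250, function(s)
    log10(sample_initial_state(cfg, c(4, 8), seed = s)$P)))
  expect_gt(stats::ks.test(draws, "punif", 4, 8)$p.value, 0.01)
})

test_that("extinction flagging records first crossings and can zero strains", {
  fx <- make_fixture("tiny", seed = 1)
  traj <- simulate_community(fx$config, fx$params, fx$init, 30, fx$settings)
  # threshold below everything: unchanged, empty log
  t0 <- apply_extinction(traj, threshold = 1e-25)
  expect_identical(t0$log_state, traj$log_state)
  expect_equal(nrow(t0$events), 0)
  # threshold above one strain's dip: flagged at or before the dip
  m <- exp(traj$log_state)
  j <- which.min(apply(m, 2, min))
  thr <- min(m[, j]) * 10
  t1 <- apply_extinction(traj, threshold = thr)
  expect_true(colnames(m)[j] %in% t1$events$name)
  expect_lte(t1$events$time[t1$events$name == colnames(m)[j]],
             traj$times[which.min(m[, j])])
  t2 <- apply_extinction(traj, threshold = thr, zero = TRUE)
  expect_equal(unname(exp(t2$log_state[nrow(t2$log_state), j])),
               traj$settings$floor)
})

test_that("density bounds terminate runs whose outcome is decided", {
  p <- default_parameters()
  cfg <- community_config(list(c(0, 0.3)))     # single class: unbounded growth
  st <- community_state(c(1e8, 1e8), 1e8, cfg)
  traj <- simulate_community(cfg, p, st, 2000,
    settings = solver_settings(stop_below = 1e-40, stop_above = 1e30))
  expect_lt(max(traj$times), 2000)
  expect_equal(traj$events$type, "solver_stop")
  expect_true(all(exp(traj$log_state) < 1e30 * 1.01))
})

test_that("trajectories round-trip through CSV plus JSON sidecar", {
  fx <- make_fixture("tiny", seed = 4)
  traj <- simulate_community(fx$config, fx$params, fx$init, 5, fx$settings,
                             seed = 4)
  tmp <- file.path(tempdir(), "traj.csv")
  write_trajectory(traj, tmp)
  back <- read_trajectory(tmp)
  expect_equal(back$times, traj$times)
  expect_equal(unname(back$state),
               unname(exp(traj$log_state)), tolerance = 1e-15)
  expect_equal(back$provenance$seed, 4)
  expect_equal(back$provenance$parameters$gamma, fx$params$gamma)
  unlink(c(tmp, paste0(tmp, ".json")))
})
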