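test_that("parameter construction enforces positivity and lysogen growth", {
  p <- model_parameters(1, 1e-3, 1, 1e-9, 10)
  expect_s3_class(p, "model_parameters")
  expect_error(model_parameters(1, 1e-3, -1, 1e-9, 10), "positive")
  expect_error(model_parameters(1, 1e-3, 1, 1e-9, 0.5), "burst")
  expect_error(model_parameters(0.01, 0.02, 1, 1e-9, 10), "cannot grow")
  expect_warning(
    model_parameters(0.01, 0.02, 1, 1e-9, 10, allow_nongrowing = TRUE),
    "cannot grow")
  expect_identical(default_parameters(), default_parameters())
  expect_gt(default_parameters()$alpha, default_parameters()$gamma)
  expect_gte(default_parameters()$b, 1)
})

test_that("community configuration validates and flattens stably", {
  cfg <- community_config(list(c(0.5, 0), 0.9))
  tab <- strain_table(cfg)
  # strains sorted by ascending f within each class, classes in order
  expect_equal(tab$f, c(0, 0.5, 0.9))
  expect_equal(tab$class, c(1L, 1L, 2L))
  expect_equal(tab$phage_index, 1:3)
  expect_equal(tab$lysogen_index, c(NA, 1L, 2L))
  expect_error(community_config(list()), "non-empty")
  expect_error(community_config(list(c(0.5, 0.5))), "distinct")
  expect_error(community_config(list(1.2)), "\\[0, 1\\]")
  expect_error(community_config(list(numeric(0))), ">= 1 strain")
})

test_that("community states reject negative densities and bad dimensions", {
  cfg <- community_config(list(c(0, 0.5)))
  expect_error(community_state(c(1, 2, 3), 1, cfg), "2 entries")
  expect_error(community_state(c(1, -2), 1, cfg), "nonnegative")
  expect_error(community_state(c(1, 2), numeric(0), cfg), "1 entries")
  st <- community_state(c(1, 2), 3, cfg)
  expect_equal(st$P, c(1, 2))
})

test_that("class lysogen totals sum temperate strains only", {
  cfg <- community_config(list(c(0.1, 0.5), 0))
  st <- community_state(c(1, 1, 1), c(2, 3), cfg)
  expect_equal(class_lysogen_totals(st, cfg), c(5, 0))
  # random states match an elementwise-sum oracle
  for (s in 1:10) {
    cfg <- random_config(seed = s)
    st <- random_state(cfg, seed = s + 100)
    tab <- strain_table(cfg)
    want <- vapply(seq_len(cfg$n_classes), function(ci) {
      idx <- tab$lysogen_index[tab$class == ci]
      sum(st$L[idx[!is.na(idx)]])
    }, numeric(1))
    expect_equal(class_lysogen_totals(st, cfg), want)
  }
})

test_that("extinction is a fixed point and the empty predation sum is exact", {
  p <- default_parameters()
  cfg <- community_config(list(0.5, c(0, 0.9)))
  zero <- community_state(rep(0, 3), rep(0, 2), cfg)
  d <- rhs(zero, p, cfg)
  expect_equal(unlist(d), rep(0, 5), ignore_attr = TRUE)
  # single class, f = 1: the cross-class sums are empty so dL = (alpha-gamma)L
  cfg1 <- community_config(list(1))
  st <- community_state(1e5, 1e7, cfg1)
  d1 <- rhs(st, p, cfg1)
  expect_identical(d1$dL, (p$alpha - p$gamma) * 1e7)
  # and the phage feels only induction, death and adsorption
  expect_equal(d1$dP, p$b * p$gamma * 1e7 - (p$delta + p$k * 1e7) * 1e5)
})

test_that("vectorized rhs matches the literal nested-loop oracle", {
  for (s in 1:100) {
    cfg <- random_config(seed = s)
    st <- random_state(cfg, seed = s + 1000)
    p <- random_params(s + 2000)
    got <- rhs(st, p, cfg)
    want <- oracle_rhs(st, p, cfg)
    expect_rel_equal(got, want, 1e-12)
  }
})

test_that("compiled log-space rhs agrees with the linear-space rhs", {
  for (s in 1:25) {
    cfg <- random_config(seed = s)
    st <- random_state(cfg, seed = s + 300, lo = 4, hi = 9)
    p <- random_params(s + 600)
    z <- log(c(st$P, st$L))
    dz <- lysochaos:::eval_log_rhs(z, cfg, p)
    lin <- rhs(st, p, cfg)
    expect_rel_equal(dz * exp(z), c(lin$dP, lin$dL), 1e-10)
  }
})

test_that("the nonnegative orthant is forward invariant", {
  for (s in 1:20) {
    cfg <- random_config(seed = s)
    st <- random_state(cfg, seed = s + 50)
    p <- random_params(s + 70)
    tab <- strain_table(cfg)
    # zero a random subset of populations
    set.seed(s)
    zp <- runif(cfg$n_strains) < 0.5
    zl <- runif(cfg$n_lysogens) < 0.5
    st$P[zp] <- 0
    st$L[zl] <- 0
    d <- rhs(st, p, cfg)
    expect_true(all(d$dP[zp] >= 0))       # induction can only push up
    expect_true(all(d$dL[zl] == 0))       # dL proportional to L
  }
})

test_that("relabelling immunity classes commutes with the rhs", {
  p <- default_parameters()
  for (s in 1:10) {
    set.seed(s)
    nc <- sample(2:5, 1)
    classes <- lapply(seq_len(nc), function(i) sort(runif(sample(1:3, 1))))
    cfg <- community_config(classes)
    st <- random_state(cfg, seed = s + 10)
    perm <- sample(nc)                    # class j of cfg2 = class perm[j]
    inv <- integer(nc); inv[perm] <- seq_len(nc)
    cfg2 <- community_config(classes[perm])
    tab <- strain_table(cfg); tab2 <- strain_table(cfg2)
    m <- match(paste(inv[tab$class], tab$f), paste(tab2$class, tab2$f))
    P2 <- numeric(length(st$P)); L2 <- numeric(length(st$L))
    P2[m] <- st$P
    temperate <- !is.na(tab$lysogen_index)
    L2[tab2$lysogen_index[m[temperate]]] <- st$L[tab$lysogen_index[temperate]]
    st2 <- community_state(P2, L2, cfg2)
    d <- rhs(st, p, cfg)
    d2 <- rhs(st2, p, cfg2)
    expect_equal(d2$dP[m], d$dP, tolerance = 1e-12)
    expect_equal(d2$dL[tab2$lysogen_index[m[temperate]]],
                 d$dL[tab$lysogen_index[temperate]], tolerance = 1e-12)
  }
})

test_that("within a class the lysogen log-derivative is strain independent", {
  p <- default_parameters()
  cfg <- community_config(list(c(0.1, 0.5, 0.9), c(0, 0.3)))
  for (s in 1:10) {
    st <- random_state(cfg, seed = s)
    d <- rhs(st, p, cfg)
    rate <- d$dL / st$L       # d/dt log L
    # class 1 strains: indices 1:3 of the lysogen block
    expect_equal(rate[1], rate[2], tolerance = 1e-14)
    expect_equal(rate[2], rate[3], tolerance = 1e-14)
  }
})

test_that("induction restores the phage ratio toward the homeostatic value", {
  p <- default_parameters()
  cfg <- community_config(list(1, 0.5))   # dormant strain + a partner class
  L1 <- 1e8; L2 <- 5e7
  ratio_star <- homeostatic_ratio(p, L1)
  for (fac in c(0.2, 0.5)) {
    below <- community_state(c(ratio_star * L1 * fac, 1e5), c(L1, L2), cfg)
    above <- community_state(c(ratio_star * L1 / fac, 1e5), c(L1, L2), cfg)
    expect_gt(rhs(below, p, cfg)$dP[1], 0)
    expect_lt(rhs(above, p, cfg)$dP[1], 0)
  }
})
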