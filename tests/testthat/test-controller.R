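test_that("initialization fills pools from concentration x volume x NA", {
  cfg <- simulationConfig(box = 1000, actin_uM = 20, n_seed_filaments = 50,
                          t_total = 1, seed = 1)
  st <- initializeSystem(cfg)
  expect_equal(totalActin(st), 12044) # 20e-6 * 1e-15 L * 6.022e23
  fr <- networkSnapshot(st)
  expect_equal(length(fr$filaments), 50)
  expect_true(all(vapply(fr$filaments, function(f) sum(f$nmono), numeric(1)) == 2))
  # linkers present from t = 0, motors only after pre-growth
  expect_equal(sum(fr$species[, 2]), round(0.1 * 20 * 1e9 * 6.022e-7))
  expect_equal(sum(fr$species[, 3]), 0)
})

test_that("equal seeds give bit-identical initial states and trajectories", {
  cfg <- simulationConfig(box = 800, actin_uM = 5, n_seed_filaments = 8,
                          t_total = 2, seed = 9,
                          protocol = list(pre_growth = 1, snapshot_interval = 1))
  s1 <- networkSnapshot(initializeSystem(cfg))
  s2 <- networkSnapshot(initializeSystem(cfg))
  expect_identical(s1$filaments, s2$filaments)
  t1 <- runSimulation(cfg)
  t2 <- runSimulation(cfg)
  last <- length(t1$frames)
  expect_identical(t1$frames[[last]]$filaments, t2$frames[[last]]$filaments)
  expect_identical(t1$frames[[last]]$species, t2$frames[[last]]$species)
})

test_that("time increases and actin is conserved across every frame", {
  cfg <- simulationConfig(box = 800, actin_uM = 5, n_seed_filaments = 8,
                          t_total = 3, seed = 4,
                          protocol = list(pre_growth = 1, snapshot_interval = 1))
  tr <- runSimulation(cfg)
  expect_true(all(diff(tr$times) > 0))
  a0 <- round(5 * 0.8^3 * 1e9 * 6.022e-7)
  for (fr in tr$frames) {
    poly <- sum(vapply(fr$filaments, function(f) sum(f$nmono), numeric(1)))
    expect_equal(poly + sum(fr$species[, 1]), a0)
  }
})

test_that("free filament growth kinetics match a deterministic ODE", {
  skip_if_not_installed("deSolve")
  # one well-mixed compartment, mechanics trivial, mechanochemistry off
  nf <- 10
  mkcfg <- function(seed) simulationConfig(
    box = 500, actin_uM = 20, n_seed_filaments = nf, t_total = 0,
    r_motor_actin = 0, r_linker_actin = 0, seed = seed,
    forcefield = list(k_vol = 0),
    mechanochemistry = list(enabled = FALSE),
    protocol = list(pre_growth = 6, snapshot_interval = 1))
  rx <- defaultChemistry()
  vol <- 500^3
  n0 <- round(20 * vol * 6.022e-7)
  ode <- deSolve::ode(
    y = c(P = 2 * nf), times = seq(0, 6, by = 1),
    func = function(t, y, parms) {
      conc <- (n0 - y[1]) / (6.022e-7 * vol)
      grow <- nf * ((rx$k_poly_plus + rx$k_poly_minus) * conc -
                      (rx$k_depoly_plus + rx$k_depoly_minus))
      list(max(grow, 0))
    }, parms = NULL)
  sims <- vapply(1:4, function(sd) {
    tr <- runSimulation(mkcfg(sd))
    vapply(tr$frames, function(fr)
      sum(vapply(fr$filaments, function(f) sum(f$nmono), numeric(1))),
      numeric(1))
  }, numeric(7))
  mid <- 4 # t = 3 s, growth still actin-limited later
  simMean <- mean(sims[mid, ])
  simSd <- sd(sims[mid, ])
  expect_lt(abs(simMean - ode[mid, "P"]),
            max(4 * simSd / sqrt(4), 0.05 * ode[mid, "P"]))
  # and at the end both should be near monomer exhaustion equilibrium
  expect_equal(unname(mean(sims[7, ]) / ode[7, "P"]), 1, tolerance = 0.1)
})

test_that("turnover scales with the chi factor", {
  mk <- function(chi, seed) {
    st <- quietFilament(rep(40L, 4),
                        chemistry = list(k_poly_plus = 0, k_poly_minus = 0,
                                         k_depoly_minus = 0,
                                         k_depoly_plus = 1.4, chi = chi),
                        seed = seed)
    counts <- matrix(0L, prod(st$dims), 3)
    setSpeciesCounts(st, counts)
    registerBindings(st)
    r <- runChemistry(st, t_stop = 20, record = TRUE)
    sum(r$events$kind == "depoly_plus")
  }
  n1 <- mean(vapply(1:3, function(s) mk(1, s), numeric(1)))
  n4 <- mean(vapply(1:3, function(s) mk(4, s), numeric(1)))
  expect_equal(n4 / n1, 4, tolerance = 0.25)
})

test_that("without motors and linkers there is no net contraction", {
  cfg <- simulationConfig(box = 800, actin_uM = 8, n_seed_filaments = 15,
                          r_motor_actin = 0, r_linker_actin = 0,
                          t_total = 20, seed = 2,
                          protocol = list(pre_growth = 5,
                                          snapshot_interval = 5))
  tr <- runSimulation(cfg)
  rg <- rgRatio(tr, t_ref = 5)
  expect_equal(tail(rg$ratio, 1), 1, tolerance = 0.12)
})
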