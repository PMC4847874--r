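test_that("propensities follow mass action and the RDME jump law", {
  # unimolecular bulk channel: a = k n
  st <- reactionNetwork(matrix(c(3L, 0L, 0L), 1),
                        list(list(react = 0L, prod = 1L, k = 2)))
  ch <- reactionChannels(st)
  expect_equal(ch$a[ch$kind == "bulk"], 6)

  # zero copies -> zero propensity
  st0 <- reactionNetwork(matrix(0L, 1, 3),
                         list(list(react = 0L, prod = 1L, k = 2)))
  expect_equal(reactionChannels(st0)$a, 0)

  # diffusion jump: a = D / h^2 * n per adjacent face
  st2 <- reactionNetwork(matrix(c(10L, rep(0L, 23)), 8, 3), box = 1000,
                         D = c(2.5e6, 0, 0))
  ch2 <- reactionChannels(st2)
  out <- ch2[ch2$kind == "diffusion" & ch2$compartment == 0 & ch2$a > 0, ]
  expect_equal(nrow(out), 3) # 3 faces out of a corner compartment
  expect_equal(out$a, rep(2.5e6 / 500^2 * 10, 3))
  expect_equal(massActionPropensity("diffusion", 2.5e6, 10), 100)

  # bimolecular conversion used by the engine matches the reference law
  expect_equal(massActionPropensity("bimolecular", 11.6, 1, 1204, h = 500),
               11.6 * 1204 / (6.022e-7 * 500^3))
})

test_that("incrementally maintained propensities equal a fresh recomputation", {
  st <- generateFixture("random_network", seed = 8, n_fil = 8, box = 1500)
  runChemistry(st, n_mech = 200)
  ch <- reactionChannels(st)
  expect_equal(ch$a, ch$a_fresh, tolerance = 1e-12)
})

test_that("single-channel waiting times are exponential with mean 1/(k n)", {
  # A -> A keeps the propensity constant at k n = 6/s
  st <- reactionNetwork(matrix(c(3L, 0L, 0L), 1),
                        list(list(react = 0L, prod = 0L, k = 2)), seed = 11)
  ev <- runChemistry(st, max_events = 4000, record = TRUE)$events
  dt <- diff(ev$time)
  expect_equal(mean(dt), 1 / 6, tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(dt, "pexp", 6))
  expect_gt(ks$p.value, 0.01)
})

test_that("deterministic seeding reproduces the event sequence", {
  mk <- function() reactionNetwork(
    matrix(c(50L, 30L, 0L), 1),
    list(list(react = 0L, prod = 1L, k = 1.5),
         list(react = 1L, prod = 0L, k = 2)), seed = 42)
  e1 <- runChemistry(mk(), max_events = 500, record = TRUE)$events
  e2 <- runChemistry(mk(), max_events = 500, record = TRUE)$events
  expect_identical(e1, e2)
})

test_that("next-reaction method and direct method are indistinguishable", {
  # fixed 5-channel network
  counts <- matrix(c(80L, 60L, 40L), 1)
  rxns <- list(list(react = 0L, prod = 1L, k = 1.5),
               list(react = 1L, prod = 0L, k = 2.0),
               list(react = c(0L, 1L), prod = 2L, k = 3.0),
               list(react = 2L, prod = 0L, k = 0.7),
               list(react = 2L, prod = 1L, k = 0.5))
  run <- function(alg, seed) {
    st <- reactionNetwork(counts, rxns, algorithm = alg, seed = seed)
    runChemistry(st, max_events = 10000, record = TRUE)$events
  }
  eN <- run("nrm", 7)
  eD <- run("direct", 13)
  expect_equal(nrow(eN), 10000)
  ks <- suppressWarnings(stats::ks.test(diff(eN$time), diff(eD$time)))
  expect_gt(ks$p.value, 0.01)
  tabN <- table(eN$channel)
  tabD <- table(eD$channel)
  expect_equal(names(tabN), names(tabD))
  cs <- suppressWarnings(stats::chisq.test(rbind(tabN, tabD)))
  expect_gt(cs$p.value, 0.01)
  # two channels with a1 = 1, a2 = 3: the faster fires ~3/4 of the time
  st <- reactionNetwork(matrix(c(1L, 0L, 0L), 1),
                        list(list(react = 0L, prod = 0L, k = 1),
                             list(react = 0L, prod = 0L, k = 3)), seed = 5)
  ev <- runChemistry(st, max_events = 10000, record = TRUE)$events
  frac <- mean(ev$channel == 1)
  expect_equal(frac, 0.75, tolerance = 0.03)
})

test_that("diffusion alone relaxes to uniform occupancy and conserves copies", {
  st <- reactionNetwork(matrix(c(1000L, rep(0L, 23)), 8, 3), box = 1000,
                        D = c(2.5e6, 0, 0), seed = 3)
  runChemistry(st, t_stop = 1)
  acc <- matrix(0, 8, 20)
  for (k in 1:20) {
    runChemistry(st, t_stop = 1 + 0.25 * k)
    acc[, k] <- getSpeciesCounts(st)[, 1]
  }
  expect_equal(sum(acc[, 20]), 1000) # conservation
  perComp <- rowMeans(acc)
  sigma <- sqrt(1000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(perComp - 125) < 3 * sigma))
})

test_that("polymerization lengthens a filament by 2.7 nm and consumes actin", {
  st <- quietFilament(c(40L, 20L),  # partially filled tip cylinder
                      chemistry = list(k_poly_minus = 0, k_depoly_plus = 0,
                                       k_depoly_minus = 0, k_poly_plus = 50))
  counts <- matrix(0L, prod(st$dims), 3)
  counts[, 1] <- 50L
  setSpeciesCounts(st, counts)
  registerBindings(st)
  a0 <- totalActin(st)
  len0 <- sum(networkSnapshot(st)$filaments[[1]]$nmono) * 2.7
  runChemistry(st, n_mech = 1)
  fr <- networkSnapshot(st)
  expect_equal(sum(fr$filaments[[1]]$nmono) * 2.7, len0 + 2.7)
  expect_equal(sum(fr$species[, 1]), 50L * prod(st$dims) - 1L)
  expect_equal(totalActin(st), a0) # conserved overall
  # geometry: bead separation of the tip also grew by 2.7
  b <- fr$filaments[[1]]$beads
  tipLen <- sqrt(sum((b[nrow(b), ] - b[nrow(b) - 1, ])^2))
  expect_equal(tipLen, 20 * 2.7 + 2.7, tolerance = 1e-9)
})

test_that("a full tip cylinder is promoted and a fresh tip appears", {
  st <- quietFilament(c(40L, 40L),  # both cylinders full
                      chemistry = list(k_poly_minus = 0, k_depoly_plus = 0,
                                       k_depoly_minus = 0, k_poly_plus = 50))
  counts <- matrix(0L, prod(st$dims), 3)
  counts[, 1] <- 50L
  setSpeciesCounts(st, counts)
  registerBindings(st)
  runChemistry(st, n_mech = 1)
  nm <- networkSnapshot(st)$filaments[[1]]$nmono
  expect_equal(nm, c(40L, 40L, 1L))
})

test_that("a motor step advances the bound position by 6 nm toward the plus end", {
  st <- newNetworkState(2000, 500, boundary = list(eps = 0),
                        chemistry = list(d_actin = 0, d_linker = 0, d_motor = 0,
                                         k_poly_plus = 0, k_poly_minus = 0,
                                         k_depoly_plus = 0, k_depoly_minus = 0,
                                         k_off_motor = 0, v0_walk = 10),
                        seed = 4)
  ctr <- c(1000, 1000, 1000)
  f1 <- addFilament(st, rbind(ctr + c(-108, 0, 0), ctr, ctr + c(108, 0, 0)),
                    c(40L, 40L))
  f2 <- addFilament(st, rbind(ctr + c(-108, 190, 0), ctr + c(0, 190, 0),
                              ctr + c(108, 190, 0)), c(40L, 40L))
  cytomech:::cmAddBoundElement(st$ptr, "motor", f1, 40.5, f2, 40.5, 20L)
  registerBindings(st)
  el0 <- networkSnapshot(st)$elements
  runChemistry(st, n_mech = 1)
  el1 <- networkSnapshot(st)$elements
  moved <- (el1$posA - el0$posA) + (el1$posB - el0$posB)
  expect_equal(moved, 6) # exactly one end stepped by d_step = 6 nm
  expect_true(all(el1$posA >= el0$posA) && all(el1$posB >= el0$posB))
  # on a 108 nm cylinder this is a fractional advance of 6/108 = 1/18
  sites <- enumerateBindingSites(st, f1)
  expect_equal(6 / 108, 1 / 18)
})

test_that("unbinding releases the species into the local compartment", {
  st <- newNetworkState(2000, 500, boundary = list(eps = 0),
                        chemistry = list(d_actin = 0, d_linker = 0, d_motor = 0,
                                         k_poly_plus = 0, k_poly_minus = 0,
                                         k_depoly_plus = 0, k_depoly_minus = 0,
                                         v0_walk = 0, k_off_motor = 10),
                        mechanochemistry = list(enabled = FALSE), seed = 4)
  ctr <- c(1000, 1000, 1000)
  f1 <- addFilament(st, rbind(ctr + c(-54, 0, 0), ctr + c(54, 0, 0)), 40L)
  f2 <- addFilament(st, rbind(ctr + c(-54, 190, 0), ctr + c(54, 190, 0)), 40L)
  cytomech:::cmAddBoundElement(st$ptr, "motor", f1, 40.5, f2, 40.5, 20L)
  registerBindings(st)
  ch <- reactionChannels(st)
  expect_equal(sum(ch$kind == "motor_unbind"), 1) # exactly one unbind channel
  m0 <- sum(getSpeciesCounts(st)[, 3])
  runChemistry(st, n_mech = 1)
  expect_equal(sum(getSpeciesCounts(st)[, 3]), m0 + 1)
  expect_equal(nrow(networkSnapshot(st)$elements), 0)
})

test_that("binding channels appear when filaments move into range", {
  st <- newNetworkState(2000, 500, boundary = list(eps = 0), seed = 1)
  ctr <- c(1000, 1000, 1000)
  addFilament(st, rbind(ctr + c(-54, 0, 0), ctr + c(54, 0, 0)), 40L)
  f2 <- addFilament(st, rbind(ctr + c(-54, 100, 0), ctr + c(54, 100, 0)), 40L)
  counts <- matrix(2L, prod(st$dims), 3)
  setSpeciesCounts(st, counts)
  registerBindings(st)
  ch0 <- reactionChannels(st)
  expect_equal(sum(ch0$kind == "linker_bind"), 0) # 100 nm: out of window
  bp <- cytomech:::cmBeadPositions(st$ptr)
  shift <- bp$pos
  shift[3:4, 2] <- shift[3:4, 2] - 65 # bring second filament to 35 nm
  cytomech:::cmSetBeadPositions(st$ptr, bp$bead, shift)
  registerBindings(st)
  ch1 <- reactionChannels(st)
  expect_gt(sum(ch1$kind == "linker_bind"), 0)
})

test_that("depolymerization releases out-of-range bound elements", {
  st <- quietFilament(rep(40L, 3),
                      chemistry = list(k_poly_plus = 0, k_poly_minus = 0,
                                       k_depoly_minus = 0, k_depoly_plus = 30,
                                       v0_walk = 0, k_off_linker = 0))
  fil <- attr(st, "filament")
  # anchor a linker at the last site (contour 310.5 of 324)
  cytomech:::cmAddBoundElement(st$ptr, "linker", fil, 13.5, fil, 310.5, 0L)
  registerBindings(st)
  l0 <- sum(getSpeciesCounts(st)[, 2])
  runChemistry(st, n_mech = 8) # shrink plus end by 21.6 nm
  expect_equal(nrow(networkSnapshot(st)$elements), 0) # forced unbinding
  expect_equal(sum(getSpeciesCounts(st)[, 2]), l0 + 1)
  expect_equal(sum(reactionChannels(st)$kind == "linker_unbind"), 0)
})

test_that("total actin is conserved through mixed event sequences", {
  st <- generateFixture("random_network", seed = 12, n_fil = 10, box = 1500)
  a0 <- totalActin(st)
  for (k in 1:5) {
    runChemistry(st, n_mech = 100)
    registerBindings(st)
    expect_equal(totalActin(st), a0)
  }
})

test_that("engines stay live and agree under heavy channel churn", {
  # dynamic bind/unbind churn creates and destroys channels constantly;
  # a stale priority-queue entry would silently stall the event flow
  run <- function(alg, seed) {
    st <- newNetworkState(2000, 500, boundary = list(eps = 0),
                          chemistry = list(d_actin = 0, d_linker = 0,
                                           d_motor = 1e5, k_poly_plus = 0,
                                           k_poly_minus = 0, k_depoly_plus = 0,
                                           k_depoly_minus = 0, v0_walk = 0,
                                           k_on_motor = 50, k_off_motor = 5),
                          mechanochemistry = list(enabled = FALSE),
                          flags = list(algorithm = alg), seed = seed)
    ctr <- c(1000, 1000, 1000)
    addFilament(st, rbind(ctr + c(-108, 0, 0), ctr, ctr + c(108, 0, 0)),
                c(40L, 40L))
    addFilament(st, rbind(ctr + c(-108, 190, 0), ctr + c(0, 190, 0),
                          ctr + c(108, 190, 0)), c(40L, 40L))
    counts <- matrix(0L, prod(st$dims), 3)
    counts[, 3] <- 2L
    setSpeciesCounts(st, counts)
    registerBindings(st)
    r <- runChemistry(st, t_stop = 40, record = TRUE)
    ev <- r$events[r$events$kind %in% c("motor_bind", "motor_unbind"), ]
    list(n = nrow(ev), tlast = max(r$events$time))
  }
  for (alg in c("nrm", "direct")) {
    res <- run(alg, 3)
    expect_gt(res$tlast, 39)  # events keep flowing to the end
    expect_gt(res$n, 50)
  }
  nN <- mean(vapply(1:3, function(s) run("nrm", s)$n, numeric(1)))
  nD <- mean(vapply(4:6, function(s) run("direct", s)$n, numeric(1)))
  expect_lt(abs(nN - nD) / nD, 0.25) # same churn statistics
})

test_that("with all propensities zero the engine reports no event", {
  for (alg in c("nrm", "direct")) {
    st <- reactionNetwork(matrix(0L, 1, 3),
                          list(list(react = 0L, prod = 1L, k = 2)),
                          algorithm = alg)
    r <- runChemistry(st, t_stop = 5, record = TRUE)
    expect_equal(r$n_events, 0)
    expect_equal(r$time, 5) # time advances to the stop point, no event
  }
})
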