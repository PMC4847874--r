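test_that("Brownian ratchet multiplier is exp(-F delta / kBT)", {
  p <- defaultMechanochemistry()
  expect_equal(ratchetMultiplier(0, p), 1)
  Fk <- p$kBT / p$ratchet_delta # F delta = kBT
  expect_equal(ratchetMultiplier(Fk, p), exp(-1))
  Fs <- seq(0, 40, by = 0.5)
  expect_true(all(diff(ratchetMultiplier(Fs, p)) < 0)) # strictly decreasing
  expect_true(all(ratchetMultiplier(Fs, p) > 0))
})

test_that("slip-bond multiplier is exp(+F x_slip / kBT)", {
  p <- defaultMechanochemistry()
  expect_equal(slipMultiplier(0, p), 1)
  Fk <- p$kBT / p$x_slip
  expect_equal(slipMultiplier(Fk, p), exp(1))
  # doubling the force squares the multiplier
  expect_equal(slipMultiplier(2 * Fk, p), slipMultiplier(Fk, p)^2)
})

test_that("motor ensemble rates: stall, catch-like unbinding, 5 s attachment", {
  p <- defaultMechanochemistry()
  r0 <- motorRates(0, n_heads = 20, params = p)
  expect_equal(r0$walk_rate, 15)
  expect_equal(1 / r0$unbind_rate, 5) # unloaded attachment time
  f_stall <- 20 * p$f_stall_per_head
  expect_equal(motorRates(f_stall, n_heads = 20, params = p)$walk_rate, 0)
  Fs <- seq(0, 60, by = 1)
  ub <- motorRates(Fs, n_heads = 20, params = p)$unbind_rate
  expect_true(all(diff(ub) < 0)) # attachment strengthens under load
  expect_true(all(ub > 0))
})

test_that("engine multipliers match the closed-form laws after equilibration", {
  st <- newNetworkState(2000, 500, boundary = list(eps = 0),
                        forcefield = list(k_vol = 0), seed = 2)
  ctr <- c(1000, 1000, 1000)
  f1 <- addFilament(st, rbind(ctr + c(-54, 0, 0), ctr + c(54, 0, 0)), 40L)
  # linker stretched beyond its 35 nm rest length -> tension -> slip factor
  f2 <- addFilament(st, rbind(ctr + c(-54, 50, 0), ctr + c(54, 50, 0)), 40L)
  cytomech:::cmAddBoundElement(st$ptr, "linker", f1, 40.5, f2, 40.5, 0L)
  up <- updateReactionRates(st)
  el <- up$elements
  p <- defaultMechanochemistry()
  Fexp <- 8 * (50 - 35) # K_linker (d - l0)
  expect_equal(el$load, Fexp)
  expect_equal(el$mult_unbind, slipMultiplier(Fexp, p))
  # unbind channel propensity carries the multiplier
  registerBindings(st)
  ch <- reactionChannels(st)
  a <- ch$a[ch$kind == "linker_unbind"]
  expect_equal(a, 0.3 * slipMultiplier(Fexp, p))
})

test_that("disabling mechanochemistry pins every multiplier to one", {
  st <- newNetworkState(2000, 500, boundary = list(eps = 0),
                        mechanochemistry = list(enabled = FALSE), seed = 2)
  ctr <- c(1000, 1000, 1000)
  f1 <- addFilament(st, rbind(ctr + c(-54, 0, 0), ctr + c(54, 0, 0)), 40L)
  f2 <- addFilament(st, rbind(ctr + c(-54, 60, 0), ctr + c(54, 60, 0)), 40L)
  cytomech:::cmAddBoundElement(st$ptr, "linker", f1, 40.5, f2, 40.5, 0L)
  cytomech:::cmAddBoundElement(st$ptr, "motor", f1, 67.5, f2, 67.5, 20L)
  up <- updateReactionRates(st)
  expect_true(all(up$elements$mult_unbind == 1))
  expect_true(all(up$elements$mult_walk_a == 1))
  expect_true(all(up$filaments$poly_mult == 1))
  # force-independent kinetics: channel propensities equal the base rates
  registerBindings(st)
  ch <- reactionChannels(st)
  expect_equal(ch$a[ch$kind == "linker_unbind"], 0.3)
  expect_equal(ch$a[ch$kind == "motor_unbind"], 0.2)
})

test_that("a loaded filament tip polymerizes more slowly (ratchet in engine)", {
  # filament grown against the wall: compressive tip load
  st <- newNetworkState(1000, 500, seed = 3,
                        boundary = list(eps = 100, lambda = 2.7))
  # plus end 2.5 nm from the wall: compressive boundary load on the tip
  addFilament(st, rbind(c(889.5, 500, 500), c(997.5, 500, 500)), 40L)
  up <- updateReactionRates(st)
  pm <- up$filaments$poly_mult
  expect_lt(pm, 1)
  expect_gt(pm, 0)
})
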