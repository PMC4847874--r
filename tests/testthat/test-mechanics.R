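test_that("stretching energy is harmonic with equal and opposite end forces", {
  r <- stretchingEnergy(c(0, 0, 0), c(108, 0, 0), 100, 108)
  expect_equal(r$U, 0)
  expect_equal(max(abs(r$grad)), 0)
  r2 <- stretchingEnergy(c(0, 0, 0), c(109, 0, 0), 2, 108)
  expect_equal(r2$U, 1)            # 1/2 K dl^2 = 0.5 * 2 * 1
  expect_equal(r2$grad[2, 1], 2)   # |F| = K dl
  expect_equal(r2$grad[1, 1], -2)
  set.seed(1)
  x <- rnorm(6, sd = 40)
  g <- fdGradient(function(p) stretchingEnergy(p[1:3], p[4:6], 7, 60)$U, x)
  ga <- as.vector(t(stretchingEnergy(x[1:3], x[4:6], 7, 60)$grad))
  expect_lt(max(abs(g - ga)) / max(abs(g)), 1e-6)
})

test_that("bending energy follows eps(1 - cos theta)", {
  expect_equal(bendingEnergy(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 380)$U, 0)
  expect_equal(bendingEnergy(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), 5)$U, 5)
  expect_equal(bendingEnergy(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), 380)$U,
               380 * (1 - sqrt(2) / 2))
  set.seed(2)
  x <- c(0, 0, 0, 90, 10, -20, 150, 80, 40) + rnorm(9, sd = 5)
  g <- fdGradient(function(p) bendingEnergy(p[1:3], p[4:6], p[7:9], 380)$U, x)
  ga <- as.vector(t(bendingEnergy(x[1:3], x[4:6], x[7:9], 380)$grad))
  expect_lt(max(abs(g - ga)) / max(abs(g)), 1e-6)
})

test_that("excluded volume matches quadrature, symmetry and the far-field law", {
  skip_if_not_installed("pracma")
  xi1 <- c(0, 0, 0); xi2 <- c(100, 10, -5)
  xj1 <- c(20, 45, 30); xj2 <- c(95, 80, 55)
  ev <- excludedVolumeEnergy(xi1, xi2, xj1, xj2, 280)
  expect_equal(ev$U, evQuadrature(xi1, xi2, xj1, xj2, 280), tolerance = 1e-6)
  # argument swap: identical energy, swapped gradients
  ev2 <- excludedVolumeEnergy(xj1, xj2, xi1, xi2, 280)
  expect_equal(ev2$U, ev$U, tolerance = 1e-12)
  expect_equal(ev2$grad, ev$grad[c(3, 4, 1, 2), ], tolerance = 1e-10)
  # net force of an isolated pair vanishes
  expect_lt(max(abs(colSums(ev$grad))), 1e-8 * max(abs(ev$grad)))
  # far-separated short segments: U -> K L_i L_j / d^4
  a1 <- c(0, 0, 0); a2 <- c(4, 0.5, 0.2)
  b1 <- c(2, 300, 5); b2 <- c(3, 301, 9)
  Li <- sqrt(sum((a2 - a1)^2)); Lj <- sqrt(sum((b2 - b1)^2))
  d <- sqrt(sum(((a1 + a2) / 2 - (b1 + b2) / 2)^2))
  U <- excludedVolumeEnergy(a1, a2, b1, b2, 280)$U
  expect_equal(U, 280 * Li * Lj / d^4, tolerance = 1e-3)
  # softened kernel equals quadrature of 1/(r^2 + r0^2)^2
  Us <- excludedVolumeEnergy(xi1, xi2, xj1, xj2, 280, r_soft = 2)
  expect_equal(Us$U, evQuadrature(xi1, xi2, xj1, xj2, 280, r_soft = 2),
               tolerance = 1e-6)
})

test_that("excluded-volume gradients match finite differences, incl. skew 60 deg", {
  th <- 60 * pi / 180
  xi1 <- c(-80, 0, 0); xi2 <- c(80, 0, 0)
  xj1 <- c(-80 * cos(th), -80 * sin(th), 30)
  xj2 <- c(80 * cos(th), 80 * sin(th), 30)
  ev <- excludedVolumeEnergy(xi1, xi2, xj1, xj2, 280)
  expect_equal(ev$U, evQuadrature(xi1, xi2, xj1, xj2, 280), tolerance = 1e-6)
  pts <- c(xi1, xi2, xj1, xj2)
  g <- fdGradient(function(p)
    excludedVolumeEnergy(p[1:3], p[4:6], p[7:9], p[10:12], 280)$U, pts,
    h = 1e-3)
  ga <- as.vector(t(ev$grad))
  expect_lt(max(abs(g - ga)) / max(abs(g)), 1e-5)
  # degenerate configuration (exactly intersecting axes): finite result
  dg <- excludedVolumeEnergy(c(-50, 0, 0), c(50, 0, 0),
                             c(0, -50, 0), c(0, 50, 0), 280)
  expect_true(is.finite(dg$U) && all(is.finite(dg$grad)))
  # exactly parallel support lines: finite via documented perturbation
  pp <- excludedVolumeEnergy(c(0, 0, 0), c(100, 0, 0),
                             c(0, 30, 0), c(100, 30, 0), 280)
  expect_true(is.finite(pp$U) && all(is.finite(pp$grad)))
})

test_that("branching junction energy vanishes at equilibrium and obeys FD", {
  p <- list(theta0 = 70 * pi / 180, phi0 = 0, d0 = 6)
  th <- 70 * pi / 180
  xi1 <- c(0, 0, 0); xi2 <- c(108, 0, 0)
  xib <- c(54, 0, 0)
  td <- 110 * pi / 180 # tether in-plane beyond the branch angle: phi = 0
  base <- xib + 6 * c(cos(td), sin(td), 0)
  dend <- base + 108 * c(cos(th), sin(th), 0)
  U0 <- branchingEnergy(xi1, xi2, 0.5, base, dend, p)$U
  # stretch and angle vanish; the dihedral is 0 here by plane alignment
  expect_lt(U0, 1e-9)
  set.seed(3)
  xs <- c(0, 0, 0, 100, 10, -5, 20, 40, 30, 60, 120, 80) + rnorm(12, sd = 3)
  pr <- list(theta0 = 70 * pi / 180, phi0 = 0.3)
  g <- fdGradient(function(q)
    branchingEnergy(q[1:3], q[4:6], 0.37, q[7:9], q[10:12], pr)$U, xs,
    h = 1e-5)
  ga <- as.vector(t(branchingEnergy(xs[1:3], xs[4:6], 0.37, xs[7:9],
                                    xs[10:12], pr)$grad))
  expect_lt(max(abs(g - ga)) / max(abs(g)), 1e-5)
})

test_that("bond energy uses the lever rule at fractional positions", {
  r <- bondEnergy(c(0, 0, 0), c(108, 0, 0), c(0, 35, 0), c(108, 35, 0),
                  0.5, 0.5, 8, 35)
  expect_equal(r$U, 0)
  # stretched bond at alpha = 0.5: each endpoint takes half the bond force
  r2 <- bondEnergy(c(0, 0, 0), c(108, 0, 0), c(0, 50, 0), c(108, 50, 0),
                   0.5, 0.5, 2.5, 35)
  Fbond <- 2.5 * 15
  expect_equal(r2$grad[3, 2], Fbond / 2)
  expect_equal(r2$grad[4, 2], Fbond / 2)
  expect_equal(r2$grad[1, 2], -Fbond / 2)
  set.seed(4)
  xs <- rnorm(12, sd = 50)
  al <- 0.3; be <- 0.8
  g <- fdGradient(function(q)
    bondEnergy(q[1:3], q[4:6], q[7:9], q[10:12], al, be, 8, 35)$U, xs)
  ga <- as.vector(t(bondEnergy(xs[1:3], xs[4:6], xs[7:9], xs[10:12],
                               al, be, 8, 35)$grad))
  expect_lt(max(abs(g - ga)) / max(abs(g)), 1e-6)
})

test_that("boundary repulsion is exponential in the wall distance", {
  box <- c(1000, 1000, 1000)
  atWall <- boundaryEnergy(c(0, 500, 500), c(108, 500, 500), box,
                           eps = 100, lambda = 2.7)
  expect_equal(atWall$U, 100)                      # d = 0
  atLambda <- boundaryEnergy(c(2.7, 500, 500), c(110, 500, 500), box,
                             eps = 100, lambda = 2.7)
  expect_equal(atLambda$U, 100 / exp(1))           # d = lambda
  # gradient magnitude U / lambda at any distance
  expect_equal(sqrt(sum(atLambda$grad[1, ]^2)), atLambda$U / 2.7)
  # strictly decreasing in d
  ds <- seq(0, 20, by = 1)
  us <- vapply(ds, function(d)
    boundaryEnergy(c(d, 500, 500), c(400, 500, 500), box)$U, numeric(1))
  expect_true(all(diff(us) < 0))
})

test_that("assembled forces equal minus the finite-difference total gradient", {
  st <- generateFixture("random_network", seed = 5, n_fil = 6, box = 1500)
  cytomech:::cmAddBoundElement(st$ptr, "linker", 0, 40.5, 1, 67.5, 0L)
  cytomech:::cmAddBoundElement(st$ptr, "motor", 2, 13.5, 3, 40.5, 20L)
  f <- networkForces(st)
  bp <- cytomech:::cmBeadPositions(st$ptr)
  set.seed(6)
  sel <- sample(seq_along(bp$bead), 20)
  for (i in sel) {
    for (k in 1:3) {
      h <- 1e-4
      pp <- bp$pos; pp[i, k] <- pp[i, k] + h
      cytomech:::cmSetBeadPositions(st$ptr, bp$bead, pp)
      Up <- networkEnergy(st)$total
      pp[i, k] <- pp[i, k] - 2 * h
      cytomech:::cmSetBeadPositions(st$ptr, bp$bead, pp)
      Um <- networkEnergy(st)$total
      cytomech:::cmSetBeadPositions(st$ptr, bp$bead, bp$pos)
      gfd <- (Up - Um) / (2 * h)
      expect_lt(abs(-gfd - f$force[i, k]),
                1e-5 * max(abs(f$force)) + 1e-6)
    }
  }
})

test_that("energy is invariant under global translation and rotation", {
  st <- generateFixture("random_network", seed = 9, n_fil = 5, box = 1500,
                        forcefield = list())
  # boundary off for the symmetry check
  st2 <- generateFixture("random_network", seed = 9, n_fil = 5, box = 1500,
                         boundary = list(eps = 0))
  U0 <- networkEnergy(st2)$total
  bp <- cytomech:::cmBeadPositions(st2$ptr)
  cytomech:::cmSetBeadPositions(st2$ptr, bp$bead,
                                sweep(bp$pos, 2, c(13, -7, 21), "+"))
  expect_equal(networkEnergy(st2)$total, U0, tolerance = 1e-10)
  # net force ~ 0 (translational symmetry)
  f <- networkForces(st2)
  expect_lt(max(abs(colSums(f$force))), 1e-6 * max(abs(f$force)))
  # rotation about the box center
  th <- 0.37
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- matrix(rep(c(750, 750, 750), each = nrow(bp$pos)), ncol = 3)
  rot <- t(Rz %*% t(bp$pos - ctr)) + ctr
  cytomech:::cmSetBeadPositions(st2$ptr, bp$bead, rot)
  expect_equal(networkEnergy(st2)$total, U0, tolerance = 1e-9)
})

test_that("minimization relaxes a pre-stretched cylinder to l0", {
  st <- newNetworkState(2000, 500, boundary = list(eps = 0), seed = 1)
  addFilament(st, rbind(c(700, 1000, 1000), c(830, 1000, 1000)), 40L)
  r <- equilibrate(st, 0.5, 2000)
  expect_true(r$converged)
  expect_lte(r$max_force, 0.5)
  b <- networkSnapshot(st)$filaments[[1]]$beads
  expect_equal(sqrt(sum((b[2, ] - b[1, ])^2)), 108, tolerance = 1e-2)
  expect_true(all(diff(r$energy_trace) <= 1e-9))
})

test_that("minimization separates overlapping filaments monotonically", {
  st <- generateFixture("crossing_pair", gap_nm = 15)
  e0 <- networkEnergy(st)$exclvol
  fr0 <- networkSnapshot(st)
  gap0 <- min(abs(fr0$filaments[[2]]$beads[, 3] - 1000))
  r <- suppressWarnings(equilibrate(st, 0.5, 3000))
  expect_true(all(diff(r$energy_trace) <= 1e-9)) # never increases
  expect_lt(r$U1, r$U0)
  expect_lt(networkEnergy(st)$exclvol, e0)
})

test_that("an isolated branch junction relaxes to the 70 degree angle", {
  st <- generateFixture("branch_junction", angle_deg = 30)
  r <- equilibrate(st, 0.01, 30000)
  expect_true(r$converged)
  expect_equal(branchAngle(st), 70, tolerance = 0.01)
  expect_lt(r$U1, 1e-3)
})

test_that("sphere and capsule boundaries use the correct wall distance", {
  # sphere of diameter 1000 centered at (500,500,500)
  s <- boundaryEnergy(c(500, 500, 500), c(700, 500, 500), rep(1000, 3),
                      shape = "sphere", eps = 100, lambda = 2.7)
  # nearer endpoint is at r = 200 -> d = 300
  expect_equal(s$U, 100 * exp(-300 / 2.7))
  # capsule box (1000, 500, 500): radius 250, axis along x at y = z = 250
  cpo <- boundaryEnergy(c(500, 250, 250), c(500, 350, 250),
                        c(1000, 500, 500), shape = "capsule",
                        eps = 100, lambda = 50)
  # nearer endpoint (500,350,250) is 100 off-axis -> d = 150
  expect_equal(cpo$U, 100 * exp(-150 / 50))
})
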