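test_that("radius of gyration matches direct evaluation", {
  # coincident points
  expect_equal(radiusOfGyration(matrix(rep(c(1, 2, 3), 5), 5, byrow = TRUE)), 0)
  # two points at +/- a on an axis -> Rg = a
  expect_equal(radiusOfGyration(rbind(c(-7, 0, 0), c(7, 0, 0))), 7)
  # four printed toy points against hand evaluation of the formula
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 10))
  ctr <- colMeans(pts)
  expected <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
  expect_equal(radiusOfGyration(pts), expected)
  expect_equal(radiusOfGyration(pts), 8.29156, tolerance = 1e-4)
  # translation invariance, linear scaling under dilation
  expect_equal(radiusOfGyration(sweep(pts, 2, c(5, -3, 11), "+")), expected)
  expect_equal(radiusOfGyration(pts * 3.5), 3.5 * expected)
  # frame interface: computed over cylinder midpoints
  st <- generateFixture("bundle_parallel", n_fil = 4)
  fr <- networkSnapshot(st)
  expect_equal(radiusOfGyration(fr), radiusOfGyration(cylinderMidpoints(fr)))
  expect_error(radiusOfGyration(matrix(numeric(0), 0, 3)), "empty")
})

test_that("order parameter: aligned gives 1, exact isotropy gives 0", {
  aligned <- matrix(rep(c(1, 2, 2) / 3, 20), 20, byrow = TRUE)
  expect_equal(orderParameter(aligned)$S, 1, tolerance = 1e-12)
  iso <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  opI <- orderParameter(iso)
  expect_equal(opI$S, 0, tolerance = 1e-12)
  expect_equal(max(abs(opI$Q)), 0, tolerance = 1e-12)
  # half along x, half along y -> eigenvalues (1/4, 1/4, -1/2)
  half <- rbind(matrix(rep(c(1, 0, 0), 10), 10, byrow = TRUE),
                matrix(rep(c(0, 1, 0), 10), 10, byrow = TRUE))
  expect_equal(orderParameter(half)$S, 0.25, tolerance = 1e-12)
})

test_that("Q is symmetric traceless; S invariant to rotation and u -> -u", {
  set.seed(7)
  for (rep in 1:5) {
    u <- matrix(rnorm(3 * 30), 30)
    u <- u / sqrt(rowSums(u^2))
    op <- orderParameter(u)
    expect_lt(abs(sum(diag(op$Q))), 1e-10)
    expect_equal(op$Q, t(op$Q), tolerance = 1e-12)
    # flip random subset of directions
    fl <- sample(c(-1, 1), 30, replace = TRUE)
    expect_equal(orderParameter(u * fl)$S, op$S, tolerance = 1e-12)
    # random rotation (QR of a gaussian matrix)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(orderParameter(u %*% t(Q))$S, op$S, tolerance = 1e-10)
  }
})

test_that("MSD exponent recovers known scaling laws", {
  # exact power laws through the fitting path
  for (nu in c(0.5, 1, 1.5, 2)) {
    msd <- data.frame(lag = seq(1, 50, by = 1))
    msd$msd <- 3.7 * msd$lag^nu
    est <- msdExponent(msd)
    expect_equal(est$nu, nu, tolerance = 1e-10)
  }
  # ballistic synthetic trajectory: x = v t -> nu = 2
  times <- seq(0, 20, by = 1)
  set.seed(1)
  vel <- matrix(rnorm(3 * 12), 12)
  mk <- function(fun) {
    frames <- lapply(times, function(t)
      frameFromCenters(fun(t), t = t))
    tr <- list(frames = frames, times = times,
               config = list(protocol = list(pre_growth = 0)))
    class(tr) <- "cmTrajectory"
    tr
  }
  ball <- mk(function(t) 1000 + vel * t * 10)
  estB <- msdExponent(ball, t_min = 0)
  expect_equal(estB$nu, 2, tolerance = 1e-6)
  # pure random walk -> nu ~ 1 within 3 standard errors
  set.seed(42)
  nfil <- 60
  steps <- array(rnorm(3 * nfil * length(times), sd = 12),
                 c(nfil, 3, length(times)))
  pos <- apply(steps, c(1, 2), cumsum) # time x fil x 3
  rw <- mk(function(t) {
    k <- which(times == t)
    1e5 + matrix(pos[k, , ], nfil, 3)
  })
  estR <- msdExponent(rw, t_min = 0, fit_window_s = 10)
  expect_lt(abs(estR$nu - 1), 3 * estR$stderr + 0.1)
})

test_that("polarity metrics separate polar and antiparallel bundles", {
  stp <- generateFixture("bundle_parallel", n_fil = 6)
  pm <- polarityMetrics(networkSnapshot(stp))
  cl <- attr(pm, "clusters")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$polarity_fraction, 1)
  sta <- generateFixture("bundle_antiparallel", n_fil = 6)
  pma <- polarityMetrics(networkSnapshot(sta))
  expect_equal(attr(pma, "clusters")$polarity_fraction, 0.5)
})

test_that("cluster assignment agrees with a brute-force transitive closure", {
  # three separated parallel bundles
  st <- newNetworkState(4000, 1000, boundary = list(eps = 0), seed = 1)
  offs <- list(c(500, 500, 500), c(2500, 500, 500), c(1500, 2600, 500))
  for (o in offs)
    for (i in 1:3)
      addFilament(st, rbind(o + c(-108, 35 * i, 0), o + c(0, 35 * i, 0),
                            o + c(108, 35 * i, 0)), c(40L, 40L))
  fr <- networkSnapshot(st)
  pm <- polarityMetrics(fr)
  expect_equal(nrow(attr(pm, "clusters")), 3)
  # oracle: adjacency by thresholds, closure via boolean matrix powers
  u <- filamentDirections(fr)
  mids <- lapply(fr$filaments, function(f) {
    b <- f$beads
    (b[-nrow(b), , drop = FALSE] + b[-1, , drop = FALSE]) / 2
  })
  n <- length(mids)
  adj <- diag(n) > 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dmin <- min(as.matrix(stats::dist(rbind(mids[[i]], mids[[j]])))[
      seq_len(nrow(mids[[i]])), -seq_len(nrow(mids[[i]]))])
    ok <- dmin < 64 && abs(sum(u[i, ] * u[j, ])) > 0.9
    adj[i, j] <- adj[j, i] <- ok
  }
  reach <- adj
  for (k in 1:n) reach <- reach | (reach %*% reach) > 0
  oracle <- match(apply(reach, 1, paste, collapse = ""),
                  unique(apply(reach, 1, paste, collapse = "")))
  expect_equal(as.integer(factor(pm$cluster)), oracle)
})
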