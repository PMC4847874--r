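# central-difference gradient of a scalar function of a coordinate vector
fdGradient <- function(f, x, h = 1e-4) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

relErr <- function(a, b) {
  s <- max(abs(a), abs(b), 1e-12)
  abs(a - b) / s
}

# adaptive 2-D quadrature of the (optionally softened) inverse-quartic pair
# kernel over both segments, arc-length measure
evQuadrature <- function(xi1, xi2, xj1, xj2, k_vol, r_soft = 0,
                         reltol = 1e-10) {
  u <- xi2 - xi1; v <- xj2 - xj1; c0 <- xi1 - xj1
  q <- pracma::integral2(function(t, s) {
    rx <- c0[1] + t * u[1] - s * v[1]
    ry <- c0[2] + t * u[2] - s * v[2]
    rz <- c0[3] + t * u[3] - s * v[3]
    (rx^2 + ry^2 + rz^2 + r_soft^2)^-2
  }, 0, 1, 0, 1, reltol = reltol)$Q
  k_vol * sqrt(sum(u^2)) * sqrt(sum(v^2)) * q
}

# inter-cylinder angle of the two-filament branch fixture, degrees
branchAngle <- function(state) {
  s <- networkSnapshot(state)
  bm <- s$filaments[[1]]$beads
  bd <- s$filaments[[2]]$beads
  um <- bm[2, ] - bm[1, ]
  ud <- bd[2, ] - bd[1, ]
  acos(sum(um * ud) / sqrt(sum(um^2) * sum(ud^2))) * 180 / pi
}

# assemble a minimal cmFrame from filament center positions (single
# zero-ish-length cylinders), for analysis-function tests
frameFromCenters <- function(centers, t = 0, dirs = NULL) {
  fil <- lapply(seq_len(nrow(centers)), function(i) {
    u <- if (is.null(dirs)) c(1, 0, 0) else dirs[i, ]
    list(id = i - 1L,
         beads = rbind(centers[i, ] - 2.7 * u, centers[i, ] + 2.7 * u),
         nmono = 2L, minus_abs = 0L)
  })
  fr <- list(time = t, filaments = fil,
             elements = data.frame(), species = matrix(0L, 1, 3))
  class(fr) <- "cmFrame"
  fr
}

# a single filament of the given monomer counts, centered in a quiet box
quietFilament <- function(nmono, seed = 1, chemistry = list(), ...) {
  st <- newNetworkState(4000, 500, boundary = list(eps = 0),
                        chemistry = modifyList(
                          list(d_actin = 0, d_linker = 0, d_motor = 0),
                          chemistry),
                        seed = seed, ...)
  ctr <- c(2000, 2000, 2000)
  n <- length(nmono)
  xs <- c(0, cumsum(nmono * 2.7))
  beads <- t(vapply(xs, function(x) ctr + c(x, 0, 0), numeric(3)))
  fid <- addFilament(st, beads, as.integer(nmono))
  attr(st, "filament") <- fid
  st
}

# closest distance between two segments (oracle-side reimplementation)
segDist <- function(p1, p2, q1, q2) {
  ts <- seq(0, 1, length.out = 41)
  m <- outer(ts, ts, Vectorize(function(t, s) {
    d <- (p1 + t * (p2 - p1)) - (q1 + s * (q2 - q1))
    sqrt(sum(d^2))
  }))
  min(m)
}
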