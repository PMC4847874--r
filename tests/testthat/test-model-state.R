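test_that("binding sites are spaced 27 nm from the minus end", {
  # 270 nm filament = 100 monomers -> 10 complete sites
  st <- quietFilament(c(40L, 40L, 20L))
  sites <- enumerateBindingSites(st, attr(st, "filament"))
  expect_equal(nrow(sites), 10)
  expect_equal(diff(sites$contour), rep(27, 9))
  expect_equal(sites$contour[1], 13.5)

  # shorter than one site spacing -> no complete site
  st2 <- quietFilament(9L) # 24.3 nm
  expect_equal(nrow(enumerateBindingSites(st2, attr(st2, "filament"))), 0)

  # one full 108 nm cylinder: midpoint-of-interval fractional positions
  st3 <- quietFilament(40L)
  s3 <- enumerateBindingSites(st3, attr(st3, "filament"))
  expect_equal(s3$frac, c(0.125, 0.375, 0.625, 0.875))
})

test_that("contour length equals monomer count times 2.7 nm at rest", {
  st <- quietFilament(c(40L, 40L, 13L))
  fr <- networkSnapshot(st)
  b <- fr$filaments[[1]]$beads
  seg <- sqrt(rowSums((b[-1, ] - b[-nrow(b), ])^2))
  expect_equal(sum(seg), 93 * 2.7, tolerance = 1e-12)
})

test_that("occupied binding sites stay put under minus-end polymerization", {
  st <- quietFilament(c(40L, 40L),
                      chemistry = list(k_poly_plus = 0, k_depoly_plus = 0,
                                       k_depoly_minus = 0, k_poly_minus = 50))
  fil <- attr(st, "filament")
  cytomech:::cmAddBoundElement(st$ptr, "linker", fil, 40.5, fil, 94.5, 0L)
  before <- enumerateBindingSites(st, fil)
  occ0 <- before$site[before$linker_bound]
  counts <- matrix(0L, prod(st$dims), 3)
  counts[, 1] <- 100L # G-actin available wherever the minus end wanders
  setSpeciesCounts(st, counts)
  registerBindings(st)
  runChemistry(st, n_mech = 10) # ten minus-end additions
  after <- enumerateBindingSites(st, fil)
  occ1 <- after$site[after$linker_bound]
  expect_equal(occ1, occ0) # same absolute site indices: no relocation
  # minus end grew by 27 nm, so the occupied site is 27 nm farther from it
  expect_equal(after$contour[match(occ0[1], after$site)] -
                 before$contour[match(occ0[1], before$site)], 27)
})

test_that("pair candidates respect binding windows and distinct filaments", {
  mk <- function(gap) {
    st <- newNetworkState(2000, 500, boundary = list(eps = 0), seed = 1)
    ctr <- c(1000, 1000, 1000)
    addFilament(st, rbind(ctr + c(-54, 0, 0), ctr + c(54, 0, 0)), 40L)
    addFilament(st, rbind(ctr + c(-54, gap, 0), ctr + c(54, gap, 0)), 40L)
    st
  }
  # two parallel single-cylinder filaments 35 nm apart
  st <- mk(35)
  pc <- pairCandidates(st)
  expect_gt(sum(pc$kind == "linker"), 0)
  expect_equal(sum(pc$kind == "motor"), 0) # max site distance ~88 nm < 175
  d <- pc$dist[pc$kind == "linker"]
  expect_true(all(d >= 30 - 1e-9 & d <= 40 + 1e-9))

  # 200 nm apart: motor candidates appear
  st2 <- mk(200)
  pc2 <- pairCandidates(st2)
  expect_gt(sum(pc2$kind == "motor"), 0)
  expect_equal(sum(pc2$kind == "linker"), 0)

  # sites on the same filament are never paired
  st3 <- quietFilament(rep(40L, 6)) # long filament, plenty of sites
  expect_equal(nrow(pairCandidates(st3)), 0)

  # no duplicated unordered pairs
  key <- apply(pc[, c("filA", "siteA", "filB", "siteB", "kind")], 1, paste,
               collapse = "/")
  expect_equal(anyDuplicated(key), 0)
})

test_that("pair candidates vanish when sites are occupied", {
  st <- newNetworkState(2000, 500, boundary = list(eps = 0), seed = 1)
  ctr <- c(1000, 1000, 1000)
  f1 <- addFilament(st, rbind(ctr + c(-54, 0, 0), ctr + c(54, 0, 0)), 40L)
  f2 <- addFilament(st, rbind(ctr + c(-54, 35, 0), ctr + c(54, 35, 0)), 40L)
  n0 <- nrow(pairCandidates(st, "linker"))
  cytomech:::cmAddBoundElement(st$ptr, "linker", f1, 13.5, f2, 13.5, 0L)
  n1 <- nrow(pairCandidates(st, "linker"))
  expect_lt(n1, n0)
})

test_that("compartment indexing uses half-open intervals and errors outside", {
  st <- newNetworkState(1000, 500, seed = 1)
  expect_equal(unname(compartmentOf(st, c(0, 0, 0))[1:3]), c(0L, 0L, 0L))
  expect_equal(unname(compartmentOf(st, c(500, 0, 0))[1:3]), c(1L, 0L, 0L))
  expect_equal(unname(compartmentOf(st, c(999, 999, 999))[1:3]), c(1L, 1L, 1L))
  expect_error(compartmentOf(st, c(1500, 0, 0)), "outside")
  expect_error(compartmentOf(st, c(-1, 0, 0)), "outside")
})
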