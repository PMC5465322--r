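test_that("greedy linking builds clean tracks and raises QC flags", {
  # one detection per frame drifting 2 um/frame: single unflagged track
  det <- data.frame(frame = 0:10, x = 2 * (0:10), y = 0, z = 0, area = 50)
  lk <- linkTracks(det, layer = "DCL")
  expect_equal(unique(lk$tracks$id), 1L)
  expect_equal(nrow(lk$flags), 0L)

  # a 40 um jump: link made but speed flag raised
  det2 <- data.frame(frame = c(0, 1), x = c(0, 40), y = 0, z = 0)
  lk2 <- linkTracks(det2, layer = "DCL")
  expect_equal(unique(lk2$tracks$id), 1L)
  expect_true("speed" %in% lk2$flags$flag)

  # area jumps flagged at 50% (DCL) but not at the EVL tolerance
  det3 <- data.frame(frame = c(0, 1), x = 0, y = 0, z = 0, area = c(50, 90))
  expect_true("area" %in% linkTracks(det3, layer = "DCL")$flags$flag)
  expect_false("area" %in% linkTracks(det3, layer = "EVL")$flags$flag)

  # appearance and disappearance
  det4 <- rbind(data.frame(frame = 0, x = 0, y = 0, z = 0),
                data.frame(frame = 1, x = c(1, 100), y = 0, z = 0))
  expect_true("appeared" %in% linkTracks(det4)$flags$flag)
  det5 <- rbind(data.frame(frame = 0, x = c(0, 100), y = 0, z = 0),
                data.frame(frame = 1, x = 1, y = 0, z = 0))
  expect_true("disappeared" %in% linkTracks(det5)$flags$flag)
})

test_that("greedy linking mismatches on crossing cells are flagged", {
  # two cells cross between frames; the greedy linker swaps them relative
  # to the optimal assignment, and the excessive implied speed is flagged
  det <- rbind(data.frame(frame = 0, x = c(0, 100), y = 0, z = 0),
               data.frame(frame = 1, x = c(95, 5), y = 0, z = 0))
  lk <- linkTracks(det, maxSpeed = 35)
  # brute-force optimal assignment oracle on the toy scene
  d <- outer(c(0, 100), c(95, 5), function(a, b) abs(a - b))
  costs <- c(d[1, 1] + d[2, 2], d[1, 2] + d[2, 1])
  optimal <- which.min(costs)
  expect_equal(optimal, 2L)  # optimal keeps identities through the cross
  # greedy links 0 -> 5 and 100 -> 95 (both small moves): here greedy agrees
  # with optimal, so no speed flag
  expect_false("speed" %in% lk$flags$flag)
  # forced ambiguity: both candidates nearly equidistant, greedy may take
  # either; any implied > 35 um link must be flagged
  det2 <- rbind(data.frame(frame = 0, x = c(0, 10), y = 0, z = 0),
                data.frame(frame = 1, x = c(60, 50), y = 0, z = 0))
  lk2 <- linkTracks(det2, maxSpeed = 35)
  expect_true(all(c("speed") %in% lk2$flags$flag))
})

test_that("MSD matches stationary, ballistic and Brownian closed forms", {
  still <- data.frame(frame = 0:20, id = 1, layer = "DCL", x = 5, y = 5,
                      z = 5)
  m0 <- msdCurve(TrackTable(still, frameInterval = 1), maxLag = 5)
  expect_equal(m0$msd, rep(0, 5))

  v <- 3.2
  line <- data.frame(frame = 0:30, id = 1, layer = "DCL", x = v * (0:30),
                     y = 0, z = 0)
  m1 <- msdCurve(TrackTable(line, frameInterval = 1), maxLag = 10)
  expect_equal(m1$msd, (v * m1$time)^2, tolerance = 1e-9)

  w <- makeRandomWalks(500, D = 2, dt = 1, nFrames = 30, R = 592, seed = 40)
  m2 <- msdCurve(w, maxLag = 10)
  fit <- fitDiffusion(m2)
  expect_lt(abs(fit$D - 2) / 2, 0.05)
})

test_that("MSD window counts decrease with lag and warn when exceeded", {
  tr <- TrackTable(data.frame(frame = 0:9, id = 1, layer = "DCL",
                              x = rnorm(10), y = 0, z = 0),
                   frameInterval = 1)
  m <- msdCurve(tr, maxLag = 5)
  expect_true(all(diff(m$n) <= 0))
  expect_warning(msdCurve(tr, maxLag = 50), "valid lags")
})

test_that("diffusion fit equals the normal-equations solution", {
  msd <- data.frame(lag = 1:10, time = 1:10,
                    msd = 4 * 2.5 * (1:10), n = 10)
  f <- fitDiffusion(msd)
  expect_equal(f$D, 2.5, tolerance = 1e-12)
  expect_equal(f$rSquared, 1, tolerance = 1e-12)

  set.seed(41)
  msd2 <- data.frame(lag = 1:10, time = 1:10,
                     msd = 3 * (1:10) + rnorm(10), n = 10)
  f2 <- fitDiffusion(msd2)
  X <- cbind(1, msd2$time)
  beta <- solve(t(X) %*% X, t(X) %*% msd2$msd)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f2$slope, beta[2], tolerance = 1e-10)

  zero <- data.frame(lag = 1:5, time = 1:5, msd = 0, n = 5)
  expect_true(fitDiffusion(zero)$flagged)
})

test_that("directionality: straight line 1, loop 0, L-shape sqrt(2)/2", {
  expect_equal(directionality(cbind(0:5, 0, 0)), 1)
  loop <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(directionality(loop), 0)
  ell <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(directionality(ell), sqrt(2) / 2)
  expect_warning(directionality(matrix(1, 3, 3)), "zero path")
})

test_that("nearest-neighbour distances match the all-pairs oracle", {
  p2 <- fromSpherical(c(0.3, 0.5), c(0, 1), 592)
  nn <- nearestNeighbourDistance(p2, 1, 592)
  expect_equal(nn[1], nn[2])
  expect_equal(nn[1], geodesicDistance(p2[1, ], p2[2, ], 592))

  pts <- fxCapPoints(25, seed = 42)
  got <- nearestNeighbourDistance(pts, 6, 592)
  # O(n^2) brute force
  for (i in c(1, 7, 25)) {
    d <- vapply(seq_len(25), function(j)
      geodesicDistance(pts[i, ], pts[j, ], 592), numeric(1))
    expect_equal(got[i], mean(sort(d[-i])[1:6]), tolerance = 1e-9)
  }
  # permutation invariance
  perm <- sample(25)
  expect_equal(nearestNeighbourDistance(pts[perm, ], 6, 592), got[perm])
  expect_error(nearestNeighbourDistance(pts, 25, 592), "smaller")
})

test_that("border-distance distribution matches the analytic disc baseline", {
  # all points on borders: mass entirely in the first bin
  mesh <- fxMesh(30)
  v <- meshVertices(mesh)
  onBorder <- v[meshCells(mesh)[[1]], ]
  db <- distanceToBorderDistribution(onBorder, v, meshCells(mesh), 592)
  expect_equal(sum(db$counts[-1]), 0)

  # uniform points in a disc of radius 120: histogram matches
  # p(d) = 2 (120 - d) / 120^2 within binomial error
  set.seed(43)
  n <- 1e5
  r <- 120 * sqrt(runif(n))
  d <- 120 - r  # distance to the disc border
  db2 <- distanceToBorderDistribution(distances = d, binWidth = 5, Rc = 120)
  pbin <- diff(-(120 - pmin(db2$breaks, 120))^2 / 120^2)
  sdbin <- sqrt(pbin * (1 - pbin) / n) / 5
  expect_true(all(abs(db2$density - pbin / 5) < 4 * sdbin + 1e-12))

  # baseline integrates to 1 over [0, Rc]
  expect_equal(integrate(borderBaselineDensity, 0, 120, Rc = 120)$value, 1,
               tolerance = 1e-8)
})

test_that("covered area: octant closed form, planar limit, hull oracle", {
  oct <- rbind(c(592, 0, 1), c(0, 592, 1), c(0, 0, 592))
  oct[1:2, 3] <- 0
  expect_equal(coveredArea(oct, 592), pi * 592^2 / 2, tolerance = 1e-6)

  # small cluster near the pole: within 0.5% of the planar hull area
  set.seed(44)
  xy <- matrix(rnorm(40, 0, 10), ncol = 2)
  pts <- projectToSphere(xy[, 1], xy[, 2], 592)
  h <- chull(xy)
  planar <- abs(sum(xy[h, 1] * xy[c(h[-1], h[1]), 2] -
                      xy[c(h[-1], h[1]), 1] * xy[h, 2])) / 2
  expect_equal(coveredArea(pts, 592), planar, tolerance = 5e-3)

  # monotone under addition of points
  a1 <- coveredArea(pts[1:10, ], 592)
  a2 <- coveredArea(pts, 592)
  expect_gte(a2, a1 - 1e-9)
  expect_error(coveredArea(cbind(1:5, 2 * (1:5), 0), 592), "collinear")
})

test_that("epiboly index is 0/50/100 at pole, equator, vegetal pole", {
  expect_equal(epibolyIndex(matrix(c(0, 0, 592), 1), 592), 0)
  eq <- fromSpherical(rep(pi / 2, 8), seq(-pi, pi, length.out = 8), 592)
  expect_equal(epibolyIndex(eq, 592), 50, tolerance = 1e-9)
  expect_equal(epibolyIndex(matrix(c(0, 0, -592), 1), 592), 100)
  expect_error(epibolyIndex(matrix(0, 0, 3), 592), "empty")
})

test_that("area relation reproduces OLS and flags degenerate input", {
  x <- seq(1e6, 2e6, length.out = 10)
  r <- areaRelation(x, 0.9 * x)
  expect_equal(r$rSquared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.9, tolerance = 1e-12)

  set.seed(45)
  y <- 0.8 * x + rnorm(10, 0, 1e4)
  r2 <- areaRelation(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r2$slope, beta[2], tolerance = 1e-10)
  expect_warning(r3 <- areaRelation(rep(1, 5), rep(2, 5)), "constant")
  expect_true(r3$flagged)
})
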