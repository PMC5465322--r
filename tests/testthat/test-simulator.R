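smallPop <- function(n = 12L, seed = 20L)
  makeDclPopulation(n, 592, pi / 4, radius = 12, divisionWindow = NULL,
                    seed = seed)

test_that("spring forces vanish at rest length and obey Hooke's law", {
  mesh <- fxMesh(30)
  F0 <- evlSpringForces(mesh, U0 = 0.05)
  expect_equal(max(abs(F0)), 0)

  # stretch one vertex radially-tangentially and check the stretched edge
  m2 <- mesh
  sp <- meshSprings(mesh)
  s <- which(sp$type == "edge")[1]
  i <- sp$from[s]; j <- sp$to[s]
  dirv <- m2@vertices[j, ] - m2@vertices[i, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  F <- evl_forces_cpp(mesh@vertices, mesh@springs[, 1] - 1L,
                      mesh@springs[, 2] - 1L,
                      mesh@restLength - ifelse(seq_along(mesh@restLength) ==
                                                 s, 1, 0),
                      mesh@springStiff, 0.05, FALSE)
  # only spring s is off rest length, stretched by delta = 1 um
  expect_equal(sqrt(sum(F[i, ]^2)), 0.05 * 1, tolerance = 1e-9)
  expect_equal(F[i, ], -F[j, ], tolerance = 1e-12)
  expect_equal(sum(F[i, ] * dirv), 0.05, tolerance = 1e-9)
})

test_that("spring forces match the numerical gradient of the energy", {
  mesh <- fxMesh(30)
  set.seed(21)
  m2 <- mesh
  bulk <- which(!mesh@isBorder)
  m2@vertices <- mesh@vertices * (1 + 0.02 * runif(nrow(mesh@vertices)))
  F <- evl_forces_cpp(m2@vertices, m2@springs[, 1] - 1L,
                      m2@springs[, 2] - 1L, m2@restLength, m2@springStiff,
                      0.05, FALSE)
  h <- 1e-5
  for (i in bulk[1:8]) {
    for (k in 1:3) {
      vp <- m2@vertices; vp[i, k] <- vp[i, k] + h
      vm <- m2@vertices; vm[i, k] <- vm[i, k] - h
      g <- (evlSpringEnergy(m2, 0.05, vp) - evlSpringEnergy(m2, 0.05, vm)) /
        (2 * h)
      expect_equal(F[i, k], -g, tolerance = 1e-5 * max(1, abs(g)))
    }
  }
})

test_that("coincident spring endpoints are rejected", {
  mesh <- fxMesh(30)
  m2 <- mesh
  m2@vertices[m2@springs[1, 2], ] <- m2@vertices[m2@springs[1, 1], ]
  expect_error(evl_forces_cpp(m2@vertices, m2@springs[, 1] - 1L,
                              m2@springs[, 2] - 1L, m2@restLength,
                              m2@springStiff, 0.05, TRUE), "coincident")
})

test_that("border advance moves margin vertices along meridians", {
  mesh <- fxMesh(30)
  expect_identical(advanceBorder(mesh, 0, 0.5)@vertices, mesh@vertices)
  adv <- advanceBorder(mesh, V0 = 0.3, dt = 0.5)
  idx <- which(mesh@isBorder)
  s0 <- toSpherical(mesh@vertices[idx, ])
  s1 <- toSpherical(adv@vertices[idx, ])
  expect_equal(s1$phi, s0$phi, tolerance = 1e-12)
  expect_equal(s1$theta - s0$theta, rep(0.3 * 0.5 / 592, length(idx)),
               tolerance = 1e-12)
  # bulk untouched
  expect_identical(adv@vertices[-idx, ], mesh@vertices[-idx, ])
  # n steps accumulate polar arc n * V0 * dt
  m <- mesh
  for (k in 1:40) m <- advanceBorder(m, 0.3, 0.5)
  sN <- toSpherical(m@vertices[idx, ])
  expect_equal((sN$theta - s0$theta) * 592, rep(40 * 0.3 * 0.5, length(idx)),
               tolerance = 1e-6)
})

test_that("barycentric weights reconstruct points and flag degeneracy", {
  tri <- rbind(c(0, 0), c(2, 0), c(0, 3))
  expect_equal(barycentricWeights(c(0, 0), tri), c(1, 0, 0))
  expect_equal(barycentricWeights(colMeans(tri), tri), rep(1 / 3, 3))
  set.seed(22)
  for (i in 1:20) {
    tri3 <- matrix(rnorm(9), 3)
    ok <- tryCatch({
      w <- barycentricWeights(tri3[1, ] * 0.2 + tri3[2, ] * 0.3 +
                                tri3[3, ] * 0.5, tri3)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, c(0.2, 0.3, 0.5), tolerance = 1e-8)
  }
  expect_error(barycentricWeights(c(1, 1), rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("DCL forces: stationary, pure advection and attraction gradient", {
  mesh <- fxMesh(30)
  pop <- smallPop()
  # all amplitudes zero, static EVL, full drag: no displacement
  p0 <- SimParams(U1 = 0, U2 = 0, sigma = 0, drag = 1)
  d <- dclDisplacement(pop, mesh, p0, noise = FALSE)
  expect_equal(max(abs(d)), 0)

  # uniform EVL velocity, drag 1: displacement is exactly v * dt (before
  # tangential projection, checked on the tangent component)
  v <- c(0.2, -0.1, 0.05)
  vel <- matrix(v, nrow(mesh@vertices), 3, byrow = TRUE)
  d2 <- dclDisplacement(pop, mesh, p0, evlVelocities = vel, noise = FALSE)
  for (i in seq_len(nrow(d2))) {
    rhat <- unname(pop@positions[i, ] / 592)
    vtan <- (v - sum(v * rhat) * rhat) * p0@dt
    expect_equal(d2[i, ], vtan, tolerance = 1e-9)
  }

  # U2 only: displacement matches the analytic gradient of the Gaussian
  # potential in geodesic distance to the nearest border
  pU2 <- SimParams(U1 = 0, U2 = 0.3, sigma = 0, drag = 0)
  d3 <- dclDisplacement(pop, mesh, pU2, noise = FALSE)
  edges <- epiboly:::.meshBorderEdges(mesh)
  u <- pop@positions / 592
  uv <- mesh@vertices / sqrt(rowSums(mesh@vertices^2))
  dist <- 592 * point_segments_min_angle(u, uv, edges[, 1] - 1L,
                                         edges[, 2] - 1L)
  for (i in seq_len(nrow(d3))) {
    mag <- 0.3 * epiboly:::borderAttractionScale * (dist[i] / 15^2) *
      exp(-dist[i]^2 / (2 * 15^2)) * pU2@dt
    got <- sqrt(sum(d3[i, ]^2))
    # tangential projection can only shrink the magnitude very slightly
    expect_equal(got, mag, tolerance = 1e-3)
  }
})

test_that("divisions halve volume, never repeat, and double the count", {
  pop <- smallPop()
  expect_identical(applyDivisions(pop, 100), pop)  # empty schedule

  pop2 <- pop
  pop2@divisionTime <- rep(50, nrow(pop@positions))
  set.seed(23)
  div <- applyDivisions(pop2, 60)
  expect_equal(nrow(particlePositions(div)), 2 * nrow(pop@positions))
  expect_equal(particleRadii(div), rep(12 * 0.5^(1 / 3), 24))
  expect_true(all(div@hasDivided))
  # daughters one parent radius apart
  d <- sqrt(sum((particlePositions(div)[1, ] -
                   particlePositions(div)[13, ])^2))
  expect_equal(d, 12, tolerance = 1e-3)
  # re-scheduling a divided cell is rejected
  bad <- div
  bad@divisionTime[1] <- 70
  expect_error(validObject(bad), "divide")
})

test_that("simulation with all amplitudes zero is the identity", {
  mesh <- fxMesh(30)
  pop <- smallPop()
  p <- SimParams(U0 = 0, V0 = 0, U1 = 0, U2 = 0, sigma = 0, drag = 0,
                 nFrames = 5L)
  tr <- runSimulation(p, mesh, pop)
  r <- trackRecords(tr)
  for (f in 0:5) {
    rf <- r[r$frame == f & r$layer == "DCL", ]
    expect_equal(as.matrix(rf[order(rf$id), c("x", "y", "z")]),
                 pop@positions, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("noise-only ensembles diffuse at the configured coefficient", {
  mesh <- fxMesh(30)
  pop <- makeDclPopulation(200, 592, pi / 4, radius = 5,
                           divisionWindow = NULL, seed = 24L)
  sigma <- 2e4  # maps to D = 2 um^2/min
  p <- SimParams(U0 = 0, V0 = 0, U1 = 0, U2 = 0, sigma = sigma, drag = 0,
                 nFrames = 30L, seed = 25L)
  tr <- runSimulation(p, mesh, pop)
  m <- msdCurve(tr, maxLag = 10)
  fit <- fitDiffusion(m)
  Dconf <- sigma * sigmaDiffusionScale
  expect_lt(abs(fit$D - Dconf) / Dconf, 0.1)
})

test_that("pure advection preserves barycentric coordinates", {
  mesh <- fxMesh(30)
  pop <- smallPop(8L, seed = 26L)
  p <- SimParams(U1 = 0, U2 = 0, sigma = 0, drag = 1, nFrames = 10L,
                 seed = 27L)
  tr <- runSimulation(p, mesh, pop)
  evl <- evlVertexFrames(tr)
  r <- trackRecords(tr)
  dcl0 <- r[r$layer == "DCL" & r$frame == 0, ]
  dclN <- r[r$layer == "DCL" & r$frame == 10, ]
  dcl0 <- dcl0[order(dcl0$id), ]; dclN <- dclN[order(dclN$id), ]
  tested <- 0L
  for (i in seq_len(nrow(dcl0))) {
    p0 <- as.numeric(dcl0[i, c("x", "y", "z")])
    pN <- as.numeric(dclN[i, c("x", "y", "z")])
    dd <- sqrt(rowSums(sweep(evl[[1]], 2, p0)^2))
    nn <- order(dd)[1:3]
    w0 <- bary3_weights_cpp(p0, evl[[1]][nn, ])
    # restrict to particles actually enclosed by their nearest-vertex
    # triangle (extrapolated weights amplify interpolation error)
    if (min(w0) < -0.05 || max(w0) > 1.05) next
    tested <- tested + 1L
    wN <- bary3_weights_cpp(pN, evl[[11]][nn, ])
    expect_equal(wN, w0, tolerance = 0.05)
  }
  expect_gte(tested, 3L)
})

test_that("spring energy is non-increasing without driving or noise", {
  mesh <- fxMesh(30)
  # perturb bulk vertices off rest, then relax
  set.seed(28)
  m2 <- mesh
  bulk <- which(!m2@isBorder)
  pert <- m2@vertices[bulk, ] + matrix(rnorm(length(bulk) * 3, 0, 3),
                                       ncol = 3)
  m2@vertices[bulk, ] <- pert * 592 / sqrt(rowSums(pert^2))
  pop <- smallPop(4L)
  p <- SimParams(U0 = 0.05, V0 = 0, U1 = 0, U2 = 0, sigma = 0, drag = 0,
                 nFrames = 10L, frameInterval = 5, dt = 0.5)
  tr <- runSimulation(p, m2, pop)
  evl <- evlVertexFrames(tr)
  en <- vapply(evl, function(v) evlSpringEnergy(m2, 0.05, v), numeric(1))
  expect_true(all(diff(en) <= 1e-8 * en[1]))
  expect_lt(en[length(en)], en[1])
})

test_that("halving dt changes a deterministic run at first order", {
  mesh <- fxMesh(30)
  pop <- smallPop(6L)
  final <- function(dt) {
    p <- SimParams(sigma = 0, dt = dt, nFrames = 4L, frameInterval = 4,
                   seed = 29L)
    r <- trackRecords(runSimulation(p, mesh, pop))
    rf <- r[r$frame == 4 & r$layer == "DCL", ]
    as.matrix(rf[order(rf$id), c("x", "y", "z")])
  }
  e1 <- max(abs(final(1) - final(0.5)))
  e2 <- max(abs(final(0.5) - final(0.25)))
  expect_lt(e2, e1)           # refinement shrinks the difference
  expect_lt(e2 / e1, 0.75)    # roughly first order
})

test_that("simulation runs are reproducible from the seed", {
  mesh <- fxMesh(30)
  pop <- smallPop(10L)
  p <- SimParams(nFrames = 3L, seed = 31L)
  r1 <- trackRecords(runSimulation(p, mesh, pop))
  r2 <- trackRecords(runSimulation(p, mesh, pop))
  expect_identical(r1, r2)
})
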