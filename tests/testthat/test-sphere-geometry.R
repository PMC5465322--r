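test_that("algebraic sphere fit recovers exact and noisy spheres", {
  pts <- fxSpherePoints(100, R = 1, seed = 1)
  sf <- fitSphere(pts)
  expect_equal(sphereCenter(sf), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sphereRadius(sf), 1, tolerance = 1e-9)

  noisy <- fxSpherePoints(2000, R = 592, noise = 1, seed = 2)
  sf2 <- fitSphere(noisy)
  expect_lt(abs(sphereRadius(sf2) - 592), 0.5)

  # agrees with an independent iterative geometric least-squares fit
  par <- oracleGeometricSphereFit(noisy)
  expect_lt(abs(sphereRadius(sf2) - par[4]), 0.5)
})

test_that("sphere fit rejects degenerate point sets", {
  flat <- cbind(runif(20), runif(20), 0)
  expect_error(fitSphere(flat), "degenerate")
  expect_error(fitSphere(matrix(1, 3, 3)), "at least 4")
})

test_that("projection recovers the upper hemisphere", {
  expect_equal(projectToSphere(0, 0, 10), cbind(x = 0, y = 0, z = 10))
  expect_equal(projectToSphere(10, 0, 10)[1, "z"], c(z = 0))
  set.seed(3)
  r <- 592 * sqrt(runif(50)) * 0.999
  a <- runif(50, -pi, pi)
  p <- projectToSphere(r * cos(a), r * sin(a), 592)
  expect_equal(sqrt(rowSums(p^2)), rep(592, 50), tolerance = 1e-9)
  expect_error(projectToSphere(600, 0, 592), "outside")
})

test_that("geodesic distance matches closed forms and quadrature", {
  p <- c(0, 0, 7)
  expect_equal(geodesicDistance(p, p, 7), 0)
  expect_equal(geodesicDistance(c(0, 0, 7), c(0, 0, -7), 7), pi * 7)
  # quadrature oracle: arc length integrated along the great circle
  set.seed(4)
  for (i in 1:5) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    w <- v - sum(u * v) * u; w <- w / sqrt(sum(w^2))
    ang <- acos(pmin(1, pmax(-1, sum(u * v))))
    ts <- seq(0, ang, length.out = 20001)
    pts <- outer(cos(ts), u) + outer(sin(ts), w)
    arc <- sum(sqrt(rowSums((pts[-1, ] - pts[-nrow(pts), ])^2)))
    expect_equal(geodesicDistance(u, v, 1), arc, tolerance = 1e-6)
  }
  expect_error(geodesicDistance(c(0, 0, 0), c(1, 0, 0), 1), "zero-length")
})

test_that("geodesic distance satisfies the triangle inequality", {
  set.seed(5)
  for (i in 1:25) {
    m <- matrix(rnorm(9), 3)
    m <- m / sqrt(rowSums(m^2))
    d12 <- geodesicDistance(m[1, ], m[2, ], 592)
    d13 <- geodesicDistance(m[1, ], m[3, ], 592)
    d23 <- geodesicDistance(m[2, ], m[3, ], 592)
    expect_lte(d12, d13 + d23 + 1e-9)
  }
})

test_that("spherical polygon area: octant, planar limit, l'Huilier oracle", {
  expect_equal(sphericalPolygonArea(diag(3) * 592, 592), pi * 592^2 / 2,
               tolerance = 1e-10)
  # small square near the pole approaches its planar area
  s <- 2  # um on R = 592
  half <- s / 2 / 592
  sq <- rbind(fromSpherical(half * sqrt(2), pi / 4, 592),
              fromSpherical(half * sqrt(2), 3 * pi / 4, 592),
              fromSpherical(half * sqrt(2), -3 * pi / 4, 592),
              fromSpherical(half * sqrt(2), -pi / 4, 592))
  expect_equal(sphericalPolygonArea(sq, 592), s^2, tolerance = 1e-3)
  # random convex spherical polygons vs fan of l'Huilier triangles
  set.seed(6)
  for (i in 1:5) {
    th0 <- runif(1, 0.2, 0.6)
    ph <- sort(runif(6, -pi, pi))
    poly <- fromSpherical(th0 * (1 + 0.2 * runif(6)), ph, 1)
    ctr <- colMeans(poly); ctr <- ctr / sqrt(sum(ctr^2))
    fan <- sum(vapply(seq_len(6), function(k)
      oracleLHuilier(ctr, poly[k, ], poly[k %% 6 + 1, ]), numeric(1)))
    expect_equal(sphericalPolygonArea(poly, 1), fan, tolerance = 1e-8)
  }
  expect_error(sphericalPolygonArea(diag(3)[1:2, ], 1), ">= 3")
})

test_that("polygon area is invariant to vertex rotation and reversal", {
  set.seed(7)
  poly <- fromSpherical(runif(5, 0.3, 0.5), sort(runif(5, -pi, pi)), 592)
  a0 <- sphericalPolygonArea(poly, 592)
  expect_equal(sphericalPolygonArea(poly[c(3:5, 1:2), ], 592), a0)
  expect_equal(sphericalPolygonArea(poly[5:1, ], 592), a0)
})

test_that("tessellation cells partition the spherical cap area", {
  mesh <- fxMesh(30)
  expect_equal(sum(evlCellAreas(mesh)), sphericalCapArea(pi / 3, 592),
               tolerance = 1e-4)
})

test_that("distance to a polyline on the sphere", {
  line <- rbind(fromSpherical(0.5, 0, 592), fromSpherical(0.5, 0.3, 592))
  expect_equal(distanceToPolylineOnSphere(line[1, ], line, 592), 0,
               tolerance = 1e-9)
  # dense-sampling oracle
  set.seed(8)
  for (i in 1:5) {
    p <- fromSpherical(runif(1, 0.2, 0.8), runif(1, -0.3, 0.6), 592)[1, ]
    ts <- seq(0, 1, length.out = 40000)
    u <- line[1, ] / 592; v <- line[2, ] / 592
    ang <- acos(sum(u * v))
    w <- (v - sum(u * v) * u); w <- w / sqrt(sum(w^2))
    dense <- outer(cos(ts * ang), u) + outer(sin(ts * ang), w)
    brute <- min(geodesicDistance(
      matrix(rep(p, nrow(dense)), ncol = 3, byrow = TRUE) / 592, dense, 592))
    expect_equal(distanceToPolylineOnSphere(p, line, 592), brute,
                 tolerance = 0.02)
  }
  expect_error(distanceToPolylineOnSphere(c(0, 0, 1), matrix(0, 1, 3), 1),
               "at least 2")
})

test_that("drift removal recovers known rotations under isotropic growth", {
  p0 <- fxCapPoints(40, seed = 9)
  ident <- removeRotationalDrift(list(p0, p0))
  expect_equal(ident$rotations[[2]], diag(3), tolerance = 1e-12)

  Rm <- rotationMatrix(c(0.2, -0.5, 1), 5 * pi / 180)
  p1 <- (1.1 * p0) %*% t(Rm)
  dr <- removeRotationalDrift(list(p0, p1))
  angle <- acos(pmin(1, (sum(diag(dr$rotations[[2]])) - 1) / 2)) * 180 / pi
  expect_lt(abs(angle - 5), 0.1)
  # corrected cloud equals pure isotropic growth of the reference
  expect_equal(dr$corrected[[2]], 1.1 * p0, tolerance = 1e-9)

  # with 1 um positional noise, within 0.5 deg of a grid-search oracle
  set.seed(10)
  p1n <- p1 + matrix(rnorm(nrow(p1) * 3), ncol = 3)
  drn <- removeRotationalDrift(list(p0, p1n))
  angn <- acos(pmin(1, (sum(diag(drn$rotations[[2]])) - 1) / 2)) * 180 / pi
  grid <- seq(4, 6, by = 0.01)
  rss <- vapply(grid, function(a) {
    Rg <- rotationMatrix(c(0.2, -0.5, 1), a * pi / 180)
    u1 <- p1n / sqrt(rowSums(p1n^2))
    u0 <- (p0 %*% t(Rg)); u0 <- u0 / sqrt(rowSums(u0^2))
    sum((u1 - u0)^2)
  }, numeric(1))
  expect_lt(abs(angn - grid[which.min(rss)]), 0.5)
})

test_that("drift removal re-application reproduces the input frames", {
  p0 <- fxCapPoints(25, seed = 11)
  frames <- list(p0, (1.05 * p0) %*% t(rotationMatrix(c(1, 2, 3), 0.04)),
                 (1.10 * p0) %*% t(rotationMatrix(c(1, 2, 3), 0.09)))
  dr <- removeRotationalDrift(frames)
  for (k in seq_along(frames))
    expect_equal(dr$corrected[[k]] %*% t(dr$rotations[[k]]) %*%
                   dr$rotations[[k]], dr$corrected[[k]], tolerance = 1e-12)
  # corrected frames have no net rotation relative to the reference
  for (k in 2:3) {
    chk <- removeRotationalDrift(list(p0, dr$corrected[[k]]))
    expect_equal(chk$rotations[[2]], diag(3), tolerance = 1e-6)
  }
  expect_error(removeRotationalDrift(list(p0[1:2, ], p0[1:2, ])),
               "underdetermined")
})

test_that("axis alignment puts the animal-vegetal axis on +z", {
  p0 <- fxCapPoints(30, seed = 12)
  ax <- c(0.3, 0.4, 0.86)
  dr <- removeRotationalDrift(list(p0), axis = ax)
  cor <- dr$corrected[[1]]
  # rigid re-orientation: each point keeps its angle to the axis, with the
  # axis direction now on +z
  angBefore <- geodesicDistance(p0, matrix(ax, nrow(p0), 3, byrow = TRUE), 1)
  angAfter <- geodesicDistance(cor, matrix(c(0, 0, 1), nrow(p0), 3,
                                           byrow = TRUE), 1)
  expect_equal(angAfter, angBefore, tolerance = 1e-9)
  expect_equal(sqrt(rowSums(cor^2)), sqrt(rowSums(p0^2)), tolerance = 1e-9)
})
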