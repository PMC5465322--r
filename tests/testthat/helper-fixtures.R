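# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fxMesh <- function(nCells = 30L, seed = 2L) {
  key <- paste0("mesh", nCells, "_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- makeEvlTessellation(nCells, 592, pi / 3, seed = seed)
  .fx[[key]]
}

fxSpherePoints <- function(n, R = 592, noise = 0, seed = 1L) {
  set.seed(seed)
  th <- acos(runif(n, -1, 1))
  ph <- runif(n, -pi, pi)
  p <- R * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  if (noise > 0) p <- p + matrix(rnorm(3 * n, 0, noise), ncol = 3)
  p
}

fxCapPoints <- function(n, R = 592, capExtent = pi / 3, seed = 1L) {
  set.seed(seed)
  cth <- 1 - runif(n) * (1 - cos(capExtent))
  ph <- runif(n, -pi, pi)
  sth <- sin(acos(cth))
  cbind(R * sth * cos(ph), R * sth * sin(ph), R * cth)
}

rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# independent geometric (iterative) sphere fit used as oracle
oracleGeometricSphereFit <- function(points) {
  obj <- function(par) {
    r <- sqrt(rowSums(sweep(points, 2, par[1:3])^2))
    sum((r - par[4])^2)
  }
  ctr <- colMeans(points)
  r0 <- mean(sqrt(rowSums(sweep(points, 2, ctr)^2)))
  optim(c(ctr, r0), obj, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-14))$par
}

# l'Huilier spherical triangle area (oracle for polygon areas)
oracleLHuilier <- function(a, b, cc, R = 1) {
  ang <- function(u, v) atan2(sqrt(sum(pracma::cross(u, v)^2)), sum(u * v))
  u <- a / sqrt(sum(a^2)); v <- b / sqrt(sum(b^2)); w <- cc / sqrt(sum(cc^2))
  A <- ang(v, w); B <- ang(u, w); C <- ang(u, v)
  s <- (A + B + C) / 2
  E <- 4 * atan(sqrt(max(0, tan(s / 2) * tan((s - A) / 2) *
                           tan((s - B) / 2) * tan((s - C) / 2))))
  E * R^2
}
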