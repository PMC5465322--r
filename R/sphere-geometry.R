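# Geometry on and around the egg sphere: algebraic sphere fitting, upper
# hemisphere projection, geodesics, spherical polygon areas, distances to
# border polylines, and rotational drift removal.

.rowNorms <- function(m) sqrt(rowSums(m * m))

.unitRows <- function(m) {
  n <- .rowNorms(m)
  if (any(n == 0)) stop("zero-length vector")
  m / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fit a sphere to a 3D point cloud (algebraic least squares)
#'
#' Linear least-squares solution of the algebraic sphere equation
#' `x^2 + y^2 + z^2 + a x + b y + c z + d = 0`, giving centre
#' `(-a/2, -b/2, -c/2)` and radius `sqrt(a^2/4 + b^2/4 + c^2/4 - d)`.
#' This is the fit used to recover the egg radius (about 592 um for the
#' killifish egg) from segmented surface points.
#'
#' @param points numeric matrix (n x 3), n >= 4 non-coplanar points (um).
#' @return A [SphereFit-class].
#' @examples
#' th <- acos(runif(200, -1, 1)); ph <- runif(200, -pi, pi)
#' pts <- 592 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
#' fitSphere(pts)
#' @export
fitSphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points")
  A <- cbind(points, 1)
  b <- -rowSums(points^2)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop("degenerate geometry: points are coplanar or collinear")
  coefs <- qr.coef(qrA, b)
  center <- -coefs[1:3] / 2
  r2 <- sum(center^2) - coefs[4]
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate geometry: no real sphere fits these points")
  radius <- sqrt(r2)
  resid <- .rowNorms(sweep(points, 2, center)) - radius
  new("SphereFit", center = unname(center), radius = unname(radius),
      rmsResidual = sqrt(mean(resid^2)))
}

#' Project planar (x, y) locations onto the upper hemisphere
#'
#' Recovers the z-component of segmented locations by intersecting the
#' vertical line through (x, y) with the fitted egg sphere, keeping the
#' animal (upper, +z) solution.
#'
#' @param x,y coordinates (um); vectors of equal length.
#' @param sphere a [SphereFit-class], or a single numeric radius (centre at
#'   the origin).
#' @return numeric matrix (n x 3) of points on the sphere.
#' @export
projectToSphere <- function(x, y, sphere) {
  if (is(sphere, "SphereFit")) {
    ctr <- sphereCenter(sphere); R <- sphereRadius(sphere)
  } else {
    ctr <- c(0, 0, 0); R <- as.numeric(sphere)
  }
  dx <- x - ctr[1]; dy <- y - ctr[2]
  h2 <- R^2 - dx^2 - dy^2
  if (any(h2 < -1e-9 * R^2))
    stop("point(s) outside the projected disc of the sphere")
  h2[h2 < 0] <- 0
  cbind(x = x, y = y, z = ctr[3] + sqrt(h2))
}

#' Geodesic (great-circle) distance between points on a sphere
#'
#' `R * angle(p, q)`, with the angle computed as
#' `atan2(|p x q|, p . q)` for numerical stability near 0 and pi. Inputs are
#' radially normalized, so points need not lie exactly on the sphere.
#'
#' @param p,q numeric vectors of length 3, or matrices (n x 3) paired by row.
#' @param R sphere radius (um).
#' @return numeric vector of distances (um).
#' @export
geodesicDistance <- function(p, q, R) {
  p <- if (is.matrix(p)) p else matrix(p, 1)
  q <- if (is.matrix(q)) q else matrix(q, 1)
  u <- .unitRows(p); v <- .unitRows(q)
  dotpq <- rowSums(u * v)
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  R * atan2(.rowNorms(cr), dotpq)
}

#' Area of a spherical polygon
#'
#' Signed solid-angle computation: the polygon is fanned into spherical
#' triangles about its (normalized) vertex centroid and each triangle's
#' signed solid angle is accumulated with the Van Oosterom-Strackee formula
#' -- a discrete form of the Green's-theorem line integral used for cell
#' areas on the egg surface. The result is orientation-independent.
#'
#' @param vertices numeric matrix (n x 3), n >= 3, ordered simple closed
#'   contour on the sphere (do not repeat the first vertex).
#' @param R sphere radius (um).
#' @return area in um^2.
#' @examples
#' oct <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' sphericalPolygonArea(oct, 1)  # pi/2, one octant
#' @export
sphericalPolygonArea <- function(vertices, R) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("a spherical polygon needs >= 3 vertices")
  u <- .unitRows(vertices)
  if (any(.rowNorms(u - u[c(2:nrow(u), 1), , drop = FALSE]) < 1e-12))
    stop("polygon has coincident consecutive vertices")
  ctr <- colSums(u)
  if (sqrt(sum(ctr^2)) < 1e-12) stop("degenerate polygon (zero centroid)")
  ctr <- ctr / sqrt(sum(ctr^2))
  n <- nrow(u)
  omega <- 0
  for (i in seq_len(n)) {
    a <- ctr; b <- u[i, ]; cc <- u[if (i == n) 1L else i + 1L, ]
    num <- sum(a * .cross3(b, cc))
    den <- 1 + sum(a * b) + sum(b * cc) + sum(cc * a)
    omega <- omega + 2 * atan2(num, den)
  }
  abs(omega) * R^2
}

#' Closed-form area of a spherical cap
#'
#' `2 pi R^2 (1 - cos(theta))` for polar half-angle `theta` from the animal
#' pole; used as the partition-of-area reference for tessellations.
#'
#' @param theta polar half-angle (radians).
#' @param R sphere radius (um).
#' @return area in um^2.
#' @export
sphericalCapArea <- function(theta, R) 2 * pi * R^2 * (1 - cos(theta))

#' Minimum geodesic distance from points to a polyline on the sphere
#'
#' Distance from each query point to the nearest point of any great-circle
#' segment of a polyline (or a set of independent segments), as used for the
#' DCL-cell to EVL-cell-border distance. Computation is exact: the foot of
#' the great-circle perpendicular is used when it falls inside a segment,
#' otherwise the nearer endpoint.
#'
#' @param p numeric vector (3) or matrix (n x 3) of query points.
#' @param polyline matrix (m x 3) of consecutive polyline vertices (m >= 2),
#'   used if `segments` is NULL.
#' @param R sphere radius (um).
#' @param segments optional 2-column integer matrix of vertex-index pairs
#'   into `polyline`, giving an explicit segment set (e.g. all EVL cell
#'   borders at once).
#' @return numeric vector of distances (um).
#' @export
distanceToPolylineOnSphere <- function(p, polyline, R, segments = NULL) {
  p <- if (is.matrix(p)) p else matrix(p, 1)
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 vertices")
  if (is.null(segments))
    segments <- cbind(seq_len(nrow(polyline) - 1L), 2:nrow(polyline))
  u <- .unitRows(p)
  verts <- .unitRows(polyline)
  d <- point_segments_min_angle(u, verts, segments[, 1] - 1L,
                                segments[, 2] - 1L)
  R * d
}

#' Remove rigid rotational drift from tracked point clouds
#'
#' Per-frame rotation-only orthogonal Procrustes (Kabsch) on radially
#' normalized points: because epibolic growth is radial/tangential scaling
#' on the unit sphere, normalizing radii isolates the rigid rotation of the
#' egg within the chorion. Each frame's recovered rotation is removed;
#' optionally all frames are then re-oriented so a given animal-vegetal axis
#' maps to +z.
#'
#' @param frames list of numeric matrices (n x 3); row i of every frame is
#'   the same tracked point. At least 3 points per frame.
#' @param axis optional numeric(3): the animal-vegetal axis direction in the
#'   reference (first) frame, rotated onto +z in all corrected frames.
#' @return list with `rotations` (list of 3 x 3 matrices, one per frame,
#'   mapping reference-frame directions onto observed-frame directions) and
#'   `corrected` (list of drift-free point matrices).
#' @export
removeRotationalDrift <- function(frames, axis = NULL) {
  if (!length(frames)) stop("no frames given")
  if (any(vapply(frames, nrow, 1L) < 3L))
    stop("underdetermined: need >= 3 corresponded points per frame")
  ref <- .unitRows(frames[[1]])
  axisRot <- diag(3)
  if (!is.null(axis)) {
    a <- axis / sqrt(sum(axis^2))
    z <- c(0, 0, 1)
    v <- .cross3(a, z); s <- sqrt(sum(v^2)); cth <- sum(a * z)
    if (s < 1e-12) {
      axisRot <- if (cth > 0) diag(3) else diag(c(1, -1, -1))
    } else {
      vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      axisRot <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
    }
  }
  rotations <- vector("list", length(frames))
  corrected <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    uk <- .unitRows(frames[[k]])
    H <- t(ref) %*% uk
    sv <- svd(H)
    dsign <- sign(det(sv$v %*% t(sv$u)))
    Rk <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)  # ref -> frame k
    rotations[[k]] <- Rk
    corrected[[k]] <- frames[[k]] %*% Rk %*% t(axisRot)
  }
  list(rotations = rotations, corrected = corrected)
}

#' Convert between Cartesian and spherical coordinates on the egg
#'
#' Polar angle `theta` is measured from the animal pole (+z); azimuth `phi`
#' in `[-pi, pi]`.
#'
#' @param p matrix (n x 3) of Cartesian points.
#' @return data.frame with columns `theta`, `phi`, `r`.
#' @export
toSpherical <- function(p) {
  p <- if (is.matrix(p)) p else matrix(p, 1)
  r <- .rowNorms(p)
  data.frame(theta = acos(pmin(1, pmax(-1, p[, 3] / r))),
             phi = atan2(p[, 2], p[, 1]), r = r)
}

#' @rdname toSpherical
#' @param theta,phi,r spherical coordinates (theta from +z).
#' @export
fromSpherical <- function(theta, phi, r) {
  cbind(x = r * sin(theta) * cos(phi), y = r * sin(theta) * sin(phi),
        z = r * cos(theta))
}

# Azimuthal equidistant projection about the animal pole: preserves geodesic
# distance from the pole; used for 2D Delaunay lookups in the analysis cap.
azimuthalProjection <- function(p, R) {
  s <- toSpherical(p)
  arc <- R * s$theta
  cbind(u = arc * cos(s$phi), v = arc * sin(s$phi))
}

azimuthalUnprojection <- function(uv, R) {
  arc <- sqrt(rowSums(uv^2))
  theta <- arc / R
  phi <- atan2(uv[, 2], uv[, 1])
  fromSpherical(theta, phi, R)
}
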