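# Decomposition of DCL trajectories into a non-autonomous EVL-advected
# component and an autonomous component, via geometric models of the EVL
# deformation field evaluated in the animal-pole azimuthal-equidistant
# projection.

.deformationModels <- c("delaunay_barycentric", "two_closest_vertices",
                        "cell_center_of_mass")

# 2D chart of an EVL configuration: projected vertices plus their Delaunay
# triangulation (deldir prints adjacency diagnostics; discard them)
.evlChart <- function(evl0, R) {
  v2 <- azimuthalProjection(evl0, R)
  dd <- NULL
  utils::capture.output(
    dd <- deldir::deldir(v2[, 1], v2[, 2], suppressMsge = TRUE))
  list(v2 = v2, triangles = deldir::triMat(dd))
}

.pointInPolygon <- function(px, py, xs, ys) {
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

# Enclosing Delaunay triangle of a 2D point; nearest triangle (by centroid)
# as fallback. Returns list(tri = vertex indices, weights, fallback).
.locateTriangle <- function(p2, v2, triangles) {
  nT <- nrow(triangles)
  best <- NULL; bestMin <- -Inf
  for (t in seq_len(nT)) {
    tri <- triangles[t, ]
    w <- tryCatch(barycentricWeights(p2, v2[tri, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(w)) next
    m <- min(w)
    if (m > bestMin) {
      bestMin <- m
      best <- list(tri = tri, weights = w, fallback = m < -1e-9)
    }
    if (m >= -1e-9) break
  }
  if (is.null(best)) stop("no usable triangle in the triangulation")
  best
}

#' EVL-advected displacement of a point under a deformation model
#'
#' Predicts the displacement a passively carried point at `p` would undergo
#' between two EVL configurations, using one of three geometric models of
#' the EVL deformation field evaluated in the animal-pole
#' azimuthal-equidistant projection:
#' * `delaunay_barycentric` -- barycentric interpolation of the vertex
#'   displacements over the enclosing Delaunay triangle of the EVL
#'   vertices (weights recomputed at each frame);
#' * `two_closest_vertices` -- inverse-distance-weighted mean of the two
#'   nearest vertices' displacements (plain mean with
#'   `aggregate = "mean"`);
#' * `cell_center_of_mass` -- displacement of the vertex centroid of the
#'   EVL cell containing the point.
#'
#' A point outside the triangulation/polygon set falls back to the nearest
#' triangle or cell and is flagged in the `fallback` attribute.
#'
#' @param p numeric(3), the point in frame-0 coordinates.
#' @param evl0,evl1 EVL vertex matrices at the two frames (same row order).
#' @param model one of the three model names.
#' @param R sphere radius (um).
#' @param cells list of cell vertex cycles (needed for
#'   `cell_center_of_mass`).
#' @param aggregate for `two_closest_vertices`: `"idw"` (default) or
#'   `"mean"`.
#' @param chart optional precomputed chart of `evl0` (internal caching for
#'   many queries against the same frame pair).
#' @return numeric(3) displacement (um), with attribute `fallback`.
#' @export
advectedDisplacement <- function(p, evl0, evl1,
                                 model = .deformationModels, R,
                                 cells = NULL, aggregate = c("idw", "mean"),
                                 chart = NULL) {
  model <- match.arg(model)
  aggregate <- match.arg(aggregate)
  disp <- evl1 - evl0
  fallback <- FALSE
  if (model == "two_closest_vertices") {
    d <- .rowNorms(sweep(evl0, 2, p))
    nn <- order(d)[1:2]
    w <- if (aggregate == "idw") {
      iv <- 1 / pmax(d[nn], 1e-9); iv / sum(iv)
    } else c(0.5, 0.5)
    out <- as.numeric(w %*% disp[nn, , drop = FALSE])
  } else if (model == "delaunay_barycentric") {
    if (is.null(chart)) chart <- .evlChart(evl0, R)
    p2 <- azimuthalProjection(matrix(p, 1), R)[1, ]
    loc <- .locateTriangle(p2, chart$v2, chart$triangles)
    fallback <- loc$fallback
    out <- as.numeric(loc$weights %*% disp[loc$tri, , drop = FALSE])
  } else {
    if (is.null(cells)) stop("cell_center_of_mass model needs `cells`")
    v2 <- if (!is.null(chart)) chart$v2 else azimuthalProjection(evl0, R)
    p2 <- azimuthalProjection(matrix(p, 1), R)[1, ]
    hit <- NULL
    for (ci in seq_along(cells)) {
      cyc <- cells[[ci]]
      if (.pointInPolygon(p2[1], p2[2], v2[cyc, 1], v2[cyc, 2])) {
        hit <- ci; break
      }
    }
    if (is.null(hit)) {
      fallback <- TRUE
      cen <- t(vapply(cells, function(cyc) colMeans(v2[cyc, , drop = FALSE]),
                      numeric(2)))
      hit <- which.min((cen[, 1] - p2[1])^2 + (cen[, 2] - p2[2])^2)
    }
    cyc <- cells[[hit]]
    out <- colMeans(evl1[cyc, , drop = FALSE]) -
      colMeans(evl0[cyc, , drop = FALSE])
  }
  attr(out, "fallback") <- fallback
  out
}

#' Decompose a DCL track into advected and autonomous components
#'
#' Per frame pair, the EVL-advected displacement at the current DCL position
#' is predicted by the chosen deformation model and subtracted from the
#' total displacement; the autonomous component is the remainder, so
#' `total = advected + autonomous` holds exactly by construction. The
#' cumulative autonomous track (starting at the first observed position) is
#' returned for downstream MSD/diffusion analysis.
#'
#' @param dclTrack matrix (n x 3) or data.frame with x, y, z for one DCL
#'   cell across consecutive frames.
#' @param evlFrames list of EVL vertex matrices, one per frame (same frames
#'   as `dclTrack`), e.g. from [evlVertexFrames()].
#' @param model deformation model (see [advectedDisplacement()]).
#' @param R sphere radius (um).
#' @param cells cell cycles for the centre-of-mass model.
#' @return data.frame with per-step displacement components (`dx_adv`,
#'   `dy_adv`, `dz_adv`, `dx_auto`, `dy_auto`, `dz_auto`) and the cumulative
#'   autonomous positions (`x_auto`, `y_auto`, `z_auto`); attribute
#'   `fallbackSteps` lists flagged intervals.
#' @export
decomposeTrack <- function(dclTrack, evlFrames,
                           model = .deformationModels, R, cells = NULL) {
  model <- match.arg(model)
  p <- if (is.data.frame(dclTrack)) as.matrix(dclTrack[, c("x", "y", "z")])
       else as.matrix(dclTrack)
  n <- nrow(p)
  if (length(evlFrames) != n)
    stop("EVL coverage must span every frame of the track")
  adv <- matrix(0, n - 1, 3)
  fb <- logical(n - 1)
  for (k in seq_len(n - 1)) {
    chart <- if (model == "delaunay_barycentric")
      .evlChart(evlFrames[[k]], R) else NULL
    a <- advectedDisplacement(p[k, ], evlFrames[[k]], evlFrames[[k + 1]],
                              model, R, cells, chart = chart)
    adv[k, ] <- a
    fb[k] <- attr(a, "fallback")
  }
  tot <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  auto <- tot - adv
  cum <- rbind(p[1, ], sweep(apply(auto, 2, cumsum), 2, p[1, ], `+`))
  out <- data.frame(frame = seq_len(n - 1),
                    dx_tot = tot[, 1], dy_tot = tot[, 2], dz_tot = tot[, 3],
                    dx_adv = adv[, 1], dy_adv = adv[, 2], dz_adv = adv[, 3],
                    dx_auto = auto[, 1], dy_auto = auto[, 2],
                    dz_auto = auto[, 3])
  attr(out, "autonomousTrack") <- cum
  attr(out, "fallbackSteps") <- which(fb)
  out
}

#' Compare the three EVL deformation models on a synthetic scenario
#'
#' Scores each geometric model against the known analytic deformation field
#' of a synthetic scenario (isotropic or anisotropic EVL expansion): the
#' mean absolute error between predicted and true displacement over random
#' test points in the cap, pooled over frame pairs. Barycentric
#' interpolation over the Delaunay triangulation reproduces affine fields
#' in the chart and has the lowest error of the three (on average slightly
#' underestimating the deformation between vertices).
#'
#' @param variant `"isotropic"` or `"anisotropic"`.
#' @param magnitude per-frame scale increment (default 0.05).
#' @param nPoints number of random test points (default 200).
#' @param seed RNG seed for the test points.
#' @param scenario optional pre-built scenario from
#'   [makeDeformationScenario()].
#' @return data.frame with one row per model: `model`, `meanError` (um).
#' @export
compareDeformationModels <- function(variant = c("isotropic", "anisotropic"),
                                     magnitude = 0.05, nPoints = 200L,
                                     seed = 1L, scenario = NULL) {
  variant <- match.arg(variant)
  if (is.null(scenario))
    scenario <- makeDeformationScenario(variant, magnitude)
  mesh <- scenario$mesh
  R <- mesh@R
  evl <- evlVertexFrames(scenario$tracks)
  nF <- length(evl)
  set.seed(seed)
  cth <- 1 - runif(nPoints) * (1 - cos(pi / 3.5))
  pts <- fromSpherical(acos(cth), runif(nPoints, -pi, pi), R)
  err <- setNames(numeric(length(.deformationModels)), .deformationModels)
  cnt <- 0
  for (f in seq_len(nF - 1)) {
    p0 <- pts
    if (f > 1) {
      # carry the material points with the true field
      for (g in seq_len(f - 1))
        p0 <- p0 + scenario$field(p0, g - 1, g)
    }
    true <- scenario$field(p0, f - 1, f)
    chart <- .evlChart(evl[[f]], R)
    for (m in .deformationModels) {
      pred <- t(vapply(seq_len(nPoints), function(i)
        as.numeric(advectedDisplacement(p0[i, ], evl[[f]], evl[[f + 1]],
                                        m, R, mesh@cells, chart = chart)),
        numeric(3)))
      err[m] <- err[m] + sum(.rowNorms(pred - true))
    }
    cnt <- cnt + nPoints
  }
  data.frame(model = names(err), meanError = unname(err) / cnt)
}
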