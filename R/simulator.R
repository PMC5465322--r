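# The three-force interacting point-particle model: EVL vertex-spring network
# with a constant-velocity free border, and DCL particles under soft-sphere
# repulsion, Gaussian border attraction, barycentric drag and tangential
# noise, integrated with an overdamped forward-Euler scheme on the sphere.

# Attraction potential depth per unit U2 (um^2/min). Together with
# sigmaDiffusionScale this fixes the dimensionless balance between border
# attraction and noise: at the fitted optimum (U2 = 0.3, sigma = 2e4) the
# potential depth is 3x the effective diffusion coefficient, giving the
# border-concentrated stationary distribution seen in the data.
borderAttractionScale <- 20

.meshBorderEdges <- function(mesh) {
  ed <- do.call(rbind, lapply(mesh@cells, function(cyc)
    cbind(cyc, cyc[c(2:length(cyc), 1L)])))
  ed <- t(apply(ed, 1, sort))
  unique(ed)
}

#' Spring forces on the EVL vertex network
#'
#' Force on vertex i is the negative gradient of the total harmonic spring
#' energy `sum U0/2 * w_s * (|r_i - r_j| - L_s)^2` over cell-edge springs and
#' opposite-vertex springs, optionally projected onto the local tangent
#' plane of the sphere (particles are confined to the surface).
#'
#' @param mesh an [EVLMesh-class].
#' @param U0 spring elastic constant (1/min).
#' @param project logical; project forces to the tangent plane (default).
#' @return numeric matrix (nVertices x 3) of forces.
#' @export
evlSpringForces <- function(mesh, U0, project = TRUE) {
  evl_forces_cpp(mesh@vertices, mesh@springs[, 1] - 1L,
                 mesh@springs[, 2] - 1L, mesh@restLength, mesh@springStiff,
                 U0, project)
}

#' Total harmonic spring energy of an EVL mesh
#'
#' @inheritParams evlSpringForces
#' @param vertices optional replacement vertex matrix (for gradient checks).
#' @return scalar energy (um^2/min when multiplied by U0's units).
#' @export
evlSpringEnergy <- function(mesh, U0, vertices = mesh@vertices) {
  i <- mesh@springs[, 1]; j <- mesh@springs[, 2]
  len <- .rowNorms(vertices[i, , drop = FALSE] - vertices[j, , drop = FALSE])
  sum(U0 / 2 * mesh@springStiff * (len - mesh@restLength)^2)
}

#' Advance the free (vegetal) border of the EVL
#'
#' Each margin vertex is displaced by arc length `V0 * dt` along its local
#' meridian toward the vegetal pole (increasing polar angle), staying on the
#' sphere; bulk vertices are untouched. A vertex already at the vegetal pole
#' has no defined meridian tangent and is clamped there (with a warning).
#'
#' @param mesh an [EVLMesh-class] with at least one border vertex.
#' @param V0 margin speed (um/min).
#' @param dt time step (min).
#' @return the advanced [EVLMesh-class].
#' @export
advanceBorder <- function(mesh, V0, dt) {
  idx <- which(mesh@isBorder)
  if (!length(idx)) stop("mesh has no border vertices")
  if (V0 == 0 || dt == 0) return(mesh)
  s <- toSpherical(mesh@vertices[idx, , drop = FALSE])
  atPole <- s$theta >= pi - 1e-9
  if (any(atPole))
    warning(sum(atPole), " border vertex/vertices clamped at the vegetal pole")
  th <- pmin(pi, s$theta + ifelse(atPole, 0, V0 * dt / mesh@R))
  mesh@vertices[idx, ] <- fromSpherical(th, s$phi, mesh@R)
  mesh
}

#' Barycentric coordinates of a point in a triangle
#'
#' Weights `(g1, g2, g3)` with `sum(g) = 1` reconstructing `p` as
#' `g1 r1 + g2 r2 + g3 r3` (least-squares in the triangle plane for 3D
#' input). Used to express a DCL position in terms of its three associated
#' EVL vertices.
#'
#' @param p numeric(2 or 3), the query point.
#' @param triangle matrix (3 x 2 or 3 x 3) of vertex positions (rows).
#' @return numeric(3) of weights summing to 1.
#' @examples
#' tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
#' barycentricWeights(c(1 / 3, 1 / 3), tri)
#' @export
barycentricWeights <- function(p, triangle) {
  triangle <- as.matrix(triangle)
  if (ncol(triangle) == 2L) {
    triangle <- cbind(triangle, 0)
    p <- c(p, 0)
  }
  e1 <- triangle[2, ] - triangle[1, ]
  e2 <- triangle[3, ] - triangle[1, ]
  a <- sum(e1 * e1); b <- sum(e1 * e2); cc <- sum(e2 * e2)
  det <- a * cc - b^2
  if (det < 1e-10 * max(a, cc)^2 || max(a, cc) == 0)
    stop("degenerate triangle")
  q <- p - triangle[1, ]
  r1 <- sum(e1 * q); r2 <- sum(e2 * q)
  g2 <- (cc * r1 - b * r2) / det
  g3 <- (a * r2 - b * r1) / det
  c(1 - g2 - g3, g2, g3)
}

.tangentBasis <- function(rhat) {
  ax <- if (abs(rhat[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- .cross3(rhat, ax); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(rhat, e1)
  rbind(e1, e2)
}

.closestOnBorder <- function(p, verts, edges) {
  # exact geodesic closest point over all border segments; p, verts in um
  R <- sqrt(sum(p^2))
  up <- p / R
  uv <- .unitRows(verts)
  best <- Inf; bestPt <- NULL
  for (s in seq_len(nrow(edges))) {
    a <- uv[edges[s, 1], ]; b <- uv[edges[s, 2], ]
    n <- .cross3(a, b); nn <- sqrt(sum(n^2))
    if (nn < 1e-14) next
    n <- n / nn
    sv <- up - sum(up * n) * n
    sn <- sqrt(sum(sv^2))
    cand <- list(a, b)
    if (sn > 1e-14) {
      f <- sv / sn
      ab <- atan2(sqrt(sum(.cross3(a, b)^2)), sum(a * b))
      af <- atan2(sqrt(sum(.cross3(a, f)^2)), sum(a * f))
      fb <- atan2(sqrt(sum(.cross3(f, b)^2)), sum(f * b))
      if (af + fb <= ab + 1e-10) cand <- c(cand, list(f))
    }
    for (q in cand) {
      d <- atan2(sqrt(sum(.cross3(up, q)^2)), sum(up * q))
      if (d < best) { best <- d; bestPt <- q }
    }
  }
  list(dist = best * R, point = bestPt * R)
}

#' One-step displacement of DCL particles
#'
#' Reference implementation of the per-step displacement
#' `dt * (F_repulsion + F_attraction + drag * v_EVL) + noise`, with each
#' force as in the full integrator: harmonic soft-sphere repulsion of
#' amplitude `U1` active when two particles overlap; attraction to the
#' nearest EVL cell border with the Gaussian potential
#' `-U2 * borderAttractionScale * exp(-d^2 / (2 a2^2))`; drag equal to the
#' barycentric blend of the three nearest EVL vertex velocities; and
#' zero-mean tangential Gaussian noise with per-component variance
#' `2 * sigma * sigmaDiffusionScale * dt`. The result is the displacement
#' before re-projection to the sphere. Used for unit-level checks; the
#' production integrator is [runSimulation()].
#'
#' @param pop a [DCLPopulation-class].
#' @param mesh an [EVLMesh-class] (current vertex positions).
#' @param params a [SimParams-class].
#' @param evlVelocities numeric matrix (nVertices x 3) of the current EVL
#'   vertex velocities (um/min); zero matrix if NULL.
#' @param noise logical; include the stochastic term (uses the R RNG).
#' @return numeric matrix (nParticles x 3) of displacements (um).
#' @export
dclDisplacement <- function(pop, mesh, params, evlVelocities = NULL,
                            noise = TRUE) {
  pos <- pop@positions
  n <- nrow(pos)
  if (is.null(evlVelocities))
    evlVelocities <- matrix(0, nrow(mesh@vertices), 3)
  edges <- .meshBorderEdges(mesh)
  disp <- matrix(0, n, 3)
  sdStep <- sqrt(2 * params@sigma * sigmaDiffusionScale * params@dt)
  for (i in seq_len(n)) {
    p <- pos[i, ]
    rhat <- p / sqrt(sum(p^2))
    f <- c(0, 0, 0)
    if (params@U1 > 0 && n > 1) {
      for (j in seq_len(n)[-i]) {
        d <- p - pos[j, ]
        len <- sqrt(sum(d^2))
        touch <- pop@radius[i] + pop@radius[j]
        if (len < touch && len > 1e-9)
          f <- f + params@U1 * (touch - len) * d / len
      }
    }
    if (params@U2 > 0 && nrow(edges)) {
      cl <- .closestOnBorder(p, mesh@vertices, edges)
      if (is.finite(cl$dist) && cl$dist > 1e-9) {
        dir <- cl$point - p
        dir <- dir / sqrt(sum(dir^2))
        fm <- params@U2 * borderAttractionScale *
          (cl$dist / params@a2^2) * exp(-cl$dist^2 / (2 * params@a2^2))
        f <- f + fm * dir
      }
    }
    if (params@drag > 0) {
      dd <- .rowNorms(sweep(mesh@vertices, 2, p))
      nn <- order(dd)[1:3]
      w <- bary3_weights_cpp(p, mesh@vertices[nn, , drop = FALSE])
      f <- f + params@drag * as.numeric(w %*% evlVelocities[nn, , drop = FALSE])
    }
    f <- f - sum(f * rhat) * rhat
    d <- f * params@dt
    if (noise && sdStep > 0) {
      tb <- .tangentBasis(rhat)
      d <- d + rnorm(1, 0, sdStep) * tb[1, ] + rnorm(1, 0, sdStep) * tb[2, ]
    }
    disp[i, ] <- d
  }
  disp
}

#' Apply scheduled DCL cell divisions
#'
#' Every division scheduled at or before time `t` replaces its parent with
#' two daughters of radius `(1/2)^(1/3)` times the parent radius (halving
#' the cell volume), separated by one parent radius along a random tangent
#' direction. Both daughters are marked as divided; a cell can divide only
#' once.
#'
#' @param pop a [DCLPopulation-class].
#' @param t current time (min); divisions with `divisionTime <= t` fire.
#' @return the updated [DCLPopulation-class].
#' @export
applyDivisions <- function(pop, t) {
  due <- which(!is.na(pop@divisionTime) & pop@divisionTime <= t)
  if (!length(due)) return(pop)
  if (any(pop@hasDivided[due]))
    stop("schedule validation: division scheduled for an already-divided cell")
  R <- sqrt(sum(pop@positions[1, ]^2))
  for (i in due) {
    p <- pop@positions[i, ]
    rhat <- p / sqrt(sum(p^2))
    tb <- .tangentBasis(rhat)
    phi <- runif(1, 0, 2 * pi)
    dir <- cos(phi) * tb[1, ] + sin(phi) * tb[2, ]
    half <- pop@radius[i] / 2
    rd <- pop@radius[i] * 0.5^(1 / 3)
    q1 <- p + half * dir; q1 <- q1 * R / sqrt(sum(q1^2))
    q2 <- p - half * dir; q2 <- q2 * R / sqrt(sum(q2^2))
    pop@positions[i, ] <- q1
    pop@positions <- rbind(pop@positions, q2)
    pop@radius[i] <- rd
    pop@radius <- c(pop@radius, rd)
    pop@hasDivided[i] <- TRUE
    pop@hasDivided <- c(pop@hasDivided, TRUE)
    pop@divisionTime[i] <- NA_real_
    pop@divisionTime <- c(pop@divisionTime, NA_real_)
  }
  validObject(pop)
  pop
}

#' Run the full three-force simulation
#'
#' Overdamped forward-Euler integration of the EVL vertex-spring network and
#' the DCL particle population on the egg sphere, with re-projection to the
#' sphere after every step and recording at the configured frame interval.
#' Fully reproducible from `params@seed`. Aborts with a diagnostic if any
#' per-step displacement exceeds `0.1 * R` (integration instability).
#'
#' @param params a [SimParams-class].
#' @param mesh initial [EVLMesh-class] (e.g. from [makeEvlTessellation()]).
#' @param pop initial [DCLPopulation-class] (e.g. from [makeDclPopulation()]).
#' @return a [TrackTable-class] with per-frame positions of all EVL vertices
#'   (`layer == "EVL_vertex"`, id = vertex index) and DCL particles
#'   (`layer == "DCL"`, with `radius`), plus the EVL cell polygons.
#' @export
runSimulation <- function(params, mesh, pop) {
  stopifnot(is(params, "SimParams"), is(mesh, "EVLMesh"),
            is(pop, "DCLPopulation"))
  validObject(params); validObject(mesh); validObject(pop)
  recordEvery <- as.integer(round(params@frameInterval / params@dt))
  nSteps <- recordEvery * params@nFrames
  divStep <- ifelse(is.na(pop@divisionTime), -1L,
                    pmin(nSteps - 1L,
                         pmax(0L, as.integer(floor(pop@divisionTime /
                                                     params@dt)))))
  edges <- .meshBorderEdges(mesh)
  sdStep <- sqrt(2 * params@sigma * sigmaDiffusionScale * params@dt)
  set.seed(params@seed)
  res <- simulate_core(mesh@vertices, mesh@isBorder,
                       mesh@springs[, 1] - 1L, mesh@springs[, 2] - 1L,
                       mesh@restLength, mesh@springStiff,
                       edges[, 1] - 1L, edges[, 2] - 1L,
                       pop@positions, pop@radius, as.integer(divStep),
                       params@U0, params@V0, params@U1, params@U2, params@a2,
                       sdStep, params@drag, params@dt, params@R,
                       nSteps, recordEvery, borderAttractionScale)
  nFrames <- res$nFrames
  nv <- nrow(mesh@vertices)
  maxn <- dim(res$dcl)[2]
  frames <- rep(seq_len(nFrames) - 1L, each = nv)
  evl <- data.frame(frame = frames,
                    id = rep(seq_len(nv), nFrames),
                    layer = "EVL_vertex",
                    x = as.vector(res$evl[1, , ]),
                    y = as.vector(res$evl[2, , ]),
                    z = as.vector(res$evl[3, , ]),
                    radius = NA_real_)
  dcl <- data.frame(frame = rep(seq_len(nFrames) - 1L, each = maxn),
                    id = rep(seq_len(maxn), nFrames),
                    layer = "DCL",
                    x = as.vector(res$dcl[1, , ]),
                    y = as.vector(res$dcl[2, , ]),
                    z = as.vector(res$dcl[3, , ]),
                    radius = as.vector(res$radius))
  dcl <- dcl[!is.na(dcl$x), ]
  TrackTable(rbind(evl, dcl), cells = mesh@cells,
             sphere = new("SphereFit", center = c(0, 0, 0), radius = params@R,
                          rmsResidual = 0),
             frameInterval = params@frameInterval)
}

#' Per-frame EVL meshes from a track table
#'
#' Rebuilds the EVL vertex matrix of each recorded frame (topology is
#' constant over a run).
#'
#' @param tracks a [TrackTable-class] with an `EVL_vertex` layer.
#' @param frames integer vector of frame numbers (default all).
#' @return named list of numeric vertex matrices, one per frame.
#' @export
evlVertexFrames <- function(tracks, frames = NULL) {
  r <- tracks@records
  r <- r[r$layer == "EVL_vertex", ]
  if (!nrow(r)) stop("track table has no EVL_vertex layer")
  if (is.null(frames)) frames <- sort(unique(r$frame))
  out <- lapply(frames, function(f) {
    rf <- r[r$frame == f, ]
    rf <- rf[order(rf$id), ]
    m <- as.matrix(rf[, c("x", "y", "z")])
    rownames(m) <- rf$id
    m
  })
  names(out) <- frames
  out
}
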