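# Generators producing every input the pipeline needs with known ground
# truth: EVL cap tessellations, DCL populations, full reference datasets,
# pure random walks, analytic deformation scenarios and label masks.

.polygonCentroid <- function(x, y) {
  n <- length(x)
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * A)
}

# Voronoi tessellation of the disc r <= rmax via deldir with mirror ghost
# seeds across the margin circle; returns tile polygons of the real seeds.
.discVoronoi <- function(seeds, rmax) {
  r <- sqrt(rowSums(seeds^2))
  gr <- 2 * rmax - r
  ghosts <- seeds * (gr / pmax(r, 1e-9))
  allpts <- rbind(seeds, ghosts)
  w <- 2.05 * rmax
  dd <- deldir::deldir(allpts[, 1], allpts[, 2], rw = c(-w, w, -w, w),
                       suppressMsge = TRUE)
  list(deldir = dd, tiles = deldir::tile.list(dd)[seq_len(nrow(seeds))],
       nReal = nrow(seeds))
}

#' Generate an EVL cap tessellation on the egg sphere
#'
#' Builds the substrate tissue: a Lloyd-relaxed Voronoi tessellation of the
#' animal-pole cap into polygonal EVL cells, with shared vertices, cell-edge
#' and opposite-vertex springs, and margin (free border) flags. The
#' construction runs in the azimuthal-equidistant projection about the
#' animal pole and is lifted back to the sphere; margin edges are subdivided
#' along the margin circle so the cells partition the spherical cap to high
#' accuracy. The study condition is 50-60 cells on a 592-um egg.
#'
#' @param nCells number of EVL cells (default 55).
#' @param R sphere radius (um, default 592).
#' @param capExtent polar angle of the margin at start (radians, default
#'   pi/3, i.e. the cap reaching 60 degrees from the animal pole).
#' @param seed integer RNG seed.
#' @param lloydIter Lloyd relaxation sweeps (default 25).
#' @param maxArc maximum azimuthal arc (radians) of one subdivided margin
#'   edge (default 0.01).
#' @return an [EVLMesh-class].
#' @export
makeEvlTessellation <- function(nCells = 55L, R = 592, capExtent = pi / 3,
                                seed = 1L, lloydIter = 25L, maxArc = 0.02) {
  if (nCells < 4L) stop("need at least 4 EVL cells")
  set.seed(seed)
  rmax <- R * capExtent
  if (pi * rmax^2 / nCells < (8 * maxArc * rmax)^2 / 10)
    stop("cap too small for the requested cell count")
  rr <- rmax * sqrt(runif(nCells))
  aa <- runif(nCells, 0, 2 * pi)
  seeds <- cbind(rr * cos(aa), rr * sin(aa))
  for (it in seq_len(lloydIter)) {
    dv <- .discVoronoi(seeds, rmax)
    for (i in seq_len(nCells)) {
      ctr <- .polygonCentroid(dv$tiles[[i]]$x, dv$tiles[[i]]$y)
      cr <- sqrt(sum(ctr^2))
      if (cr > 0.999 * rmax) ctr <- ctr * 0.999 * rmax / cr
      seeds[i, ] <- ctr
    }
  }
  dv <- .discVoronoi(seeds, rmax)

  # merged vertex table keyed on rounded coordinates
  key <- function(x, y) paste(round(x, 6), round(y, 6))
  vkeys <- character(0); vx <- numeric(0); vy <- numeric(0)
  cycles <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    tx <- dv$tiles[[i]]$x; ty <- dv$tiles[[i]]$y
    ks <- key(tx, ty)
    idx <- match(ks, vkeys)
    miss <- which(is.na(idx))
    if (length(miss)) {
      vkeys <- c(vkeys, ks[miss])
      vx <- c(vx, tx[miss]); vy <- c(vy, ty[miss])
      idx <- match(ks, vkeys)
    }
    # enforce counter-clockwise orientation
    n <- length(tx)
    a2s <- sum(tx * ty[c(2:n, 1)] - tx[c(2:n, 1)] * ty)
    cycles[[i]] <- if (a2s >= 0) idx else rev(idx)
  }

  # border vertices: endpoints of Voronoi edges separating a real seed from
  # a ghost seed; snapped exactly onto the margin circle
  sgs <- dv$deldir$dirsgs
  ghostEdge <- (sgs$ind1 > dv$nReal) != (sgs$ind2 > dv$nReal)
  bkeys <- unique(c(key(sgs$x1[ghostEdge], sgs$y1[ghostEdge]),
                    key(sgs$x2[ghostEdge], sgs$y2[ghostEdge])))
  isBorder <- vkeys %in% bkeys
  br <- sqrt(vx[isBorder]^2 + vy[isBorder]^2)
  vx[isBorder] <- vx[isBorder] * rmax / br
  vy[isBorder] <- vy[isBorder] * rmax / br

  # springs from the un-subdivided cycles
  edgePairs <- unique(t(apply(do.call(rbind, lapply(cycles, function(cyc)
    cbind(cyc, cyc[c(2:length(cyc), 1L)]))), 1, sort)))
  oppPairs <- NULL; oppStiff <- NULL
  for (cyc in cycles) {
    m <- length(cyc)
    if (m < 4L) next
    half <- floor(m / 2)
    pr <- cbind(cyc, cyc[(seq_len(m) + half - 1L) %% m + 1L])
    st <- rep(if (m %% 2 == 0) 1 else 0.5, m)
    if (m %% 2 == 1) {
      pr <- rbind(pr, cbind(cyc, cyc[(seq_len(m) + half) %% m + 1L]))
      st <- c(st, rep(0.5, m))
    }
    pr <- t(apply(pr, 1, sort))
    keep <- !duplicated(pr)
    oppPairs <- rbind(oppPairs, pr[keep, , drop = FALSE])
    oppStiff <- c(oppStiff, st[keep])
  }
  if (!is.null(oppPairs)) {
    dup <- duplicated(rbind(edgePairs, oppPairs))[-seq_len(nrow(edgePairs))]
    oppPairs <- oppPairs[!dup, , drop = FALSE]
    oppStiff <- oppStiff[!dup]
  }

  # subdivide margin chords along the circle (new border vertices, in-cycle)
  nv0 <- length(vx)
  for (i in seq_len(nCells)) {
    cyc <- cycles[[i]]
    out <- integer(0)
    m <- length(cyc)
    for (k in seq_len(m)) {
      a <- cyc[k]; b <- cyc[if (k == m) 1L else k + 1L]
      out <- c(out, a)
      if (isBorder[a] && isBorder[b]) {
        pha <- atan2(vy[a], vx[a]); phb <- atan2(vy[b], vx[b])
        dph <- (phb - pha) %% (2 * pi)
        if (dph > pi) dph <- dph - 2 * pi
        nseg <- max(1L, ceiling(abs(dph) / maxArc))
        if (nseg > 1L) {
          phs <- pha + dph * seq_len(nseg - 1L) / nseg
          newIdx <- length(vx) + seq_along(phs)
          vx <- c(vx, rmax * cos(phs)); vy <- c(vy, rmax * sin(phs))
          isBorder <- c(isBorder, rep(TRUE, length(phs)))
          out <- c(out, newIdx)
        }
      }
    }
    cycles[[i]] <- out
  }

  # break the exact cocircularity of the margin vertices (degenerate for
  # downstream Delaunay triangulations) with a deterministic radial jitter
  # far below any analysis tolerance
  jit <- which(isBorder)
  ph <- atan2(vy[jit], vx[jit])
  fac <- 1 + 1e-7 * sin(9901 * ph)
  vx[jit] <- vx[jit] * fac
  vy[jit] <- vy[jit] * fac

  verts <- azimuthalUnprojection(cbind(vx, vy), R)
  springs <- rbind(edgePairs, oppPairs)
  stiff <- c(rep(1, nrow(edgePairs)), oppStiff)
  type <- c(rep("edge", nrow(edgePairs)),
            rep("opposite", if (is.null(oppPairs)) 0 else nrow(oppPairs)))
  rest <- .rowNorms(verts[springs[, 1], , drop = FALSE] -
                    verts[springs[, 2], , drop = FALSE])
  mesh <- new("EVLMesh", vertices = verts, isBorder = isBorder,
              cells = cycles, springs = springs, springType = type,
              restLength = rest, springStiff = stiff, R = R)

  targetRadius <- sqrt(sphericalCapArea(capExtent, R) / (nCells * pi))
  areas <- vapply(cycles, function(cyc)
    sphericalPolygonArea(verts[cyc, , drop = FALSE], R), numeric(1))
  if (abs(mean(sqrt(areas / pi)) / targetRadius - 1) > 0.15)
    warning("mean equivalent cell radius deviates > 15% from target")
  mesh
}

#' Areas of the EVL cells of a mesh
#'
#' @param mesh an [EVLMesh-class], or a vertex matrix plus `cells`.
#' @param cells list of vertex cycles when `mesh` is a matrix.
#' @param R sphere radius when `mesh` is a matrix.
#' @return numeric vector of spherical polygon areas (um^2).
#' @export
evlCellAreas <- function(mesh, cells = NULL, R = NULL) {
  if (is(mesh, "EVLMesh")) {
    verts <- mesh@vertices; cells <- mesh@cells; R <- mesh@R
  } else verts <- mesh
  vapply(cells, function(cyc)
    sphericalPolygonArea(verts[cyc, , drop = FALSE], R), numeric(1))
}

#' Generate an initial DCL particle population
#'
#' Particles uniformly distributed over the tessellated animal cap (the
#' pre-epiboly DCL is spread under the EVL with free intercellular space),
#' with an asynchronous division schedule drawn uniformly over a window.
#' The study condition is 100-120 cells doubling once.
#'
#' @param nCells initial DCL cell count (default 110).
#' @param R sphere radius (um).
#' @param capExtent polar extent of the seeded cap (radians); use the
#'   tessellation's extent.
#' @param radius cell radius (um, default 12).
#' @param divisionWindow numeric(2), time window (min) over which division
#'   times are drawn uniformly; NULL for no divisions.
#' @param seed integer RNG seed.
#' @return a [DCLPopulation-class].
#' @export
makeDclPopulation <- function(nCells = 110L, R = 592, capExtent = pi / 3,
                              radius = 12, divisionWindow = c(150, 450),
                              seed = 1L) {
  set.seed(seed)
  cth <- 1 - runif(nCells) * (1 - cos(capExtent))
  th <- acos(cth)
  ph <- runif(nCells, -pi, pi)
  pos <- fromSpherical(th, ph, R)
  divt <- if (is.null(divisionWindow)) rep(NA_real_, nCells)
          else runif(nCells, divisionWindow[1], divisionWindow[2])
  new("DCLPopulation", positions = pos, radius = rep(radius, nCells),
      hasDivided = rep(FALSE, nCells), divisionTime = divt)
}

#' Generate a full reference dataset with known ground truth
#'
#' Builds a tessellation and a DCL population under the study conditions and
#' runs the three-force simulation, returning the tracks together with a
#' sealed record of the generating inputs for parameter-recovery tests.
#' Stands in for experiment-like 4D track data.
#'
#' @param params a [SimParams-class] (the generating parameters).
#' @param nEvlCells,nDclCells cell counts (defaults 55 and 110).
#' @param capExtent cap polar extent (radians).
#' @param dclRadius DCL cell radius (um).
#' @param divisionWindow division time window (min); the default covers all
#'   initial cells so the population doubles over the run.
#' @param seed integer seed for the generators (the simulation itself uses
#'   `params@seed`).
#' @return list with `tracks` ([TrackTable-class]), `mesh`, `pop`, and
#'   `truth` (list of the generating parameter values).
#' @export
makeReferenceDataset <- function(params = SimParams(),
                                 nEvlCells = 55L, nDclCells = 110L,
                                 capExtent = pi / 3, dclRadius = 12,
                                 divisionWindow = NULL, seed = 1L) {
  if (is.null(divisionWindow)) {
    total <- params@nFrames * params@frameInterval
    divisionWindow <- c(0.25, 0.75) * total
  }
  mesh <- makeEvlTessellation(nEvlCells, params@R, capExtent, seed = seed)
  pop <- makeDclPopulation(nDclCells, params@R, capExtent, dclRadius,
                           divisionWindow, seed = seed + 1L)
  tracks <- runSimulation(params, mesh, pop)
  list(tracks = tracks, mesh = mesh, pop = pop,
       truth = list(U0 = params@U0, V0 = params@V0, U1 = params@U1,
                    U2 = params@U2, a2 = params@a2, sigma = params@sigma,
                    drag = params@drag, seed = params@seed))
}

#' Generate pure tangential random walks on the sphere
#'
#' Independent Brownian tracks with per-tangent-component step variance
#' `2 * D * dt`, re-projected to the sphere after every step: the null model
#' of autonomous DCL motility (the measured coefficient in the killifish
#' data is D = 31.2 um^2/s).
#'
#' @param n number of tracks.
#' @param D diffusion coefficient (um^2 per unit of `dt`).
#' @param dt frame interval (any time unit, consistent with `D`).
#' @param nFrames frames after the first.
#' @param R sphere radius (um).
#' @param seed integer RNG seed.
#' @param capExtent polar extent over which starting points are spread.
#' @return a [TrackTable-class] with layer `"DCL"` and `frameInterval = dt`.
#' @export
makeRandomWalks <- function(n, D, dt, nFrames, R = 592, seed = 1L,
                            capExtent = pi / 3) {
  set.seed(seed)
  cth <- 1 - runif(n) * (1 - cos(capExtent))
  pos <- fromSpherical(acos(cth), runif(n, -pi, pi), R)
  sdStep <- sqrt(2 * D * dt)
  out <- vector("list", nFrames + 1L)
  out[[1]] <- pos
  for (f in seq_len(nFrames)) {
    for (i in seq_len(n)) {
      rhat <- pos[i, ] / sqrt(sum(pos[i, ]^2))
      tb <- .tangentBasis(rhat)
      p <- pos[i, ] + rnorm(1, 0, sdStep) * tb[1, ] +
        rnorm(1, 0, sdStep) * tb[2, ]
      pos[i, ] <- p * R / sqrt(sum(p^2))
    }
    out[[f + 1L]] <- pos
  }
  rec <- do.call(rbind, lapply(seq_along(out), function(f)
    data.frame(frame = f - 1L, id = seq_len(n), layer = "DCL",
               x = out[[f]][, 1], y = out[[f]][, 2], z = out[[f]][, 3])))
  TrackTable(rec, sphere = new("SphereFit", center = c(0, 0, 0), radius = R,
                               rmsResidual = 0), frameInterval = dt)
}

#' Generate an EVL deformation scenario with a known displacement field
#'
#' Deforms the vertices of a tessellated cap by an analytic field and
#' returns both the vertex tracks and the field function, for exercising
#' and scoring the EVL deformation models. `isotropic` scales the polar arc
#' from the animal pole uniformly; `anisotropic` scales the two
#' azimuthal-equidistant chart axes by different factors.
#'
#' @param variant `"isotropic"` or `"anisotropic"`.
#' @param magnitude scale increment per frame (e.g. 0.05 for 5% per frame).
#' @param mesh an [EVLMesh-class]; default builds one under study conditions.
#' @param nFrames number of deformation steps (default 5).
#' @param anisotropy ratio of the v-axis to u-axis scaling for the
#'   anisotropic variant (default 0.25).
#' @return list with `tracks` ([TrackTable-class]), `field` (function of a
#'   point matrix and frame pair `(f0, f1)` returning true displacements),
#'   and `mesh`.
#' @export
makeDeformationScenario <- function(variant = c("isotropic", "anisotropic"),
                                    magnitude = 0.05, mesh = NULL,
                                    nFrames = 5L, anisotropy = 0.25) {
  variant <- match.arg(variant)
  if (is.null(mesh)) mesh <- makeEvlTessellation(seed = 1L)
  R <- mesh@R
  scaleAt <- function(f) {
    su <- 1 + magnitude * f
    sv <- 1 + magnitude * f * (if (variant == "anisotropic") anisotropy else 1)
    c(su, sv)
  }
  warp <- function(p, f) {
    uv <- azimuthalProjection(p, R)
    s <- scaleAt(f)
    azimuthalUnprojection(cbind(uv[, 1] * s[1], uv[, 2] * s[2]), R)
  }
  field <- function(p, f0, f1) {
    # true displacement of material points at p observed in frame f0
    uv <- azimuthalProjection(p, R)
    s0 <- scaleAt(f0); s1 <- scaleAt(f1)
    uv0 <- cbind(uv[, 1] / s0[1], uv[, 2] / s0[2])
    warpTo <- azimuthalUnprojection(cbind(uv0[, 1] * s1[1],
                                          uv0[, 2] * s1[2]), R)
    warpTo - p
  }
  base <- mesh@vertices
  rec <- do.call(rbind, lapply(0:nFrames, function(f) {
    v <- warp(base, f)
    data.frame(frame = f, id = seq_len(nrow(v)), layer = "EVL_vertex",
               x = v[, 1], y = v[, 2], z = v[, 3])
  }))
  tracks <- TrackTable(rec, cells = mesh@cells,
                       sphere = new("SphereFit", center = c(0, 0, 0),
                                    radius = R, rmsResidual = 0),
                       frameInterval = 10)
  list(tracks = tracks, field = field, mesh = mesh)
}

#' Generate synthetic body/membrane label-mask pairs
#'
#' Voxelizes a cell body (disc) with attached protrusion shapes of known
#' class for exercising the protrusion detector: `"bar"` gives an elongated
#' protrusion, `"bump"` a round (half-disc) one.
#'
#' @param bodyRadius body radius (um).
#' @param protrusions list of lists with fields `type` (`"bar"` or
#'   `"bump"`), `angle` (radians, orientation from the body centre),
#'   `length`, `width` (um; `width` is the bump radius for `"bump"`).
#' @param spacing pixel size (um/px, default 0.22).
#' @param pad padding (px).
#' @return list with `body` and `membrane` (integer matrices; membrane
#'   includes the body plus protrusions), and `spacing`.
#' @export
makeLabelMasks <- function(bodyRadius = 5, protrusions = list(),
                           spacing = 0.22, pad = 12L) {
  ext <- bodyRadius + max(c(0, vapply(protrusions, function(p)
    p$length + p$width, numeric(1))))
  npx <- 2L * (as.integer(ceiling(ext / spacing)) + pad)
  cx <- (npx + 1) / 2
  xs <- (seq_len(npx) - cx) * spacing
  X <- matrix(xs, npx, npx)
  Y <- t(X)
  body <- (X^2 + Y^2 <= bodyRadius^2) * 1L
  mem <- body
  for (p in protrusions) {
    ca <- cos(p$angle); sa <- sin(p$angle)
    U <- X * ca + Y * sa   # along the protrusion axis
    V <- -X * sa + Y * ca
    if (p$type == "bar") {
      shape <- (U >= bodyRadius - 2 * spacing) &
        (U <= bodyRadius + p$length) & (abs(V) <= p$width / 2)
    } else if (p$type == "bump") {
      shape <- ((U - bodyRadius)^2 + V^2 <= p$width^2) & (U >= bodyRadius)
      # ensure contact with the body
      shape <- shape | ((U >= bodyRadius - 2 * spacing) & (U <= bodyRadius) &
                          (abs(V) <= p$width))
    } else stop("unknown protrusion type: ", p$type)
    touch <- EBImage::dilate(body, EBImage::makeBrush(3, "box")) > 0
    if (!any(shape & touch)) stop("protrusion does not touch the body")
    mem[shape] <- 1L
  }
  list(body = body, membrane = mem, spacing = c(spacing, spacing))
}
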