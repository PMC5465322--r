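# Cell-parameter analytics on track tables: greedy linking with QC flags,
# MSD and diffusion fitting, directionality, neighbour distances,
# distance-to-border distributions, covered area, epiboly index and the
# EVL-DCL area relation.

#' Link per-frame detections into tracks (greedy nearest-centroid)
#'
#' Distance-based tracking over the cell centre of mass: each active track
#' is linked to the closest unclaimed detection in the next frame, taking
#' candidate links in order of increasing distance. Quality-control flags
#' are raised -- never silently dropping data -- for per-frame area change
#' above `areaTolerance` (200% for EVL cells, 50% for DCL cells),
#' displacement above `maxSpeed` (35 um per frame), and appearing or
#' disappearing trajectories.
#'
#' @param detections data.frame with columns `frame`, `x`, `y`, `z` and
#'   optionally `area`.
#' @param layer `"DCL"` or `"EVL"`; sets the default area tolerance.
#' @param maxSpeed displacement flag threshold (um per frame).
#' @param areaTolerance relative area-change flag threshold (2 for EVL,
#'   0.5 for DCL when NULL).
#' @return list with `tracks` (the input rows plus `id`) and `flags`
#'   (data.frame of `frame`, `id`, `flag`).
#' @export
linkTracks <- function(detections, layer = c("DCL", "EVL"), maxSpeed = 35,
                       areaTolerance = NULL) {
  layer <- match.arg(layer)
  if (is.null(areaTolerance)) areaTolerance <- if (layer == "EVL") 2 else 0.5
  hasArea <- "area" %in% names(detections)
  frames <- sort(unique(detections$frame))
  det <- split(detections, detections$frame)
  flags <- data.frame(frame = integer(0), id = integer(0),
                      flag = character(0))
  addFlag <- function(f, id, what)
    flags <<- rbind(flags, data.frame(frame = f, id = id, flag = what))
  first <- det[[as.character(frames[1])]]
  first$id <- seq_len(nrow(first))
  nextId <- nrow(first) + 1L
  out <- list(first)
  active <- first
  for (k in seq_along(frames)[-1]) {
    cur <- det[[as.character(frames[k])]]
    if (is.null(cur) || !nrow(cur)) {
      for (id in active$id) addFlag(frames[k], id, "disappeared")
      active <- active[0, ]
      next
    }
    cur$id <- NA_integer_
    if (nrow(active)) {
      dmat <- outer(seq_len(nrow(active)), seq_len(nrow(cur)),
                    Vectorize(function(i, j)
                      sqrt(sum((c(active$x[i], active$y[i], active$z[i]) -
                                c(cur$x[j], cur$y[j], cur$z[j]))^2))))
      ord <- order(dmat)
      usedA <- logical(nrow(active)); usedC <- logical(nrow(cur))
      for (o in ord) {
        i <- (o - 1L) %% nrow(active) + 1L
        j <- (o - 1L) %/% nrow(active) + 1L
        if (usedA[i] || usedC[j]) next
        usedA[i] <- TRUE; usedC[j] <- TRUE
        cur$id[j] <- active$id[i]
        if (dmat[i, j] > maxSpeed)
          addFlag(frames[k], active$id[i], "speed")
        if (hasArea && is.finite(active$area[i]) && active$area[i] > 0) {
          rel <- abs(cur$area[j] - active$area[i]) / active$area[i]
          if (rel > areaTolerance)
            addFlag(frames[k], active$id[i], "area")
        }
      }
      for (i in which(!usedA)) addFlag(frames[k], active$id[i], "disappeared")
    }
    newborn <- which(is.na(cur$id))
    if (length(newborn)) {
      cur$id[newborn] <- nextId + seq_along(newborn) - 1L
      nextId <- nextId + length(newborn)
      for (j in newborn) addFlag(frames[k], cur$id[j], "appeared")
    }
    out[[k]] <- cur
    active <- cur
  }
  list(tracks = do.call(rbind, out), flags = flags)
}

.dclTrackMatrix <- function(tracks, layer = "DCL") {
  r <- if (is(tracks, "TrackTable")) tracks@records else tracks
  r <- r[r$layer == layer, c("frame", "id", "x", "y", "z")]
  split(r[order(r$frame), ], r$id[order(r$frame)])
}

#' Mean square displacement of tracks
#'
#' Sliding-window MSD: for each lag (1 to `maxLag` frames), the mean squared
#' 3D Euclidean displacement between window start and end, over all windows
#' of all tracks (`pooled = TRUE`, default) or averaged per track first.
#'
#' @param tracks a [TrackTable-class] or a records data.frame; only rows
#'   with `layer == layer` are used.
#' @param maxLag largest window size in frames (default 25).
#' @param pooled pool all window displacements before averaging.
#' @param layer layer to analyse (default `"DCL"`).
#' @return data.frame with columns `lag` (frames), `time` (in frame-interval
#'   units), `msd` (um^2), `n` (windows); MSD(0) = 0 is not included.
#' @export
msdCurve <- function(tracks, maxLag = 25L, pooled = TRUE, layer = "DCL") {
  fi <- if (is(tracks, "TrackTable")) tracks@frameInterval else 1
  trs <- .dclTrackMatrix(tracks, layer)
  len <- vapply(trs, nrow, 1L)
  if (max(len) < 2L) stop("need tracks with at least 2 frames")
  if (maxLag >= max(len))
    warning("maxLag >= longest track; computing only valid lags")
  lags <- seq_len(min(maxLag, max(len) - 1L))
  perLag <- lapply(lags, function(L) {
    vals <- lapply(trs, function(tr) {
      n <- nrow(tr)
      if (n <= L) return(NULL)
      p <- as.matrix(tr[, c("x", "y", "z")])
      rowSums((p[(1 + L):n, , drop = FALSE] -
                 p[1:(n - L), , drop = FALSE])^2)
    })
    if (pooled) {
      v <- unlist(vals)
      c(mean(v), length(v))
    } else {
      m <- vapply(vals[!vapply(vals, is.null, TRUE)], mean, numeric(1))
      c(mean(m), length(m))
    }
  })
  out <- do.call(rbind, perLag)
  data.frame(lag = lags, time = lags * fi, msd = out[, 1], n = out[, 2])
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Ordinary least squares of MSD against lag time; for a random walk on the
#' locally flat egg surface (two tangent dimensions), `D = slope / 4`.
#'
#' @param msd data.frame from [msdCurve()] (columns `time`, `msd`).
#' @param dims surface dimensionality convention (default 2; use 3 to switch
#'   to slope/6).
#' @return list with `D` (um^2 per time unit), `rSquared`, `slope`,
#'   `intercept`, `flagged` (TRUE when the fit is undefined).
#' @export
fitDiffusion <- function(msd, dims = 2L) {
  if (nrow(msd) < 3L) stop("need at least 3 lags")
  if (all(msd$msd == 0))
    return(list(D = 0, rSquared = NA_real_, slope = 0, intercept = 0,
                flagged = TRUE))
  fit <- lm(msd ~ time, data = msd)
  list(D = unname(coef(fit)[2]) / (2 * dims),
       rSquared = suppressWarnings(summary(fit)$r.squared),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       flagged = FALSE)
}

#' Directionality of a track
#'
#' Ratio of net displacement over total trajectory length, both in 3D:
#' 1 for straight-line motion, 0 for a closed loop.
#'
#' @param track matrix (n x 3) of positions, or a one-track data.frame with
#'   x, y, z columns.
#' @return scalar in `[0, 1]`; NA (with a warning) for zero path length.
#' @export
directionality <- function(track) {
  p <- if (is.data.frame(track)) as.matrix(track[, c("x", "y", "z")])
       else as.matrix(track)
  if (nrow(p) < 2L) stop("need at least 2 frames")
  steps <- .rowNorms(p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])
  L <- sum(steps)
  if (L == 0) {
    warning("zero path length; directionality undefined")
    return(NA_real_)
  }
  sqrt(sum((p[nrow(p), ] - p[1, ])^2)) / L
}

#' Mean geodesic distance to the k nearest neighbours
#'
#' Per-cell mean of the geodesic distances to its k nearest neighbours on
#' the egg sphere (k = 6 for the dispersion statistic, k = 3 for the
#' close-neighbour variant).
#'
#' @param positions matrix (n x 3) of cell positions.
#' @param k neighbour count; must satisfy `k < n`.
#' @param R sphere radius (um).
#' @return numeric(n) of per-cell mean distances (um).
#' @export
nearestNeighbourDistance <- function(positions, k, R) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (k >= n) stop("k must be smaller than the number of points")
  u <- .unitRows(positions)
  cosang <- tcrossprod(u)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  d <- R * acos(cosang)
  vapply(seq_len(n), function(i)
    mean(sort(d[i, -i], partial = k)[seq_len(k)]), numeric(1))
}

#' Analytic distance-to-border density for uniform points in a disc
#'
#' For points uniform in a disc of radius `Rc` (the equivalent EVL cell
#' surface radius, 120 um in the killifish data), the distance to the disc
#' border has density `p(d) = 2 (Rc - d) / Rc^2` on `[0, Rc]` -- the
#' straight-line random baseline against which border preference is judged.
#'
#' @param d distances (um).
#' @param Rc equivalent cell radius (um, default 120).
#' @return density values.
#' @export
borderBaselineDensity <- function(d, Rc = 120) {
  ifelse(d >= 0 & d <= Rc, 2 * (Rc - d) / Rc^2, 0)
}

#' Distances of DCL positions to the nearest EVL cell border
#'
#' Exact minimum geodesic distance of each position to any border segment
#' of the EVL polygon set.
#'
#' @param positions matrix (n x 3) of DCL positions.
#' @param vertices matrix of EVL vertex positions.
#' @param cells list of cell vertex cycles.
#' @param R sphere radius (um).
#' @return numeric(n) of distances (um).
#' @export
dclBorderDistances <- function(positions, vertices, cells, R) {
  edges <- do.call(rbind, lapply(cells, function(cyc)
    cbind(cyc, cyc[c(2:length(cyc), 1L)])))
  edges <- unique(t(apply(edges, 1, sort)))
  u <- .unitRows(as.matrix(positions))
  uv <- .unitRows(as.matrix(vertices))
  R * point_segments_min_angle(u, uv, edges[, 1] - 1L, edges[, 2] - 1L)
}

#' Distribution of DCL distance to EVL cell borders
#'
#' Normalized histogram of the DCL-to-nearest-border distances plus the
#' analytic uniform-in-disc baseline. Points outside all polygons can be
#' flagged and excluded by passing their indices.
#'
#' @param positions matrix (n x 3) of DCL positions.
#' @param vertices,cells,R the EVL polygon set as in [dclBorderDistances()],
#'   or `distances` directly.
#' @param distances optional precomputed distances (um); overrides the
#'   polygon inputs.
#' @param binWidth histogram bin width (um, default 5).
#' @param Rc equivalent cell radius for the baseline (um, default 120).
#' @return list with `breaks`, `mid`, `density` (sums to 1 when multiplied
#'   by `binWidth`), `counts`, `baseline` (analytic density at `mid`),
#'   `modalDistance` (centre of the modal bin, um).
#' @export
distanceToBorderDistribution <- function(positions = NULL, vertices = NULL,
                                         cells = NULL, R = NULL,
                                         distances = NULL, binWidth = 5,
                                         Rc = 120) {
  if (is.null(distances))
    distances <- dclBorderDistances(positions, vertices, cells, R)
  distances <- distances[is.finite(distances)]
  if (!length(distances)) stop("no finite distances")
  breaks <- seq(0, max(distances) + binWidth, by = binWidth)
  h <- hist(distances, breaks = breaks, plot = FALSE)
  dens <- h$counts / sum(h$counts) / binWidth
  list(breaks = breaks, mid = h$mids, density = dens, counts = h$counts,
       baseline = borderBaselineDensity(h$mids, Rc),
       modalDistance = h$mids[which.max(h$counts)])
}

#' Spherical area covered by the DCL
#'
#' Convex hull of the DCL centres in the 2D projection (ignoring z); the
#' hull cells' own positions, radially projected onto the sphere, bound
#' the covered region and its spherical polygon area is returned. Using
#' the cells' true heights (rather than reconstructing z from x, y) keeps
#' the measure valid once spreading crosses the equator.
#'
#' @param positions matrix (n x 3) of DCL positions (n >= 3, not collinear).
#' @param sphere a [SphereFit-class] or a single radius (centre at origin).
#' @return area (um^2).
#' @export
coveredArea <- function(positions, sphere) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 3L) stop("need at least 3 points")
  hull <- chull(positions[, 1], positions[, 2])
  if (length(hull) < 3L) stop("points are collinear")
  R <- if (is(sphere, "SphereFit")) sphereRadius(sphere) else sphere
  ctr <- if (is(sphere, "SphereFit")) sphereCenter(sphere) else c(0, 0, 0)
  onSphere <- sweep(positions[hull, , drop = FALSE], 2, ctr)
  onSphere <- onSphere * R / .rowNorms(onSphere)
  sphericalPolygonArea(onSphere, R)
}

#' Epiboly index of a margin configuration
#'
#' Percent progression of the blastoderm margin along the animal-vegetal
#' axis: `100 * (R - mean(z)) / (2 R)` with z the margin height above the
#' egg centre. 0% at the animal pole, 50% at the equator, 100% at the
#' vegetal pole.
#'
#' @param margin matrix (n x 3) of margin vertex positions.
#' @param sphere a [SphereFit-class] or a single radius.
#' @return percent (0-100).
#' @export
epibolyIndex <- function(margin, sphere) {
  margin <- as.matrix(margin)
  if (!nrow(margin)) stop("empty margin")
  R <- if (is(sphere, "SphereFit")) sphereRadius(sphere) else sphere
  ctr <- if (is(sphere, "SphereFit")) sphereCenter(sphere) else c(0, 0, 0)
  100 * (R - mean(margin[, 3] - ctr[3])) / (2 * R)
}

#' Linear relation between EVL total area and DCL covered area
#'
#' OLS regression of the DCL covered area on the total EVL surface area
#' across frames, reporting the slope, intercept and r-squared (the
#' coupled-spreading linearity statistic; 0.9916 in the killifish data).
#'
#' @param evlAreas,dclAreas numeric series of equal length (>= 3 frames).
#' @return list with `slope`, `intercept`, `rSquared`, `flagged`.
#' @export
areaRelation <- function(evlAreas, dclAreas) {
  if (length(evlAreas) != length(dclAreas)) stop("series lengths differ")
  if (length(evlAreas) < 3L) stop("need at least 3 frames")
  if (sd(evlAreas) == 0 || sd(dclAreas) == 0) {
    warning("constant series; r-squared undefined")
    return(list(slope = NA_real_, intercept = NA_real_,
                rSquared = NA_real_, flagged = TRUE))
  }
  fit <- lm(dclAreas ~ evlAreas)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       rSquared = suppressWarnings(summary(fit)$r.squared), flagged = FALSE)
}

#' Per-frame summary series of a simulation run
#'
#' Convenience extraction of the series used by the spreading analytics and
#' the model-fitting target functions: total EVL area, DCL covered area,
#' mean k-nearest-neighbour distance and DCL border distances per frame.
#'
#' @param tracks a [TrackTable-class] carrying EVL cells.
#' @param frames frames to evaluate (default all).
#' @param k neighbour count for the dispersion statistic (default 6).
#' @return list of per-frame vectors/lists: `frames`, `evlArea`, `dclArea`,
#'   `nnd` (mean over cells), `borderDistances` (list).
#' @export
spreadingSeries <- function(tracks, frames = NULL, k = 6L) {
  r <- tracks@records
  allFrames <- sort(unique(r$frame))
  if (is.null(frames)) frames <- allFrames
  R <- sphereRadius(tracks@sphere)
  vlist <- evlVertexFrames(tracks, frames)
  evlArea <- numeric(length(frames)); dclArea <- numeric(length(frames))
  nnd <- numeric(length(frames)); bd <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    verts <- vlist[[as.character(f)]]
    evlArea[i] <- sum(evlCellAreas(verts, tracks@cells, R))
    d <- r[r$layer == "DCL" & r$frame == f, ]
    pos <- as.matrix(d[, c("x", "y", "z")])
    dclArea[i] <- coveredArea(pos, tracks@sphere)
    nnd[i] <- mean(nearestNeighbourDistance(pos, min(k, nrow(pos) - 1L), R))
    bd[[i]] <- dclBorderDistances(pos, verts, tracks@cells, R)
  }
  list(frames = frames, evlArea = evlArea, dclArea = dclArea, nnd = nnd,
       borderDistances = bd)
}
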