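#' Sphere fitted to a 3D point cloud
#'
#' Result of [fitSphere()]: the centre, radius and root-mean-square radial
#' residual of the sphere best fitting a point cloud, in egg-centred
#' micrometre coordinates.
#'
#' @slot center numeric(3), sphere centre (um).
#' @slot radius positive numeric(1), sphere radius (um).
#' @slot rmsResidual numeric(1) >= 0, rms of `|p - center| - radius`.
#' @export
setClass("SphereFit",
  representation(center = "numeric", radius = "numeric",
                 rmsResidual = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@center) != 3L || !all(is.finite(object@center)))
      msg <- c(msg, "center must be 3 finite numbers")
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0)
      msg <- c(msg, "radius must be a single positive number")
    if (length(object@rmsResidual) != 1L || object@rmsResidual < 0)
      msg <- c(msg, "rmsResidual must be a single nonnegative number")
    if (is.null(msg)) TRUE else msg
  })

#' Simulation parameters of the three-force model
#'
#' All model constants of the EVL expansion / DCL movement model. Forces act
#' in an overdamped (unit-mobility) regime, so amplitudes carry units of
#' velocity per unit displacement where applicable. Lengths are um, time is
#' minutes.
#'
#' @slot U0 EVL spring elastic constant (1/min); both edge springs and
#'   opposite-vertex springs share it.
#' @slot V0 speed of free-border (margin) vertices toward the vegetal pole
#'   (um/min).
#' @slot U1 DCL-DCL soft-sphere repulsion amplitude (1/min).
#' @slot U2 EVL-cell-border attraction amplitude (um/min at the inflection
#'   scale; the force magnitude is `U2*d/a2^2*exp(-d^2/(2 a2^2))*a2^2`
#'   rescaled, see [dclDisplacement()]).
#' @slot a2 Gaussian length of the border attraction (um).
#' @slot sigma noise amplitude (dimensionless; see [sigmaDiffusionScale]).
#' @slot drag dimensionless EVL-DCL drag coupling in `[0, 1]`.
#' @slot dt integration time step (min).
#' @slot R egg sphere radius (um).
#' @slot nFrames number of recorded frames (excluding frame 0).
#' @slot frameInterval time between recorded frames (min); must be a
#'   multiple of `dt`.
#' @slot seed integer RNG seed making runs reproducible.
#' @export
setClass("SimParams",
  representation(U0 = "numeric", V0 = "numeric", U1 = "numeric",
                 U2 = "numeric", a2 = "numeric", sigma = "numeric",
                 drag = "numeric", dt = "numeric", R = "numeric",
                 nFrames = "integer", frameInterval = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    num1 <- function(x) length(x) == 1L && is.finite(x)
    for (nm in c("U0", "V0", "U1", "U2", "a2", "sigma", "drag", "dt", "R",
                 "frameInterval")) {
      v <- slot(object, nm)
      if (!num1(v) || v < 0) msg <- c(msg, paste(nm, "must be nonnegative"))
    }
    if (num1(object@dt) && object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (num1(object@R) && object@R <= 0) msg <- c(msg, "R must be > 0")
    if (num1(object@drag) && (object@drag < 0 || object@drag > 1))
      msg <- c(msg, "drag must lie in [0, 1]")
    if (length(object@nFrames) != 1L || object@nFrames < 1L)
      msg <- c(msg, "nFrames must be a positive integer")
    if (num1(object@frameInterval) && num1(object@dt)) {
      ratio <- object@frameInterval / object@dt
      if (abs(ratio - round(ratio)) > 1e-8)
        msg <- c(msg, "frameInterval must be a multiple of dt")
    }
    if (is.null(msg)) TRUE else msg
  })

#' EVL vertex-spring mesh on the egg sphere
#'
#' The substrate tissue: polygonal EVL cells whose vertices are point
#' particles connected by harmonic springs (cell-edge springs between
#' consecutive cycle vertices, and opposite-vertex springs across each cell
#' to prevent over-expansion). Margin (free border) vertices carry the
#' epibolic boundary condition.
#'
#' @slot vertices numeric matrix (nVertices x 3), positions on the sphere (um).
#' @slot isBorder logical, TRUE for vertices on the free (vegetal) margin.
#' @slot cells list of integer vectors; each is the ordered vertex cycle of
#'   one EVL cell (1-based indices into `vertices`, not closed).
#' @slot springs integer matrix (nSprings x 2) of vertex index pairs.
#' @slot springType character, `"edge"` or `"opposite"` per spring.
#' @slot restLength numeric, spring rest length (um).
#' @slot springStiff numeric, per-spring stiffness multiplier on `U0` (1 for
#'   edge springs; 1/2 for the doubled near-opposite pairs of odd cycles).
#' @slot R sphere radius (um).
#' @export
setClass("EVLMesh",
  representation(vertices = "matrix", isBorder = "logical", cells = "list",
                 springs = "matrix", springType = "character",
                 restLength = "numeric", springStiff = "numeric",
                 R = "numeric"),
  validity = function(object) {
    msg <- NULL
    nv <- nrow(object@vertices)
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (length(object@isBorder) != nv)
      msg <- c(msg, "isBorder length must match vertex count")
    if (nrow(object@springs) != length(object@restLength) ||
        nrow(object@springs) != length(object@springType) ||
        nrow(object@springs) != length(object@springStiff))
      msg <- c(msg, "springs, springType, restLength, springStiff lengths differ")
    if (nrow(object@springs) && (min(object@springs) < 1L ||
        max(object@springs) > nv))
      msg <- c(msg, "spring indices out of range")
    if (any(object@restLength < 0)) msg <- c(msg, "negative rest length")
    for (cyc in object@cells) {
      if (length(cyc) < 3L) { msg <- c(msg, "cell cycle shorter than 3"); break }
      if (anyDuplicated(cyc)) { msg <- c(msg, "cell cycle revisits a vertex"); break }
      if (min(cyc) < 1L || max(cyc) > nv) { msg <- c(msg, "cell index out of range"); break }
    }
    r <- sqrt(rowSums(object@vertices^2))
    if (nv && any(abs(r - object@R) > 1e-6 * object@R * 10))
      msg <- c(msg, "vertices not on the sphere")
    if (is.null(msg)) TRUE else msg
  })

#' DCL particle population
#'
#' Embryonic deep-layer cells as soft spheres on the egg surface, with an
#' asynchronous division schedule. Each cell divides at most once; at
#' division the parent is replaced by two daughters of radius
#' `(1/2)^(1/3)` times the parent radius (volume halving).
#'
#' @slot positions numeric matrix (n x 3), particle centres on the sphere (um).
#' @slot radius numeric, particle radii (um), all > 0.
#' @slot hasDivided logical, per particle.
#' @slot divisionTime numeric, per particle scheduled division time (min);
#'   `NA` for cells that never divide (including daughters).
#' @export
setClass("DCLPopulation",
  representation(positions = "matrix", radius = "numeric",
                 hasDivided = "logical", divisionTime = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@positions)
    if (ncol(object@positions) != 3L) msg <- c(msg, "positions must be n x 3")
    if (length(object@radius) != n || any(object@radius <= 0))
      msg <- c(msg, "radius must be positive, one per particle")
    if (length(object@hasDivided) != n)
      msg <- c(msg, "hasDivided length must match particle count")
    if (length(object@divisionTime) != n)
      msg <- c(msg, "divisionTime length must match particle count")
    if (any(object@hasDivided & !is.na(object@divisionTime)))
      msg <- c(msg, "a divided cell cannot be scheduled to divide again")
    if (is.null(msg)) TRUE else msg
  })

#' Tidy per-frame track table
#'
#' The shared container for simulator output, synthetic data and analytics
#' input: one row per entity per frame, with the entity layer
#' (`"EVL_vertex"` or `"DCL"`), 3D position, and optional radius and EVL-cell
#' membership. EVL cell polygons (constant topology) are carried alongside.
#'
#' @slot records data.frame with columns `frame` (integer, starting at 0),
#'   `id` (entity id, unique within layer), `layer`, `x`, `y`, `z` (um), and
#'   optionally `radius` and `cell`.
#' @slot cells list of integer vertex cycles of the EVL cells (ids into the
#'   `EVL_vertex` layer), possibly empty.
#' @slot sphere a [SphereFit-class] (egg sphere) or NULL-like empty list.
#' @slot frameInterval numeric(1), time between frames (min).
#' @export
setClass("TrackTable",
  representation(records = "data.frame", cells = "list", sphere = "ANY",
                 frameInterval = "numeric"),
  validity = function(object) {
    msg <- NULL
    need <- c("frame", "id", "layer", "x", "y", "z")
    if (!all(need %in% names(object@records)))
      msg <- c(msg, paste("records must have columns:",
                          paste(need, collapse = ", ")))
    else if (anyDuplicated(object@records[c("frame", "id", "layer")]))
      msg <- c(msg, "(frame, id, layer) must be unique")
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
      msg <- c(msg, "frameInterval must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SphereFit", function(object) {
  cat(sprintf("SphereFit: centre (%.2f, %.2f, %.2f) um, radius %.2f um, rms residual %.3f um\n",
              object@center[1], object@center[2], object@center[3],
              object@radius, object@rmsResidual))
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams (three-force model)\n")
  cat(sprintf("  EVL: U0 = %g /min, V0 = %g um/min\n", object@U0, object@V0))
  cat(sprintf("  DCL: U1 = %g, U2 = %g, a2 = %g um, sigma = %g, drag = %g\n",
              object@U1, object@U2, object@a2, object@sigma, object@drag))
  cat(sprintf("  integration: dt = %g min, R = %g um, %d frames every %g min, seed %d\n",
              object@dt, object@R, object@nFrames, object@frameInterval,
              object@seed))
})

setMethod("show", "EVLMesh", function(object) {
  cat(sprintf("EVLMesh: %d vertices (%d on the margin), %d cells, %d springs on a sphere of radius %.1f um\n",
              nrow(object@vertices), sum(object@isBorder),
              length(object@cells), nrow(object@springs), object@R))
})

setMethod("show", "DCLPopulation", function(object) {
  cat(sprintf("DCLPopulation: %d particles (mean radius %.2f um), %d divided, %d divisions pending\n",
              nrow(object@positions), mean(object@radius),
              sum(object@hasDivided), sum(!is.na(object@divisionTime))))
})

setMethod("show", "TrackTable", function(object) {
  r <- object@records
  cat(sprintf("TrackTable: %d records, frames %d..%d (every %g min), %d EVL vertices, %d DCL tracks, %d EVL cells\n",
              nrow(r), min(r$frame), max(r$frame), object@frameInterval,
              length(unique(r$id[r$layer == "EVL_vertex"])),
              length(unique(r$id[r$layer == "DCL"])), length(object@cells)))
})
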