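#' @name accessors
#' @title Accessors for epiboly S4 containers
#' @description Slot accessors for [SphereFit-class], [SimParams-class],
#'   [EVLMesh-class], [DCLPopulation-class] and [TrackTable-class]. Use these
#'   instead of `@`.
#' @param object an epiboly S4 object.
#' @param x a `TrackTable` (for `as.data.frame`).
#' @param ... unused.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("sphereCenter", function(object) standardGeneric("sphereCenter"))
#' @rdname accessors
#' @export
setGeneric("sphereRadius", function(object) standardGeneric("sphereRadius"))
#' @rdname accessors
#' @export
setGeneric("rmsResidual", function(object) standardGeneric("rmsResidual"))
#' @rdname accessors
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("isBorder", function(object) standardGeneric("isBorder"))
#' @rdname accessors
#' @export
setGeneric("meshCells", function(object) standardGeneric("meshCells"))
#' @rdname accessors
#' @export
setGeneric("meshSprings", function(object) standardGeneric("meshSprings"))
#' @rdname accessors
#' @export
setGeneric("particlePositions",
           function(object) standardGeneric("particlePositions"))
#' @rdname accessors
#' @export
setGeneric("particleRadii", function(object) standardGeneric("particleRadii"))
#' @rdname accessors
#' @export
setGeneric("trackRecords", function(object) standardGeneric("trackRecords"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setMethod("sphereCenter", "SphereFit", function(object) object@center)
#' @rdname accessors
#' @export
setMethod("sphereRadius", "SphereFit", function(object) object@radius)
#' @rdname accessors
#' @export
setMethod("rmsResidual", "SphereFit", function(object) object@rmsResidual)
#' @rdname accessors
#' @export
setMethod("meshVertices", "EVLMesh", function(object) object@vertices)
#' @rdname accessors
#' @export
setMethod("isBorder", "EVLMesh", function(object) object@isBorder)
#' @rdname accessors
#' @export
setMethod("meshCells", "EVLMesh", function(object) object@cells)
#' @rdname accessors
#' @export
setMethod("meshSprings", "EVLMesh", function(object)
  data.frame(from = object@springs[, 1], to = object@springs[, 2],
             type = object@springType, restLength = object@restLength,
             stiffness = object@springStiff))
#' @rdname accessors
#' @export
setMethod("sphereRadius", "EVLMesh", function(object) object@R)
#' @rdname accessors
#' @export
setMethod("particlePositions", "DCLPopulation",
          function(object) object@positions)
#' @rdname accessors
#' @export
setMethod("particleRadii", "DCLPopulation", function(object) object@radius)
#' @rdname accessors
#' @export
setMethod("trackRecords", "TrackTable", function(object) object@records)
#' @rdname accessors
#' @export
setMethod("frameInterval", "TrackTable", function(object)
  object@frameInterval)
#' @rdname accessors
#' @export
setMethod("meshCells", "TrackTable", function(object) object@cells)

#' @rdname accessors
#' @export
as.data.frame.TrackTable <- function(x, ...) x@records

#' Construct simulation parameters
#'
#' Defaults are the study conditions: egg radius 592 um, 10-min imaging
#' cadence, 0.5-min integration step, and the fitted optimum of the free
#' parameters (`drag = 1`, `sigma = 2e4`, `U2 = 0.3`).
#'
#' @param U0 EVL spring constant (1/min).
#' @param V0 margin speed (um/min).
#' @param U1 DCL-DCL repulsion amplitude (1/min).
#' @param U2 border-attraction amplitude.
#' @param a2 border-attraction Gaussian length (um).
#' @param sigma noise amplitude (see [sigmaDiffusionScale]).
#' @param drag EVL-DCL drag coupling in `[0, 1]`.
#' @param dt time step (min).
#' @param R sphere radius (um).
#' @param nFrames recorded frames after frame 0.
#' @param frameInterval minutes between frames; multiple of `dt`.
#' @param seed integer RNG seed.
#' @return A [SimParams-class] object.
#' @examples
#' SimParams(nFrames = 10L)
#' @export
SimParams <- function(U0 = 0.05, V0 = 0.3, U1 = 0.2, U2 = 0.3, a2 = 15,
                      sigma = 2e4, drag = 1, dt = 0.5, R = 592,
                      nFrames = 60L, frameInterval = 10, seed = 1L) {
  new("SimParams", U0 = U0, V0 = V0, U1 = U1, U2 = U2, a2 = a2,
      sigma = sigma, drag = drag, dt = dt, R = R,
      nFrames = as.integer(nFrames), frameInterval = frameInterval,
      seed = as.integer(seed))
}

#' Construct a track table
#'
#' @param records data.frame with columns frame, id, layer, x, y, z (and
#'   optionally radius, cell).
#' @param cells list of EVL cell vertex cycles (ids), or empty.
#' @param sphere [SphereFit-class] or NULL.
#' @param frameInterval minutes between frames.
#' @return A [TrackTable-class].
#' @export
TrackTable <- function(records, cells = list(), sphere = NULL,
                       frameInterval = 10) {
  records$frame <- as.integer(records$frame)
  new("TrackTable", records = records, cells = cells,
      sphere = if (is.null(sphere)) list() else sphere,
      frameInterval = frameInterval)
}
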