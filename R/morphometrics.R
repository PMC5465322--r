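# Second-moment cell-shape indices and the protrusion detector/classifier,
# operating on 2D/3D label masks with physical voxel spacing.

.shoelace <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

.convexHullArea <- function(px, py, spacing) {
  # hull of the pixel squares (corners at +/- half a pixel)
  cx <- c(px - 0.5, px + 0.5, px - 0.5, px + 0.5) * spacing[1]
  cy <- c(py - 0.5, py - 0.5, py + 0.5, py + 0.5) * spacing[2]
  h <- chull(cx, cy)
  .shoelace(cx[h], cy[h])
}

.momentAxes <- function(coords) {
  # population covariance of voxel centres; axis magnitudes are the square
  # roots of the eigenvalues (lengths, not variances)
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  covm <- crossprod(cc) / nrow(cc)
  ev <- eigen(covm, symmetric = TRUE)
  list(lambda = sqrt(pmax(0, ev$values)), axes = ev$vectors, center = ctr)
}

#' Second-moment shape indices of a labelled object
#'
#' Principal axis magnitudes from the spacing-aware second-order moment
#' tensor of the object's voxels (lambda1 >= lambda2 >= lambda3, square
#' roots of the covariance eigenvalues, so they scale with object extent),
#' and the derived indices: elongation `1 - lambda2/lambda1`, flatness
#' `1 - lambda3/lambda2` (3D only), entropy `-sum(l' log l')` with
#' `l' = lambda / sum(lambda)` (maximal when all axes are equal), and the
#' eccentricity of the ellipse with the same second moments
#' (focal distance over major axis, `sqrt(1 - (lambda2/lambda1)^2)`).
#'
#' @param mask integer matrix (2D) or array (3D) of labels.
#' @param label the label to measure (default 1).
#' @param spacing voxel spacing per axis (um), recycled to the mask
#'   dimensionality.
#' @param minVoxels minimum voxel count (default 10).
#' @return list with `lambda`, `elongation`, `flatness`, `entropy`,
#'   `eccentricity`, `center` (um), `nVoxels`.
#' @export
shapeIndices <- function(mask, label = 1L, spacing = 1, minVoxels = 10L) {
  nd <- length(dim(mask))
  if (!nd %in% c(2L, 3L)) stop("mask must be 2D or 3D")
  spacing <- rep(spacing, length.out = nd)
  idx <- which(mask == label, arr.ind = TRUE)
  if (nrow(idx) < minVoxels)
    stop("label ", label, " absent or smaller than ", minVoxels, " voxels")
  coords <- sweep(idx, 2, spacing, `*`)
  ma <- .momentAxes(coords)
  lam <- ma$lambda
  lp <- lam / sum(lam)
  lp <- lp[lp > 0]
  list(lambda = lam,
       elongation = 1 - lam[2] / lam[1],
       flatness = if (nd == 3L) 1 - lam[3] / lam[2] else NA_real_,
       entropy = -sum(lp * log(lp)),
       eccentricity = sqrt(max(0, 1 - (lam[2] / lam[1])^2)),
       center = ma$center, nVoxels = nrow(idx))
}

#' Detect and classify DCL membrane protrusions
#'
#' Connected components of the membrane mask outside the cell body that are
#' in contact with the body and larger than `minArea` (1.1 um^2) are
#' protrusions. The decision cascade classifies each one: second-moment
#' ellipse eccentricity > 0.97 gives an elongated protrusion; otherwise
#' solidity (area over convex-hull area) > 0.65 gives a round protrusion;
#' anything else is an object with multiple elongated protrusions. The base
#' position (centroid of the pixels touching the body) defines the
#' orientation angle with respect to the cell centre of mass.
#'
#' @param body binary/integer matrix: the segmented cell body.
#' @param membrane binary/integer matrix, same size: the membrane
#'   segmentation (protrusions plus body).
#' @param spacing pixel size per axis (um), length 1 or 2.
#' @param minArea detection threshold (um^2, default 1.1).
#' @param eccThreshold elongated-class threshold (default 0.97).
#' @param solidityThreshold round-class threshold (default 0.65).
#' @return data.frame with one row per protrusion: `area` (um^2), `class`,
#'   `eccentricity`, `solidity`, `baseX`, `baseY` (um), `orientation`
#'   (radians in `[-pi, pi]` relative to the cell centre of mass).
#' @export
detectProtrusions <- function(body, membrane, spacing = c(0.22, 0.22),
                              minArea = 1.1, eccThreshold = 0.97,
                              solidityThreshold = 0.65) {
  if (!all(dim(body) == dim(membrane)))
    stop("body and membrane masks must be aligned")
  spacing <- rep(spacing, length.out = 2L)
  pxArea <- prod(spacing)
  outside <- (membrane > 0) & !(body > 0)
  labels <- EBImage::bwlabel(outside)  # 8-connectivity
  bodyHalo <- EBImage::dilate(body > 0, EBImage::makeBrush(3, "box"))
  comps <- setdiff(unique(as.vector(labels)), 0)
  bodyIdx <- which(body > 0, arr.ind = TRUE)
  com <- colMeans(bodyIdx) * spacing
  rows <- list()
  for (lb in comps) {
    pix <- which(labels == lb, arr.ind = TRUE)
    area <- nrow(pix) * pxArea
    if (area <= minArea) next
    touching <- labels == lb & bodyHalo
    if (!any(touching)) next  # floating object, not a protrusion
    ma <- .momentAxes(sweep(pix, 2, spacing, `*`))
    lam <- ma$lambda
    ecc <- sqrt(max(0, 1 - (lam[2] / max(lam[1], 1e-12))^2))
    solidity <- area / .convexHullArea(pix[, 1], pix[, 2], spacing)
    cls <- if (ecc > eccThreshold) "elongated"
           else if (solidity > solidityThreshold) "round"
           else "multiple_elongated"
    basePix <- which(touching, arr.ind = TRUE)
    base <- colMeans(basePix) * spacing
    rows[[length(rows) + 1L]] <- data.frame(
      area = area, class = cls, eccentricity = ecc, solidity = solidity,
      baseX = base[1], baseY = base[2],
      orientation = atan2(base[2] - com[2], base[1] - com[1]))
  }
  if (!length(rows))
    return(data.frame(area = numeric(0), class = character(0),
                      eccentricity = numeric(0), solidity = numeric(0),
                      baseX = numeric(0), baseY = numeric(0),
                      orientation = numeric(0)))
  do.call(rbind, rows)
}

#' Eccentricity time course of a tracked cell
#'
#' Per-frame second-moment eccentricity of one label across a mask series
#' (cell elongation readout, e.g. during EVL cell extrusion). Missing
#' frames are reported as NA.
#'
#' @param masks list of label masks (one per frame).
#' @param label tracked label.
#' @param spacing voxel spacing (um).
#' @return data.frame with `frame`, `eccentricity`, and attribute `gaps`
#'   (frames where the label was absent).
#' @export
eccentricityTimecourse <- function(masks, label = 1L, spacing = 1) {
  ecc <- vapply(masks, function(m) {
    tryCatch(shapeIndices(m, label, spacing)$eccentricity,
             error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(frame = seq_along(masks), eccentricity = ecc)
  attr(out, "gaps") <- which(is.na(ecc))
  if (length(attr(out, "gaps")))
    warning("label missing in ", length(attr(out, "gaps")), " frame(s)")
  out
}
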