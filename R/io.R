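# Plain-text interchange: track tables as tidy CSV, EVL polygons and
# per-frame rotations as JSON, simulation configuration as YAML/JSON.

#' Read and write track tables as tidy CSV
#'
#' Columns: frame, id, layer, x, y, z, and optionally radius and cell. The
#' sphere and cell polygons travel in sidecar JSON via [writeCellsJSON()].
#'
#' @param tracks a [TrackTable-class].
#' @param path CSV file path.
#' @param frameInterval minutes between frames (for reading).
#' @param sphere optional [SphereFit-class] attached on reading.
#' @param cells optional cell cycle list attached on reading.
#' @return `readTrackTable` returns a [TrackTable-class];
#'   `writeTrackTable` returns `path` invisibly.
#' @export
writeTrackTable <- function(tracks, path) {
  write.csv(tracks@records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrackTable
#' @export
readTrackTable <- function(path, frameInterval = 10, sphere = NULL,
                           cells = list()) {
  TrackTable(read.csv(path), cells = cells, sphere = sphere,
             frameInterval = frameInterval)
}

#' Write/read EVL cell polygons as JSON
#'
#' One entry per cell: the ordered vertex ids of its cycle.
#'
#' @param cells list of integer vertex cycles.
#' @param path JSON file path.
#' @return reading returns the cycle list; writing returns `path` invisibly.
#' @export
writeCellsJSON <- function(cells, path) {
  jsonlite::write_json(setNames(cells, paste0("cell", seq_along(cells))),
                       path)
  invisible(path)
}

#' @rdname writeCellsJSON
#' @export
readCellsJSON <- function(path) {
  unname(lapply(jsonlite::read_json(path, simplifyVector = TRUE),
                as.integer))
}

#' Write per-frame drift rotations as JSON quaternions
#'
#' @param rotations list of 3x3 rotation matrices (from
#'   [removeRotationalDrift()]).
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
writeRotationsJSON <- function(rotations, path) {
  toQuat <- function(Rm) {
    tr <- sum(diag(Rm))
    if (tr > 0) {
      s <- sqrt(tr + 1) * 2
      q <- c(s / 4, (Rm[3, 2] - Rm[2, 3]) / s, (Rm[1, 3] - Rm[3, 1]) / s,
             (Rm[2, 1] - Rm[1, 2]) / s)
    } else {
      i <- which.max(diag(Rm))
      j <- i %% 3 + 1; k <- j %% 3 + 1
      s <- sqrt(1 + Rm[i, i] - Rm[j, j] - Rm[k, k]) * 2
      q <- numeric(4)
      q[1] <- (Rm[k, j] - Rm[j, k]) / s
      q[i + 1] <- s / 4
      q[j + 1] <- (Rm[j, i] + Rm[i, j]) / s
      q[k + 1] <- (Rm[k, i] + Rm[i, k]) / s
    }
    setNames(as.list(q), c("w", "x", "y", "z"))
  }
  jsonlite::write_json(lapply(rotations, toQuat), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read simulation parameters from a YAML or JSON config file
#'
#' Recognised fields are the [SimParams()] arguments; missing fields take
#' the defaults.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a [SimParams-class].
#' @export
readSimConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(SimParams))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) warning("ignoring unknown fields: ",
                           paste(bad, collapse = ", "))
  do.call(SimParams, cfg[intersect(names(cfg), known)])
}
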