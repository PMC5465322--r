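# Target functions comparing simulation to reference track statistics,
# simplex optimization of the free parameters, and parameter-landscape
# sampling.

#' EVL target function: squared area discrepancy
#'
#' Sum over corresponding EVL cells and frames of squared area differences,
#' normalized by the squared mean reference area. Used to calibrate the
#' spring constant U0.
#'
#' @param simAreas,refAreas numeric matrices (cells x frames) with matching
#'   dimnames on rows (cell ids).
#' @return scalar >= 0, zero iff the areas coincide.
#' @export
targetEvl <- function(simAreas, refAreas) {
  simAreas <- as.matrix(simAreas); refAreas <- as.matrix(refAreas)
  if (!is.null(rownames(refAreas))) {
    missing <- setdiff(rownames(refAreas), rownames(simAreas))
    if (length(missing))
      stop("unmatched EVL cells: ", paste(missing, collapse = ", "))
    simAreas <- simAreas[rownames(refAreas), , drop = FALSE]
  }
  if (!all(dim(simAreas) == dim(refAreas)))
    stop("area matrices must have matching dimensions")
  scale <- mean(refAreas)
  sum((simAreas - refAreas)^2) / scale^2
}

.histDensity <- function(x, breaks) {
  x <- x[is.finite(x)]
  x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
  h <- hist(x, breaks = breaks, plot = FALSE)
  h$counts / sum(h$counts) / diff(breaks)
}

#' Summary statistics of DCL behaviour for model fitting
#'
#' The four statistical quantities entering the DCL target function: the
#' per-frame mean distance to the six nearest neighbouring DCL cells, the
#' probability density of the distance to the nearest EVL cell border, the
#' mean square displacement of DCL cells, and the probability density of
#' the per-frame displacement.
#'
#' @param tracks a [TrackTable-class] with EVL cells.
#' @param frames frames at which to evaluate per-frame statistics
#'   (default every 5th).
#' @param maxLag MSD window cap (frames).
#' @param borderBreaks,stepBreaks fixed histogram breaks (um).
#' @return list of statistic vectors (`nnd`, `borderPdf`, `msd`, `stepPdf`).
#' @export
dclStatistics <- function(tracks, frames = NULL, maxLag = 15L,
                          borderBreaks = seq(0, 120, by = 5),
                          stepBreaks = seq(0, 40, by = 2)) {
  r <- tracks@records
  allFrames <- sort(unique(r$frame))
  if (is.null(frames))
    frames <- allFrames[seq(1, length(allFrames), by = 5)]
  ss <- spreadingSeries(tracks, frames)
  msd <- msdCurve(tracks, maxLag = maxLag)
  dcl <- r[r$layer == "DCL", ]
  dcl <- dcl[order(dcl$id, dcl$frame), ]
  steps <- unlist(lapply(split(dcl, dcl$id), function(tr) {
    if (nrow(tr) < 2) return(NULL)
    p <- as.matrix(tr[, c("x", "y", "z")])
    .rowNorms(p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])
  }))
  list(nnd = ss$nnd,
       borderPdf = .histDensity(unlist(ss$borderDistances), borderBreaks),
       msd = msd$msd,
       stepPdf = .histDensity(steps, stepBreaks))
}

#' DCL target function: weighted L2 discrepancy of four statistics
#'
#' Weighted sum of L2 distances between the simulation's and the
#' reference's statistic curves/histograms, each normalized by the L2 norm
#' of the reference statistic so the components are comparable. Symmetric
#' in its arguments; zero iff all compared statistics coincide.
#'
#' @param simStats,refStats statistic lists from [dclStatistics()] (or a
#'   [TrackTable-class], which is summarised first).
#' @param include statistics to include.
#' @param weights named weights (default equal).
#' @return scalar target value with attribute `components`.
#' @export
targetDcl <- function(simStats, refStats,
                      include = c("nnd", "borderPdf", "msd", "stepPdf"),
                      weights = NULL) {
  if (is(simStats, "TrackTable")) simStats <- dclStatistics(simStats)
  if (is(refStats, "TrackTable")) refStats <- dclStatistics(refStats)
  if (is.null(weights)) weights <- setNames(rep(1, length(include)), include)
  comp <- setNames(numeric(length(include)), include)
  for (s in include) {
    a <- simStats[[s]]; b <- refStats[[s]]
    if (!length(a) || !length(b) || length(a) != length(b)) {
      warning("statistic '", s, "' empty or mismatched; excluded")
      comp[s] <- NA_real_
      next
    }
    ref2 <- sqrt(sum(b^2)) + sqrt(sum(a^2))
    comp[s] <- if (ref2 == 0) 0 else sqrt(sum((a - b)^2)) / (ref2 / 2)
  }
  total <- sum(weights[include] * comp, na.rm = TRUE)
  attr(total, "components") <- comp
  total
}

#' Build a deterministic simulation objective for parameter fitting
#'
#' Returns a function of a named parameter vector that reruns the
#' three-force simulation from fixed initial conditions with those values
#' substituted, summarises it with [dclStatistics()], and scores it against
#' the reference statistics with [targetDcl()]. The simulation seed is held
#' fixed across evaluations (common random numbers), making the objective a
#' deterministic function of the parameters.
#'
#' @param refStats reference statistics (list from [dclStatistics()]).
#' @param baseParams a [SimParams-class] providing all non-free values.
#' @param mesh,pop initial conditions shared by all evaluations.
#' @param frames,maxLag passed to [dclStatistics()].
#' @return function(par) -> scalar target.
#' @export
makeSimObjective <- function(refStats, baseParams, mesh, pop,
                             frames = NULL, maxLag = 15L) {
  force(refStats); force(baseParams); force(mesh); force(pop)
  function(par) {
    p <- baseParams
    for (nm in names(par)) slot(p, nm) <- unname(par[nm])
    sim <- runSimulation(p, mesh, pop)
    as.numeric(targetDcl(dclStatistics(sim, frames, maxLag), refStats))
  }
}

#' Nelder-Mead (simplex) minimization with box clamping and restarts
#'
#' Simplex descent on a box-constrained objective: proposals outside the
#' bounds are clamped to the box and charged a quadratic penalty for the
#' excess, which steers the simplex back inside while leaving on-boundary
#' optima reachable. Optionally restarts from the incumbent to escape
#' degenerate simplices. The evaluation trace is recorded.
#'
#' @param objective function of a named parameter vector.
#' @param init named numeric vector of starting values.
#' @param lower,upper named bounds (same names as `init`).
#' @param maxit maximum simplex iterations per start.
#' @param restarts additional restarts from the incumbent (default 1).
#' @return list with `par`, `value`, `initialValue`, `trace` (data.frame of
#'   evaluations), `convergence`.
#' @export
optimizeParams <- function(objective, init, lower, upper, maxit = 60L,
                           restarts = 1L) {
  nms <- names(init)
  traceEnv <- new.env()
  traceEnv$rows <- list()
  wrapped <- function(x) {
    names(x) <- nms
    cl <- pmin(pmax(x, lower[nms]), upper[nms])
    pen <- sum(((x - cl) / pmax(upper[nms] - lower[nms], 1e-12))^2)
    val <- objective(cl)
    if (!is.finite(val))
      stop("non-finite objective at ", paste(signif(cl, 4), collapse = ", "))
    traceEnv$rows[[length(traceEnv$rows) + 1L]] <-
      c(cl, value = val + 100 * pen)
    val + 100 * pen
  }
  initialValue <- wrapped(init)
  best <- list(par = init, value = initialValue)
  cur <- init
  for (s in seq_len(restarts + 1L)) {
    # optim warns that 1-D Nelder-Mead is unreliable; restarts cover that
    opt <- if (length(init) == 1L)
      suppressWarnings(optim(cur, wrapped, method = "Nelder-Mead",
                             control = list(maxit = maxit)))
    else optim(cur, wrapped, method = "Nelder-Mead",
               control = list(maxit = maxit))
    if (opt$value <= best$value) {
      best <- list(par = pmin(pmax(opt$par, lower[nms]), upper[nms]),
                   value = opt$value)
    }
    cur <- best$par
  }
  tr <- as.data.frame(do.call(rbind, traceEnv$rows))
  list(par = setNames(as.numeric(best$par), nms), value = best$value,
       initialValue = initialValue, trace = tr,
       convergence = best$value <= initialValue)
}

#' Sample the objective on a parameter grid
#'
#' Evaluates the objective at every grid point and min-max normalizes the
#' values to `[0, 1]` (the parameter-landscape map over drag, sigma and
#' U2), reporting the location of the minimum.
#'
#' @param grid data.frame, one column per free parameter, one row per grid
#'   point.
#' @param objective function of a named parameter vector.
#' @return the grid with columns `value` (raw) and `normalized`; attribute
#'   `minimum` holds the argmin row.
#' @export
sampleLandscape <- function(grid, objective) {
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    par <- as.numeric(grid[i, , drop = TRUE])
    names(par) <- names(grid)
    objective(par)
  }, numeric(1))
  rng <- range(vals)
  norm <- if (diff(rng) == 0) rep(0, length(vals))
          else (vals - rng[1]) / diff(rng)
  out <- cbind(grid, value = vals, normalized = norm)
  attr(out, "minimum") <- out[which.min(vals), , drop = FALSE]
  out
}
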