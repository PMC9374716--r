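#' Construct a central-axis depth curve
#'
#' @param depths strictly increasing depths (cm).
#' @param values non-negative flux or weighted dose values.
#' @param relErr optional fractional errors.
#' @param tissue optional tissue context for weighted curves.
#' @return data.frame of class `depthCurve`.
#' @export
depthCurve <- function(depths, values, relErr = NA_real_, tissue = NA) {
  if (length(depths) < 1 || any(diff(depths) <= 0))
    stop("depths must be strictly increasing")
  if (any(values < 0)) stop("values must be >= 0")
  structure(data.frame(depth = depths, value = values, relErr = relErr),
            class = c("depthCurve", "data.frame"), tissue = tissue)
}

#' Central-axis curve from a cylindrical tally
#'
#' Volume-weighted mean over the radial rings whose centers lie within the
#' averaging radius, per depth bin, with propagated relative error.
#'
#' @param tally a cylindrical [TallyGrid-class].
#' @param averagingRadius cm (> 0).
#' @param quantity group label ("thermal", "epithermal", "fast"), "photon"
#'   (energy fluence), or a numeric (nr x nz) matrix to average (e.g. a
#'   weighted-dose grid).
#' @param zOffset subtracted from the tally z centers, so depths are
#'   measured from e.g. the phantom front face.
#' @return a `depthCurve` data.frame (depth, value, relErr).
#' @export
centralAxisCurve <- function(tally, averagingRadius = 1, quantity = "thermal",
                             zOffset = 0) {
  stopifnot(is(tally, "TallyGrid"), tally@type == "cylindrical")
  if (averagingRadius <= 0) stop("averagingRadius must be > 0")
  rc <- tally@mesh$rCenters
  sel <- which(rc < averagingRadius)
  if (!length(sel)) stop("no radial bins within the averaging radius")
  if (is.character(quantity)) {
    if (quantity == "photon") {
      vals <- tally@photonFluence; rel <- tally@relErrPhoton
    } else {
      vals <- groupFlux(tally, quantity)
      rel <- as.array(.takeLast(tally@relErr,
                                match(quantity, tally@groupLabels),
                                drop = TRUE))
    }
  } else {
    vals <- quantity
    rel <- array(NA_real_, dim = dim(vals))
  }
  re <- tally@mesh$rEdges
  w <- (re[sel + 1]^2 - re[sel]^2)  # ring volumes (common dz cancels)
  w <- w / sum(w)
  v <- as.numeric(t(vals[sel, , drop = FALSE]) %*% w)
  relErr <- sqrt(as.numeric(t((vals[sel, , drop = FALSE] *
                               rel[sel, , drop = FALSE])^2) %*% w^2)) /
    ifelse(v > 0, v, NA_real_)
  depthCurve(tally@mesh$zCenters - zOffset, v, relErr)
}

#' Advantage depth
#'
#' The depth at which the tumour's weighted-dose curve first falls to the
#' peak value of the healthy-tissue weighted-dose curve, linearly
#' interpolated between bracketing samples. The search starts at the depth
#' of the healthy peak (first crossing beyond the peak); identical curves
#' therefore return the healthy-peak depth.
#'
#' @param tumourCurve,healthyCurve `depthCurve` data.frames (Gy_w); they
#'   are resampled onto the union depth grid of their overlap.
#' @return list: `depth` (cm, NA when there is no crossing), `crossed`
#'   (logical), `healthyPeak` (Gy_w), `peakDepth` (cm).
#' @export
advantageDepth <- function(tumourCurve, healthyCurve) {
  if (!nrow(tumourCurve) || !nrow(healthyCurve))
    stop("curves must be non-empty")
  lo <- max(min(tumourCurve$depth), min(healthyCurve$depth))
  hi <- min(max(tumourCurve$depth), max(healthyCurve$depth))
  if (hi <= lo) stop("curves do not overlap in depth")
  grid <- sort(unique(c(tumourCurve$depth, healthyCurve$depth)))
  grid <- grid[grid >= lo & grid <= hi]
  tum <- approx(tumourCurve$depth, tumourCurve$value, grid)$y
  hea <- approx(healthyCurve$depth, healthyCurve$value, grid)$y
  peak <- max(hea)
  ipk <- which.max(hea)
  res <- list(depth = NA_real_, crossed = FALSE, healthyPeak = peak,
              peakDepth = grid[ipk])
  if (max(tum) < peak) return(res)  # tumour never reaches the healthy peak
  for (i in seq(ipk, length(grid))) {
    if (tum[i] <= peak) {
      if (i == ipk || tum[i] == peak) {
        res$depth <- grid[i]
      } else {
        f <- (tum[i - 1] - peak) / (tum[i - 1] - tum[i])
        res$depth <- grid[i - 1] + f * (grid[i] - grid[i - 1])
      }
      res$crossed <- TRUE
      return(res)
    }
  }
  res  # stays above the peak through the grid end: no crossing inside grid
}

#' Construct a lateral (off-axis) profile
#'
#' @param offsets strictly increasing offsets from the beam axis (cm).
#' @param values non-negative dose values.
#' @param depth profile depth, cm (default 2).
#' @return data.frame of class `lateralProfile`.
#' @export
lateralProfile <- function(offsets, values, depth = 2) {
  if (any(diff(offsets) <= 0)) stop("offsets must be strictly increasing")
  if (any(values < 0)) stop("values must be >= 0")
  structure(data.frame(offset = offsets, value = values),
            class = c("lateralProfile", "data.frame"), depth = depth)
}

#' Lateral profile at fixed depth from a cylindrical grid
#'
#' Mirrors the radial values across the axis (the scene is axisymmetric) to
#' produce a full off-axis profile at the requested depth.
#'
#' @param tally a cylindrical [TallyGrid-class] (for the mesh).
#' @param values (nr x nz) matrix, e.g. a weighted-dose grid on that mesh.
#' @param depth cm, measured with `zOffset` subtracted from tally z.
#' @param zOffset typically the phantom front z.
#' @return a `lateralProfile` data.frame.
#' @export
profileAtDepth <- function(tally, values, depth = 2, zOffset = 0) {
  zc <- tally@mesh$zCenters - zOffset
  iz <- which.min(abs(zc - depth))
  v <- values[, iz]
  rc <- tally@mesh$rCenters
  lateralProfile(c(-rev(rc), rc), c(rev(v), v), depth = zc[iz])
}

#' Isodose width of a lateral profile
#'
#' Width between the outermost left and right crossings of
#' `level * max(profile)`, linearly interpolated between samples. When the
#' profile does not fall below the level before the grid edge on one side,
#' the width extends to that edge and the result is flagged.
#'
#' @param profile a `lateralProfile` data.frame.
#' @param level fraction of the profile maximum, in (0, 1) (0.5 and 0.8 for
#'   the 50%/80% isodose widths).
#' @return list: `width` (cm), `flagged` (logical, TRUE when clipped by the
#'   grid edge).
#' @export
isodoseWidth <- function(profile, level) {
  if (level <= 0 || level >= 1) stop("level must be inside (0, 1)")
  x <- profile$offset; v <- profile$value
  mx <- max(v)
  if (mx <= 0) stop("profile must have a positive maximum")
  thr <- level * mx
  n <- length(v)
  above <- which(v >= thr)
  i <- above[1]; j <- above[length(above)]
  flagged <- FALSE
  if (i == 1) { xl <- x[1]; flagged <- TRUE } else {
    f <- (thr - v[i - 1]) / (v[i] - v[i - 1])
    xl <- x[i - 1] + f * (x[i] - x[i - 1])
  }
  if (j == n) { xr <- x[n]; flagged <- TRUE } else {
    f <- (v[j] - thr) / (v[j] - v[j + 1])
    xr <- x[j] + f * (x[j + 1] - x[j])
  }
  list(width = xr - xl, flagged = flagged)
}

# weighted-dose (nr x nz) grid for one tissue from a cylindrical tally over
# a homogeneous phantom material
.weightedDoseGrid <- function(tally, material, tissue, params, kerma,
                              bloodBoron = 25) {
  dims <- dim(tally@flux)
  G <- dims[3]
  N <- dims[1] * dims[2]
  flux <- t(matrix(tally@flux, nrow = N, ncol = G))
  boron <- boronConcentration(tissue, bloodBoron, params)
  comp <- physicalDose(flux, material, boron = boron, kerma = kerma,
                       photonEnergyFluence = as.numeric(tally@photonFluence))
  matrix(weightedDose(comp, tissue, params), dims[1], dims[2])
}

#' Air-gap sweep of beam metrics
#'
#' For each (collimator kind, air gap) pair, transports the beam into the
#' 30 cm tissue cube (uniform 25 ug/g 10B) and reports the advantage depth,
#' the irradiation time to deliver the mucosal prescription, the 80%/50%
#' isodose widths at 2 cm depth, and the on-axis surface thermal flux.
#' All runs share the same seed (common random numbers), so differences
#' between rows are not dominated by independent MC noise, and two sweeps
#' with the same seed give identical tables.
#'
#' @param kinds collimator kinds to sweep.
#' @param gaps air gaps (cm).
#' @param source a [SourceModel-class].
#' @param config a [RunConfig-class] reused (same seed) for every run.
#' @param params,kerma weighting parameters and KERMA factors.
#' @param prescription a `prescription` (12 Gy_w to mucosa by default).
#' @param dz,dr tally bin widths (cm).
#' @return data.frame, one row per (kind, gap): advantageDepth, timeMin,
#'   width50, width80, surfaceThermal (+ relErr), ok flag (FALSE rows mark
#'   failed sub-runs, they are never dropped).
#' @export
gapSweep <- function(kinds, gaps, source, config,
                     params = defaultWeightingParams(),
                     kerma = defaultKerma(),
                     prescription = prescriptionSpec(), dz = 0.5, dr = 0.5) {
  rows <- list()
  for (kind in kinds) for (gap in gaps) {
    row <- data.frame(kind = kind, gap = gap, advantageDepth = NA_real_,
                      timeMin = NA_real_, width50 = NA_real_,
                      width80 = NA_real_, surfaceThermal = NA_real_,
                      surfaceThermalRelErr = NA_real_, ok = FALSE)
    res <- tryCatch({
      scene <- makeCubicPhantomScene(kind, gap)
      front <- phantomFront(scene)
      tally <- cylTally(c(front, front + 30), dz, 15, dr)
      run <- runTransport(scene, source, config, tally)
      tg <- run$tallies[[1]]
      tissueMat <- scene@materials$tissue
      mucosa <- .weightedDoseGrid(tg, tissueMat, "mucosa", params, kerma)
      tumour <- .weightedDoseGrid(tg, tissueMat, "tumour", params, kerma)
      mCurve <- centralAxisCurve(tg, 1, mucosa, zOffset = front)
      tCurve <- centralAxisCurve(tg, 1, tumour, zOffset = front)
      ad <- advantageDepth(tCurve, mCurve)
      ratePerMin <- max(mucosa) * source@intensity * 60
      it <- irradiationTime(ratePerMin, prescription = prescription)
      prof <- profileAtDepth(tg, mucosa, 2, zOffset = front)
      thermalCurve <- centralAxisCurve(tg, 1, "thermal", zOffset = front)
      row$advantageDepth <- ad$depth
      row$timeMin <- it$minutes
      row$width50 <- isodoseWidth(prof, 0.5)$width
      row$width80 <- isodoseWidth(prof, 0.8)$width
      row$surfaceThermal <- thermalCurve$value[1]
      row$surfaceThermalRelErr <- thermalCurve$relErr[1]
      row$ok <- TRUE
      row
    }, error = function(e) {
      row$note <- conditionMessage(e)
      row
    })
    rows[[length(rows) + 1L]] <- res
  }
  do.call(rbind, lapply(rows, function(r) {
    r$note <- if (is.null(r$note)) "" else r$note
    r
  }))
}
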