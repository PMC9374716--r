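#' Monte-Carlo run configuration
#'
#' @slot nHistories number of primary histories.
#' @slot seed integer seed of the engine RNG (xoshiro256++).
#' @slot batches number of statistical batches (>= 2) used for the
#'   relative-error estimate.
#' @slot weightCutoff weight below which Russian roulette is played.
#' @slot rouletteSurvival survival weight of Russian roulette.
#' @export
setClass("RunConfig",
  representation(nHistories = "numeric", seed = "numeric",
                 batches = "numeric", weightCutoff = "numeric",
                 rouletteSurvival = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nHistories < 1) msg <- c(msg, "nHistories must be >= 1")
    if (object@batches < 2) msg <- c(msg, "batches must be >= 2")
    if (object@nHistories < object@batches)
      msg <- c(msg, "nHistories must be >= batches")
    if (!(object@weightCutoff > 0 &&
          object@weightCutoff < object@rouletteSurvival))
      msg <- c(msg, "need 0 < weightCutoff < rouletteSurvival")
    if (length(msg)) msg else TRUE
  })

#' Construct a run configuration
#'
#' @param nHistories number of primary histories (rounded up to a multiple
#'   of `batches`).
#' @param seed RNG seed.
#' @param batches statistical batches, default 20.
#' @param weightCutoff roulette trigger weight, default 1e-3.
#' @param rouletteSurvival roulette survival weight, default 1e-2.
#' @return A [RunConfig-class].
#' @export
runConfig <- function(nHistories, seed = 1, batches = 20,
                      weightCutoff = 1e-3, rouletteSurvival = 1e-2) {
  new("RunConfig", nHistories = as.numeric(nHistories), seed = as.numeric(seed),
      batches = as.numeric(batches), weightCutoff = weightCutoff,
      rouletteSurvival = rouletteSurvival)
}

#' Track-length tally results
#'
#' Per-bin, per-group track-length flux (cm^-2 per source particle), the
#' photon energy-fluence channel (MeV cm^-2 per source particle) and
#' batch-based fractional standard errors. Zero-mean bins carry NA relative
#' error (flagged undefined).
#'
#' @slot type "cylindrical", "voxel" or "sphere".
#' @slot mesh mesh description (bin edges / origin / centers).
#' @slot flux neutron flux array; last dimension indexes energy groups.
#' @slot photonFluence photon energy-fluence array.
#' @slot relErr,relErrPhoton fractional standard errors, same shapes.
#' @slot nHistories histories actually run.
#' @slot groupLabels energy-group labels.
#' @export
setClass("TallyGrid",
  representation(type = "character", mesh = "list", flux = "array",
                 photonFluence = "array", relErr = "array",
                 relErrPhoton = "array", nHistories = "numeric",
                 groupLabels = "character"),
  validity = function(object) {
    if (any(object@flux < 0, na.rm = TRUE)) "flux must be >= 0"
    else if (any(object@relErr < 0, na.rm = TRUE)) "relErr must be >= 0"
    else TRUE
  })

setMethod("show", "TallyGrid", function(object) {
  cat("TallyGrid (", object@type, "), ", sep = "")
  cat(paste(dim(object@flux), collapse = " x "), "bins;",
      format(object@nHistories, big.mark = ","), "histories\n")
  re <- object@relErr[is.finite(object@relErr)]
  if (length(re))
    cat("  median rel. error:", signif(stats::median(re), 3), "\n")
})

#' Cylindrical tally specification
#'
#' Uniform (r, z) mesh centred on the beam axis.
#'
#' @param zRange `c(zmin, zmax)` in cm.
#' @param dz axial bin width, cm.
#' @param rMax radial extent, cm (bins start at r = 0).
#' @param dr radial bin width, cm.
#' @return tally spec for [runTransport()].
#' @export
cylTally <- function(zRange, dz, rMax, dr) {
  nz <- as.integer(round((zRange[2] - zRange[1]) / dz))
  nr <- as.integer(round(rMax / dr))
  stopifnot(nz >= 1, nr >= 1)
  structure(list(type = 1L, z0 = zRange[1], dz = dz, nz = nz, dr = dr,
                 nr = nr), class = "tallySpec")
}

#' Voxel tally specification
#'
#' @param origin `c(x, y, z)` of the grid corner, cm.
#' @param h voxel edge, cm.
#' @param dims `c(nx, ny, nz)` voxel counts.
#' @return tally spec for [runTransport()].
#' @export
voxelTally <- function(origin, h, dims) {
  structure(list(type = 2L, origin = as.numeric(origin), h = h,
                 dims = as.integer(dims)), class = "tallySpec")
}

#' Small-sphere tally specification
#'
#' @param centers n x 3 matrix of sphere centers, cm.
#' @param radius sphere radius, cm.
#' @return tally spec for [runTransport()].
#' @export
sphereTally <- function(centers, radius) {
  centers <- if (is.matrix(centers)) centers else matrix(centers, ncol = 3)
  structure(list(type = 3L, centers = centers, radius = radius),
            class = "tallySpec")
}

#' Run the multigroup Monte-Carlo transport
#'
#' Analog transport of neutrons (group-to-group isotropic scattering,
#' capture with hydrogen-capture photon emission) and photons (straight-line
#' exponential attenuation) through a [Scene-class]. Results are
#' reproducible bit-identically for identical (seed, config, scene).
#'
#' @param scene a [Scene-class].
#' @param source a [SourceModel-class].
#' @param config a [RunConfig-class].
#' @param tallies a single tally spec or a list of tally specs.
#' @return list with `tallies` (list of [TallyGrid-class]) and `summary`
#'   (class `mcRunSummary`): emitted/secondary/absorbed/escaped weights,
#'   roulette terms and the weight-balance residual.
#' @export
runTransport <- function(scene, source, config, tallies) {
  stopifnot(is(scene, "Scene"), is(source, "SourceModel"),
            is(config, "RunConfig"))
  validObject(config)
  if (inherits(tallies, "tallySpec")) tallies <- list(tallies)
  glabels <- c("fast", "epithermal", "thermal")
  res <- cpp_run(scene@engine, .sourceEngine(source),
                 list(nHistories = config@nHistories, seed = config@seed,
                      batches = as.integer(config@batches),
                      weightCutoff = config@weightCutoff,
                      rouletteSurvival = config@rouletteSurvival),
                 lapply(tallies, unclass))
  G <- length(glabels)
  nh <- res$summary[["nHistories"]]
  out <- vector("list", length(tallies))
  for (i in seq_along(tallies)) {
    sp <- tallies[[i]]
    r <- res$tallies[[i]]
    if (sp$type == 1L) {
      arr <- array(r$mean, dim = c(sp$nr, sp$nz, G + 1))
      rel <- array(r$relerr, dim = c(sp$nr, sp$nz, G + 1))
      mesh <- list(rEdges = seq(0, sp$nr * sp$dr, by = sp$dr),
                   zEdges = seq(sp$z0, sp$z0 + sp$nz * sp$dz, by = sp$dz),
                   rCenters = (seq_len(sp$nr) - 0.5) * sp$dr,
                   zCenters = sp$z0 + (seq_len(sp$nz) - 0.5) * sp$dz)
      type <- "cylindrical"
    } else if (sp$type == 2L) {
      arr <- array(r$mean, dim = c(sp$dims, G + 1))
      rel <- array(r$relerr, dim = c(sp$dims, G + 1))
      mesh <- list(origin = sp$origin, h = sp$h, dims = sp$dims)
      type <- "voxel"
    } else {
      ns <- nrow(sp$centers)
      arr <- array(r$mean, dim = c(ns, 1, G + 1))
      rel <- array(r$relerr, dim = c(ns, 1, G + 1))
      mesh <- list(centers = sp$centers, radius = sp$radius)
      type <- "sphere"
    }
    nd <- length(dim(arr))
    idxG <- seq_len(G)
    flux <- .takeLast(arr, idxG); relf <- .takeLast(rel, idxG)
    pflu <- .takeLast(arr, G + 1, drop = TRUE)
    relp <- .takeLast(rel, G + 1, drop = TRUE)
    out[[i]] <- new("TallyGrid", type = type, mesh = mesh, flux = flux,
                    photonFluence = as.array(pflu), relErr = relf,
                    relErrPhoton = as.array(relp), nHistories = nh,
                    groupLabels = glabels)
  }
  summary <- as.list(res$summary)
  summary$rng <- "xoshiro256++"
  class(summary) <- "mcRunSummary"
  list(tallies = out, summary = summary)
}

# index the last dimension of an array
.takeLast <- function(arr, idx, drop = FALSE) {
  nd <- length(dim(arr))
  args <- c(list(arr), rep(list(quote(expr = )), nd - 1), list(idx),
            list(drop = drop))
  do.call(`[`, args)
}

#' @export
print.mcRunSummary <- function(x, ...) {
  cat("MC run:", format(x$nHistories, big.mark = ","), "histories, seed",
      x$seed, paste0("(", x$rng, ")\n"))
  cat(sprintf("  emitted %.6g (+ %.6g secondary), absorbed %.6g, escaped %.6g\n",
              x$emitted, x$secondary, x$absorbed, x$escaped))
  cat(sprintf("  roulette killed %.3g / gained %.3g; balance residual %.3g\n",
              x$rouletteKilled, x$rouletteGained, x$balance))
  invisible(x)
}

#' Relative weight-balance residual of a run
#'
#' |emitted + secondary - absorbed - escaped - roulette net| relative to the
#' total emitted weight. The transport engine conserves statistical weight,
#' so this is zero to floating-point accumulation error.
#'
#' @param summary an `mcRunSummary` from [runTransport()].
#' @return non-negative number.
#' @export
weightBalance <- function(summary) {
  abs(summary$balance) / (summary$emitted + summary$secondary)
}

#' Batch-based relative error
#'
#' Standard error of the batch means divided by the grand mean, per bin.
#' Bins with zero mean are flagged with NA.
#'
#' @param batchMeans matrix with one row per bin and one column per batch
#'   (a vector is treated as a single bin).
#' @return numeric vector of fractional standard errors per bin.
#' @export
relativeError <- function(batchMeans) {
  if (is.vector(batchMeans)) batchMeans <- matrix(batchMeans, nrow = 1)
  B <- ncol(batchMeans)
  if (B < 2) stop("need at least 2 batches")
  m <- rowMeans(batchMeans)
  se <- apply(batchMeans, 1, sd) / sqrt(B)
  ifelse(m == 0, NA_real_, se / m)
}

#' Group-resolved flux extraction
#'
#' @param tally a [TallyGrid-class].
#' @param group group label ("fast", "epithermal", "thermal") or index.
#' @return array of per-bin flux for that group (last dimension dropped).
#' @export
groupFlux <- function(tally, group = "thermal") {
  g <- if (is.character(group)) match(group, tally@groupLabels) else group
  if (is.na(g)) stop("unknown group; labels: ",
                     paste(tally@groupLabels, collapse = ", "))
  as.array(.takeLast(tally@flux, g, drop = TRUE))
}

#' Free-in-air surface scan along the collimator
#'
#' Places small spherical tallies at the given positions (all must lie in
#' air, outside solid regions) and reports the thermal flux and photon dose
#' per source particle at each, emulating foil/TLD leakage scans along the
#' collimator surface.
#'
#' @param scene a [Scene-class].
#' @param source a [SourceModel-class].
#' @param config a [RunConfig-class].
#' @param positions n x 3 matrix of scan positions, cm.
#' @param radius tally sphere radius, cm.
#' @param kerma a [KermaSet-class] used to convert photon energy fluence to
#'   gamma dose.
#' @return data.frame: position columns, thermalFlux (+ relErr),
#'   photonFluence (+ relErr), gammaDose (Gy per source particle).
#' @export
surfaceScan <- function(scene, source, config, positions, radius = 0.75,
                        kerma = defaultKerma()) {
  positions <- if (is.matrix(positions)) positions else
    matrix(positions, ncol = 3)
  mats <- locate(scene, positions)
  if (any(mats != "air"))
    stop("scan positions must lie in air; position(s) ",
         paste(which(mats != "air"), collapse = ", "), " are inside ",
         paste(unique(mats[mats != "air"]), collapse = "/"))
  res <- runTransport(scene, source, config, sphereTally(positions, radius))
  tg <- res$tallies[[1]]
  thermal <- groupFlux(tg, "thermal")
  relT <- as.array(.takeLast(tg@relErr, match("thermal", tg@groupLabels),
                             drop = TRUE))
  data.frame(x = positions[, 1], y = positions[, 2], z = positions[, 3],
             thermalFlux = as.numeric(thermal), thermalRelErr = as.numeric(relT),
             photonFluence = as.numeric(tg@photonFluence),
             photonRelErr = as.numeric(tg@relErrPhoton),
             gammaDose = as.numeric(tg@photonFluence) * kerma@photonFactor)
}
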