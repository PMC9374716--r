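#' Validate an experiment configuration
#'
#' Rejects physically invalid inputs before any compute, reporting the
#' offending field paths.
#'
#' @param config configuration list (or path to a YAML file).
#' @return the (possibly YAML-loaded) config list, invisibly on success;
#'   errors with field paths otherwise.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- character()
  chk <- function(cond, path) if (!cond) bad <<- c(bad, path)
  if (!is.null(config[["airGap"]])) chk(config[["airGap"]] >= 0, "airGap (must be >= 0)")
  if (!is.null(config[["gaps"]])) chk(all(config[["gaps"]] >= 0), "gaps (must be >= 0)")
  if (!is.null(config[["kind"]]))
    chk(config[["kind"]] %in% c("standard", "extended5", "extended10"), "kind")
  if (!is.null(config[["kinds"]]))
    chk(all(config[["kinds"]] %in% c("standard", "extended5", "extended10")),
        "kinds")
  src <- config$source
  if (!is.null(src$groupSpectrum))
    chk(abs(sum(src$groupSpectrum) - 1) <= 1e-9 &&
          all(src$groupSpectrum >= 0), "source$groupSpectrum (must sum to 1)")
  if (!is.null(src$photonFraction))
    chk(src$photonFraction >= 0 && src$photonFraction <= 1,
        "source$photonFraction (must be in [0,1])")
  if (!is.null(src$intensity)) chk(src$intensity > 0, "source$intensity")
  run <- config$run
  if (!is.null(run$nHistories)) {
    chk(run$nHistories >= 1, "run$nHistories (must be >= 1)")
    b <- if (is.null(run$batches)) 20 else run$batches
    chk(run$nHistories >= b, "run$nHistories (must be >= run$batches)")
  }
  if (!is.null(run$batches)) chk(run$batches >= 2, "run$batches (>= 2)")
  if (!is.null(config[["bloodBoron"]])) chk(config[["bloodBoron"]] >= 0, "bloodBoron")
  if (length(bad))
    stop("invalid configuration field(s): ", paste(bad, collapse = "; "))
  invisible(config)
}

.configSource <- function(config) {
  a <- config$source
  if (is.null(a)) return(defaultSource())
  do.call(sourceModel, a)
}

.configRun <- function(config, defaultHistories = 2e4) {
  a <- config$run
  if (is.null(a)) a <- list()
  if (is.null(a$nHistories)) a$nHistories <- defaultHistories
  if (is.null(a$seed)) a$seed <- 1
  do.call(runConfig, a)
}

#' Run one of the four computational experiments
#'
#' Executes the full pipeline for the requested experiment — scene build,
#' transport, dosimetry, metrics/DVH — and writes its tables plus a run
#' manifest (config snapshot, seeds, software version, per-stage timings,
#' output inventory with checksums). Re-running with an identical config
#' and seed reproduces identical outputs (identical checksums).
#'
#' @param config configuration list or YAML path. Common fields: `kind` /
#'   `kinds`, `airGap` / `gaps`, `source` (passed to [sourceModel()]),
#'   `run` (passed to [runConfig()]), `bloodBoron`; plan-case additionally
#'   takes `case` ("nasopharynx"/"hypopharynx") and `plans` (list of
#'   `list(kind=, airGap=)`).
#' @param experiment one of "water-characterisation", "surface-leakage",
#'   "gap-sweep", "plan-case".
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly (list of class `runManifest`).
#' @export
runExperiment <- function(config,
                          experiment = c("water-characterisation",
                                         "surface-leakage", "gap-sweep",
                                         "plan-case"),
                          outDir = tempfile("bnct_run_")) {
  experiment <- match.arg(experiment)
  config <- validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  source <- .configSource(config)
  cfg <- .configRun(config)
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  files <- character()
  mark <- function(name) {
    stages[[name]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
  }
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  if (experiment == "water-characterisation") {
    kind <- if (is.null(config[["kind"]])) "standard" else config[["kind"]]
    gap <- if (is.null(config[["airGap"]])) 0 else config[["airGap"]]
    scene <- makeWaterPhantomScene(kind, gap)
    front <- phantomFront(scene)
    tally <- cylTally(c(front, front + 22), 0.5, 12, 0.5)
    mark("scene")
    run <- runTransport(scene, source, cfg, tally)
    mark("transport")
    tg <- run$tallies[[1]]
    emit(centralAxisCurve(tg, 1, "thermal", zOffset = front),
         "central_axis_thermal.csv")
    gcur <- centralAxisCurve(tg, 1, "photon", zOffset = front)
    gcur$value <- gcur$value * defaultKerma()@photonFactor  # gamma dose
    emit(gcur, "central_axis_gamma.csv")
    summary <- run$summary
    mark("metrics")
  } else if (experiment == "surface-leakage") {
    kind <- if (is.null(config[["kind"]])) "standard" else config[["kind"]]
    coll <- buildCollimator(kind)
    scene <- buildScene(coll, 0, NULL)
    spacing <- if (is.null(config[["spacing"]])) 2 else config[["spacing"]]
    zs <- seq(1, exitPlane(coll) - 1, by = spacing)
    pos <- cbind(coll@outerRadius + 1.5, 0, zs)
    mark("scene")
    scan <- surfaceScan(scene, source, cfg, pos)
    emit(scan, "surface_leakage.csv")
    summary <- NULL
    mark("transport")
  } else if (experiment == "gap-sweep") {
    kinds <- if (is.null(config[["kinds"]])) "standard" else config[["kinds"]]
    gaps <- if (is.null(config[["gaps"]])) c(0, 5, 10) else config[["gaps"]]
    mark("scene")
    tab <- gapSweep(kinds, gaps, source, cfg)
    emit(tab, "gap_sweep.csv")
    summary <- NULL
    mark("transport")
  } else {  # plan-case
    caseId <- if (is.null(config[["case"]])) "nasopharynx" else config[["case"]]
    plans <- config[["plans"]]
    if (is.null(plans))
      plans <- list(list(kind = "standard", airGap = 10),
                    list(kind = "extended10", airGap = 0))
    case <- headNeckCase(caseId,
                         seed = if (is.null(config[["caseSeed"]])) 1L
                                else config[["caseSeed"]])
    doses <- list(); times <- numeric()
    for (pl in plans) {
      hn <- makeHeadNeckPhantom(case, kind = pl$kind, airGap = pl$airGap)
      vp <- hn$phantom
      front <- phantomFront(hn$scene)
      tally <- voxelTally(c(vp@origin, front), vp@voxelEdge,
                          dim(vp@labels))
      run <- runTransport(hn$scene, source, cfg, tally)
      plan <- planDose(hn$scene, run$tallies[[1]],
                       intensity = source@intensity,
                       bloodBoron = if (is.null(config[["bloodBoron"]])) 25
                                    else config[["bloodBoron"]])
      doses[[pl$kind]] <- plan$weighted
      times[pl$kind] <- plan$minutes
      phantom <- hn$phantom
    }
    mark("transport")
    cmp <- comparePlans(doses[[1]], doses[[2]], organMasks(phantom))
    names(cmp$table)[3:4] <- names(doses)
    emit(cmp$table, paste0("dvh_", caseId, ".csv"))
    emit(data.frame(plan = names(times), minutes = unname(times)),
         paste0("times_", caseId, ".csv"))
    summary <- NULL
    mark("metrics")
  }

  manifest <- list(experiment = experiment, config = config,
                   seed = cfg@seed, rng = "xoshiro256++",
                   version = as.character(utils::packageVersion("bnctbeam")),
                   timings = stages,
                   mcSummary = if (!is.null(summary)) unclass(summary),
                   outputs = data.frame(
                     file = basename(files),
                     md5 = unname(tools::md5sum(files))))
  class(manifest) <- "runManifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest$outDir <- outDir
  invisible(manifest)
}

#' @export
print.runManifest <- function(x, ...) {
  cat("runManifest:", x$experiment, "(seed", x$seed, ", version",
      x$version, ")\n")
  cat("  outputs:", paste(x$outputs$file, collapse = ", "), "\n")
  invisible(x)
}

#' Export a dose grid
#'
#' Supported modes: `"csv"` (x, y, z, value rows, full precision), `"json"`
#' (full double-precision round trip), `"nifti"` (label-map/dose volume via
#' RNifti) and
#' `"rtdose"` (JSON container mimicking the DICOM RT Dose grid-scaling
#' contract: uint16 values with a dose-grid scaling factor, round trip
#' within one scaling quantum per voxel).
#'
#' @param grid numeric 3-D array (Gy or Gy_w).
#' @param mesh list with `origin` (corner, cm) and `h` (voxel edge, cm).
#' @param mode export mode.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportDose <- function(grid, mesh, mode = c("csv", "json", "nifti", "rtdose"),
                       file) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) stop("unsupported export mode '",
                                            mode[1], "'"))
  dims <- dim(grid)
  if (mode == "csv") {
    idx <- arrayInd(seq_along(grid), dims)
    df <- data.frame(
      x = mesh$origin[1] + (idx[, 1] - 0.5) * mesh$h,
      y = mesh$origin[2] + (idx[, 2] - 0.5) * mesh$h,
      z = mesh$origin[3] + (idx[, 3] - 0.5) * mesh$h,
      value = as.numeric(grid))
    write.csv(df, file, row.names = FALSE)
  } else if (mode == "json") {
    jsonlite::write_json(list(origin = mesh$origin, h = mesh$h, dims = dims,
                              values = as.numeric(grid)),
                         file, auto_unbox = TRUE, digits = NA)
  } else if (mode == "nifti") {
    img <- RNifti::asNifti(grid, pixdim = rep(mesh$h, 3))
    RNifti::writeNifti(img, file)
  } else {  # rtdose: quantized uint16 + dose-grid scaling
    mx <- max(grid)
    scaling <- if (mx > 0) mx / 65535 else 1
    jsonlite::write_json(list(doseGridScaling = scaling, dims = dims,
                              origin = mesh$origin, h = mesh$h,
                              values = as.integer(round(grid / scaling))),
                         file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Read back an exported dose grid
#'
#' @param file path written by [exportDose()].
#' @param mode the mode it was written with.
#' @return list with `grid` and `mesh`.
#' @export
readDose <- function(file, mode = c("csv", "json", "nifti", "rtdose")) {
  mode <- match.arg(mode)
  if (mode == "csv") {
    df <- read.csv(file)
    xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
    zs <- sort(unique(df$z))
    h <- if (length(xs) > 1) xs[2] - xs[1] else 1
    grid <- array(df$value[order(df$z, df$y, df$x)],
                  dim = c(length(xs), length(ys), length(zs)))
    list(grid = grid, mesh = list(origin = c(xs[1], ys[1], zs[1]) - h / 2,
                                  h = h))
  } else if (mode == "json") {
    j <- jsonlite::read_json(file, simplifyVector = TRUE)
    list(grid = array(j$values, dim = j$dims),
         mesh = list(origin = j$origin, h = j$h))
  } else if (mode == "nifti") {
    img <- RNifti::readNifti(file)
    list(grid = array(as.numeric(img), dim = dim(img)),
         mesh = list(h = RNifti::pixdim(img)[1]))
  } else {
    j <- jsonlite::read_json(file, simplifyVector = TRUE)
    list(grid = array(j$values * j$doseGridScaling, dim = j$dims),
         mesh = list(origin = j$origin, h = j$h))
  }
}
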