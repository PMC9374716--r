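#' Voxel phantom
#'
#' Labelled voxel grid with a label-to-tissue/material map and per-label
#' 10B concentrations. Every non-air voxel must map to a tissue row of the
#' weighting table.
#'
#' @slot labels 3-D integer array of organ labels (1 = air).
#' @slot voxelEdge voxel edge length, cm (default 0.3).
#' @slot origin `c(x, y)` of the grid corner in beam coordinates; z = 0 is
#'   the grid front face (placed at the phantom front by [buildScene()]).
#' @slot labelMap data.frame: label, organ, tissue, material.
#' @slot boronPerLabel named numeric, 10B concentration (ug/g) per label.
#' @export
setClass("VoxelPhantom",
  representation(labels = "array", voxelEdge = "numeric", origin = "numeric",
                 labelMap = "data.frame", boronPerLabel = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@voxelEdge <= 0) msg <- c(msg, "voxelEdge must be > 0")
    labs <- unique(as.integer(object@labels))
    if (!all(labs %in% object@labelMap$label))
      msg <- c(msg, paste("labels without mapping:",
                          paste(setdiff(labs, object@labelMap$label),
                                collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

setMethod("show", "VoxelPhantom", function(object) {
  d <- dim(object@labels)
  cat("VoxelPhantom:", paste(d, collapse = " x "), "voxels of",
      object@voxelEdge, "cm\n")
  cnt <- table(factor(as.integer(object@labels),
                      levels = object@labelMap$label,
                      labels = object@labelMap$organ))
  cnt <- cnt[cnt > 0]
  cat("  organs:", paste(names(cnt), " (", as.integer(cnt), ")",
                         sep = "", collapse = ", "), "\n")
})

#' Organ masks of a voxel phantom
#'
#' @param phantom a [VoxelPhantom-class].
#' @return named list of logical arrays, one per organ label.
#' @export
organMasks <- function(phantom) {
  lm <- phantom@labelMap
  masks <- lapply(lm$label, function(l) phantom@labels == l)
  names(masks) <- lm$organ
  masks[vapply(masks, any, logical(1))]
}

#' Water phantom scene
#'
#' Acrylic-walled water box: interior 21 cm (x) x 28 cm (y, height) x 21 cm
#' (z, depth), 1 cm walls except a 2 mm front wall, with its front face at
#' the collimator exit plane plus the air gap.
#'
#' @param kind collimator kind.
#' @param airGap cm.
#' @param collimator optional pre-built [CollimatorSpec-class] (overrides
#'   `kind`).
#' @return a [Scene-class].
#' @export
makeWaterPhantomScene <- function(kind = "standard", airGap = 0,
                                  collimator = NULL) {
  if (is.null(collimator)) collimator <- buildCollimator(kind)
  buildScene(collimator, airGap,
             boxPhantom("water", c(21, 28, 21),
                        walls = list(material = "acrylic", front = 0.2,
                                     other = 1)))
}

#' Cubic tissue phantom scene
#'
#' The 30 x 30 x 30 cm tissue cube (density 1 g/cm^3; H/C/N/O weight
#' fractions 0.1/0.1/0.03/0.77) with a uniform 25 ug/g 10B load, used for
#' the air-gap dose study (the whole cube is treated as mucosal membrane
#' when prescribing).
#'
#' @param kind collimator kind.
#' @param airGap cm.
#' @param boron uniform 10B concentration, ug/g.
#' @return a [Scene-class].
#' @export
makeCubicPhantomScene <- function(kind = "standard", airGap = 0, boron = 25) {
  buildScene(buildCollimator(kind), airGap,
             boxPhantom("tissue", c(30, 30, 30), boron = boron))
}

#' Stylised head-and-neck case description
#'
#' Placement rules for the two mock cases: a 1 cm^3 spherical tumour in the
#' left nasopharynx at about 6 cm depth with a left-lateral beam
#' (nasopharynx case), or in the anterior midline neck below the thyroid,
#' in front of the esophagus, with an anterior beam (hypopharynx case).
#' Organ primitives are stylised ellipsoids, cylinders and slabs; the seed
#' applies a small (+/- 0.15 cm) deterministic jitter to organ centres.
#'
#' @param id "nasopharynx" or "hypopharynx".
#' @param seed integer seed.
#' @return list of class `caseDescription`.
#' @export
headNeckCase <- function(id = c("nasopharynx", "hypopharynx"), seed = 1L) {
  id <- match.arg(id)
  structure(list(id = id,
                 tumourVolume = 1,           # cm^3
                 tumourDepth = if (id == "nasopharynx") 6 else 2.5,
                 beamEntry = if (id == "nasopharynx") "left lateral"
                             else "anterior",
                 seed = as.integer(seed)),
            class = "caseDescription")
}

# geometry primitives on the voxel-center coordinate arrays
.ellipsoid <- function(X, Y, Z, c0, s) {
  ((X - c0[1]) / s[1])^2 + ((Y - c0[2]) / s[2])^2 + ((Z - c0[3]) / s[3])^2 <= 1
}
.sphere <- function(X, Y, Z, c0, r) .ellipsoid(X, Y, Z, c0, c(r, r, r))
.cylY <- function(X, Y, Z, x0, z0, r, y0, y1) {
  (X - x0)^2 + (Z - z0)^2 <= r^2 & Y >= y0 & Y <= y1
}
.boxm <- function(X, Y, Z, b) {
  X >= b[1] & X <= b[2] & Y >= b[3] & Y <= b[4] & Z >= b[5] & Z <= b[6]
}

#' Build a stylised head-and-neck voxel phantom and scene
#'
#' Beam coordinates: z is depth from the entry surface along the beam axis,
#' x/y are lateral. The phantom is deterministic for a given case seed.
#' The tumour is a 1 cm^3 sphere (volume within one voxel of 1 cm^3) placed
#' per the case rules, fully inside the body; all organ masks are clipped
#' to the body.
#'
#' @param case a `caseDescription` from [headNeckCase()].
#' @param kind collimator kind for the scene.
#' @param airGap cm between collimator exit and the phantom box front.
#' @param voxelEdge cm, default 0.3 (3 mm voxels).
#' @return list with `phantom` (a [VoxelPhantom-class]) and `scene`
#'   (a [Scene-class]).
#' @export
makeHeadNeckPhantom <- function(case, kind = "standard", airGap = 10,
                                voxelEdge = 0.3) {
  stopifnot(inherits(case, "caseDescription"))
  h <- voxelEdge
  # deterministic jitter from the case seed, without touching the session RNG
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(case$seed)
  jit <- function() runif(3, -0.15, 0.15)

  if (case$id == "nasopharynx") {
    xr <- c(-10, 10); yr <- c(-18, 11); zr <- c(0, 16)
  } else {
    xr <- c(-17, 17); yr <- c(-15, 20); zr <- c(0, 14)
  }
  nx <- ceiling(diff(xr) / h); ny <- ceiling(diff(yr) / h)
  nz <- ceiling(diff(zr) / h)
  cx <- xr[1] + (seq_len(nx) - 0.5) * h
  cy <- yr[1] + (seq_len(ny) - 0.5) * h
  cz <- (seq_len(nz) - 0.5) * h
  X <- array(rep(cx, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(cy, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(cz, each = nx * ny), dim = c(nx, ny, nz))

  soft <- function(org) data.frame(label = NA, organ = org,
                                   tissue = "soft tissue",
                                   material = "tissue")
  if (case$id == "nasopharynx") {
    # beam from the patient's left: z = depth from the left head surface
    head <- .ellipsoid(X, Y, Z, c(0, 0, 8), c(8.5, 10, 8))
    neck <- .cylY(X, Y, Z, 0, 8, 5, -16, -5)
    shoulders <- .boxm(X, Y, Z, c(-10, 10, -18, -14.5, 2, 15))
    body <- head | neck | shoulders
    organs <- list(
      brain = .ellipsoid(X, Y, Z, c(0, 3, 8) + jit(), c(6, 5.2, 6.2)),
      brainstem = .cylY(X, Y, Z, -2, 8, 1.2, -2, 3) ,
      `spinal cord` = .cylY(X, Y, Z, -3.5, 8, 0.6, -16, -2),
      eye_l = .sphere(X, Y, Z, c(6.6, 3.5, 5.3) + jit(), 1.15),
      eye_r = .sphere(X, Y, Z, c(6.6, 3.5, 10.7) + jit(), 1.15),
      esophagus = .cylY(X, Y, Z, -1.5, 8, 0.8, -14, -4),
      parotid_l = .ellipsoid(X, Y, Z, c(1, -0.5, 2.6) + jit(),
                             c(1.5, 2, 1.1)),
      parotid_r = .ellipsoid(X, Y, Z, c(1, -0.5, 13.4) + jit(),
                             c(1.5, 2, 1.1)),
      thyroid = .ellipsoid(X, Y, Z, c(3.5, -8, 8) + jit(), c(1.1, 1.5, 1.8)),
      mandible = .boxm(X, Y, Z, c(4, 6.2, -3.2, -1.2, 4, 12)),
      mucosa = .ellipsoid(X, Y, Z, c(3.5, -1, 8), c(3, 4, 2.6)) &
        !.ellipsoid(X, Y, Z, c(3.5, -1, 8), c(2.2, 3.2, 1.8)))
    tumourC <- c(0, 0, case$tumourDepth) + c(0, 0, runif(1, -0.1, 0.1))
  } else {
    # anterior beam: z = depth from the anterior neck surface
    neck <- .cylY(X, Y, Z, 0, 5, 5, -8, 9)
    head <- .ellipsoid(X, Y, Z, c(0, 13, 6), c(8.5, 9, 7.5))
    shoulders <- .boxm(X, Y, Z, c(-17, 17, -15, -7.5, 1, 13))
    body <- head | neck | shoulders
    organs <- list(
      brain = .ellipsoid(X, Y, Z, c(0, 14, 6) + jit(), c(6.5, 6, 6)),
      brainstem = .cylY(X, Y, Z, 0, 6.5, 1.2, 7, 10.5),
      `spinal cord` = .cylY(X, Y, Z, 0, 8.3, 0.6, -14, 8),
      eye_l = .sphere(X, Y, Z, c(-2.7, 15.5, 1.8) + jit(), 1.15),
      eye_r = .sphere(X, Y, Z, c(2.7, 15.5, 1.8) + jit(), 1.15),
      esophagus = .cylY(X, Y, Z, 0, 6.6, 0.8, -8, 6),
      lung = .ellipsoid(X, Y, Z, c(-6, -11, 7) + jit(), c(4, 2.6, 4)) |
        .ellipsoid(X, Y, Z, c(6, -11, 7) + jit(), c(4, 2.6, 4)),
      parotid_l = .ellipsoid(X, Y, Z, c(-6, 9.5, 5.5) + jit(),
                             c(1.1, 1.6, 2)),
      parotid_r = .ellipsoid(X, Y, Z, c(6, 9.5, 5.5) + jit(),
                             c(1.1, 1.6, 2)),
      thyroid = .ellipsoid(X, Y, Z, c(0, 0.5, 2.2), c(1.8, 1.2, 1.1)),
      mandible = .boxm(X, Y, Z, c(-4, 4, 7.5, 9.5, 0.8, 3)),
      mucosa = .cylY(X, Y, Z, 0, 4.2, 1.7, -6, 7) &
        !.cylY(X, Y, Z, 0, 4.2, 1.1, -6.5, 7.5))
    tumourC <- c(0, -2, case$tumourDepth) + c(0, 0, runif(1, -0.1, 0.1))
  }
  # voxelise the 1 cm^3 sphere as exactly the round(V/h^3) voxel centres
  # nearest the tumour centre, so the discretised volume is within one
  # voxel of the nominal volume
  nTum <- max(1L, as.integer(round(case$tumourVolume / h^3)))
  d2 <- (X - tumourC[1])^2 + (Y - tumourC[2])^2 + (Z - tumourC[3])^2
  tumour <- array(FALSE, dim = dim(d2))
  tumour[order(as.numeric(d2))[seq_len(nTum)]] <- TRUE
  if (any(tumour & !body))
    stop("tumour placement falls outside the body mask")

  lm <- rbind(data.frame(label = NA, organ = "air", tissue = "air",
                         material = "air"),
              data.frame(label = NA, organ = "body", tissue = "soft tissue",
                         material = "tissue"),
              soft("brain"), soft("brainstem"), soft("spinal cord"),
              soft("eye_l"), soft("eye_r"), soft("esophagus"))
  lm$tissue[lm$organ == "brain"] <- "brain"
  if (case$id == "hypopharynx") lm <- rbind(lm, soft("lung"))
  lm <- rbind(lm, soft("parotid_l"), soft("parotid_r"), soft("thyroid"),
              data.frame(label = NA, organ = "mandible", tissue = "bone",
                         material = "tissue"),
              data.frame(label = NA, organ = "mucosa", tissue = "mucosa",
                         material = "tissue"),
              data.frame(label = NA, organ = "tumour", tissue = "tumour",
                         material = "tissue"))
  lm$label <- seq_len(nrow(lm))

  labels <- array(1L, dim = c(nx, ny, nz))
  labels[body] <- lm$label[lm$organ == "body"]
  for (org in names(organs)) {
    m <- organs[[org]] & body  # organs clipped to the body mask
    labels[m] <- lm$label[lm$organ == org]
  }
  labels[tumour] <- lm$label[lm$organ == "tumour"]

  boron <- boronConcentration(lm$tissue, 25)
  names(boron) <- as.character(lm$label)
  vp <- new("VoxelPhantom", labels = labels, voxelEdge = h,
            origin = c(xr[1], yr[1]), labelMap = lm, boronPerLabel = boron)
  scene <- buildScene(buildCollimator(kind), airGap, voxelPhantomRegion(vp))
  list(phantom = vp, scene = scene, case = case, tumourCentre = tumourC)
}

#' Synthetic foil/TLD-style measurements of a truth curve
#'
#' Samples the truth at a fixed spacing (5 mm segments in-phantom, 1--2 cm
#' on the collimator surface are the typical choices) and applies
#' multiplicative lognormal noise of a configured coefficient of variation,
#' optionally with Poisson counting noise. The truth is retained so recovery
#' can be tested. `noise = NULL` gives noiseless readings.
#'
#' @param truth data.frame with columns `position` (or `depth`) and `value`.
#' @param spacing sample spacing, cm.
#' @param noise NULL (noiseless) or a list with `cv` (> 0), and optionally
#'   `counts` (mean counts at the truth maximum for Poisson noise).
#' @param seed integer seed.
#' @return data.frame of class `measurementSet`: position, reading, sigma,
#'   truth.
#' @export
synthMeasurement <- function(truth, spacing = 0.5, noise = list(cv = 0.03),
                             seed = 1L) {
  pos <- if ("position" %in% names(truth)) truth$position else truth$depth
  if (is.null(pos)) stop("truth needs a position/depth column")
  if (all(truth$value <= 0)) stop("truth must be positive somewhere")
  at <- seq(min(pos), max(pos), by = spacing)
  tv <- approx(pos, truth$value, at)$y
  if (is.null(noise)) {
    read <- tv
    sig <- rep(0, length(tv))
  } else {
    if (is.null(noise$cv) || noise$cv <= 0)
      stop("noise cv must be > 0 (use noise = NULL for noiseless readings)")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise$cv^2))
    read <- tv * rlnorm(length(tv), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    sig <- tv * noise$cv
    if (!is.null(noise$counts)) {   # foil-like counting statistics
      scale <- noise$counts / max(tv)
      read <- rpois(length(read), read * scale) / scale
      sig <- sqrt(sig^2 + tv / scale)
    }
  }
  structure(data.frame(position = at, reading = read, sigma = sig,
                       truth = tv),
            class = c("measurementSet", "data.frame"), seed = seed)
}

#' Fit an exponential attenuation curve to measurements
#'
#' Log-linear least squares of `reading ~ position`; for in-air axial decay
#' the fitted rate is the generating attenuation constant.
#'
#' @param measurements a `measurementSet` (or any data.frame with position
#'   and reading columns); non-positive readings are dropped.
#' @return list: `rate` (cm^-1), `lambda` (= 1/rate, cm), `amplitude`.
#' @export
fitAttenuation <- function(measurements) {
  d <- measurements[measurements$reading > 0, ]
  fit <- lm(log(reading) ~ position, data = d)
  rate <- -unname(coef(fit)[2])
  list(rate = rate, lambda = 1 / rate,
       amplitude = exp(unname(coef(fit)[1])))
}

#' Cadmium-difference thermal response
#'
#' Differences a bare and a cadmium-covered synthetic response to isolate
#' the sub-cadmium (thermal) component, mirroring the foil-activation
#' technique. With the multigroup representation the covered response is
#' simply the epithermal-and-above part, so the difference recovers the
#' thermal channel.
#'
#' @param bare,covered `measurementSet` data.frames on the same positions.
#' @return data.frame: position, thermal (bare - covered, floored at 0).
#' @export
cadmiumDifference <- function(bare, covered) {
  stopifnot(nrow(bare) == nrow(covered),
            all(abs(bare$position - covered$position) < 1e-9))
  data.frame(position = bare$position,
             thermal = pmax(bare$reading - covered$reading, 0))
}
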