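#' Simulation scene
#'
#' Axisymmetric collimator regions plus a box or voxel phantom, embedded in
#' an air world. The beam axis is z, with the origin at the
#' beam-shaping-assembly exit (the source plane). Region lookup is
#' first-match in declared order with the phantom declared first, so the
#' voxel phantom has the highest priority.
#'
#' @slot sourcePlaneZ axial origin (0 cm by construction).
#' @slot collimator a [CollimatorSpec-class], or NULL for open scenes.
#' @slot airGap cm between the collimator exit plane and the phantom front.
#' @slot regions ordered list of region descriptors (internal form).
#' @slot materials named list of [MaterialSpec-class] used by the scene.
#' @slot phantom phantom description list (or empty).
#' @slot worldBounds numeric(6): xlo, xhi, ylo, yhi, zlo, zhi of the world.
#' @slot engine cached translation of the scene for the compiled engine.
#' @include materials.R collimator.R
#' @export
setClass("Scene",
  representation(sourcePlaneZ = "numeric", collimator = "ANY",
                 airGap = "numeric", regions = "list", materials = "list",
                 phantom = "list", worldBounds = "numeric", engine = "list"))

#' Front face of the phantom in a scene
#' @param scene a [Scene-class].
#' @return z (cm) of the phantom front face.
#' @export
phantomFront <- function(scene) scene@phantom$frontZ

#' Source-plane-to-phantom-surface distance
#' @param scene a [Scene-class].
#' @return cm from the source plane to the phantom front face.
#' @export
sourceToSurface <- function(scene) phantomFront(scene) - scene@sourcePlaneZ

#' Describe a homogeneous box phantom
#'
#' @param material phantom material: a [MaterialSpec-class] or the name of a
#'   bundled material.
#' @param size interior dimensions `c(x, y, z)` in cm (z along the beam).
#' @param walls optional list `list(material =, front =, other =)` giving a
#'   wall material and thicknesses (cm); the front wall faces the beam.
#' @param boron uniform 10B concentration in the phantom interior (ug/g).
#' @return phantom description list for [buildScene()].
#' @export
boxPhantom <- function(material, size, walls = NULL, boron = 0) {
  list(kind = "box", material = material, size = as.numeric(size),
       walls = walls, boron = boron)
}

#' Describe a voxel phantom for scene building
#'
#' @param phantom a [VoxelPhantom-class].
#' @return phantom description list for [buildScene()].
#' @export
voxelPhantomRegion <- function(phantom) {
  list(kind = "voxel", phantom = phantom)
}

.resolveMaterial <- function(m) {
  if (is(m, "MaterialSpec")) return(m)
  lib <- defaultMaterials()
  if (is.character(m) && m %in% names(lib)) return(lib[[m]])
  stop("unknown material: ", deparse(m))
}

#' Build a collimator + phantom scene
#'
#' Places the phantom front face at the collimator exit plane plus the air
#' gap. A scene built with the standard collimator and gap `g` has the same
#' source-to-surface distance as one built with the L-cm extended collimator
#' and gap `g - L`.
#'
#' @param collimator a [CollimatorSpec-class], or NULL for an open (air-only)
#'   scene with the phantom front at `z = airGap`.
#' @param airGap cm, >= 0.
#' @param phantom a phantom description from [boxPhantom()] or
#'   [voxelPhantomRegion()], or NULL for a phantom-free scene.
#' @return A [Scene-class].
#' @export
buildScene <- function(collimator, airGap, phantom = NULL) {
  if (airGap < 0) stop("air gap must be >= 0, got ", airGap)
  mats <- list(air = defaultMaterials()$air)
  regions <- list()
  exitZ <- 0
  if (!is.null(collimator)) {
    stopifnot(is(collimator, "CollimatorSpec"))
    exitZ <- exitPlane(collimator)
    wall <- collimator@wallMaterial
    mats[[wall@name]] <- wall
  }
  frontZ <- exitZ + airGap
  phinfo <- list(frontZ = frontZ, kind = "none")

  if (!is.null(phantom)) {
    if (identical(phantom$kind, "box")) {
      pm <- .resolveMaterial(phantom$material)
      mats[[pm@name]] <- pm
      sz <- phantom$size
      if (!is.null(phantom$walls)) {
        wm <- .resolveMaterial(phantom$walls$material)
        mats[[wm@name]] <- wm
        ft <- phantom$walls$front
        ot <- phantom$walls$other
        # interior (declared first -> higher priority than the wall shell)
        regions <- c(regions, list(list(
          type = "box", material = pm@name,
          bounds = c(-sz[1] / 2, sz[1] / 2, -sz[2] / 2, sz[2] / 2,
                     frontZ + ft, frontZ + ft + sz[3]))))
        regions <- c(regions, list(list(
          type = "box", material = wm@name,
          bounds = c(-sz[1] / 2 - ot, sz[1] / 2 + ot, -sz[2] / 2 - ot,
                     sz[2] / 2 + ot, frontZ, frontZ + ft + sz[3] + ot))))
        backZ <- frontZ + ft + sz[3] + ot
      } else {
        regions <- c(regions, list(list(
          type = "box", material = pm@name,
          bounds = c(-sz[1] / 2, sz[1] / 2, -sz[2] / 2, sz[2] / 2,
                     frontZ, frontZ + sz[3]))))
        backZ <- frontZ + sz[3]
      }
      phinfo <- list(frontZ = frontZ, kind = "box", material = pm@name,
                     size = sz, boron = phantom$boron, backZ = backZ,
                     walls = phantom$walls)
    } else if (identical(phantom$kind, "voxel")) {
      vp <- phantom$phantom
      stopifnot(is(vp, "VoxelPhantom"))
      usedMats <- unique(vp@labelMap$material)
      for (mn in usedMats) mats[[mn]] <- .resolveMaterial(mn)
      dims <- dim(vp@labels)
      regions <- c(regions, list(list(
        type = "voxel", phantom = vp,
        origin = c(vp@origin[1], vp@origin[2], frontZ),
        h = vp@voxelEdge, dims = dims)))
      phinfo <- list(frontZ = frontZ, kind = "voxel", phantom = vp,
                     backZ = frontZ + dims[3] * vp@voxelEdge)
    } else stop("unknown phantom kind: ", deparse(phantom$kind))
  } else {
    phinfo$backZ <- frontZ
  }

  if (!is.null(collimator)) {
    tp <- collimator@taperProfile
    regions <- c(regions, list(list(
      type = "cone", material = collimator@wallMaterial@name,
      z0 = 0, z1 = exitZ, outerRadius = collimator@outerRadius, knots = tp)))
  }

  rmax <- max(25, if (!is.null(collimator)) collimator@outerRadius + 20 else 0)
  world <- c(-rmax, rmax, -rmax, rmax, -10, phinfo$backZ + 30)

  sc <- new("Scene", sourcePlaneZ = 0, collimator = collimator,
            airGap = airGap, regions = regions, materials = mats,
            phantom = phinfo, worldBounds = world, engine = list())
  sc@engine <- .sceneEngine(sc)
  sc
}

# translate a Scene into the flat list consumed by the compiled engine
.sceneEngine <- function(scene) {
  mats <- scene@materials
  matNames <- names(mats)
  G <- length(mats[[1]]@sigmaAbs)
  M <- length(mats)
  st <- sa <- matrix(0, M, G)
  scm <- matrix(0, M, G * G)
  mu <- ppa <- capE <- numeric(M)
  for (i in seq_len(M)) {
    m <- mats[[i]]
    sa[i, ] <- m@sigmaAbs
    st[i, ] <- sigmaTotal(m)
    scm[i, ] <- as.vector(t(m@scatterMatrix))  # row-major: from g to g'
    mu[i] <- m@photonAttenuation
    ppa[i] <- m@capturePhoton[["yield"]]
    capE[i] <- m@capturePhoton[["energy"]]
  }
  regions <- lapply(scene@regions, function(rg) {
    if (rg$type == "box") {
      list(type = 3L, mat = match(rg$material, matNames),
           params = as.numeric(rg$bounds))
    } else if (rg$type == "cone") {
      kn <- rg$knots
      list(type = 1L, mat = match(rg$material, matNames),
           params = c(rg$z0, rg$z1, rg$outerRadius, nrow(kn),
                      as.numeric(t(kn))))
    } else if (rg$type == "cylinder") {
      list(type = 2L, mat = match(rg$material, matNames),
           params = c(rg$z0, rg$z1, rg$radius))
    } else if (rg$type == "voxel") {
      vp <- rg$phantom
      lab2mat <- match(vp@labelMap$material[order(vp@labelMap$label)],
                       matNames)
      list(type = 4L, labels = as.integer(vp@labels),
           dims = as.integer(rg$dims), origin = as.numeric(rg$origin),
           h = rg$h, lab2mat = as.integer(lab2mat))
    } else stop("unknown region type")
  })
  list(mat_st = st, mat_sa = sa, mat_sc = scm, mat_mu = mu, mat_ppa = ppa,
       mat_capE = capE, mat_names = matNames,
       air_index = match("air", matNames), world = scene@worldBounds,
       regions = regions)
}

#' Material at a point
#'
#' Total and deterministic: every finite point maps to exactly one material,
#' with air as the world fallback (also outside the world bounds).
#'
#' @param scene a [Scene-class].
#' @param point numeric(3) or an n x 3 matrix of positions (cm).
#' @return character vector of material names.
#' @export
locate <- function(scene, point) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  if (any(!is.finite(pts))) stop("coordinates must be finite")
  idx <- cpp_locate(scene@engine, pts)
  scene@engine$mat_names[idx]
}

#' Distance to the next region boundary along a ray
#'
#' @param scene a [Scene-class].
#' @param position numeric(3), cm.
#' @param direction numeric(3), must be normalised to 1 +/- 1e-9.
#' @return list with `length` (cm) and `nextMaterial` (a material name, or
#'   `"escape"` when the ray leaves the world).
#' @export
distanceToBoundary <- function(scene, position, direction) {
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9)
    stop("direction must be normalised to 1 +/- 1e-9 (|d| = ", nrm, ")")
  res <- cpp_distance(scene@engine, as.numeric(position),
                      as.numeric(direction))
  nm <- if (res$mat == 0L || !is.finite(res$dist)) "escape"
        else scene@engine$mat_names[res$mat]
  list(length = res$dist, nextMaterial = nm)
}

setMethod("show", "Scene", function(object) {
  cat("Scene:", length(object@regions), "regions;",
      if (!is.null(object@collimator)) object@collimator@kind else "no",
      "collimator; air gap", object@airGap, "cm\n")
  if (!identical(object@phantom$kind, "none"))
    cat("  phantom:", object@phantom$kind, "front at z =",
        object@phantom$frontZ, "cm (SSD", sourceToSurface(object), "cm)\n")
  cat("  materials:", paste(names(object@materials), collapse = ", "), "\n")
})
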