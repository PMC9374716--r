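#' Collimator specification
#'
#' Axisymmetric collimator wall made of LiF-loaded polyethylene. The inner
#' surface is a piecewise-linear taper (ordered knots of axial position and
#' inner radius); the outer surface is a cylinder. The standard collimator
#' tapers and then runs straight to the beam exit; the extended variants
#' taper all the way to the exit, which sits exactly 5 or 10 cm further
#' downstream.
#'
#' @slot kind one of `"standard"`, `"extended5"`, `"extended10"`.
#' @slot upstreamDiameter cm, opening abutting the moderator.
#' @slot apertureDiameter cm, beam aperture at the exit.
#' @slot extensionLength cm (0, 5 or 10).
#' @slot taperProfile matrix with columns `z`, `r`: inner-radius knots (cm).
#' @slot outerRadius cm, outer cylindrical surface of the wall.
#' @slot wallMaterial a [MaterialSpec-class].
#' @include materials.R
#' @export
setClass("CollimatorSpec",
  representation(kind = "character", upstreamDiameter = "numeric",
                 apertureDiameter = "numeric", extensionLength = "numeric",
                 taperProfile = "matrix", outerRadius = "numeric",
                 wallMaterial = "MaterialSpec"),
  validity = function(object) {
    msg <- character()
    tp <- object@taperProfile
    if (ncol(tp) != 2L) msg <- c(msg, "taperProfile needs columns z, r")
    if (any(diff(tp[, 1]) <= 0)) msg <- c(msg, "knot z must increase")
    if (any(diff(tp[, 2]) > 0))
      msg <- c(msg, "inner radius must be non-increasing along +z")
    if (abs(tp[1, 2] - object@upstreamDiameter / 2) > 1e-9)
      msg <- c(msg, "first knot radius must be upstreamDiameter/2")
    if (abs(tp[nrow(tp), 2] - object@apertureDiameter / 2) > 1e-9)
      msg <- c(msg, "last knot radius must be apertureDiameter/2")
    if (object@outerRadius <= object@upstreamDiameter / 2)
      msg <- c(msg, "outerRadius must exceed the upstream inner radius")
    if (length(msg)) msg else TRUE
  })

# axial layout of the standard collimator: 20 cm taper + 10 cm straight
# barrel (exit at z = 30 cm from the beam-shaping-assembly exit plane)
.STD_TAPER_LEN <- 20
.STD_STRAIGHT_LEN <- 10

#' Build one of the three collimator variants
#'
#' `"standard"` tapers from the upstream radius to the aperture radius over
#' 20 cm and then runs straight for 10 cm; `"extended5"` / `"extended10"`
#' taper continuously over the full length, with exit planes exactly 5 and
#' 10 cm downstream of the standard exit.
#'
#' @param kind `"standard"`, `"extended5"` or `"extended10"`.
#' @param apertureDiameter cm, default 12.
#' @param upstreamDiameter cm, default 30.
#' @param wallMaterial wall [MaterialSpec-class]; defaults to the bundled
#'   LiF-loaded polyethylene.
#' @param outerRadius cm; default upstream radius + 5.
#' @return A [CollimatorSpec-class].
#' @examples
#' std <- buildCollimator("standard")
#' exitPlane(std)                      # 30 cm
#' exitPlane(buildCollimator("extended10"))  # 40 cm
#' @export
buildCollimator <- function(kind, apertureDiameter = 12, upstreamDiameter = 30,
                            wallMaterial = NULL, outerRadius = NULL) {
  kinds <- c("standard", "extended5", "extended10")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds))
    stop("unknown collimator kind ", deparse(kind), "; valid kinds: ",
         paste(kinds, collapse = ", "))
  if (apertureDiameter <= 0 || upstreamDiameter <= 0)
    stop("diameters must be positive")
  if (apertureDiameter >= upstreamDiameter)
    stop("apertureDiameter must be smaller than upstreamDiameter")
  if (is.null(wallMaterial)) wallMaterial <- defaultMaterials()$lif_polyethylene
  if (is.null(outerRadius)) outerRadius <- upstreamDiameter / 2 + 5
  r0 <- upstreamDiameter / 2
  r1 <- apertureDiameter / 2
  ext <- switch(kind, standard = 0, extended5 = 5, extended10 = 10)
  exitZ <- .STD_TAPER_LEN + .STD_STRAIGHT_LEN + ext
  if (kind == "standard") {
    tp <- rbind(c(0, r0), c(.STD_TAPER_LEN, r1), c(exitZ, r1))
  } else {
    tp <- rbind(c(0, r0), c(exitZ, r1))  # tapered all the way to the exit
  }
  colnames(tp) <- c("z", "r")
  new("CollimatorSpec", kind = kind, upstreamDiameter = upstreamDiameter,
      apertureDiameter = apertureDiameter, extensionLength = ext,
      taperProfile = tp, outerRadius = outerRadius,
      wallMaterial = wallMaterial)
}

#' Beam-exit plane of a collimator
#'
#' @param collimator a [CollimatorSpec-class].
#' @return z position (cm) of the exit plane, measured from the
#'   beam-shaping-assembly exit plane.
#' @export
exitPlane <- function(collimator) {
  max(collimator@taperProfile[, "z"])
}

#' Inner radius of the collimator at an axial position
#'
#' @param collimator a [CollimatorSpec-class].
#' @param z axial position(s), cm.
#' @return inner radius (cm), linearly interpolated between knots.
#' @export
innerRadius <- function(collimator, z) {
  tp <- collimator@taperProfile
  approx(tp[, "z"], tp[, "r"], xout = z, rule = 2)$y
}

setMethod("show", "CollimatorSpec", function(object) {
  cat("CollimatorSpec:", object@kind,
      sprintf("(aperture %g cm, upstream %g cm, exit at z = %g cm)\n",
              object@apertureDiameter, object@upstreamDiameter,
              exitPlane(object)))
  cat("  extension:", object@extensionLength, "cm; wall:",
      object@wallMaterial@name, "\n")
})
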