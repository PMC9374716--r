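#' Multigroup material specification
#'
#' Per-group macroscopic cross sections plus composition for one material.
#' The total cross section is not stored: it is defined as
#' `sigmaAbs + rowSums(scatterMatrix)` so the partition of the total into
#' absorption and group-to-group scattering holds by construction (see
#' [sigmaTotal()]).
#'
#' @slot name material identifier.
#' @slot density g/cm^3.
#' @slot weightFractions named numeric, element mass fractions (sum to 1).
#' @slot sigmaAbs per-group macroscopic absorption cross section (cm^-1).
#' @slot scatterMatrix G x G macroscopic scattering transfer matrix (cm^-1),
#'   entry \[g, g'\] is scattering from group g into group g'.
#' @slot capturePhoton numeric, `c(energy = MeV, yield = photons per
#'   absorption)`; the 2.22 MeV hydrogen-capture line for hydrogenous media.
#' @slot photonAttenuation total photon attenuation coefficient (cm^-1) at
#'   the capture-photon energy.
#' @slot boronCapable logical, whether 10B can be assigned to this material.
#' @export
setClass("MaterialSpec",
  representation(name = "character", density = "numeric",
                 weightFractions = "numeric", sigmaAbs = "numeric",
                 scatterMatrix = "matrix", capturePhoton = "numeric",
                 photonAttenuation = "numeric", boronCapable = "logical"),
  validity = function(object) {
    msg <- character()
    G <- length(object@sigmaAbs)
    if (!all(dim(object@scatterMatrix) == c(G, G)))
      msg <- c(msg, "scatterMatrix must be G x G")
    if (any(object@sigmaAbs < 0) || any(object@scatterMatrix < 0))
      msg <- c(msg, "cross sections must be >= 0")
    if (abs(sum(object@weightFractions) - 1) > 1e-6)
      msg <- c(msg, "weight fractions must sum to 1 +/- 1e-6")
    if (G >= 2L && any(object@scatterMatrix[G, seq_len(G - 1L)] != 0))
      msg <- c(msg, "no upscatter out of the thermal group allowed")
    if (object@photonAttenuation < 0)
      msg <- c(msg, "photon attenuation must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a material
#'
#' @param name identifier.
#' @param density g/cm^3.
#' @param weightFractions named element mass fractions summing to 1.
#' @param sigmaAbs per-group absorption (cm^-1).
#' @param scatterMatrix G x G scattering transfer matrix (cm^-1).
#' @param capturePhoton `c(energy, yield)`: capture-photon energy (MeV) and
#'   photons emitted per neutron absorption.
#' @param photonAttenuation photon attenuation coefficient (cm^-1).
#' @param boronCapable can 10B be assigned to this material?
#' @return A [MaterialSpec-class] object.
#' @export
materialSpec <- function(name, density, weightFractions, sigmaAbs,
                         scatterMatrix, capturePhoton = c(energy = 2.22, yield = 0),
                         photonAttenuation = 0, boronCapable = FALSE) {
  new("MaterialSpec", name = name, density = density,
      weightFractions = weightFractions, sigmaAbs = as.numeric(sigmaAbs),
      scatterMatrix = scatterMatrix,
      capturePhoton = setNames(as.numeric(capturePhoton), c("energy", "yield")),
      photonAttenuation = photonAttenuation, boronCapable = boronCapable)
}

#' Total macroscopic cross section per group
#'
#' Defined as absorption plus the row sums of the scattering transfer
#' matrix, so `sigmaTotal(m)[g] == m@sigmaAbs[g] + sum(m@scatterMatrix[g, ])`
#' holds exactly for every group.
#'
#' @param material a [MaterialSpec-class].
#' @return numeric vector, cm^-1 per group.
#' @export
sigmaTotal <- function(material) {
  material@sigmaAbs + rowSums(material@scatterMatrix)
}

#' Element mass fraction accessor
#'
#' @param material a [MaterialSpec-class].
#' @param element element symbol, e.g. `"H"` or `"N"`.
#' @return mass fraction (0 if the element is absent).
#' @export
weightFraction <- function(material, element) {
  wf <- unname(material@weightFractions[element])
  wf[is.na(wf)] <- 0
  wf
}

setMethod("show", "MaterialSpec", function(object) {
  cat("MaterialSpec:", object@name, sprintf("(%.4g g/cm^3)\n", object@density))
  cat("  sigma_abs  :", signif(object@sigmaAbs, 3), "cm^-1\n")
  cat("  sigma_total:", signif(sigmaTotal(object), 3), "cm^-1\n")
  cat("  capture photon:", object@capturePhoton[["energy"]], "MeV, yield",
      object@capturePhoton[["yield"]], "\n")
})

#' Load a material library from YAML
#'
#' Reads a versioned multigroup cross-section file (see
#' `inst/extdata/materials_default.yaml` for the schema) into a named list of
#' [MaterialSpec-class] objects.
#'
#' @param file path to a YAML material library.
#' @return named list of materials, with attributes `version` and
#'   `groupLabels`.
#' @export
materialLibrary <- function(file = system.file("extdata",
                                               "materials_default.yaml",
                                               package = "bnctbeam")) {
  raw <- yaml::read_yaml(file)
  mats <- lapply(names(raw$materials), function(nm) {
    m <- raw$materials[[nm]]
    materialSpec(
      name = nm, density = m$density,
      weightFractions = unlist(m$weight_fractions),
      sigmaAbs = unlist(m$sigma_abs),
      scatterMatrix = do.call(rbind, m$scatter_matrix),
      capturePhoton = c(energy = m$capture_photon$energy,
                        yield = m$capture_photon$yield),
      photonAttenuation = m$photon_attenuation,
      boronCapable = isTRUE(m$boron_capable))
  })
  names(mats) <- names(raw$materials)
  attr(mats, "version") <- raw$version
  attr(mats, "groupLabels") <- unlist(raw$group_labels)
  mats
}

#' Bundled default materials
#'
#' Cached copy of the bundled three-group library: water, tissue
#' (H/C/N/O mass fractions 0.10/0.10/0.03/0.77), air, LiF-loaded
#' polyethylene (collimator wall) and acrylic (phantom walls).
#'
#' @return named list of [MaterialSpec-class] objects.
#' @export
defaultMaterials <- function() {
  if (is.null(.bnct_cache$materials))
    .bnct_cache$materials <- materialLibrary()
  .bnct_cache$materials
}
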