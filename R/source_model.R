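#' Neutron/photon source model
#'
#' Disk source at the beam-shaping-assembly exit plane (z = 0), emitting
#' into the +z half-space with a forward-peaked cos^n(theta) angular
#' distribution. A small fraction of primaries are beam-contamination
#' photons.
#'
#' @slot diskRadius cm.
#' @slot angularExponent n of the cos^n(theta) distribution.
#' @slot groupSpectrum per-group emission probabilities (sums to 1).
#' @slot photonFraction fraction of primaries that are photons, in \[0, 1\].
#' @slot photonEnergy energy of primary photons (MeV).
#' @slot intensity source particles per second.
#' @export
setClass("SourceModel",
  representation(diskRadius = "numeric", angularExponent = "numeric",
                 groupSpectrum = "numeric", photonFraction = "numeric",
                 photonEnergy = "numeric", intensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (abs(sum(object@groupSpectrum) - 1) > 1e-9)
      msg <- c(msg, "groupSpectrum must sum to 1")
    if (any(object@groupSpectrum < 0)) msg <- c(msg, "spectrum entries >= 0")
    if (object@photonFraction < 0 || object@photonFraction > 1)
      msg <- c(msg, "photonFraction must be in [0, 1]")
    if (object@intensity <= 0) msg <- c(msg, "intensity must be > 0")
    if (object@diskRadius < 0) msg <- c(msg, "diskRadius must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a source model
#'
#' @param diskRadius source disk radius, cm.
#' @param angularExponent forward-peaking exponent n of cos^n(theta).
#' @param groupSpectrum per-group emission probabilities (fast, epithermal,
#'   thermal), summing to 1.
#' @param photonFraction fraction of primaries emitted as photons.
#' @param photonEnergy primary photon energy, MeV.
#' @param intensity source particles per second.
#' @return A [SourceModel-class].
#' @export
sourceModel <- function(diskRadius = 7.5, angularExponent = 5,
                        groupSpectrum = c(0.03, 0.95, 0.02),
                        photonFraction = 0.01, photonEnergy = 2.22,
                        intensity = 1e12) {
  new("SourceModel", diskRadius = diskRadius,
      angularExponent = angularExponent,
      groupSpectrum = as.numeric(groupSpectrum),
      photonFraction = photonFraction, photonEnergy = photonEnergy,
      intensity = intensity)
}

#' Default epithermal-dominant synthetic beam
#'
#' Stand-in for an unpublished accelerator beam model: epithermal-dominant
#' spectrum (fast, epithermal, thermal) = (0.03, 0.95, 0.02), 7.5 cm disk
#' radius, cos^5(theta) forward peaking, 1% photon contamination, 1e12
#' source particles per second. All values are synthetic defaults.
#'
#' @return A [SourceModel-class].
#' @export
defaultSource <- function() sourceModel()

.sourceEngine <- function(source) {
  list(diskRadius = source@diskRadius, angularExponent = source@angularExponent,
       groupSpectrum = source@groupSpectrum,
       photonFraction = source@photonFraction,
       photonEnergy = source@photonEnergy)
}

#' Sample primary particles from a source
#'
#' Positions are uniform on the source disk at z = 0; directions follow
#' cos^n(theta) about +z; neutron groups are drawn from the group spectrum.
#' Uses the engine's own seeded generator (xoshiro256++), so a given seed
#' reproduces the same particles bit-identically.
#'
#' @param source a [SourceModel-class].
#' @param n number of particles.
#' @param seed integer seed.
#' @return data.frame with columns species ("neutron"/"photon"), x, y, z,
#'   ux, uy, uz, group (1-based index; NA for photons), energy (MeV) and
#'   weight (always 1).
#' @export
sampleSource <- function(source, n, seed = 1L) {
  stopifnot(is(source, "SourceModel"), n >= 1)
  m <- cpp_sample_source(.sourceEngine(source), as.integer(n), as.double(seed))
  data.frame(species = ifelse(m[, 1] == 0, "neutron", "photon"),
             x = m[, 2], y = m[, 3], z = m[, 4],
             ux = m[, 5], uy = m[, 6], uz = m[, 7],
             group = m[, 8], energy = m[, 9], weight = 1)
}

setMethod("show", "SourceModel", function(object) {
  cat("SourceModel: disk radius", object@diskRadius, "cm, cos^",
      object@angularExponent, "(theta)\n", sep = "")
  cat("  spectrum (fast, epithermal, thermal):",
      paste(object@groupSpectrum, collapse = ", "), "\n")
  cat("  photon fraction:", object@photonFraction, "; intensity:",
      format(object@intensity, scientific = TRUE), "/s\n")
})
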