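#' Flux-to-dose (KERMA) conversion factors
#'
#' Converts per-group neutron fluence and photon energy fluence into the
#' four BNCT dose components. The boron and nitrogen factors come from
#' 1/v thermal capture and are therefore concentrated in the thermal group;
#' the hydrogen factor represents fast/epithermal elastic recoil.
#'
#' @slot boronFactor Gy cm^2 per (ug/g 10B), per group.
#' @slot nitrogenFactor Gy cm^2 per unit nitrogen mass fraction, per group.
#' @slot hydrogenFactor Gy cm^2 per unit hydrogen mass fraction, per group.
#' @slot photonFactor Gy cm^2 per MeV of photon energy fluence.
#' @slot version version of the factor file.
#' @export
setClass("KermaSet",
  representation(boronFactor = "numeric", nitrogenFactor = "numeric",
                 hydrogenFactor = "numeric", photonFactor = "numeric",
                 version = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(c(object@boronFactor, object@nitrogenFactor,
              object@hydrogenFactor, object@photonFactor) < 0))
      msg <- c(msg, "all factors must be >= 0")
    G <- length(object@boronFactor)
    if (sum(object@boronFactor) > 0 && which.max(object@boronFactor) != G)
      msg <- c(msg, "boron factor must be concentrated in the thermal group")
    if (sum(object@nitrogenFactor) > 0 &&
        which.max(object@nitrogenFactor) != G)
      msg <- c(msg, "nitrogen factor must be concentrated in the thermal group")
    if (length(msg)) msg else TRUE
  })

#' Load a KERMA factor set from YAML
#'
#' @param file YAML file; defaults to the bundled versioned set.
#' @return A [KermaSet-class].
#' @export
kermaSet <- function(file = system.file("extdata", "kerma_default.yaml",
                                        package = "bnctbeam")) {
  raw <- yaml::read_yaml(file)
  new("KermaSet", boronFactor = unlist(raw$boron_factor),
      nitrogenFactor = unlist(raw$nitrogen_factor),
      hydrogenFactor = unlist(raw$hydrogen_factor),
      photonFactor = raw$photon_factor, version = raw$version)
}

#' Bundled default KERMA factors
#' @return cached [KermaSet-class].
#' @export
defaultKerma <- function() {
  if (is.null(.bnct_cache$kerma)) .bnct_cache$kerma <- kermaSet()
  .bnct_cache$kerma
}

#' CBE/RBE weighting parameters per tissue
#'
#' The biologically weighted dose (Gy_w) of a tissue is
#' `CBE * D_B + RBE_N * D_N + RBE_H * D_H + RBE_gamma * D_gamma`, and the
#' tissue 10B concentration is `tissueToBlood` times the blood
#' concentration.
#'
#' @slot table data.frame with rownames = tissue names and columns CBE,
#'   RBE_N, RBE_H, RBE_gamma, tissueToBlood.
#' @export
setClass("WeightingParams",
  representation(table = "data.frame"),
  validity = function(object) {
    tb <- object@table
    need <- c("CBE", "RBE_N", "RBE_H", "RBE_gamma", "tissueToBlood")
    if (!all(need %in% colnames(tb))) return("missing weighting columns")
    if (any(as.matrix(tb[need]) < 0)) return("all entries must be >= 0")
    if ("air" %in% rownames(tb) && any(tb["air", need] != 0))
      return("air row must be all zeros")
    TRUE
  })

#' Default weighting table
#'
#' The standard fixed RBE/CBE table for BPA-based head-and-neck BNCT:
#' tumour (CBE 3.8, tissue-to-blood 3.5), skin (CBE 2.5), bone (1),
#' brain and soft tissue (1.34), water (CBE 1, RBE_N 0) and air (all
#' zeros); RBE_N = 2.9 and RBE_H = 2.4 for tissues, RBE_gamma = 1.
#' The mucosal membrane has no separate published CBE here, so the mucosa
#' row defaults to the soft-tissue values (CBE 1.34) and can be overridden.
#'
#' @param mucosaCBE CBE assigned to the mucosa row (default: soft tissue's
#'   1.34).
#' @return A [WeightingParams-class].
#' @export
defaultWeightingParams <- function(mucosaCBE = 1.34) {
  tb <- data.frame(
    CBE           = c(3.8, 2.5, 1.0, 1.34, 1.34, 1.0, 0.0, mucosaCBE),
    RBE_N         = c(2.9, 2.9, 2.9, 2.9, 2.9, 0.0, 0.0, 2.9),
    RBE_H         = c(2.4, 2.4, 2.4, 2.4, 2.4, 2.4, 0.0, 2.4),
    RBE_gamma     = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 0.0, 1.0),
    tissueToBlood = c(3.5, 1.0, 1.0, 1.0, 1.0, 1.0, 0.0, 1.0),
    row.names = c("tumour", "skin", "bone", "brain", "soft tissue",
                  "water", "air", "mucosa"))
  new("WeightingParams", table = tb)
}

#' Tissues known to a weighting table
#' @param params a [WeightingParams-class].
#' @return character vector of tissue names.
#' @export
tissues <- function(params) rownames(params@table)

.tissueRow <- function(params, tissue) {
  if (!all(tissue %in% tissues(params)))
    stop("unknown tissue ", paste(setdiff(tissue, tissues(params)),
                                  collapse = ", "),
         "; known tissues: ", paste(tissues(params), collapse = ", "))
  params@table[tissue, , drop = FALSE]
}

setMethod("show", "WeightingParams", function(object) {
  cat("WeightingParams (", nrow(object@table), " tissues)\n", sep = "")
  print(object@table)
})

#' Tissue boron concentration from blood concentration
#'
#' Applies the tissue-to-blood ratio (3.5 for tumour with BPA, 1 for most
#' healthy tissues, 0 for air).
#'
#' @param tissue tissue name(s).
#' @param bloodConcentration blood 10B concentration, ug/g (default 25).
#' @param params a [WeightingParams-class].
#' @return 10B concentration(s) in ug/g.
#' @examples
#' boronConcentration("tumour", 25)   # 87.5
#' @export
boronConcentration <- function(tissue, bloodConcentration = 25,
                               params = defaultWeightingParams()) {
  if (any(bloodConcentration < 0)) stop("blood concentration must be >= 0")
  .tissueRow(params, tissue)$tissueToBlood * bloodConcentration
}

#' Physical dose components from group fluence
#'
#' The four-way split of the physical dose: boron 10B(n,alpha)7Li, nitrogen
#' 14N(n,p)14C, hydrogen 1H(n,n')p recoil, and the gamma-ray dose from the
#' photon energy fluence. Components are reported separately and sum to the
#' total physical dose.
#'
#' @param flux per-group neutron fluence: numeric of length G, or a G x N
#'   matrix for N locations (cm^-2 per source particle).
#' @param material a [MaterialSpec-class] (supplies the nitrogen and
#'   hydrogen mass fractions).
#' @param boron 10B concentration, ug/g (scalar or length N).
#' @param kerma a [KermaSet-class].
#' @param photonEnergyFluence photon energy fluence (MeV cm^-2), scalar or
#'   length N.
#' @return list of class `doseComponents` with elements boron, nitrogen,
#'   hydrogen, gamma (Gy per source particle).
#' @export
physicalDose <- function(flux, material, boron = 0, kerma = defaultKerma(),
                         photonEnergyFluence = 0) {
  flux <- if (is.matrix(flux)) flux else matrix(flux, ncol = 1)
  if (any(flux < 0)) stop("flux must be >= 0")
  wN <- weightFraction(material, "N")
  wH <- weightFraction(material, "H")
  comp <- list(
    boron = as.numeric(colSums(flux * kerma@boronFactor)) * boron,
    nitrogen = as.numeric(colSums(flux * kerma@nitrogenFactor)) * wN,
    hydrogen = as.numeric(colSums(flux * kerma@hydrogenFactor)) * wH,
    gamma = as.numeric(photonEnergyFluence) * kerma@photonFactor)
  structure(comp, class = "doseComponents")
}

#' Construct dose components directly
#' @param boron,nitrogen,hydrogen,gamma component doses (Gy).
#' @return list of class `doseComponents`.
#' @export
doseComponents <- function(boron = 0, nitrogen = 0, hydrogen = 0, gamma = 0) {
  structure(list(boron = boron, nitrogen = nitrogen, hydrogen = hydrogen,
                 gamma = gamma), class = "doseComponents")
}

#' Total physical dose of a component split
#' @param components a `doseComponents` list.
#' @return total dose (Gy), the sum of the four components.
#' @export
totalDose <- function(components) {
  components$boron + components$nitrogen + components$hydrogen +
    components$gamma
}

#' Biologically weighted dose (Gy_w)
#'
#' `CBE * D_B + RBE_N * D_N + RBE_H * D_H + RBE_gamma * D_gamma` with the
#' weights of the given tissue row. Linear in every component.
#'
#' @param components a `doseComponents` list (elements may be vectors).
#' @param tissue tissue name.
#' @param params a [WeightingParams-class].
#' @return weighted dose in Gy_w.
#' @examples
#' weightedDose(doseComponents(1, 1, 1, 1), "tumour")  # 10.1
#' weightedDose(doseComponents(1, 0, 0, 0), "skin")    # 2.5
#' @export
weightedDose <- function(components, tissue,
                         params = defaultWeightingParams()) {
  w <- .tissueRow(params, tissue)
  w$CBE * components$boron + w$RBE_N * components$nitrogen +
    w$RBE_H * components$hydrogen + w$RBE_gamma * components$gamma
}

#' Dose prescription
#'
#' @param tissue prescription tissue (default mucosa).
#' @param statistic prescription statistic; only "maximum" is supported.
#' @param dose prescription dose in Gy_w (default 12).
#' @return list of class `prescription`.
#' @export
prescriptionSpec <- function(tissue = "mucosa", statistic = "maximum",
                             dose = 12) {
  stopifnot(identical(statistic, "maximum"))
  if (dose <= 0) stop("prescription dose must be > 0")
  structure(list(tissue = tissue, statistic = statistic, dose = dose),
            class = "prescription")
}

#' Irradiation time to reach a prescription
#'
#' Time (minutes) needed for the maximum weighted dose rate over the
#' prescription mask to accumulate the prescription dose:
#' `time = dose / max(rate)`. The returned scaling factor converts the rate
#' grid to total delivered dose (`scaling * rate == delivered dose`, with
#' the mask maximum equal to the prescription exactly).
#'
#' @param rate weighted dose-rate grid in Gy_w per minute (any shape).
#' @param mask logical mask of prescription-tissue bins (default: all).
#' @param prescription a `prescription` from [prescriptionSpec()].
#' @return list with `minutes` and `scaling` (minutes, = dose / max rate).
#' @export
irradiationTime <- function(rate, mask = NULL,
                            prescription = prescriptionSpec()) {
  if (is.null(mask)) mask <- rep(TRUE, length(rate))
  vals <- rate[mask]
  if (!length(vals)) stop("prescription mask is empty")
  mx <- max(vals)
  if (!is.finite(mx) || mx <= 0)
    stop("prescription unreachable: all dose rates are zero in the mask")
  minutes <- prescription$dose / mx
  list(minutes = minutes, scaling = minutes)
}

#' Voxel-phantom treatment-plan dose
#'
#' Converts a voxel tally into per-voxel physical dose components and
#' biologically weighted dose, then normalises the plan so that the maximum
#' weighted dose over the prescription tissue equals the prescription dose
#' (12 Gy_w to the mucosa by default). Also reports the irradiation time
#' implied by the source intensity.
#'
#' @param scene a [Scene-class] holding a voxel phantom.
#' @param tally the voxel [TallyGrid-class] from [runTransport()] (aligned
#'   with the phantom grid).
#' @param params a [WeightingParams-class].
#' @param kerma a [KermaSet-class].
#' @param prescription a `prescription`.
#' @param intensity source particles per second (defaults to the source
#'   model's 1e12).
#' @param bloodBoron blood 10B concentration, ug/g.
#' @return list: `weighted` (Gy_w array, prescription-normalised),
#'   `components` (list of Gy arrays), `perParticle` (weighted Gy_w per
#'   source particle), `minutes` (irradiation time), `particles` (total
#'   source particles delivered), `prescription`.
#' @export
planDose <- function(scene, tally, params = defaultWeightingParams(),
                     kerma = defaultKerma(),
                     prescription = prescriptionSpec(), intensity = 1e12,
                     bloodBoron = 25) {
  if (!identical(scene@phantom$kind, "voxel"))
    stop("planDose needs a scene with a voxel phantom")
  vp <- scene@phantom$phantom
  lm <- vp@labelMap
  labs <- as.integer(vp@labels)
  lab2row <- match(sort(unique(labs)), lm$label)
  if (anyNA(lab2row))
    stop("voxel label(s) without tissue mapping: ",
         paste(setdiff(unique(labs), lm$label), collapse = ", "))
  tissue <- lm$tissue[match(labs, lm$label)]
  matName <- lm$material[match(labs, lm$label)]
  bad <- !(tissue %in% tissues(params))
  if (any(bad))
    stop("voxel label(s) map to unknown tissue: ",
         paste(unique(tissue[bad]), collapse = ", "))
  dims <- dim(vp@labels)
  N <- length(labs)
  G <- length(tally@groupLabels)
  flux <- t(matrix(tally@flux, nrow = N, ncol = G))  # G x N
  pflu <- as.numeric(tally@photonFluence)
  boron <- boronConcentration(tissue, bloodBoron, params)

  # component doses per voxel; hydrogen/nitrogen fractions follow the voxel
  # material (air voxels carry zero mass fractions of N and H)
  wN <- vapply(names(scene@materials), function(nm)
    weightFraction(scene@materials[[nm]], "N"), numeric(1))
  wH <- vapply(names(scene@materials), function(nm)
    weightFraction(scene@materials[[nm]], "H"), numeric(1))
  comp <- list(
    boron = as.numeric(colSums(flux * kerma@boronFactor)) * boron,
    nitrogen = as.numeric(colSums(flux * kerma@nitrogenFactor)) *
      unname(wN[matName]),
    hydrogen = as.numeric(colSums(flux * kerma@hydrogenFactor)) *
      unname(wH[matName]),
    gamma = pflu * kerma@photonFactor)
  class(comp) <- "doseComponents"
  w <- params@table[tissue, ]
  weighted_pp <- w$CBE * comp$boron + w$RBE_N * comp$nitrogen +
    w$RBE_H * comp$hydrogen + w$RBE_gamma * comp$gamma

  presMask <- tissue == prescription$tissue
  if (!any(presMask))
    stop("no voxels of prescription tissue '", prescription$tissue, "'")
  mx <- max(weighted_pp[presMask])
  if (mx <= 0)
    stop("prescription unreachable: all-zero weighted dose in '",
         prescription$tissue, "' voxels")
  particles <- prescription$dose / mx
  minutes <- particles / intensity / 60

  shape <- function(v) array(v, dim = dims)
  list(weighted = shape(weighted_pp * particles),
       components = lapply(comp, function(v) shape(v * particles)),
       perParticle = shape(weighted_pp),
       minutes = minutes, particles = particles,
       prescription = prescription)
}
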