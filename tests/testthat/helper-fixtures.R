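# Shared fixtures, all built in code.

# homogeneous pure-absorber slab of optical thickness sigma * d on the beam
# axis, with a pencil beam source: transmitted fraction has the analytic
# value exp(-sigma * d)
absorberSlabScene <- function(sigma, thickness) {
  m <- materialSpec("absorber", 1, c(X = 1), sigmaAbs = rep(sigma, 3),
                    scatterMatrix = matrix(0, 3, 3), photonAttenuation = 0)
  buildScene(NULL, 1, boxPhantom(m, c(60, 60, thickness)))
}

# true vacuum (all cross sections zero)
vacuumScene <- function() {
  m <- materialSpec("vacuum", 1e-12, c(X = 1), sigmaAbs = rep(0, 3),
                    scatterMatrix = matrix(0, 3, 3), photonAttenuation = 0)
  buildScene(NULL, 0, boxPhantom(m, c(40, 40, 20)))
}

# on-axis pencil beam of epithermal neutrons
pencilSource <- function() {
  sourceModel(diskRadius = 0, angularExponent = 1e9,
              groupSpectrum = c(0, 1, 0), photonFraction = 0)
}

# a small hand-built voxel phantom: air shell around a tissue cube holding a
# tumour sphere and a mucosa shell, for dosimetry/DVH tests
tinyVoxelPhantom <- function(n = 12, h = 0.5) {
  lm <- data.frame(label = 1:4,
                   organ = c("air", "body", "mucosa", "tumour"),
                   tissue = c("air", "soft tissue", "mucosa", "tumour"),
                   material = c("air", "tissue", "tissue", "tissue"))
  labels <- array(1L, dim = c(n, n, n))
  labels[3:(n - 2), 3:(n - 2), 3:(n - 2)] <- 2L
  labels[3:(n - 2), 3:(n - 2), 3] <- 3L             # mucosa at the front
  mid <- as.integer(n / 2)
  labels[mid + (-1:1), mid + (-1:1), mid + (-1:1)] <- 4L
  new("VoxelPhantom", labels = labels, voxelEdge = h,
      origin = c(-n * h / 2, -n * h / 2), labelMap = lm,
      boronPerLabel = setNames(boronConcentration(lm$tissue, 25),
                               as.character(lm$label)))
}

# TallyGrid with prescribed uniform values on a voxel mesh
uniformVoxelTally <- function(dims, flux = c(0, 0, 1e-3), photon = 1e-3,
                              h = 0.5, origin = c(0, 0, 0)) {
  fl <- array(rep(flux, each = prod(dims)), dim = c(dims, 3))
  new("TallyGrid", type = "voxel",
      mesh = list(origin = origin, h = h, dims = dims), flux = fl,
      photonFluence = array(photon, dim = dims),
      relErr = array(0.01, dim = c(dims, 3)),
      relErrPhoton = array(0.01, dim = dims), nHistories = 1e5,
      groupLabels = c("fast", "epithermal", "thermal"))
}

# TallyGrid with prescribed values on a cylindrical mesh
cylTallyGrid <- function(values, dz = 0.5, dr = 0.5) {
  nr <- nrow(values); nz <- ncol(values)
  fl <- array(0, dim = c(nr, nz, 3))
  fl[, , 3] <- values
  new("TallyGrid", type = "cylindrical",
      mesh = list(rEdges = seq(0, nr * dr, by = dr),
                  zEdges = seq(0, nz * dz, by = dz),
                  rCenters = (seq_len(nr) - 0.5) * dr,
                  zCenters = (seq_len(nz) - 0.5) * dz),
      flux = fl, photonFluence = array(0, dim = c(nr, nz)),
      relErr = array(0, dim = c(nr, nz, 3)),
      relErrPhoton = array(0, dim = c(nr, nz)), nHistories = 1e5,
      groupLabels = c("fast", "epithermal", "thermal"))
}

# brute-force D_x oracle: largest candidate dose d with
# fraction(doses >= d) >= x/100
bruteDx <- function(doses, x) {
  cand <- sort(unique(doses), decreasing = TRUE)
  keep <- vapply(cand, function(d) mean(doses >= d) >= x / 100, logical(1))
  cand[keep][1]
}
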