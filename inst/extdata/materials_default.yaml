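# Default three-group macroscopic cross-section library, version 1.
#
# Group order: fast (10 keV - 10 MeV), epithermal (0.5 eV - 10 keV),
# thermal (< 0.5 eV; below the cadmium cutoff).
#
# These are order-of-magnitude multigroup constants assembled from standard
# 2200 m/s thermal values and coarse group averages for H, C, N, O, 6Li and F
# at the stated densities. They are deliberately simple, fully configurable
# defaults for a qualitative collimation study, not an evaluated library.
# Units: cm^-1 for all macroscopic cross sections; g/cm^3 for density;
# MeV for photon energies; photon_attenuation is the total attenuation
# coefficient at the 2.22 MeV hydrogen-capture line.
version: 1
group_labels: [fast, epithermal, thermal]
materials:
  water:
    density: 1.0
    weight_fractions: {"H": 0.112, "O": 0.888}
    sigma_abs: [1.0e-4, 6.0e-4, 0.0222]
    scatter_matrix:        # rows: from-group; columns: to-group
      - [0.42, 0.18, 0.0]
      - [0.0,  1.38, 0.12]
      - [0.0,  0.0,  3.45]
    capture_photon: {energy: 2.22, yield: 1.0}
    photon_attenuation: 0.0455
    boron_capable: false
  tissue:
    # ICRU-like soft tissue of the cubic-phantom study:
    # H/C/N/O weight fractions 0.1/0.1/0.03/0.77, density 1 g/cm^3.
    density: 1.0
    weight_fractions: {"H": 0.10, "C": 0.10, "N": 0.03, "O": 0.77}
    sigma_abs: [1.0e-4, 5.5e-4, 0.0224]
    scatter_matrix:
      - [0.38, 0.16, 0.0]
      - [0.0,  1.24, 0.105]
      - [0.0,  0.0,  3.10]
    capture_photon: {energy: 2.22, yield: 0.89}   # H share of thermal absorption
    photon_attenuation: 0.0455
    boron_capable: true
  air:
    density: 1.205e-3
    weight_fractions: {"N": 0.755, "O": 0.232, "Ar": 0.013}
    sigma_abs: [1.0e-8, 5.0e-8, 4.0e-6]
    scatter_matrix:
      - [3.0e-5, 5.0e-6, 0.0]
      - [0.0,    4.0e-5, 2.0e-6]
      - [0.0,    0.0,    1.0e-4]
    capture_photon: {energy: 2.22, yield: 0.0}
    photon_attenuation: 5.5e-5
    boron_capable: false
  lif_polyethylene:
    # Collimator wall: polyethylene loaded with natural LiF, 30% LiF by mass
    # (loading fraction is a documented assumption; the 6Li 940 b thermal
    # capture dominates thermal absorption).
    density: 1.2
    weight_fractions: {"H": 0.1, "C": 0.6, "Li": 0.08, "F": 0.22}
    sigma_abs: [2.0e-4, 0.03, 0.60]
    scatter_matrix:
      - [0.45, 0.20, 0.0]
      - [0.0,  1.60, 0.15]
      - [0.0,  0.0,  3.00]
    capture_photon: {energy: 2.22, yield: 0.04}   # Li/F captures emit no transported photon
    photon_attenuation: 0.052
    boron_capable: false
  acrylic:
    # PMMA phantom walls.
    density: 1.19
    weight_fractions: {"H": 0.0805, "C": 0.5998, "O": 0.3197}
    sigma_abs: [1.0e-4, 5.0e-4, 0.0185]
    scatter_matrix:
      - [0.40, 0.15, 0.0]
      - [0.0,  1.25, 0.09]
      - [0.0,  0.0,  2.60]
    capture_photon: {energy: 2.22, yield: 1.0}
    photon_attenuation: 0.049
    boron_capable: false
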