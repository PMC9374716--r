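---
title: "Models and methods behind bnctbeam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bnctbeam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bnctbeam` studies how collimator geometry and patient--collimator air gaps
shape an epithermal neutron beam for BNCT of the head and neck. This
vignette documents the models, the tunable parameters and their defaults,
the numerical choices, and the limits of what the synthetic setup can show.

## The transport model

Neutrons are transported in three energy groups — fast (10 keV--10 MeV),
epithermal (0.5 eV--10 keV) and thermal (below 0.5 eV). The 0.5 eV split is
the cadmium cutoff, chosen so that the simulated thermal/epithermal
separation corresponds to the bare-versus-cadmium-covered foil technique;
10 keV is the conventional epithermal/fast boundary in BNCT beam
characterisation. The group structure is a deliberate simplification: the
engine is meant to reproduce the *mechanisms* of collimation (divergence,
wall scattering and absorption, in-phantom moderation) at desk scale, not
library-grade spectra.

Within a history:

* free-flight lengths are sampled as $-\ln\xi/\Sigma_t$ of the local
  material;
* at a collision, the neutron is absorbed with probability
  $\Sigma_a/\Sigma_t$ (analog capture — implicit capture is off, so
  statistical weights stay at 1 and the Russian-roulette terms of the
  weight balance are exactly zero in default runs), otherwise it scatters;
* scattering is isotropic in the laboratory frame, with the outgoing group
  drawn from the material's group-transfer matrix; there is no upscatter
  out of the thermal group;
* absorption in hydrogenous media emits one 2.22 MeV capture photon with a
  per-material yield equal to hydrogen's share of thermal absorption
  (water 1.0, tissue 0.89, LiF-polyethylene 0.04 — ⁶Li and ¹⁰B captures
  emit no transported photon, the 478 keV boron line being folded into the
  local boron KERMA);
* photons travel in straight lines with exponential attenuation and die at
  their first collision. Gamma dose is estimated from the track-length
  photon *energy fluence* times a tissue energy-absorption factor, so the
  missing Compton build-up mainly affects the depth of the gamma maximum,
  not its order of magnitude.

Every run records a weight balance — emitted + secondary = absorbed +
escaped + roulette net — which the test suite asserts to 10⁻⁹ relative on
every scene.

The random-number generator is xoshiro256++ seeded through splitmix64,
owned by the engine itself. Identical (seed, configuration, scene) inputs
give bit-identical tallies regardless of the R session's RNG state, and the
seed is written into every run summary and manifest.

## Cross sections and flux-to-dose factors

The multigroup constants live in versioned YAML files under
`inst/extdata/` and are fully configurable. They are order-of-magnitude
values assembled from standard 2200 m/s cross sections and coarse group
averages for H, C, N, O, ⁶Li and F: e.g. water's thermal absorption
0.0222 cm⁻¹ comes from the 0.332 b hydrogen capture; the collimator wall
(polyethylene loaded with 30% natural LiF by mass — the loading fraction is
an assumption, exposed as a material parameter) takes its 0.60 cm⁻¹
thermal absorption from the 940 b ⁶Li capture. The epithermal→thermal
transfer entries were set so that water moderation produces the familiar
sub-surface thermal maximum at ~2 cm depth.

KERMA factors convert group fluence to the four dose components:
8.66×10⁻¹⁴ Gy·cm² per µg/g ¹⁰B (σ = 3837 b, Q = 2.34 MeV),
7.9×10⁻¹² Gy·cm² per unit nitrogen mass fraction (σ = 1.83 b,
Q = 0.626 MeV), a fast-group hydrogen recoil factor of
2.0×10⁻¹⁰ Gy·cm² per unit hydrogen fraction, and
4.2×10⁻¹³ Gy·cm² per MeV of photon energy fluence (µ_en/ρ of soft tissue
near 2.2 MeV). The 1/v capture factors are concentrated in the thermal
group by construction, and `physicalDose()` reports the four components
separately so their sum always reconstructs the total physical dose.

At 25 µg/g, ¹⁰B adds ~6×10⁻³ cm⁻¹ of thermal absorption — a quarter of the
tissue's own — so boron is treated as a dosimetric perturbation (it enters
the flux-to-dose conversion, not the transport cross sections).

## Weighted dose, prescription and irradiation time

`weightedDose()` applies the fixed CBE/RBE table: tumour CBE 3.8 and
tissue-to-blood ratio 3.5, skin 2.5, bone 1, brain and soft tissue 1.34,
water (CBE 1, RBE_N 0), air all zeros; RBE_N = 2.9, RBE_H = 2.4,
RBE_γ = 1 elsewhere. The mucosal membrane — the prescription tissue — has
no separate published CBE in this table, so the mucosa row defaults to the
soft-tissue values (CBE 1.34) and is exposed as a parameter
(`defaultWeightingParams(mucosaCBE = …)`) rather than guessed; whether a
mucosa-specific CBE should differ is left to the user.

Plans are normalised so the *maximum* weighted dose over the prescription
tissue equals 12 Gy_w, and the irradiation time is that normalisation
divided by the source intensity. The intensity default, 10¹² source
particles per second, is a free synthetic parameter (the relation between
a real accelerator's integrated proton charge and the neutron source
strength is not derivable here); it was chosen once so that desk-scale
mucosal irradiation times land in the tens of minutes typical of
accelerator BNCT, and it cancels from every between-collimator ratio.

## Geometry

The scene is axisymmetric about the beam axis z, with the origin at the
beam-shaping-assembly exit plane. The collimator wall is a piecewise-linear
taper inside an outer cylinder: all variants open at 30 cm diameter and
close to a 12 cm aperture. The printed record of the wall profile is only
graphical, so the axial layout is a documented choice: the standard
collimator tapers over 20 cm and then runs straight for 10 cm (exit at
z = 30 cm, "tapered then straightened"), while the 5/10 cm extended
variants taper continuously to exits at exactly 35/40 cm. The taper knots
are constructor arguments, so other profiles can be swapped in.

Region lookup is first-match in declared order with the voxel phantom
first, then phantom walls, then the collimator, with air as the world
fallback; `locate()` is total and deterministic, and `distanceToBoundary()`
is cross-validated against ray marching in the test suite. Boundary
crossings nudge the particle 10⁻⁷ cm past the surface to avoid sticking.

## Tallies and errors

Flux uses track-length estimators on uniform cylindrical (r, z) or voxel
meshes. Segments are deposited by sub-segment chopping at half the smallest
bin dimension — a deliberate trade of a tiny geometric misassignment for
robustness over exact analytic bin-crossing; the spherical scan tallies use
exact chord lengths. Transmission oracles in the tests rely on the
engine's termination record, not on tallies, so the two are independently
validated.

Relative errors are batch-based (default 20 batches): the standard error of
the batch means over the grand mean, per bin, with zero-mean bins flagged
NA. The test suite checks both the closed-form case and that the estimate
agrees with the spread of independent-seed replicates within 1.5×. Note
that extreme statistics *of* noisy grids (the maximum over a voxel organ,
the peak of a depth curve) inherit more variance than any single bin;
plan-level quantities are therefore run at 4×10⁵ histories in the
reproduction script, and sweep rows share one seed (common random numbers)
so between-row differences are not dominated by independent noise.

## Beam metrics: conventions and tie-breaks

* **Advantage depth** — the depth where the tumour weighted-dose curve
  first falls to the *peak* of the healthy-tissue curve. Curves are
  linearly interpolated on the union grid of their overlap; the search
  starts at the healthy peak (first crossing beyond the peak), so identical
  curves return the peak depth, and a tumour curve that never reaches the
  healthy peak returns a no-crossing flag instead of a number.
* **Isodose widths** — relative to the profile's own maximum at that depth
  (the on-axis value and the maximum coincide for symmetric beams), taking
  the *outermost* left/right crossings with linear interpolation. A profile
  that never falls below the level before the grid edge is clipped there
  and flagged. No smoothing is applied to MC noise by default.
* **D_x** — the largest dose d such that at least x% of the organ volume
  receives ≥ d, evaluated on raw voxel doses by order statistics
  (dose to the hottest x% of volume, ≥-threshold, no interpolation).
  Whether the original tables interpolate is unknowable from the printed
  record, so this convention is pinned explicitly by a brute-force oracle
  in the tests; curves (`computeDVH`, default bin 0.1 Gy_w) are for
  plotting and never feed the statistics.

## The synthetic-data generator

The generator stands in for inputs that are not publicly available:

* **Beam** — a disk source (radius 7.5 cm) at the BSA exit with a
  forward-peaked cos⁵θ angular distribution, spectrum
  (fast, epithermal, thermal) = (0.03, 0.95, 0.02) and 1% photon
  contamination. These are clearly-labelled synthetic stand-ins for an
  unpublished accelerator beam model.
* **Phantoms** — the water phantom (21×28×21 cm interior, 1 cm acrylic
  walls, 2 mm front wall), the 30 cm tissue cube (H/C/N/O mass fractions
  0.10/0.10/0.03/0.77, density 1 g/cm³, uniform 25 µg/g ¹⁰B), and two
  stylised head-and-neck voxel cases (3 mm voxels): a nasopharynx tumour
  6 cm deep with a left-lateral beam, and an anterior-midline hypopharynx
  tumour below the thyroid in front of the esophagus. Anatomy is built
  from ellipsoids, cylinders and slabs; organ primitives carry a small
  seed-deterministic jitter, the tumour is voxelised to exactly 1 cm³
  within one voxel, and all organs are clipped to the body mask.
* **Measurements** — truth curves sampled at foil/TLD-like spacings with
  multiplicative lognormal noise (default CV 3%) and optional Poisson
  counting noise; the truth is retained so recovery (attenuation constants
  within 1%, noise CV within sampling bounds) is testable.

What passing tests on these inputs *do* show: the engine's estimators are
unbiased against analytic oracles, conservation and symmetry hold, and the
qualitative collimation mechanisms (gap-driven intensity loss and field
widening, extension-driven recovery and out-of-field sparing) emerge from
the physics. What they *cannot* show: agreement with any real beam's
absolute flux or dose values, real-anatomy DVH values, or effects that
depend on continuous-energy physics.

## Known limitations

* With a disk source whose angular spread is fixed at cos⁵θ, roughly
  three-quarters of the fluence reaching the exit aperture is direct
  (never wall-scattered). The benefit of extending the collimator is then
  limited to channelling the wall-scattered minority, so the
  extension-versus-gap thermal-flux ratio in the water phantom comes out
  near ~1.4 rather than the ~2 seen when the channel carries a diffuse,
  moderator-equilibrated field. The direction of every comparison (gap
  loss, extension recovery, field-width growth, out-of-field sparing) is
  reproduced.
* No thermal scattering laws, angular distributions or continuous-energy
  data; no electron transport; no photon build-up.
* The stylised mucosa is a small central structure, unlike the extended
  aerodigestive lining of a real patient, so mucosa statistics are more
  in-field than they would be clinically (out-of-field sparing is better
  read from the body or thyroid masks).
* Exports: dose grids round-trip through CSV/JSON/NIfTI and a quantized
  JSON container that mirrors the DICOM RT Dose grid-scaling contract
  (uint16 plus a dose-grid scaling factor); binary DICOM/HDF5 writers are
  intentionally out of scope.

## Problem sizes used by the shipped checks

The test suite runs transmission oracles at 10⁵ histories, trend checks at
2×10⁵ per sweep point, and the water-phantom comparison at 4×10⁵ per run;
the reproduction script (`scripts/acceptance.R`) uses 2×10⁵ per sweep
point, 4×10⁵ for the water-phantom ratio and 4×10⁵ per treatment plan.
These sizes give per-bin relative errors of a few percent on the quantities
being compared while keeping a full run in the minutes range on one CPU.
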