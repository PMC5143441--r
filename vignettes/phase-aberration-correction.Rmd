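---
title: "Hybrid angular spectrum simulation and phase aberration correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid angular spectrum simulation and phase aberration correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hasim)
```

## The problem

Transcranial focused ultrasound concentrates the output of a phased-array
transducer at a millimetre-scale focal spot inside the head. The skull,
with a sound speed around 2740 m/s against ~1500 m/s in soft tissue,
advances or retards each element's wavefront by a position-dependent
amount. These phase aberrations displace, broaden and weaken the focus.
Because the aberration is fixed by the patient's anatomy, it can be undone
by driving each element with the *negative* of the phase its wave accrues
on the way to the treatment location — if that phase can be predicted.

`hasim` implements the simulation side of that programme in three layers:

1. **Voxelized acoustic models** — homogeneous water, a 3D-printable
   random-relief plastic aberrator, CT-derived skull models through a
   configurable Hounsfield-unit mapping, and a synthetic skull-like
   phantom for testing.
2. **The hybrid angular spectrum (HAS) solver** — a steady-state,
   full-wave, slice-marching simulator for the 3D complex pressure field.
3. **Conjugate-phase correction and treatment analysis** — per-element
   field banks, phase solutions at arbitrary treatment locations, and the
   derived treatment metrics (steering-improvement maps, misregistration
   sensitivity, phasor autocorrelation of phase-length maps).

## The solver

The steady-state field obeys the Helmholtz equation
$\nabla^2 p + k^2 p = 0$ with a spatially varying wavenumber
$k(\mathbf{x}) = 2\pi f / c(\mathbf{x})$. HAS discretizes the medium into
transverse slices along the beam axis $+z$ and alternates two steps per
slice of thickness $\Delta z$:

* **Space-domain step.** Each voxel multiplies the field by
  $e^{j\,\Delta b(x,y)\,\Delta z}\; e^{-a(x,y)\,\Delta z}$ where
  $\Delta b = b(x,y) - b'$ is the voxel's deviation from the slice-average
  propagation constant $b'$ (arithmetic mean over the slice) and $a$ is
  the attenuation in Np/m, converted from the stored dB/(cm·MHz) at the
  run frequency. Optionally (`reflection = TRUE`) the plane-wave pressure
  transmission factor $2Z_2/(Z_1+Z_2)$ is applied where the impedance
  $Z = \rho c$ changes between slices; only forward losses are modelled,
  no backward-travelling field.
* **Spectral step.** A 2D FFT decomposes the field into plane waves with
  directional cosines $\alpha = \lambda f_x$, $\beta = \lambda f_y$; each
  propagates by the transfer function
  $e^{j b' \sqrt{1-\alpha^2-\beta^2}\,\Delta z}$. Components with
  $\alpha^2+\beta^2 > 1$ are evanescent: the default policy zeroes them
  (preventing spurious growth); a real-exponential `decay` mode exists for
  near-field studies.

Sign conventions are fixed package-wide: time dependence $e^{-j\omega t}$,
forward propagation $e^{+jkz}$, correction phases $\varphi_i = -\arg p_i$.
A sign error here silently *inverts* the correction, which is why the
convention is asserted by dedicated oracle tests (a voxel slower than the
slice average must accrue *positive* relative phase).

Two geometric distances appear in the space-domain step of the general
formulation — the oblique distance along each plane-wave direction and the
perpendicular slice distance. Both are taken equal to $\Delta z$ (the
paraxial policy): a per-voxel oblique distance is not well defined without
a per-angle decomposition in the space domain, and the perpendicular step
is standard HAS practice. The consequence is the usual paraxial bias of
split-step methods, bounded in our tests by the focused-bowl oracle below.

**Radiating boundaries.** FFTs impose lateral periodicity; energy leaving
one side would re-enter at the other. The solver therefore zero-pads the
field to `pad_factor` (default 2×) times the lateral grid and applies a
raised-cosine amplitude taper (`taper`, default 10 voxels) at the padded
edge each slice. Property maps are edge-replicated into the pad region.
With padding disabled (`pad_factor = 1, taper = 0`) the solver is exactly
unitary over propagating components — the regime the energy-conservation
and reciprocity tests use.

### Numerical verification

The test suite pins the solver to independent closed forms:

* a uniform plane wave in lossless water reproduces $e^{jkz}$ to
  $10^{-6}$ relative (machine precision in practice);
* a uniform lossy medium reproduces $|p| = e^{-az}$ exactly;
* the on-axis pressure of an f/2 focused bowl (3 cm aperture, 6 cm radius
  of curvature), sourced by Rayleigh–Sommerfeld integration onto the entry
  plane, matches the O'Neil closed-form solution within 5 % of the focal
  peak over the focal region on a 128×128×200 grid at
  $\Delta z = \lambda/4$ (measured: ≈1.3 %);
* spectral energy over propagating components is conserved to better than
  $10^{-9}$ relative; swapping a point source and receiver across a
  laterally uniform slab changes the received pressure by < 1 %
  (reciprocity); halving $\Delta z$ moves the focal pressure by < 1 %.

## Sources and arrays

The reference geometry is a 256-element spherical-cap array, 14.5 cm
aperture, 13 cm focal length, 1 MHz. Since the true element layout of
such arrays is proprietary, the default layout is a deterministic Fermat
spiral in cap-area coordinates — near-uniform, equal-area
(`cap_area / n` per element) — with a single-ring option for exactly
symmetric test cases and a CSV loader (`x,y,z,nx,ny,nz,area`) for real
hardware maps. Desk-scale work in the tests uses a geometrically similar
4 cm / 6 cm, 16–64 element array so that a full element bank fits in
seconds; all solver physics is scale-free in `ka`.

Each element's pressure on the simulation entry plane is computed by
Rayleigh–Sommerfeld summation over flat-piston sub-sources at ≤ λ/2
spacing (configurable; the symmetric-field and equal-phase tests refine to
λ/4–λ/8, where the discretization error falls below $10^{-3}$ rad of
phase). The entry plane must lie in front of the element surfaces; the
water path from the curved cap to the flat plane is part of the source
computation, not of the marching loop.

## Conjugate-phase correction

`simulate_element_bank()` runs every element once at unit amplitude and
zero phase and stores the complex field over a declared treatment region
(full volume by default; a compact axis-aligned box in production use,
since 256 full complex volumes are memory-heavy). Because propagation is
linear, this bank is a complete description of what the array can do:

* `correction_phases(bank, target)` reads each element's complex pressure
  at the target (trilinear interpolation of the *phasor* — never of the
  wrapped angle, which would alias) and returns
  $\varphi_i = -\arg p_i(\mathbf{x}_t)$ wrapped to $(-\pi,\pi]$.
  Amplitudes are never altered. A zero-amplitude element gets phase 0
  with a warning (its phase is undefined; any value is equally good).
* `multi_target_solutions()` is a pure lookup — additional treatment
  locations cost microseconds, the central operational advantage of
  simulating full 3D per-element fields.
* `corrected_field()` re-runs the full array with drives
  $e^{j\varphi_i}$ and reports the peak and its lateral distance to the
  target in the target's transverse plane (the hydrophone-scan
  convention; the free-field axial peak of a focused bowl sits upstream
  of the geometric focus, so a 3D distance would conflate physics with
  targeting error).

For fixed per-element amplitudes the conjugate phases are provably
optimal: $|\sum_i |p_i| e^{j(\varphi_i + \arg p_i)}| = \sum_i |p_i|$, an
upper bound by the triangle inequality. The tests verify this against an
exhaustive phase-lattice search on 3 elements and check the in-silico
time-reversal identity: phases read from the bank coincide exactly with
phases measured by re-running each element and reading the argument at
the target ("virtual hydrophone").

## The aberrator generator

The physical reference aberrator is a plate of printable photopolymer
(measured speed 2492 m/s, attenuation 4.72 dB/(cm·MHz)), flat on the
entry side, randomly varying on the exit side: 0–4 mm of relief on a
7.5 mm base, so total thickness spans 7.5–11.5 mm. The relief span is a
*design* quantity: 4 mm of plastic-for-water substitution at 1 MHz gives

$$\Delta\varphi = 2\pi f\, d \left(\tfrac{1}{c_w} - \tfrac{1}{c_p}\right)
 = 6.67\ \text{rad} > 2\pi,$$

a full cycle of phase aberration, which is what makes the plate a
skull-strength test object.

The generator synthesizes relief as seeded uniform white noise smoothed
(periodic Gaussian, FFT-based) to a lateral feature scale — default 5 mm
FWHM, matching the visual patch size of the physical plate — then min–max
rescaled to exactly `[0, max_relief]`. Voxelization assigns plate
properties to voxels whose *center* lies inside the surface. The
construction is bitwise deterministic per seed, and the height map
exports as CSV and as a watertight ASCII STL for 3D printing. The plate
density default (1180 kg/m³, a nominal rigid-photopolymer value) only
matters when the reflection flag is on.

The synthetic skull phantom is the complementary test object: a curved
slab whose thickness varies *smoothly* (default 25 mm correlation scale
versus the aberrator's 5 mm) with seeded internal HU texture. The HU →
property mapping follows the standard structure — affine density, monotone
piecewise-linear speed and attenuation curves clamped at the end knots,
background below a soft-tissue/bone threshold — with package-default knots
(top cortical knot 2740 m/s) that stand in for externally published
optimized curves; every knot is user configuration, because the published
curve families are calibration products, not constants of nature.

## Treatment analysis

* **Steering-improvement maps**: for each target on a focal-plane
  lattice, the ratio of the corrected to the uncorrected focal-plane peak,
  where "uncorrected" means water-path geometric steering
  ($\varphi_i = -k(d_i - F)$ — zero phases would not steer at all). In
  water the map is flat at 1 provided the elements are small enough that
  point-center path lengths represent the element patch; with very few
  large elements the conjugate solution genuinely beats geometric
  steering by a few percent (patch diffraction), which the tests document
  by using 64 desk-scale elements for the flatness check (measured
  deviation ≈0.2 %).
* **Misregistration maps**: the model is translated laterally
  (whole-voxel quantization — property maps are never interpolated, which
  would smear binary material boundaries) while the phase solution for
  the *unshifted* model is held fixed; the focal-plane peak, normalized
  to the zero-shift cell, quantifies the cost of transducer/model
  registration error. The peak search uses a ±5 mm window around the
  target, emulating a 10×10 mm hydrophone raster; `window = Inf` searches
  the whole plane. At desk scale, sub-feature-scale shifts of the default
  aberrator can slightly *raise* the windowed peak (through-plate
  amplitude redistribution outweighs the small decoherence); consistent
  losses appear once shifts approach the feature scale, and the tests
  assert exactly that.
* **Phase-length maps and phasor autocorrelation**: the per-column
  accumulated phase $\varphi(x,y) = \sum_z b(x,y,z)\,\Delta z$
  (straight-ray, no refraction — the construction is a path integral, not
  a wave solve), optionally Gaussian-smoothed (σ in pixels, e.g. 2 px to
  absorb CT noise), converted to the unit phasor $e^{j\varphi}$. A
  circular patch the size of the beam footprint at the model entry
  (cone geometry: aperture radius × distance-to-focus / focal length) is
  circularly cross-correlated with the full phasor map; the magnitude is
  normalized to its global maximum (which the tests verify sits at zero
  lag) and contour areas at 25/50/75 % are reported in mm². Correlating
  phasors rather than wrapped angles is essential — angles alias at
  ±π. Broad correlation areas predict misregistration tolerance; the
  suite verifies the full qualitative chain on two aberrators differing
  only in feature scale (3 mm vs 10 mm): the broader-featured plate has
  both the larger 50 % contour area and the flatter misregistration
  response (higher mean retained pressure, smaller RMS deviation over a
  ±3 mm shift lattice).

## What the synthetic data does and does not show

The generators emulate the *structure* of the physical test objects: the
relief statistics, thickness ranges and material properties of the
printed plate; the smooth thickness variation, curvature and HU texture
of a skull flap. They do not reproduce any particular physical instance —
the published height map and the skull CT are not available — so
instance-specific published numbers (pressure patterns, exact gain
factors, specific contour areas) are out of reach by construction, and
the package asserts properties (gain > 1, optimality, monotone trends,
conservation laws, closed forms) rather than those instance values. The
three numbers that *are* instance-independent — the 2π design span, the
unit conversion, and the recovery-percentage arithmetic on the published
gain-factor pairs — are asserted at printed precision.

Problem sizes in the tests and the acceptance script (64×64×80 correction
grids, 128×128×200 oracle grid, 16–64 elements, 3×3 and 5×5 analysis
lattices) were chosen as the smallest sizes at which each property is
cleanly measurable — the beam must clear the padded lateral boundary, the
plate must subtend several relief features, and the focal region must be
interior to the volume. The full clinical workflow (256 elements,
500-voxel grids, 23×23 lattices) runs through exactly the same code paths
via the configuration system and the checkpointed bank simulator.

## Numerical choices and degenerate inputs

* Evanescent default `zero`; `decay` available. At exactly
  $\alpha^2+\beta^2 = 1$ the transfer multiplier is 1 (grazing).
* $b'$ is the arithmetic (area-weighted) slice mean; any monotone
  averaging would do, but the mean keeps the homogeneous-slice step an
  exact identity.
* Off-grid targets interpolate the complex field trilinearly; targets
  outside the stored bank region are an error, not an extrapolation.
* Sub-voxel model translations quantize to the nearest voxel; a
  zero-quantized shift returns the model unchanged (exact identity), and
  on-grid shift/unshift pairs are exact inverses on the interior.
* `max_relief = 0` produces a flat plate (all columns identical);
  zero-amplitude texture produces a homogeneous-HU slab; smoothing a
  constant map is the identity.
* Non-finite fields abort the march naming the slice; malformed layout
  CSVs name the offending line; configuration errors name the offending
  key and exit with status 2 at the CLI.

## Known limitations

Linear acoustics only: no nonlinearity, no shear-wave conversion, no
volumetric scattering, no thermal modelling. Reflection handling is
forward-transmission-loss only. The paraxial $\Delta z$ policy biases
steeply oblique components; keep f-numbers ≳1 or refine $\Delta z$.
Results that depend on the element layout (exact sidelobe levels) are
layout-sensitive, and the default spiral is a stand-in for proprietary
hardware maps. Field persistence uses R-native `.rds` plus NIfTI
magnitude export; models and HU volumes round-trip through NIfTI and
MHD/RAW with a JSON sidecar as the authoritative meter-unit geometry
record.
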