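---
title: "Digital breast phantoms and quantitative micro-elastography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital breast phantoms and quantitative micro-elastography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmephantom)
```

# What this package models

Quantitative micro-elastography (QME) is a compression variant of optical
coherence elastography: a sample is imaged with phase-sensitive OCT while a
calibrated soft silicone layer on its surface converts measured layer strain
into surface stress, and elasticity is estimated as stress over local strain.
Physical tissue-mimicking phantoms — silicone slabs replicating the geometry
of invasive ductal carcinoma (IDC), stroma and adipose regions, or a branching
milk-duct network — are the standard way to study how tissue architecture
shapes elastogram formation at boundaries.

This package is a fully digital counterpart of that workflow. It builds
voxelized phantoms with per-region mechanical and optical properties,
simulates their compression and speckle imaging, reconstructs elastograms
with the same processing chain a QME system uses, segments en-face images,
quantifies boundary spatial resolution with error-function step responses,
and exports printable mold geometry. Everything is seeded and deterministic,
so reconstruction accuracy can be judged against exact ground truth.

# Phantoms

`make_idc_phantom()` extrudes a dense-tissue mask and a nested IDC mask into
a three-material slab: adipose 18 kPa, stroma 48 kPa, IDC 230 kPa (the
fabrication reference values at 10% strain), with backscatter set to the
measured en-face OCT contrast ordering — stroma brightest (30 dB), IDC
intermediate (23 dB), adipose darkest (17 dB). The slab stacks a cover
section (default 200 um), the 1 mm structured section, and a base section;
the cover material defaults to stroma (the over-poured casting material) and
is configurable, since the physical protocol does not pin it down.

`make_duct_phantom()` rasterizes a `duct_network_spec` — centerline polylines
with per-segment diameters — into a 58 kPa bulk. Cross-sections are circles
swept along the centerline; membership uses the perpendicular projection onto
each sub-segment, giving flat end caps so that a straight tube's voxel volume
converges to the analytic cylinder volume (this is the volume oracle used in
the tests). Junctions are voxel-wise unions. The default network is a gently
curved 1 mm main duct of 22 mm arc length with a 0.8 mm branch leaving at
11 mm arc length. Hollow lumens are voids (no material, no signal);
fluid-filled lumens carry a small effective modulus (default 1 kPa) with
backscatter matched to the bulk, which lets one-dimensional mechanics express
that the lumen deforms more than the surrounding silicone without a
hydrostatic model.

`make_synthetic_masks()` generates the region geometry procedurally:
star-shaped blobs `r(theta) = r0 (1 + sum a_k cos(k theta + phi_k))` with
harmonics 2–6. This reproduces the *character* of segmented dense tissue —
lobed outlines, boundary features at the 100 um scale, a nested stiff
inclusion — not any particular specimen.

# Forward mechanics

The forward model deliberately adopts the same idealization the QME
reconstruction assumes: uniform, uniaxial stress along each lateral column
(springs in series). `solve_prestrain_stress()` finds, per column, the stress
at which total compression equals the bulk strain times the solid thickness;
linear materials give it in closed form, a nonlinear layer stress–strain
curve is solved by bisection (monotonicity guarantees a bracket; relative
tolerance 1e-10). `series_spring_deform()` then sets `strain(z) = -sigma/E(z)`
(compression negative) and integrates displacement from the fixed plate
upward.

Sign conventions: z points from the imaging window down into the sample;
the fixed plate is the last plane. Displacement is stored as motion toward
the plate (u >= 0, u = 0 at the plate), which makes `du/dz = strain` hold
exactly — so the slope returned by the strain estimator *is* the strain,
negative in compression. Void voxels are excluded from both the thickness
and compliance of their column and are invalid in all derived fields;
modeling the collapse mechanics of empty channels is out of scope, matching
the display convention of masking hollow-duct interiors.

Because column mechanics cannot produce the lateral interactions seen at
real boundaries, `lateral_coupling_blur()` provides an explicit, honest
stand-in: a normalized Gaussian blur of the strain field in the lateral
plane, renormalized over valid voxels so constants are preserved and voids
do not leak. A step blurred with kernel FWHM f yields an erf profile whose
fitted FWHM is f — which both calibrates the resolution analysis and gives
the experiments a tunable boundary-transition width. There is no
field-prescribed value for the kernel; the desk-scale experiment configs use
200 um.

# Speckle imaging

`simulate_speckle()` draws each voxel as a circularly symmetric complex
Gaussian with mean intensity `noise_floor * 10^(backscatter_dB/10)`, plus
additive complex noise at the noise floor; the two terms are drawn as a
single complex Gaussian with summed variance, which is the same
distribution. Intensity within a region is exponentially distributed, as
fully developed speckle should be. Voxels are independent (no lateral
speckle correlation) and there is no depth attenuation by default — both are
beyond what the acceptance analyses need.

`oct_pair()` builds the loaded/unloaded pair for a displacement field: the
scatterer configuration is unchanged between acquisitions, so the speckle
realization is shared and displacement enters as a pure phase factor
`exp(i * 4 pi n u / lambda0)` (double pass, common path; default
lambda0 = 1300 nm, group index n = 1.4 — the index is not stated for the
physical system and only rescales displacement consistently on both the
simulation and reconstruction side). Detection noise is drawn independently
per acquisition; without independent noise the phase difference would be
exactly noise-free at any SNR and reconstruction error could not be studied.

A modeling decision worth stating: the tomogram pair encodes a *small
actuator increment* (default 0.1% bulk strain, the microscale compression of
the ring actuator) on top of the 5% static pre-strain that sets the
operating point. Encoding the full 5% deformation would put per-voxel phase
increments inside the compliant layer far beyond the 2 pi wrapping limit
(about 4.3 rad per 3.5 um voxel), where no depth unwrapping is possible —
exactly why physical QME measures micro-scale modulation, and why reported
strains are at the millistrain scale. For linear materials the recovered
modulus is independent of the increment size.

# Reconstruction

`phase_difference_displacement()` takes `arg(loaded * conj(unloaded))`,
unwraps along depth per A-line by nearest-2pi continuity from the surface,
and scales by `lambda0 / (4 pi n)`. The surface voxel's absolute phase is
known only modulo 2 pi, so each A-line's displacement carries an arbitrary
offset of multiples of `lambda0/(2n)`; depth gradients — the quantity QME
uses — are unaffected. Voxels below the SNR gate (default 5 dB) are invalid.

`wls_strain()` fits a weighted least-squares line to displacement versus
depth over a centred 100 um window (clipped at volume edges; at least three
valid samples required). Weights default to the linear-scale OCT SNR of the
unloaded tomogram, the standard phase-noise model (phase variance
proportional to 1/SNR). The implementation uses sliding-window cumulative
sums with the depth coordinate centred on the volume to keep the normal
equations well conditioned; the tests verify it against a direct
normal-equation solve at 1e-10.

`layer_stress()` estimates the layer strain per lateral position as the mean
valid strain over the layer's axial extent, excluding half a fitting window
at each end where the regression window straddles an interface, then
evaluates the layer's stress–strain curve at that magnitude. Averaging over
the extent rather than reading a single interface voxel is a noise-robustness
choice; the margin removes the systematic bias of windows that mix layer and
sample displacement slopes.

`elasticity_map()` divides stress by local |strain|; magnitudes below a
floor (default 1e-5) give invalid voxels rather than infinities. Stress is
stored as a magnitude and strain signed, so elasticity is positive alongside
negative compressive strains.

`postprocess_enface()` centre-crops (700 px at the 15 um lateral pitch spans
10.5 mm), median-filters 3x3 per plane, and averages over a 100 um depth
range, ignoring invalid voxels. Whether filtering precedes averaging is not
fully pinned down by the physical protocol; the default is filter-then-
average with the order exposed as an argument. These operations commute with
positive scaling, which the tests assert.

# Segmentation and resolution analysis

`segment_dense_tissue()` thresholds an en-face SNR image at 23 dB
(comparison is >=; strictness only matters on exact-boundary pixels), fills
enclosed holes (EBImage's fill-hull: background components not connected to
the border), and removes connected components below 10,000 px — the 4 mm^2
criterion at the wide-field ~20 um pitch. `area_mm2_to_px()` documents that
the px/mm^2 equivalence is a rounding of the true wide-field pitch. The
default connectivity is 8; EBImage labels 4-connected components, and
8-connectivity is obtained by merging labels that touch diagonally.
Manual IDC delineations are ingested as polygons (`polygon_to_mask()`,
even-odd rule) or masks and combined with `combine_region_masks()`.

`extract_profile()` samples an image along a line with bilinear
interpolation and min-max normalizes (a constant profile maps to 0.5).
`fit_erf()` fits `A erf((x - x0)/(sigma sqrt(2))) + B` by
Levenberg–Marquardt; the derivative of the fitted edge is a Gaussian whose
FWHM (`2 sqrt(2 ln 2) sigma`) is the local spatial resolution.
Initialization: x0 at the steepest slope of a lightly smoothed difference
profile (so single noise spikes cannot hijack it), sigma multi-started at
1/12, 1/4 and 1/2 of the span plus a centre-started fallback, A and B from
the profile extrema; the best residual wins. Fits with sigma below the
sample spacing are flagged unresolved; `resolution_report()` runs batches,
flags rows with R^2 below 0.93, and never aborts on a single failure.

# Experiments

`run_recovery_experiment()` is the end-to-end accuracy check: a homogeneous
slab under the 500 um / 16 kPa layer, 5% pre-strain, 30 dB speckle, full
reconstruction, median elasticity over the central region at mid-depth. The
acceptance protocol uses 256 x 256 x 300 voxels at dz = 3.5 um (the axial
pitch is not fixed by the physical system's stated depth range; 3.5 um is
the package default). Since every forward and inverse step acts per lateral
position, the volume is processed in y-slabs with per-slab derived seeds;
this bounds memory without changing any column's computation.

`run_idc_experiment()` and `run_duct_experiment()` assemble the full
studies: region statistics on en-face maps, boundary step responses, and —
for ducts — hollow-versus-fluid comparisons. Two reporting choices matter.
First, boundary profiles in the duct study are taken from the *ungated*
reconstruction: a hollow lumen in the gated maps is a masked constant with
no step to fit, whereas physically the interior holds erroneous, noise-driven
values that are masked for display after the fact; the masking statistics
re-apply the gate. Second, the cross-duct line runs from the bulk to the
duct centerline so it crosses a single boundary, and in the fluid case the
strain profile peaks at the thin-chord edge (a stiff column concentrates all
its strain in a thin fluid sliver), so the monotone elasticity profile is
the quantity compared across configurations. Under pure column mechanics a
fluid lumen reads exactly its effective modulus with the same one-pixel edge
as a void; the observed hollow-sharp/fluid-gradual contrast emerges once
lateral coupling is enabled, which is the package's explicit emulation of
the mechanism.

# Mold export

`extrude_mask()` builds staircase prisms over pixel-boundary contours, so
mesh volume is exactly pixel count x pixel area x height — a crisp oracle.
Corners where foreground pixels meet only diagonally are split into one
vertex per edge-connected pixel fan, keeping every edge shared by exactly
two faces. `add_cylindrical_wall()` and `sweep_duct_tube()` build the mold
base (45 mm cavity, 0.2 mm cover clearance) and the 0.5 mm walled duct tube
inside a 30 mm disc shell; unions are component concatenations with
containment/overlap checks rather than CSG, since the molds are
non-overlapping by construction. `write_stl()`/`read_stl()` exchange binary
STL in mm and refuse non-watertight meshes unless forced.

# What the synthetic data does and does not show

The generator reproduces the study conditions — region moduli and contrasts,
layer properties, 5% pre-strain, fitting range, filter sizes, duct
geometry — under idealized mechanics and idealized speckle. Passing tests
demonstrate that the reconstruction chain is an exact algebraic inverse of
the forward model in the noiseless limit, that it is accurate to a few
percent under realistic speckle noise, and that the boundary analysis
recovers designed transition widths. They do not demonstrate performance
under 3D mechanical coupling, correlated speckle, depth attenuation,
refraction, or system drift; the physical phantom studies' absolute measured
values (which fold in all of those) are correspondingly out of reach, and
the experiments here are parameter-recovery studies, not re-measurements.
Material nonlinearity is supported in the layer curve but the default
materials are linear, so the distinction between moduli quoted at 10% strain
and values measured at 5% pre-strain does not arise unless a nonlinear
curve is configured.

# Problem sizes and runtimes

Defaults were chosen for desk-scale work: recovery runs at
256 x 256 x 300 voxels (a few tens of seconds each), the IDC study at
96 x 96 lateral with 10 um axial pitch, the duct study at 50 um pitch, and
the duct rasterization for geometry checks at 25 um pitch. Full-scale
800 x 800 processing is a matter of configuration, not code.
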