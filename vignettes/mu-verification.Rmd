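---
title: "Independent MU verification for stereotactic cone plans: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Independent MU verification for stereotactic cone plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereomu)
```

## The problem

Stereotactic radiosurgery with conical collimators delivers high doses to
small intracranial targets in few fractions, so an independent verification
of the planning system's monitor units (MU) is a standard QA requirement.
`stereomu` is such a secondary check: it recomputes each beam's MU at the
isocenter from commissioning data that are independent of the planning
system's beam model, and compares against the plan.

## Dose model and assumptions

The check is isocentric and one-dimensional. For a cone of size $S$ at depth
$d$ the isocenter dose is modelled as

$$D = \mathrm{MU}\cdot \mathrm{DR_{ref}}\cdot \mathrm{OF_{TMRmax}}(S)\cdot
\mathrm{TMR}(d, S),$$

with the off-axis ratio and the inverse-square term set to one: the
verification point *is* the isocenter, on the central axis, at the
source–axis distance. MU follows by inversion. The assumptions this buys:

* **Tabulated TMR, linearly interpolated.** Measured TMR curves are
  resampled to a 1 mm grid and normalized to 1 at the depth of maximum dose
  (`dmax`, e.g. 15 mm for a 6 MV FFF beam, 25 mm for 10 MV FFF). Lookups are
  exact at grid nodes and piecewise linear between them.
* **Output factors renormalized to TMR geometry.** Output factors are
  usually measured at fixed SSD and depth (950 mm / 50 mm here). They are
  converted to the depth of maximum dose in isocentric geometry through the
  PDD ratio and an inverse-square factor; PDD itself is derived from TMR
  with the phantom-scatter ratio taken as **unity**, which is a good
  approximation at these field sizes and is kept as an explicit constant in
  the code so it can be revisited.
* **Small-field correction factors as user data.** Detector-specific output
  correction factors are indexed by the equivalent square
  $s = r\sqrt{\pi}$ of the circular field and can be fitted with a two-term
  exponential $k(s) = a e^{bs} + c e^{ds}$; evaluation supports
  extrapolation below the smallest tabulated square, which is how cones
  below the published 4 mm limit are handled.
* **Arcs as segmented statics.** An arc is segmented at 1° gantry
  resolution (configurable) and uses the arithmetic mean TMR over segments,
  with the plan's per-arc isocenter dose applied to that mean — no
  per-segment dose weighting.
* **Heterogeneity as equivalent path length.** With correction on, the
  geometric depth is replaced in every TMR lookup by
  $d_\mathrm{eff} = \sum_i \rho^{el}_i x_i$: the voxel intersection lengths
  along the central axis weighted by relative electron density from the CT
  calibration curve. This 1D correction accounts for attenuation by bone,
  air cavities and the couch; it deliberately does **not** model scatter
  changes, so it is unreliable *inside or immediately next to* an
  inhomogeneity — the proper use is a point well beyond it, which is the
  radiosurgery situation.

Both MU values are always computed in one geometry pass; the
`heterogeneity` flag only chooses the headline number, because a QA review
wants to see both.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| arc resolution | 1 | deg | segment spacing for the mean TMR; finer helps over irregular surfaces (nose, ears) |
| action level, Diff_NHC | 2 | % | agreement expected of two homogeneous algorithms on the same geometry |
| action level, Diff_WHC | 5 | % | widely used planned-vs-delivered tolerance |
| `include_couch` | on | – | couch attenuation contributes to the effective depth |
| TMR smoothing window | 0 (off) | grid points | vendor software smooths measured curves with an unspecified filter; the default here is pass-through for reproducibility, with an optional odd-width moving average |
| phantom-scatter ratio | 1 | – | TMR↔PDD conversion constant for small cone fields |
| SAD | 1000 | mm | machine rotation radius |

Depths shallower than the first TMR grid point are clamped to the first
tabulated value with a warning — such geometries mean the isocenter is
nearly at the surface, where a 1D model should not be trusted anyway. Depths
beyond the last measured point are extrapolated log-linearly from the last
two nodes, since TMR decays near-exponentially at depth.

## Geometry conventions

All coordinates are DICOM patient coordinates (LPS, mm). Gantry and couch
angles follow IEC 61217 as stored in the plan; for a head-first-supine
patient, gantry 0° places the source anterior and gantry 90° on the
patient's left, and the couch angle rotates the gantry plane about the
vertical axis. Only axis-aligned HFS studies are accepted: every cone
radiosurgery study this tool targets (and every study its fixture generator
writes) is axial HFS, and the reader validates this rather than silently
mis-handling oblique orientations.

The patient surface for the geometric depth is the **rasterized external
contour** (even–odd rule, voxel centers decide membership), not an HU
threshold — this keeps the couch out of the geometric depth and matches how
the external structure is defined clinically. The consequence is surface
quantization of about half a voxel: on a centered cylinder the depth spread
over a full rotation is bounded by one voxel diagonal, and tests assert
exactly that bound. At the MU level the effect largely averages out (the
181-segment arc on a cylinder reproduces the static MU to better than
0.05% at 1 mm pitch).

Ray traversal is exact voxel-boundary (Siddon-type) enumeration from the
proximal CT face to the isocenter: intersection lengths are exact, there is
no step size to tune, and the per-voxel lengths sum to the in-body chord.
The effective depth integrates RED over *all* traversed voxels when
`include_couch` is on (air contributes ~0, couch structures their actual
RED), or over body-mask voxels only when it is off. A ray that enters the
CT volume already inside the body raises an "insufficient scan coverage"
error rather than returning a truncated depth.

## Per-beam dose resolution

The DICOM standard leaves several places for a beam's isocenter dose, so the
reader resolves it in a fixed, logged order: (1) the plan's referenced beam
dose; (2) trilinear sampling of a per-beam RT Dose grid at the isocenter;
(3) a plan-total grid apportioned by meterset weight. Which source was used
is recorded on every result (`dose_source`) and echoed by the CLI, because
the comparison is only as good as the dose it inverts.

## The synthetic-fixture generator

The generator exists so that every pipeline stage can be tested against a
known answer without any measured data:

* **Beam model**: TMR is $(d/d_{max})^2$ in the build-up region and
  $e^{-\mu (d-d_{max})}$ beyond, tabulated at 1 mm; $\mu = 0.0045$/mm
  (a realistic FFF falloff), DRref = 0.01 Gy/MU, output factors increasing
  0.67→0.87 over the 4–17.5 mm cones, CT curve through (−1000, 0), (0, 1),
  (1000, 1.6), (3000, 2.5). The shape is chosen for exact invertibility,
  not radiological realism.
* **Phantoms**: a homogeneous water cylinder; a thorax-like ellipse with two
  low-density inserts (HU −700) at the lung positions, a bone insert
  (HU 800) at the vertebral position and a couch slab; an elliptical head
  with a high-density shell for tangential-vs-normal incidence experiments.
  The body-water HU region is assigned from the same rasterized contour used
  as the body mask, so the surface seen by the depth calculation and by the
  ray tracer agree voxel for voxel.
* **Studies**: complete DICOM sets (CT series, structure set with an
  EXTERNAL contour, plan, per-beam dose grids) written with deterministic,
  seed-derived UIDs. Each beam's isocenter dose is computed **forward** from
  a chosen MU through the homogeneous geometric-depth chain — the same model
  a cone TPS algorithm without heterogeneity correction uses — so the
  homogeneous recomputation must return the embedded MU exactly, on any
  phantom, and the heterogeneity-corrected value shows the physically
  expected sign (more MU behind bone, fewer behind low density).

What passing these tests does *not* show: agreement with measured beam data,
detector effects, realistic penumbra or scatter, irregular patient surfaces,
or non-HFS setups. The fixtures validate the computational chain, not the
commissioning data a clinic would feed it.

Default fixture pitch is 2 mm (the studies build in seconds); a 1 mm option
exists for tolerance-sensitive geometry work, and is what the arc–static
symmetry test uses.

## Numerical choices

* **Two-term exponential fit**: Levenberg–Marquardt least squares from a
  fixed list of eight starting quadruples (plus data-driven anchors), best
  converged residual wins, ties broken by start order. Only fitted *curve
  values* are guaranteed (to 1e−6 relative on noise-free data);
  parameters themselves are identifiable only up to swapping the two terms.
* **Sequence and tie handling in arcs**: segments include both endpoints
  (n = span/res + 1); a stop angle that is not a multiple of the resolution
  is appended; angles wrap through 360°→0°; an arc with equal start and stop
  is treated as a single angle.
* **Archive serialization**: a versioned JSON container with full-precision
  numbers; saving a loaded archive reproduces the file byte for byte, which
  makes archives hashable for configuration control.
* **DICOM dialect**: the package carries its own minimal Explicit-VR
  little-endian codec covering the CT/RTPLAN/RTSTRUCT/RTDOSE subset it
  needs (R has no general DICOM package). Defined-length sequences only;
  unsupported transfer syntaxes are rejected with a clear error. Decimal
  strings carry 10 significant digits, so geometry round-trips far below
  the 1e−3 mm fidelity the tests require.
* **Degenerate inputs** rejected with named errors: non-positive cone
  diameters, non-monotone depth grids, dmax outside the measured range,
  isocenter outside the external contour, rays that miss the body, OF
  outside (0, 1), calibration without DRref.

## Problem sizes used by the test-suite

Studies are generated at 2 mm pitch (cylinder ~96×96×50, thorax
~150×136×40 voxels); the arc–static symmetry check uses a 1 mm cylinder;
ray-tracing is cross-checked against 0.05 mm midpoint sampling on 100 random
rays. The whole suite, including writing and re-reading every study, runs in
well under a minute.

## Known limitations

* 1D central-axis model: no off-axis dose, no scatter-aware heterogeneity
  handling, no dose inside inhomogeneities.
* Surface from the rasterized contour: depth carries ±half-voxel
  quantization; use 1 mm CTs when sub-millimetre depth fidelity matters.
* HFS, axis-aligned studies only; MLC-shaped beams are rejected by design.
* The vendor water-tank file dialect is not parsed; commissioning inputs are
  plain CSV.
* Whether the comparator TPS dose includes couch transmission is taken as
  exported; `include_couch` controls only this package's own effective
  depth.
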