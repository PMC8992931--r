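# stereomu

Independent monitor-unit (MU) verification for stereotactic radiosurgery
plans delivered with circular conical collimators (4–17.5 mm nominal
diameter). Given (a) commissioning beam data — per-cone tissue-maximum-ratio
(TMR) curves, output factors, an absolute calibration, and a CT-number to
relative-electron-density (RED) calibration — and (b) an exported DICOM-RT
study (CT series, RT Plan, RT Structure Set, RT Dose), `stereomu` recomputes
the MU of every static field and arc at the isocenter and reports percentage
differences against the treatment planning system (TPS), for use as a
secondary check in a radiotherapy QA program. It is written for medical
physicists who need an independent, scriptable check of cone-plan MU —
including a 1D heterogeneity correction that the common cone dose algorithms
omit.

## The calculation

At the isocenter there is no off-axis term and no inverse-square correction,
so the dose model reduces to the TMR formalism

```
D = MU · DRref · OF_TMRmax(S) · TMR(d, S)
```

and the MU check is its inversion,

```
MU = D / (DRref · OF_TMRmax(S) · TMR(d, S))
```

where `D` is the plan's isocenter dose for the beam, `DRref` the reference
dose rate (Gy/MU), `S` the cone size and `d` the depth along the central
axis. Measured output factors are renormalized to the depth of maximum dose
in isocentric geometry via

```
OF_TMRmax(S) = OF(S) · PDD(S, SSD, dmax)/PDD(S, SSD, d_meas) · ((SSD + dmax)/SAD)²
```

with PDD derived from TMR (phantom-scatter ratio taken as unity for small
cone fields). Circular fields map onto the equivalent square
`s = r·√π` (a 4 mm cone → 3.54 × 3.54 mm²) for small-field
output-correction-factor handling, and correction-factor points can be
fitted with the two-term exponential `k(s) = a·e^{b·s} + c·e^{d·s}`.

Arcs are segmented at 1° gantry resolution and use the arithmetic mean TMR
over the segments. Without heterogeneity correction (`MU_NHC`) the depth is
the geometric distance from the external contour to the isocenter; with
correction (`MU_WHC`) it is the effective depth (equivalent path length)

```
deff = Σ_i RED(HU_i) · x_i
```

accumulated by exact Siddon-type voxel traversal of the CT from the proximal
volume face to the isocenter (so couch structures are naturally included).
Differences are reported as `100·(MU_calc − MU_plan)/MU_plan` with advisory
action levels of 2% (homogeneous equivalence) and 5% (QA tolerance).

## Worked example

The package generates its own DICOM studies with known-answer MU. The
`thorax` scenario is an elliptical body with two low-density (lung-like)
inserts, a bone insert at the vertebral position and a couch slab, irradiated
by a 90° lateral field through the lung insert, a 180° posterior field
through the bone insert, and a 0°→180° clockwise arc crossing both:

```sh
Rscript -e 'stereomu::stereomu_cli(commandArgs(TRUE))' make-fixtures \
    --scenario thorax --out demo --seed 7
Rscript -e 'stereomu::stereomu_cli(commandArgs(TRUE))' calc \
    --archive demo/archive.json --ct-dir demo/ct \
    --rtplan demo/rtplan.dcm --rtstruct demo/rtstruct.dcm \
    --rtdose demo/rtdose_01.dcm,demo/rtdose_02.dcm,demo/rtdose_03.dcm \
    --out demo/out
```

prints

```
Beam g90_lung (static, cone 15.0 mm): MU_NHC 200.00, MU_WHC 171.93 | plan 200.00 MU (dNHC -0.00%, dWHC -14.03%)
Beam g180_bone (static, cone 15.0 mm): MU_NHC 200.00, MU_WHC 223.45 | plan 200.00 MU (dNHC +0.00%, dWHC +11.73%)
Beam arc_0_180 (arc, cone 15.0 mm): MU_NHC 300.00, MU_WHC 298.18 | plan 300.00 MU (dNHC +0.00%, dWHC -0.61%)
Diff_NHC: -0.00% +/- 0.00% | Diff_WHC: -0.97% +/- 12.88%
```

Reading: the homogeneous recomputation (`MU_NHC`) reproduces the embedded
plan MU of every beam exactly, because the fixture's isocenter doses were
computed forward through the same homogeneous chain a cone TPS algorithm
uses. The heterogeneity-corrected values show the expected physics: the beam
through the low-density insert needs *fewer* MU than a water-equivalent
patient would (−14%), the beam through bone needs *more* (+12%), and the arc
averages across both (−0.6%). Beams beyond the 5% action level are flagged in
`demo/out/mu_report.txt`; the CSV `demo/out/mu_report.csv` has one row per
beam with both MU values, differences, and (angle-averaged) geometric and
effective depths.

The synthetic inserts are deliberately large and dense (or rarefied)
compared with clinical anatomy, so these percentages are stress-test
magnitudes, not clinical expectations.

An archive is built from commissioning CSVs with
`stereomu beam-config --tmr-dir ... --of of.csv --calibration cal.csv
--ct-curve ct.csv --dmax 15 --out archive.json`, and all functionality is
also available directly in R (`make_archive()`, `read_study()`,
`compute_plan_mu()`, `write_report()`).

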