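---
title: "Quantifying outer retinal bands in geographic atrophy from OCT segmentation surfaces"
author: "octbands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying outer retinal bands in geographic atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

In geographic atrophy (GA), the late atrophic stage of age-related
macular degeneration, the retinal pigment epithelium (RPE) and the
photoreceptor bands degenerate. OCT volume scans resolve the outer
retina as a stack of hyperreflective bands — external limiting membrane
(ELM), ellipsoid zone (EZ), interdigitation zone (IZ), and the RPE —
and clinical trials increasingly use the thickness and *integrity loss*
of these bands as anatomical endpoints. `octbands` turns manually
corrected layer-segmentation surfaces (five surfaces per volume: ELM,
inner/outer EZ boundary, inner/outer RPE boundary) into en-face
thickness maps, loss areas, subretinal drusenoid deposit (SDD)
volumes, ETDRS-grid topographic summaries, and two-device or
between-region mixed-effects comparisons.

The package deliberately starts *after* segmentation: raw reflectivity
data, AI presegmentation and manual-correction tooling are out of
scope. Its substrate is a `surface_set` — per surface, an
`n_bscans x n_ascans` matrix of axial positions in µm, where a missing
value encodes that the band's reflectivity ended at that A-scan column
(band loss).

## Band definitions

Three bands are quantified, each as posterior minus anterior surface:

| band     | anterior  | posterior | rationale |
|----------|-----------|-----------|-----------|
| `ELM_MZ` | ELM       | EZ inner  | ELM plus the myoid zone |
| `EZ`     | EZ inner  | RPE inner | EZ *including* the IZ (outer-segment tips), a robust photoreceptor-integrity proxy in GA |
| `RPE`    | RPE inner | RPE outer | the RPE monolayer; basal laminar deposits, drusen and Bruch's membrane are excluded by the outer-boundary convention |

Loss of a band is encoded by its own defining surface being missing:
ELM for `ELM_MZ`, the EZ boundary pair for `EZ`, the RPE boundary pair
for `RPE`. Columns where an SDD visibly disrupts the EZ carry an
explicit per-column flag and count as EZ loss — "visibly disrupted" is
a reader judgment the pipeline cannot re-derive, so it trusts the flag.
Thickness at loss columns is *excluded* (missing), not zero-filled, so
thickness means describe surviving tissue only; thickness and loss are
reported as separate outcomes. Note one asymmetry that follows from
nested lesions: where the (wider) EZ lesion removes the EZ-inner
boundary but the ELM survives, ELM+MZ thickness is incomputable
(missing) even though there is no ELM loss — loss implies missing
thickness, but not conversely, for this band.

SDD thickness at a column is the gap between the inner RPE boundary
and the outer EZ boundary, registered only where it *strictly* exceeds
4 µm (one conventional axial pixel); "over a threshold" is read as
strictly greater, and the threshold exists to absorb residual
segmentation error and diffuse stage-1-like material. Sub-µm negative
gaps outside SDDs are tolerated and treated as 0.

## Geometry and units

A 20° × 20° volume with 1024 A-scans and 49 B-scans is the default
lattice. The lateral calibration defaults to 0.293 mm/degree because
it makes 48 B-scan intervals over 20° equal 122.08 µm — the
conventional "122 µm" spacing; the true per-eye calibration is unknown
without biometry, so the value is configurable. Spacing follows the
fence-post convention `extent / (n − 1)`; each A-scan column represents
a rectangular en-face cell (lateral pitch × slab width, about
6.99 × 10⁻⁴ mm² on the default lattice), and every integral (loss area
in mm², SDD volume in nL; 1 nL = 10⁶ µm³) is a rectangle-rule sum of
those cells. Volumes acquired with 97 B-scans can be subsampled to the
49 manually corrected pattern (every second B-scan, doubling the slab
width) with `subsample_bscans()`.

In memory, indices are 1-based (idiomatic R; B-scan 1 is the
inferior-most scan, A-scan 1 the image-left column); on disk (TSV
surface tables, JSON geometry sidecars) indices are 0-based. Surfaces
are stored in µm, never pixels, so all computation is device-agnostic;
the axial pixel pitch exists only to convert pixel-valued inputs at
ingestion.

## ETDRS topography

`etdrs_grid()` centers the standard grid on the manually annotated
fovea: rings at 0.5 / 1.5 / 3.0 mm radius (half-open bins, `[0, 0.5)`
center), quadrants split at the ±45° diagonals (a column exactly on a
diagonal joins the counter-clockwise quadrant — invisible at float
precision in practice), and nasal/temporal resolved by laterality.
Distances use the anisotropic physical spacings (≈5.7 µm A-scan pitch
vs. 122 µm slab width); no isotropy is assumed.

Relative losses divide by the *nominal* ring areas π·0.5², π(1.5²−0.5²),
π(3²−1.5²) → 0.79 / 6.28 / 21.21 mm² (2-decimal reporting, unrounded
internally) even though a 20° field (~5.86 mm) slightly clips the 6-mm
circle; the covered fraction per ring is reported as a warning metric.
Two discretization caveats are documented rather than hidden: (i)
cell-center counting can overcount a convex subfield slightly (the
discrete center circle covers ~100.7% of its nominal area on the
default lattice), so a fully lost subfield can read marginally above
100%; (ii) published tables that normalize *rounded* absolute losses
only close for the large perifoveal ring — central and parafoveal
percentages require unrounded internal values, which is how the
pipeline computes them.

Quadrant-level SDD volumes merge the parafoveal and perifoveal rings
per quadrant, plus the central circle, and an area-normalized variant
(nL/mm²) supports nasal-vs-temporal comparisons. The cohort SDD
distribution map fovea-registers all eyes (lattice shift, crop to the
common extent) and averages the per-column projected volume in µm³.

## The phantom generator

Patient OCT volumes cannot be redistributed, so validation rests on a
synthetic cohort with analytic ground truth. `phantom_spec()` defaults
describe the emulated study conditions — they are *emulation anchors*,
not ground truth about any patient:

* **Cohort**: 32 patients, 25% contributing both eyes → 40 eyes; each
  eye acquired on two simulated devices (`standard`, `high_res`) on
  identical lattices with identical fovea centers, emulating a
  registered follow-up protocol.
* **Baseline thicknesses** (standard device): ELM+MZ 20 µm, EZ 27 µm,
  RPE 21 µm, with 1.5 µm patient-level and 2–2.5 µm eye-level SD;
  `high_res` offsets −1.5 / +1.1 / −5.1 µm. These center simulated
  cohorts near published GA band means (a thinner RPE and myoid zone
  but thicker EZ band at higher axial resolution).
* **EZ eccentricity trend**: +1.8 µm/mm anchored at 2.2 mm, emulating
  the thinner EZ band near the fovea in GA.
* **Atrophy lesion**: ellipses per band with nested extents — RPE-loss
  semi-axes 1.0 × 0.5 mm (area π/2 ≈ 1.57 mm², the published RPE-loss
  scale), dilated +0.15 mm for ELM loss and +0.30 mm for EZ loss, so
  EZ ⊇ ELM ⊇ RPE. A shared lognormal factor (SD 0.25 on the log
  scale) skews loss areas right across eyes, motivating the log-scale
  analysis; the factor is truncated so the dilated ellipse always fits
  the field of view, and a spec whose *nominal* lesion cannot fit is
  rejected. Truth areas are exactly πab.
* **SDD mounds**: circular paraboloid caps (height ~13 ± 2 µm, radius
  ~0.24 mm) placed by rejection sampling in an annulus 0.8–2.6 mm from
  the fovea — zero placement mass in the central 1 mm, superior
  quadrant weighted 1.3× — outside the dilated lesion and mutually
  non-overlapping, so per-mound closed forms add. The mound lifts the
  EZ/ELM complex anteriorly above the deposit, so the measured EZ band
  (EZ inner → RPE inner) includes mound thickness, mirroring the
  segmentation rule that the EZ outer boundary is drawn above SDDs;
  truth EZ thickness records the core value excluding that elevation,
  so precise thickness-recovery checks use the RPE and ELM+MZ bands.
  Device-specific *visibility* scales the visible mound height
  (standard 1.0, high_res 1.5), emulating larger SDD volumes at higher
  resolution. The visible volume above a threshold *t* of a mound with
  peak *h* and radius *r* is `π h r² s (1 − s/2)` with `s = 1 − t/h` —
  the full-column thickness integrated where the profile exceeds *t*,
  matching what thresholded quantification measures.
* **Drusen**: Gaussian elevations of the RPE reference surface; they
  shift all surfaces equally and leave band thicknesses untouched.
* **Noise**: an independent Gaussian jitter per surface per column
  (SD 1.0 µm) with crossings projected back onto the
  anterior-to-posterior ordering (the posterior surface is raised onto
  the anterior one), plus a per-eye × device × band session offset
  (SD 0.5 µm) representing between-acquisition variability. The jitter
  SD is set so that jitter-induced spurious EZ-outer/RPE-inner gaps
  exceed the 4 µm SDD threshold in well under 1% of columns; at larger
  jitter, thresholded noise would masquerade as SDD volume. One known
  small bias of the projection: where the nominal gap is zero, raising
  crossings inflates the inner RPE boundary by ~0.5 µm on average,
  thinning measured RPE slightly on *both* devices equally — device
  contrasts are unaffected.

What the phantom does **not** emulate: reflectivity, speckle,
hypertransmission, RPE phenotypes, within-eye spatial covariance of
thickness beyond a smooth trend, or loss-area differences between
devices (device effects act on thickness and SDD visibility only).
Passing recovery tests therefore demonstrates correctness of the
geometry, masking, integration and model code — not segmentation
accuracy on real scans.

## Statistics

Comparisons use linear mixed-effects models (REML, via `lme4`):
`value ~ device` (or region) with random intercepts for patient and
for eye nested in patient, honoring the inclusion of both eyes of some
patients. If the two-level fit is singular, the intercept whose
variance collapsed is dropped and the result is *flagged* degraded,
never silently: typically the patient intercept when few patients
contribute fellow eyes, which preserves the paired within-eye design.
P-values and 95% CIs use Satterthwaite degrees of freedom (via
`lmerTest`) rather than a Wald-z approximation: with reduced cohorts
of 10–20 eyes the t correction keeps type-I error near nominal, and at
40 eyes the two are practically identical.

Right-skewed whole-field loss areas are compared on the natural-log
scale; exact zeros are offset by half the smallest positive observed
value (a documented, configurable choice — the handling of zeros under
the log is not standardized), and means, CIs and the contrast (then a
ratio) are back-transformed by exponentiation. Bonferroni correction
is `min(1, m·p)` with the family size `m` stated per family (the seven
whole-field device outcomes; all region pairs). Model software, CI
method and zero-handling are this package's declared conventions, not
inferences about any published analysis.

## Problem sizes and numerical choices

Validation uses three scales, chosen to keep the full suite fast while
still exercising the default geometry: (i) closed-form and
printed-arithmetic checks at trivial cost; (ii) single-eye recovery on
the full default 1024 × 49 lattice, where rasterized loss areas land
within 2% of πab (the discretization bound scales with perimeter ×
cell size) and SDD volumes within 5% of closed-form totals; (iii)
repeated-simulation checks (CI coverage of an injected −5.1 µm RPE
device effect over 100 re-seeded cohorts; null rejection rate over 200
cohorts) on a reduced design of 16 patients / 20 eyes on 64 × 9
lattices, small enough for hundreds of mixed-model refits. Tie-breaks
(half-open rings, counter-clockwise diagonal assignment), the strict
SDD threshold, tolerated sub-µm gap crossings and the lesion clip
policy are all fixed conventions stated above.

## Limitations

* Loss areas assume the segmentation encodes loss as missing surfaces;
  reflectivity-based loss detection and hypertransmission are out of
  scope.
* The nominal-area normalization can exceed 100% marginally by
  discretization, and the 6-mm circle is slightly clipped by a 20°
  field — both reported, not corrected.
* Published cohort means and p-values derive from unavailable patient
  data; the phantom emulates their structure, so agreement in
  magnitude is by construction of the defaults, and only the recovery
  and calibration properties above are claims the test suite actually
  verifies.
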