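---
title: "Quantitative ichnology of sediment-core CT volumes with ichnoCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ichnology of sediment-core CT volumes with ichnoCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bioturbation — the reworking of sediment by burrowing organisms — is a
primary archive of past benthic conditions, but in soft, unconsolidated
marine cores most of it is read from the slabbed core surface: a single
two-dimensional cut. X-ray computed tomography of archive halves (6.2 cm
diameter half-cylinders) images the interior in 3D, and burrows whose fills
are denser than the host mud (pyritised fills above all) appear as
high-attenuation bodies that can be isolated, measured and tracked
downcore. `ichnoCT` implements that workflow as a tested pipeline:

1. **core_prep** — locate the half-core in the scan, delete the liner and a
   ~2 mm artefact rim;
2. **burrow_segmentation** — marker-based watershed isolation of dense
   fills, connected-component separation, minimum-diameter filtering;
3. **shape_metrics** — per-burrow morphometrics: volume, best-fit axis,
   length, cylinder-equivalent diameter, z-orientation, size and
   orientation classes;
4. **downcore_analysis** — per-slice orientation volume-percentages,
   H / V / V-H interval classification, Bioturbation Index (BI, 0–6)
   logging, and combination with a 2D core-surface ichnology table;
5. **overlay_viz** — burrows projected over the core-face image and
   depth-aligned orientation strip charts;
6. **synthetic_core** — a ground-truthed simulator that generates half-core
   CT phantoms so every step above can be validated against known truth.

Because real core scans of this kind are not publicly deposited, the
package's empirical claims are recovery claims on simulated scenes; the
test suite and `scripts/acceptance.R` recompute all of them.

## Conventions

Volumes are `(x, y, z)` arrays with z the downcore axis; slice index k is
at depth `depth_origin_cm + (k - 1/2) * dz`. Spacing defaults to
0.351 × 0.351 × 0.5 mm, the usual clinical-CT reconstruction grid for core
scans, and is always explicit configuration: image stacks carry no spacing
metadata and DICOM spacing tags are read but can be overridden. Depths are
reported in cm, geometry internally in mm.

## The synthetic scene model

`generate_core()` rasterises a `scene_spec()`: a half-cylinder of host
sediment (attenuation `host_mean`, default 1000, with i.i.d. Gaussian noise
`host_sigma`, default 25 — arbitrary CT units), wrapped by a liner shell
whose contrast against sediment defaults to 0 (real core liners attenuate
like soft mud, which is why they must be removed geometrically), surrounded
by air at `host_mean - 10 * host_sigma`. Burrows are straight tubes or
branched pinch-and-swell networks (random-walk trunk, Poisson-placed
branches, sinusoidal radius modulation); a voxel belongs to a burrow iff
its centre lies inside the analytic tube, which makes voxel counts
checkable by brute force. Fill attenuation is `host_mean + contrast *
host_sigma` *before* noise, so `contrast` is expressed in noise standard
deviations and the noise realisation is identical across contrast sweeps
of the same seed. Overlaps resolve to the earlier-listed burrow; burrows
leaving the core are clipped with a warning.

What the simulator deliberately does **not** model: partial-volume
blurring, beam hardening, streaks, reconstruction kernels, or the internal
spreiten/backfill texture of real burrows (CT cannot resolve those
anyway). Passing recovery tests therefore demonstrates correctness of the
algorithms under the stated noise model, not performance on every real
scan; in particular real fills at low density contrast will be missed, as
the contrast-degradation experiment makes explicit.

Presets: `tiny_vertical` (0.5–1 mm steep tubes, Trichichnus-like),
`thick_horizontal` (> 0.5 cm sub-horizontal tubes, Thalassinoides-like),
`branched` (sub-millimetre pinch-and-swell networks, Virgaichnus-like) and
`mixed` — four 10-cm bands alternating vertical- and horizontal-dominated
populations, with the construction truth attached for interval-recovery
tests. `random_scene()` draws 10–30 disjoint tubes (1.5–3 mm diameter,
15–60 mm length, contrast 6–10 sigma) for segmentation and orientation
recovery experiments.

## Preprocessing

`fit_core_geometry()` separates core from air at the midpoint of the
bimodal histogram (1D 2-means), projects occupancy to the x–y plane and
fits a circle to the boundary. A plain least-squares circle is dragged
toward the flat slab-face chord, so the fit is a consensus search:
circumcircles of boundary-point triples scored by inlier count (fixed
internal seed, hence deterministic), refined by least squares on the arc
inliers. The liner attenuates like sediment, so the detected boundary is
the liner's *outer* wall; the known wall thickness (`liner_thickness_mm`,
default 1.5 mm) is subtracted to report the sediment radius. The face
normal points from the occupied centroid through the axis (the half-disc
centroid sits 4R/3π behind the face).

`remove_liner_and_rim()` excludes everything outside the fitted half-core,
a radial band of `rim_mm` (default 2 mm) under the curved surface, and —
because coring disturbance affects the cut face too — the same band under
the slab face (`trim_face = TRUE`; the paper trail on whether the 2 mm was
measured radially or in the slab plane is ambiguous, so both are trimmed
and configurable). Exclusion is carried as a logical mask, never as a
sentinel value in the data grid, keeping attenuation statistics clean.

## Segmentation

Markers come from threshold segmentation. The **fill** threshold is
`host median + marker_nsigma_fg * sigma_MAD` (default 4.5) computed on
retained voxels. An intensity-quantile threshold over all voxels was
considered and rejected: whenever segmentable fills occupy more than
`1 - q` of the volume — routine in densely bioturbated intervals — a
quantile threshold climbs into the fill distribution and entire
moderate-contrast burrows lose their markers. A background-relative
threshold is independent of fill abundance and is what an analyst
effectively chooses when thresholding against background. **Host** markers
are voxels below the `marker_quantile_bg` quantile (default 0.5, the
median). Fill-marker clusters smaller than `min_marker_voxels` (default 8,
26-connected — about half a cubic half-millimetre, the cross-section of
the smallest segmentable burrow) are discarded as noise specks; without
this, isolated noise voxels seed watershed basins that occasionally
survive the diameter filter, and a contrast-0 control would not return an
exactly empty result.

`watershed_segment()` priority-floods the gradient-magnitude surface
(central differences per mm; `inverted_intensity` available) from both
marker classes simultaneously; ties break FIFO, so the partition is
deterministic, covers every retained voxel, and always contains the fill
markers in the fill mask. `separate_components()` labels 6-connected
components (26 optional; face connectivity avoids spurious diagonal
bridges between tiny burrows), ordered by decreasing voxel count with
(z, y, x)-scan-order tie-breaking. `filter_small()` removes components
with cylinder-equivalent diameter under 1 mm, the practical CT resolution
limit for these fills.

## Morphometrics

For each component the principal axis is the leading eigenvector of the
voxel-centre covariance (an endpoint-chord estimator is available as
`axis_estimator = "chord"`); its sign is fixed to nonnegative z so the
z-angle `asin(|axis_z|)` lies in [0°, 90°] (0 = horizontal, 90 =
vertical). Length is the extent of voxel centres projected on the axis,
and "diameter" of an irregular body is the cylinder-equivalent
`2 * sqrt(V / (pi * L))` — orientation-free and exact for long tubes
(within 15% at aspect ratio 10). Size classes split at 5 mm equivalent
diameter (`tiny` strictly under 0.5 cm); orientation classes split at a
45° cutoff (`sub_vertical` at or above). Branched networks are treated as
one component with one global axis — no skeleton decomposition — matching
per-trace practice. Single-voxel components are degenerate: length is set
to the largest voxel spacing, the z-angle is `NA`, and they are excluded
from orientation profiles (the default pipeline removes them earlier via
the diameter filter).

## Downcore profiles, intervals and BI

`slice_profiles()` reports, per slice, the volume-% of segmented fill
belonging to sub-vertical vs sub-horizontal components (normalised per
slice, matching depth-resolved orientation logs; whole-section
normalisation would only rescale the curves) and the bioturbated fraction
`100 * fill / retained`. The CT bioturbated fraction is a *proxy*: CT sees
only high-contrast fills, so it under-represents total bioturbation — the
reason the 2D combination step exists.

`classify_intervals()` smooths with a centred `window_cm` (default 2 cm)
moving window. Smoothing is volume-weighted — the ratio of windowed
vertical-voxel and classed-voxel sums — rather than an average of
per-slice percentages, so slices with three fill voxels do not carry the
weight of slices with three thousand; where slices are equally filled the
two coincide. A depth is `V` when the smoothed vertical share is at least
`dominance` (default 60%), `H` at or below 100 − dominance, `V/H`
between; windows with no fill inherit the nearest preceding class (the
following one at the section top), and runs merge into intervals that tile
the section exactly.

`bioturbation_index()` averages the bioturbated fraction over `bin_cm`
(default 2 cm) bins and maps the means through monotone grade bands, by
default 0% → 0, (0,4] → 1, (4,30] → 2, (30,60] → 3, (60,90] → 4,
(90,99.9] → 5, >99.9 → 6 — the standard visual-comparison grading, fully
configurable. `combine_bi()` rebins a CT log and a 2D-image log onto the
intersection of their coverage and takes the per-bin maximum, adding one
grade (capped at 6) when both are nonzero and the 2D table flags its
structures as disjoint from the CT fills. The maximum rule is this
package's explicit formalisation of "the combination is never below either
input"; the +1 bonus encodes that two disjoint assemblages rework more
sediment than either alone.

## Validation scale and determinism

The acceptance experiments in `tests/testthat/test-acceptance.R` use
twenty 256 × 128 × 400-voxel scenes (10–30 tubes each, contrast 6–10
sigma), one contrast sweep at {0, 2, 4, 6, 8} sigma, and one `mixed`
preset section of 40 cm; `scripts/acceptance.R` reruns the same
measurements on eight scenes so a full report builds in a few minutes.
Every random draw — scene placement, noise, branched walks — descends
from explicit integer seeds, and generation is reproducible bit for bit.

## Known limitations

* Only high-contrast (e.g. pyritised or air-filled) structures are
  segmentable; the BI from CT alone is a lower bound.
* Touching burrows of similar intensity merge into one component unless
  marker placement separates them; no texture- or learning-based
  separation is attempted.
* The axis model assumes tube-like bodies; for strongly helicoidal or
  sheet-like traces the equivalent diameter and z-angle are summary
  statistics, not faithful shape descriptors.
* DICOM support covers single-frame little-endian series (explicit or
  implicit VR) — sufficient for scanner exports of this kind, not a
  general DICOM implementation.
* Per-slice axis wobble is not corrected beyond the single fitted axis.
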