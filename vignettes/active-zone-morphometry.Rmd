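---
title: "Synthetic active-zone scenes and AZM morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic active-zone scenes and AZM morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azmetrics)
```

## The biological system and the measurement problem

Active zones at the frog neuromuscular junction are narrow bands on the
presynaptic membrane where synaptic vesicles (50-60 nm in diameter) dock
and fuse. Dense networks of macromolecules — active zone material (AZM) —
attach to the membrane next to the docked vesicles and extend roughly 75 nm
into the cytoplasm. Electron tomography resolves the AZM into classed,
elongate macromolecules organized in three layers: *beams*, *ribs* and
*pegs* in the superficial ~15 nm; *steps* and *spars* in the intermediate
~15 nm; *masts*, *booms* and *topmasts* in the deep layer. Ribs, spars and
booms run from the core (beam/step/mast) stack to docked vesicles; *pins*
link docked vesicles directly to the membrane outside the main body;
topmasts link mast tops to undocked vesicles. In stimulated terminals,
undocked vesicles near vacated docking sites carry connections to the same
classes, with both the number of classes and the total number of
connections growing as the vesicle approaches the membrane — the anatomical
signature of a sequential docking mechanism (booms first, then spars, then
ribs and pins).

The raw tomograms behind these observations are not publicly available.
This package therefore does two things:

1. it implements the *measurement operators* of the study — filament
   dimensions, z-compression estimation and stretch correction, in-plane
   angles of approach, per-vesicle connection counts, unit-sphere
   co-alignment of connection sites, distance-binned connectivity — so they
   can be applied to any scene expressed in the package's JSON schema; and
2. it provides a *seeded synthetic generator* whose defaults are the
   published class dimensions and connection statistics, so the pipeline
   can be validated end-to-end by parameter recovery.

## Scene model and conventions

A `Scene` holds a flat membrane (the plane z = 0, cytoplasm at +z), a
vesicle table (center, radius, z semi-axis, docking state), and a filament
table (classed polylines with diameters and attachments). The band's long
axis is +y, the transverse axis x. Connection sites are never stored: they
are derived, bijectively, as the vesicle-bound filament endpoints, which
makes the site-conservation invariant structural. The membrane's curvature
into the synaptic cleft (the active-zone ridge) is not modeled: every
statistic in scope is defined relative to the flat portion of the membrane,
so a flat plane makes "distance to the presynaptic membrane" exactly the z
coordinate.

Two tolerances matter: filament endpoints must lie on their vesicle's
surface within 0.5 nm, and docked vesicles must contact the membrane
(center z equal to the z semi-axis) within 0.5 nm. Both are well below the
2-3 nm resolution of the reconstructions the measurements come from.
`validateScene()` reports violations as data rather than raising errors, so
defective scenes can be constructed, serialized-rejected, and diagnosed.

## What the generator draws, and why

`defaultSceneConfig()` carries every distribution as `c(mean, sd)`; the
defaults are the published values (lengths/diameters per class, step
spacing 48.8 +/- 14.9 nm, counts 3.9 ribs / 2.2 spars / 4.1 pins per
vesicle, 10.6 booms per mast, site depths 7.7 nm with spar/boom offsets
10.3/24.2 nm, boom origins 39.0 +/- 7.7 nm up the mast, approach angles
10.6/23.3/30.0 degrees). Where the study states only a range, the generator
uses the minimal assumption: vesicle diameters uniform on 50-60 nm,
topmasts 1-2 per mast, mast strand counts 4-9, pins clipped to the stated
3-5 range.

Distributional choices:

* Continuous lengths and depths are normal draws truncated at physical
  bounds (positive lengths; rib and pin sites confined to the 15-nm
  superficial layer). Truncation points sit 2 SD or more from the means,
  so the induced bias is below 0.1 nm everywhere.
* Integer counts are normal draws rounded and clipped to their stated
  ranges. Rounding preserves the means to within ~0.02 at the configured
  SDs.
* In-plane approach angles are generated directly in the horizontal
  projection with a random sign, i.e. the unsigned measured angle is a
  *folded* normal. This is what "random sign plus unsigned measurement"
  implies, and its bias (~0.2 degrees for ribs) is several times smaller
  than a zero-truncated draw would produce. Because the angle is generated
  in the measurement plane and the out-of-plane rise is set by endpoint
  depths, the projection protocol recovers the configured distribution with
  no projection-bias correction.
* Filaments are constructed *backwards from the measurement*: the
  vesicle-bound endpoint is placed at the drawn class depth on the facing
  hemisphere, then the origin endpoint is computed so that the arc length
  and the projected angle equal the drawn values exactly. Origin heights
  (beam top for ribs, step plane for spars, the drawn 39-nm mast height for
  booms) are honored to within the unit-vector constraint.
* Each mast's boom total is drawn once and split as evenly as possible over
  its four tetrad slots with random remainders, matching the observation
  that booms terminate on tetrad vesicles in nearly equal numbers. Note a
  consequence inherited from the published statistics themselves: two
  masts at 10.6/4 booms per slot give ~5.3 booms per vesicle, while the
  printed per-vesicle figure is 5.0 +/- 2.0; the generator parameterizes
  per-mast counts and lets the per-vesicle count emerge.
* Band layout: steps at truncated-normal spacings (minimum 15 nm) along a
  straight band; docked vesicles at the midpoints between consecutive
  steps, two rows mirrored in x, so each step is centered in a tetrad. The
  occasional angular changes of real bands are not generated — all count
  statistics being emulated were reported for straight stretches.

Activated scenes vacate a configured fraction (default one half) of docking
sites, replace the former vesicle with a flattened `vacated_marker`, and
place an undocked vesicle above the site at a membrane distance drawn
uniformly on 4-42 nm. Wiring follows the distance-bin rules (booms always;
spars and ribs gated by bin; pins only within 15 nm). Vesicles whose drawn
distance falls in one of the published inter-bin gaps (16-17, 24-29 nm) are
wired by the nearest rule but always reported as *unbinned* by the binning
operators — the bins are quoted verbatim and gap ownership is not invented.
Undocked pin length is modeled additively as distance + gamma slack, with
the gamma moments set so the pooled mean/SD recover 16.5 +/- 6.5 nm under
the default distance sampler; this gives the reported
length-grows-with-distance behavior with an exact pooled mean, which a
truncated draw of total length (conditioned on reaching the vesicle) cannot
provide. One docked slot optionally carries a `fused_omega` vesicle
retaining the full docked complement of ribs, spars and booms but no pins
(pins near fusion pores could not be discerned in the source material).

Seeding: one master seed; layout, wiring and topmast stages each derive a
deterministic 32-bit child seed, so scenes are byte-reproducible and
sub-stages can be varied independently.

## What the generator does *not* emulate

No segmentation noise, stain variability, missing-wedge anisotropy or
operator error; no vesicle-vesicle excluded volume (rows at ~49 nm spacing
with 50-60 nm vesicles overlap slightly, as a geometric idealization); no
membrane ridge curvature; no curved filament midlines (lengths are exact
by construction rather than estimated from voxels); no peg class (excluded
from the source analysis). Parameter-recovery tests therefore validate the
*measurement operators and their statistical plumbing* — they show the
pipeline is unbiased on clean geometry, not that it is robust to
segmentation artifacts in real tomograms.

## Measurement operators

* `filamentLengths()` is polyline arc length along the midline.
* `angleOfApproach()` projects the first-to-last path direction onto the
  horizontal plane and returns the unsigned angle to the perpendicular of
  the band axis, in [0, 90] degrees; vertical filaments raise a distinct
  error rather than returning an arbitrary angle.
* `estimateCompressionRatio()` is the mean over vesicles of z diameter to
  x-y diameter; `applyZCompression()` stores oblateness explicitly (z
  semi-axis = radius x ratio) so the estimate is exact by construction, and
  `zStretchCorrect(factor = 1/ratio)` inverts it to machine precision.
  `zStretchProtocol()` applies the conventional 1.2 stretch when the
  estimate falls below 0.9.
* `connectionCounts()` tabulates per-vesicle class counts with the
  main-body total (rib + spar + boom) used by the connectivity analysis.
* All SDs are sample SDs (n-1): the emulated tables report small-n sample
  statistics.

## Sphere alignment

Connection sites are mapped per vesicle to the unit sphere
((site - center)/radius), normalizing vesicle-size variability. Rough
alignment applies the minimal rotation carrying each vesicle's mean site
direction onto +x; perfectly antipodal site sets (zero mean) fall back to
identity with a warning. Fine alignment maximizes *rib connection overlap*
across vesicles.

The published overlap equation is not reproducible from the source
material (it survives only as a low-resolution figure), so the package
defines the objective it needs: a Gaussian kernel on great-circle distance,
summed over inter-vesicle rib pairs, with bandwidth 0.3 rad by default.
This form is smooth, symmetric under vesicle relabeling, invariant under a
common rotation of all vesicles, and has a brute-force-checkable optimum;
any kernel with those invariances could be swapped in via the bandwidth/
objective seam. The optimizer is deterministic coordinate ascent over
vesicles: a 10-degree z-y-z Euler grid, ties broken toward the smaller
rotation angle, followed by Nelder-Mead refinement; the current rotation
always competes with the candidates, so the objective trace is monotone
non-decreasing, and on two- and three-vesicle instances the result is
checked against an exhaustive 5-degree grid oracle.

Class centroid depths use the depth-difference reading of the published
normalization: each class centroid's membrane distance is the mean z of its
sites, normalized per vesicle to that vesicle's rib centroid. (A 3D
centroid-to-centroid distance is the other possible reading; the
depth-difference one matches the normalization to "the average position of
the rib connection sites per individual vesicle" and is what the recovery
targets use.)

## Statistics and their sample sizes

Recovery tests compare pooled measurements against the published means
within three standard errors of the *published* statistic (printed SD over
the study's n). The suite uses 30 default 500-nm scenes (~520 docked
vesicles, ~2000 ribs) for dimension/count/angle recovery, a 20-vesicle
cohort for depth statistics, and activated scenes pooled until the outer
distance bins hold 20 vesicles each — sizes chosen to keep every recovery
target's estimator noise well inside its tolerance while the whole suite
runs in about a minute.

One statistical subtlety is documented rather than hidden: the published
"not significantly different" comparisons between undocked-near-vacated-
site profiles and the docked profile hold *at the study's sample sizes*
(16 undocked vesicles split across bins, 20 docked vesicles from 3 data
sets). The configured bin means genuinely differ from the docked means
(e.g. mid-bin spars 1.7 vs docked 2.2), so a t-test at large pooled n
correctly rejects. The acceptance suite therefore runs those comparisons at
the study scale, and treats the explicitly significant published contrasts
(far-bin spars, mid-bin ribs) as positive controls. Welch's unequal-
variance t-test is used throughout, computed from profile summaries
(mean/SD/n per class); zero-variance degenerate cases return t = 0 for
identical constants.

Similarly, site-depth bands overlap slightly by construction (rib sites
7.7 +/- 3.3 nm versus spar centroids ~10.3 nm deeper): the ring of rib and
pin sites around the fusion domain is asserted as ring-centroid strictly
superficial to the spar centroid, ring sites confined to the superficial
layer, and azimuthal span above 180 degrees — not as every single ring site
lying above every spar site, which the configured distributions (and the
published site maps) do not support.

## Numerical and serialization choices

Scene JSON uses canonical key order and 6-decimal floats (0.000001 nm,
far below all tolerances), so identical scenes serialize byte-identically
and `generate -> measure -> align -> profile` is reproducible to the digest
level given (config, seed). Unknown JSON fields are rejected; parse,
schema, version and reference failures raise distinct condition classes.
Infeasible site depths (beyond the vesicle sphere) are clipped and recorded
as warnings in the scene metadata rather than failing generation.

## Known limitations

* Step horizontal/vertical diameters are generator attributes; no operator
  estimates them from geometry (the source measured them with a thickness
  tool on surface models that are out of scope here).
* The overlap objective is a declared substitute, not a reconstruction of
  the unpublished equation.
* Per-vesicle boom counts inherit the source's own internal discrepancy
  (per-mast 10.6/4 x 2 vs per-vesicle 5.0).
* The generator's regularity (straight bands, exact tetrads) makes some
  recovered SDs smaller than the printed ones; means, not SDs, are the
  recovery surface.
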