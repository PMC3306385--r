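# azmetrics

Quantitative morphometry of **active zone material (AZM)** at frog
neuromuscular junctions, at the scale of electron-tomographic
reconstructions — as a tested, fully synthetic, desk-scale pipeline.

At frog neuromuscular junctions, synaptic vesicles dock in rows along
narrow AZM bands on the presynaptic membrane. The AZM resolves into
classed macromolecules in three layers — beams/ribs (superficial),
steps/spars (intermediate), masts/booms/topmasts (deep) — plus pins that
tie docked vesicles directly to the membrane. Each docked vesicle is
connected to ~4 ribs, ~2 spars, ~5 booms and ~4 pins, with the connection
sites of each class centered at a characteristic membrane depth
(ribs ≈ 7.7 nm; spars and booms ≈ 10.3 and 24.2 nm deeper). In activated
terminals, undocked vesicles re-occupying vacated docking sites acquire
connections class by class as they approach: booms first (29–42 nm),
then spars (17–24 nm), then ribs and pins (4–16 nm), with the main-body
connection total rising ≈ 5 → 9 → 11.

The original tomograms are not public, so the package pairs the
measurement procedures with a seeded generator of synthetic 3D scenes
whose defaults are the published statistics; recovering those statistics
from generated scenes is the package's acceptance surface.

## What it provides

* **Scene model** (`Scene`, S4): flat membrane at z = 0, vesicle and
  filament tables in nm coordinates, derived connection sites, invariant
  checking as data (`validateScene()`), versioned JSON serialization with
  byte-stable output (`readScene()` / `writeScene()`).
* **Synthetic generator** (`generateRestingScene()`,
  `generateActivatedScene()`, `applyZCompression()`): band layout with
  steps centered in vesicle tetrads, class-wise wiring, distance-binned
  wiring of undocked vesicles at vacated sites, artificial z-compression.
* **Morphometry** (`morphometrySummary()` and friends): arc lengths,
  diameters, step spacing, unsigned in-plane angles of approach via the
  projection protocol, per-vesicle connection counts, pin lengths by
  docking state, z-compression estimation and the 1.2× stretch protocol.
* **Sphere alignment** (`sphereMap()`, `roughAlign()`, `fineAlign()`):
  per-vesicle connection sites on the unit sphere, co-aligned by
  maximizing a Gaussian-kernel rib-connection overlap
  `O = Σ_pairs exp(−d_gc² / 2w²)` over per-vesicle rotations
  (Euler-grid coordinate ascent + local refinement), plus class-centroid
  depth statistics and one-way ANOVA separation.
* **Connectivity** (`binUndocked()`, `binnedProfile()`,
  `compareProfiles()`): closed distance bins with explicit gap handling,
  per-bin class profiles, Welch t comparisons against the docked profile.
* **CLI**: `inst/exec/azmetrics {generate, measure, align, profile,
  report}` — a thin Rscript over the exported functions.

## Worked example

```r
library(azmetrics)

scene <- generateRestingScene(seed = 1)
scene
#> Scene (active zone, nm coordinates)
#>   membrane extent: x [-150, 150], y [0, 500]
#>   vesicles: 30 (docked: 16, undocked: 14)
#>   filaments: 429 (beam: 7, boom: 84, mast: 9, non_azm: 148, pin: 63,
#>               rib: 59, spar: 36, step: 9, topmast: 14)
#>   connection sites: 404
```

A 500-nm band holds ~9 steps (one mast each) flanked by two rows of docked
vesicles; the 14 undocked vesicles hang from topmasts deep to the band.
Measuring it:

```r
morphometrySummary(scene)
#> MorphometrySummary
#>   class dimensions (nm):
#>    class length_mean length_sd length_n diameter_mean diameter_sd diameter_n
#>     beam       71.43     18.34        7         11.49       0.523          7
#>     step       27.38      6.30        9         24.45       5.611          9
#>     mast       31.06      5.00        9         23.85       2.890          9
#>      rib       27.32      6.51       59          9.46       1.380         59
#>      pin        8.24      2.97       63          4.87       1.236         63
#>     spar       19.84      7.64       36          7.29       1.146         36
#>     boom       17.54      4.70       84          6.57       1.391         84
#>  topmast       21.03      7.38       14          6.85       2.251         14
#>   step spacing: 52.8 +/- 14.2 nm (n = 8)
#>   approach angles (degrees):
#>  class mean    sd  n
#>   boom 31.2 13.38 84
#>    rib 11.0  6.02 59
#>   spar 17.6  7.74 36
#>   docked vesicles: 16; mean connections rib 3.7, spar 2.2, boom 5.2, pin 3.9
```

Single-scene numbers scatter around the configured values (rib length
27.3 vs 27.9 nm; spacing 52.8 vs 48.8 nm at n = 8); pooled over ~30 seeds
they converge within three standard errors. Connection-site depths and an
activated-scene connectivity profile:

```r
classCentroidDepths(scene)
#>   class depth_mean depth_sd offset_mean offset_sd  n
#> 1   rib       8.64     1.52         0.0      0.00 16
#> 2  spar      19.62     3.94        11.0      3.23 16
#> 3  boom      32.24     3.18        23.6      2.96 16

act <- generateActivatedScene(seed = 2)
binnedProfile(act)[, c("bin", "n", "rib_mean", "spar_mean", "boom_mean",
                       "main_body_mean")]
#>        bin  n rib_mean spar_mean boom_mean main_body_mean
#> 1    29-42  2    0.000     0.000     4.500          4.500
#> 2    17-24  1    2.000     1.000     4.000          7.000
#> 3     4-16  3    4.000     1.667     5.333         11.000
#> 4 unbinned 15    0.267     0.133     0.533          0.933
```

Far-bin vesicles touch only booms; near-bin vesicles carry the full docked
complement (ribs appear, main-body total ≈ 11). The `unbinned` row holds
vesicles outside all bins — mostly the topmast-tethered pool deep to the
band, plus any vesicle falling in the 16–17 / 24–29 nm gaps, which are
reported rather than silently assigned.

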