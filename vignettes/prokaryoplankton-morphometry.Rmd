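---
title: "Morphometry of marine prokaryoplankton: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of marine prokaryoplankton: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prokmorph)
```

## The problem

Epifluorescence counts of DAPI-stained marine bacteria and archaea yield,
per cell, two linear dimensions — length L and width W (µm) — plus a
qualitative shape: straight, gently curved, C-shaped or S-shaped. From
these, a morphometric survey derives per-cell biovolume, carbon content,
a seven-class morphotype (cocci, coccobacilli, rods, curved rods,
vibrios, spirillae, filamentous), and community statistics: abundance
(PA, cells mL⁻¹), biomass (PB, µg C L⁻¹), the morphological index
M = %rods/%cocci, Shannon diversity of morphotype composition, volume
and length size-class spectra, and ordination against hydrographic and
nutrient covariates.

No per-cell data from such surveys of the Sicily Channel are deposited;
`prokmorph` therefore pairs every analysis step with a synthetic-data
generator parameterised by the published per-cruise summary tables
(three cruises: BANSIC-2012 and BANSIC-2013 in summer, NOVESAR-2013 in
winter), so the full pipeline — simulate → render → segment → measure →
classify → summarise → test — is reproducible and testable end to end.

## Generating cell populations

`builtin_cruise_profiles()` carries, per cruise and morphotype, the
published mean, standard deviation, minimum and maximum of L and W.
`sample_cells()` draws dimensions from a lognormal **matched on its
truncated moments**: the parameters (meanlog, sdlog) are solved (closed
form restricted moments + Nelder–Mead with a quasi-Newton polish) so
that the distribution *conditioned on the printed [min, max] range* has
the printed mean and sd. The printed statistics describe the observed,
range-limited cells, so matching the truncated rather than the parent
moments is what reproduces them: for the winter cocci
(0.40 ± 0.09 µm on [0.32, 0.95]) the sampled mean diameter is 0.40 and
the mean sphere volume 0.0396 µm³, against the published 0.039 ± 0.037.
Matching the parent moments instead would inflate the truncated mean to
≈ 0.43 µm and the mean volume to ≈ 0.045 µm³.

Three details matter:

* **Cocci are one measurement.** Coccoid cells are recorded as a single
  diameter, so the generator sets W = L exactly and the volume formula
  reduces to the sphere.
* **Orientation.** Every cell satisfies L ≥ W. Where a morphotype's
  printed W range overlaps its L range (coccobacilli, short rods), the
  constraint necessarily rejects some draws and shifts the realized
  marginal moments; where the ranges are disjoint (curved rods,
  vibrios, spirillae, cocci) recovery of the printed moments is exact.
  The moment-recovery tests use the disjoint classes.
* **Class consistency (`enforce_class`, default TRUE).** Independent
  L, W draws can land a "coccobacillus" in the cocci region
  (|L−W| < 0.10 µm) about 30% of the time. By default the generator
  redraws such pairs so ground-truth labels obey the operational
  definitions; set `enforce_class = FALSE` for pure moment emulation.
  Filamentous cells are exempt: their published length range starts at
  2.04 µm while the operational filament rule requires L > 4 µm, a
  documented inconsistency of the source — rejecting would truncate the
  published distribution.

A few published values are internally inconsistent and are repaired
once, visibly: the BANSIC-2013 curved-rod W bounds duplicate the L
bounds and exclude the W mean, and are replaced by the cruise's
total-cells W minimum (0.11 µm) and its rods' W maximum (0.65 µm); the
BANSIC-2013 filamentous W row (0.24 ± 0.012 on [0.21, 0.24]) has its
mean at the upper bound, which no truncated lognormal can attain — the
solver then returns the closest member of the family, weighting the
mean above the sd because first-moment fidelity drives the derived
biovolumes.

Morphotype **composition** per cruise was not published as numbers; the
defaults make cocci the most abundant class and fix the rods:cocci
ratio at the published morphological index (0.50, 0.90, 0.44). They are
plain numeric vectors on the profile object and can be overridden.
Cell density defaults to 10⁶ cells mL⁻¹, the published order of
magnitude. Environmental covariates (`sample_environment()`) are drawn
from normals with the published per-cruise mean/sd truncated to the
published ranges; a zero sd (the BANSIC-2013 phosphate column) yields
the constant mean.

## Rendering micrographs

`render_micrograph()` rasterises cells on a 1300 × 1030 px field at
0.106 µm px⁻¹, the survey's acquisition geometry. Straight cells are
capsules (rectangle L − W long, W wide, hemispherical caps); curved
rods and vibrios are constant-width circular arcs with total turning
drawn from (20°, 80°] and (100°, 240°]; spirillae are two
opposite-signed arcs (one inflection). Edge coverage ramps linearly
over one pixel, preserving sub-pixel geometry. The image is convolved
with a Gaussian PSF and Gaussian background noise is added.

Defaults: PSF σ = 0.1 µm and noise sd = 5% of the signal level. A
σ of 0.1 µm (FWHM ≈ 0.24 µm) matches the diffraction scale of the
100×/1.30 oil objective used for such counts; anything much blurrier
could not have resolved the 0.32 µm cells in the published tables, and
anything much sharper than the optics makes published sub-resolution
widths (down to 0.11 µm) alias into fragmented outlines the real
instrument could not produce.

Placement is uniform rejection sampling with a 10 px border margin and
a 5 px minimum clearance between cell outlines: at closer range the
overlapping PSF halos of two bright neighbours rise above the detection
threshold and merge. Overlap, clumping, uneven filtration, focus drift
and photobleaching are deliberately not modelled.

## Measuring cells

`segment_cells()` applies a global Otsu threshold floored at
median + 5 MAD (plain Otsu fails on sparse noisy fields), closes 1-px
breaks, labels connected components, and discards regions below 4 px or
touching the border. A second pass at a lower threshold rescues dim
cells that Otsu — anchored on the bright cells — misses entirely.

`measure_region()` then re-measures each region at 2× resolution on a
lightly smoothed crop cut at the **local half-maximum** (midway between
local background and object peak), where the boundary of a blurred
object sits at its true edge. All systematic size corrections follow
from one calibrated quantity, the total blur σ:

* widths of elongated cells come from the mask area given the skeleton
  length and are inverted through the exact half-max profile of a
  blurred slab;
* round and stubby cells use second-moment principal axes — the trace
  for near-isotropic regions (ordered eigenvalues of a noisy circular
  cloud are biased apart) and a stadium (capsule cross-section) fit
  otherwise, since an ellipse model overstates a capsule's width by up
  to 15% — inverted through the blurred-disc half-max model;
* lengths are skeleton geodesic length (Zhang–Suen thinning, longest
  path by double-sweep over an 8-connected graph) plus the width, with
  the cap tips reconstructed through the same disc model;
* curved cells are narrowed by σ²κ/2 (the concave inner edge's half-max
  contour shifts outward by ~σ²κ, the convex outer edge's inward by
  about half), with κ from the measured turning.

Curvature itself is read from the skeleton's signed deviations from its
end-to-end chord: a cubic fit averages staircase jitter over the whole
path; two opposite significant lobes mean an S (one inflection), a
single lobe a circular arc whose turning is τ = 4·atan(2h/c) from the
sagitta h and chord c, extrapolated over the capped tips.
`classify_curvature()` then applies the operational thresholds:
S if an inflection and τ ≥ 15°, C if no inflection and τ > 90°, curved
for 15° < τ ≤ 90°, else straight. The 15° and 90° cut-offs are
operational choices (the verbal definitions are qualitative) and are
arguments, not constants.

`calibrate_with_beads()` anchors the scale on a rendered field of
monosized 2.13 µm latex beads, as the survey did: the mean measured
bead diameter fixes the length/width scales, and an erf-profile fit to
the bead edges estimates the blur σ used by all the inversions above.
Two discretisation constants — a 0.25 px boundary-sampling offset on
moment dimensions and 1.5 px of thinning erosion on skeleton tips —
were calibrated once on controlled rendered discs and capsules across
blur and noise settings.

With all of this in place, rendering 500 cells per cruise and measuring
them back recovers per-morphotype mean L and W within 2 px noise-free
and within ~5% at default noise (for classes with enough cells to
estimate a mean), and the measured curvature class agrees with the
generating one for ≥ 95–97% of cells. Widths below ~0.25 µm (2.4 px)
remain the hardest quantity: they are below the optical resolution, and
per-cell errors there are a substantial fraction of a pixel, which is
why population means of very rare thin classes (a handful of
filamentous cells per 500) are not meaningfully testable.

`abundance_from_counts()` converts field counts to cells mL⁻¹ as
mean count × (filtration area / field area) / volume filtered, with the
SE propagated from the count sd; the default effective filtration area
(201.06 mm², a 16 mm diameter) is a conventional value, not a published
one, and is an argument.

## Traits and summaries

`classify_morphotype()` applies the operational rules in a fixed order:
filament (L > 4 µm, strict) → S → C → curved → rods (L ≥ 2W) → cocci
(L − W < 0.10 µm, strict) → coccobacilli. Putting the filament test
first means a 5 µm curved cell is filamentous; the source gives no
ordering, so this is a documented package choice (an argument-level
threshold change reverses it). Boundary conventions: a difference of
exactly 0.10 µm is *not* cocci, exactly twice the width *is* a rod,
exactly 4.0 µm is *not* filamentous; comparisons carry a 10⁻⁹ µm guard
so printed boundary values resolve as documented despite floating-point
subtraction.

Biovolume is the capped cylinder V = (π/4)·W²·(L − W/3), the standard
two-dimension formula for DAPI morphometry; at L = W it reduces exactly
to the sphere (π/6)L³, which keeps the cocci-as-diameter convention
internally consistent. Carbon content is configurable
(`carbon_model()`): the flat default of 350 fg C µm⁻³ reproduces the
published winter cocci value (0.039 µm³ × 350 ≈ 14 fg C cell⁻¹); an
allometric option CCC = 218·V^0.86 is provided because the conversion
literature for this method family is allometric. Neither choice
reproduces every published CCC; both are stated wherever used. Biomass
closes the units: PB (µg C L⁻¹) = PA × mean CCC × 10⁻⁶.

`size_class_histogram()` bins volumes into 0.03 µm³ classes from
0.02 to 0.20 µm³ with an open top class (the published labels name only
three classes; uniform 0.03-wide interpolation between them is the
package's reading) and lengths into 0.4 µm classes from zero.
`morphological_index()` is the rods:cocci count ratio (the published
percentages share a denominator), undefined when no cocci were counted.

## Community statistics

`shannon_index()` (via `vegan::diversity`, rebased; default base 2) is
generic over the category set: the published per-sample H′ values reach
3.22, which exceeds log₂7 for seven morphotypes, so the exact category
set used there (plausibly morphotype × size class) is not recoverable —
a documented limitation. `kruskal_wallis()` wraps the tie-corrected
rank statistic with a χ² p-value; the test suite checks it against an
exact-rank brute-force oracle and, for tiny samples, the full
permutation distribution. `pca_ordination()` log10(x+1)-transforms,
uses the correlation matrix by default (the covariates carry mixed
units), drops incomplete rows with a warning, and fixes component signs
by making each component's largest-magnitude loading positive, so
ordinations are reproducible to the digit. `distribution_summary()`
returns the mean/sd/median plus a Gaussian-kernel density — the
empirical shape that bean-style plots display — and
`virus_prokaryote_ratio()` is the scalar VA/PA.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit `seed`; identical
arguments and seed give byte-identical outputs, and `run_pipeline()`
stamps every artifact with the seed and a hash of the configuration.
The test suite generates all of its data programmatically: moment
recovery uses 2 × 10⁵ draws for the volume anchor and 5 × 10⁴ per
profile; rendering closure uses 500 cells per cruise (one full field
each) noise-free and at default noise; the classifier is checked
exhaustively on a 0.05 µm grid (≈ 51,000 cases) against an
independently coded rule oracle. The `analysis/` scripts simulate the
three cruises at the survey's own sample sizes (4573, 1344, 2852
cells).

## Known limitations

* Synthetic micrographs idealise real fields: no cell clumping or
  overlap, uniform focus and illumination, Gaussian noise, and capsule
  or constant-width-arc geometry. Passing closure tests certify the
  measurement chain on such images, not on real micrographs.
* Sub-resolution widths (< ~0.25 µm) carry per-cell errors that are a
  large fraction of a pixel; only class means over tens of cells are
  meaningful there.
* Morphotype compositions, per-sample abundances and the H′ category
  set are package choices constrained by, but not printed in, the
  source; quantities derived from them (PB levels, H′ ranges) are
  structurally comparable but not numerically anchored.
* The carbon model is a convention; published CCC ranges per morphotype
  cannot all be reproduced by any single flat or allometric choice.
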