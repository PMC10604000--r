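---
title: "Measuring sagittal spinopelvic alignment from segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sagittal spinopelvic alignment from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinalign)
```

## The measurement model

`spinalign` computes thirteen sagittal alignment and spinopelvic parameters
from per-structure instance segmentations of a standing whole-spine lateral
radiograph. The input is a set of labeled masks — vertebral bodies C2
through L5, the sacrum, and one or two femoral heads — either as polygon
annotations (COCO dialect) or binary rasters. Everything downstream is
plain 2D geometry on a small set of landmark points:

* the four endplate corners of each vertebral body,
* the anterior and posterior corners (and midpoint) of the sacral superior
  endplate,
* the femoral-head center (midpoint of the two per-head centroids, or the
  single centroid when the heads project onto each other).

All construction lines reduce to three primitives: the slope of an endplate
against the image horizontal, the signed angle between two directions, and
the horizontal offset between a vertical plumb line and a landmark.

### Coordinates, facing, and signs

Image coordinates follow the raster standard (origin top-left, y downward).
A facing flag states which image direction is the patient's anterior
(`"+x"` by default); every signed quantity is defined in the anatomical
frame, so mirrored radiographs produce identical values once the flag is
flipped.

Sign conventions are chosen as a coherent system rather than per-parameter:

* endplate slope is positive when the anterior corner is superior;
* pelvic tilt is positive when the sacral endplate midpoint lies anterior
  to the femoral-head center;
* lordosis is positive for C27L and LL, kyphosis positive for TK;
* SVAs are positive when the plumb line falls anterior to the reference
  corner.

Under these choices the incidence parameters satisfy the additive
identities exactly on ideal landmarks — `PI = PT + SS`, `C2I = PT + C2S`,
`T1I = PT + T1S`, and `L1I = PT + slope(L1 sup)` — which is the property
the conventions were selected to preserve; with the opposite pelvic-tilt
sign those relations would degenerate to differences. Published tables in
this field report magnitudes, so results carry both the signed value and
its magnitude, and the CSV writer emits magnitudes.

The incidence angles C2I/T1I/L1I are all measured against the *pelvic*
line (femoral-head center to sacral endplate midpoint), not against
per-level lines to the respective endplate midpoints as in some
T1-pelvic-angle-style measures; the two families coincide only at the
sacrum. The pelvic-line form is the definition implemented here, the
per-level variant is deliberately out of scope.

## From masks to landmarks

1. **Contour.** Raster masks are traced to an ordered boundary ring
   (EBImage's contour follower) using pixel-center coordinates; polygon
   inputs skip this step.
2. **Polygon approximation.** The ring is simplified by Douglas-Peucker
   with tolerance expressed as a fraction of the perimeter (default 2%).
   The fraction form makes the tolerance scale-free; at 2048² it keeps the
   four corner vertices of a rasterized quadrilateral while smoothing
   staircase noise. Because the open-chain pass always keeps its split
   points, a final cyclic pass prunes vertices whose deviation from their
   neighbors' chord is below the tolerance.
3. **Corner roles.** The four corners are the vertices maximizing the
   projection onto the four diagonal directions (anterior/posterior x
   superior/inferior) from the centroid; ties break by distance from the
   centroid, then by vertex order. The rule is a bijection for convex,
   roughly quadrilateral bodies rotated less than 45 degrees — beyond that
   the quadrants genuinely permute, so the synthetic generator refuses
   endplate tilts past 45 degrees and real cases that degenerate raise a
   corner-extraction failure that the QC gate records.
4. **Subpixel refinement.** When the full contour is available, each of
   the four edges between consecutive corners is fitted by total least
   squares (excluding a few pixels around the corners) and adjacent edge
   lines are intersected. A pixel is foreground iff its center lies inside
   the polygon, so traced boundary centers sit on average half a pixel
   inside the true edge; each fitted line is shifted half a pixel along
   its outward normal before intersection. This removes the systematic
   inward bias: on rasterized scenes the median corner error drops to
   about 0.07 px (worst case below 1 px), comfortably inside the 1.5 px
   quantization bound the tests enforce.
5. **Labeling.** Vertebral bodies are sorted by centroid height and
   labeled C2 downward — masks carry no identity beyond position, so
   strict mode demands all 23 bodies; `mode = "partial"` labels upward
   from L5 (the body adjacent to the sacrum) when cranial levels are
   missing, computing only the parameters whose landmarks exist. Explicit
   per-level category labels, when present on every body, are honored
   instead. The sacral endplate corners are the two superior-quadrant
   vertices of the sacrum polygon, refined the same way.

**Quality gate.** A case fails when a required structure is missing,
corner extraction fails, or — when reference segmentations are supplied —
any structure's IoU falls below the threshold (default 0.80, strictly:
0.79 fails). Failure is a return state, so batch success rates can be
tabulated without exception handling.

## The synthetic generator

Real annotated radiographs cannot be distributed, so validation runs on
parametric scenes: a chain of 23 convex trapezoidal vertebral bodies, a
sacral trapezoid whose superior edge realizes the target sacral slope, and
two femoral-head disks, rasterized at 2048x2048 with 0.25 mm/px spacing.
Targets (SS, PT, LL, TK or T1S, C2S, C27L, both SVAs) are realized
exactly: regional angles pin the bounding endplate slopes, intermediate
endplate tilts are linearly interpolated between the pinned ones (any
distribution satisfying the boundary endplates yields the same regional
parameters), and the SVA targets are met by horizontal placement of the
cervical block, which cannot disturb any angle. Unspecified targets are
drawn from seeded uniform ranges chosen to resemble normal adults
(SS 32-44, PT 8-16, LL = SS + 8-18, TK 10-22, C2S 8-18, C27L 10-22,
C7 SVA -5-35 mm, C2-7 SVA 8-28 mm); lumbar lordosis is drawn relative to
sacral slope because the two covary strongly in normal cohorts and
independent draws would imply implausibly steep junctional endplates.
TK and T1S are linked through `T1S = (SS - LL) - TK`, so supplying both
inconsistently is an error rather than a silent override.

At 0.25 mm/px a 2048-pixel frame spans 512 mm, less than an adult
C2-to-femoral-head distance, so the default body heights are
proportionally compact (cervical 40 px, thoracic 58 px, lumbar 76 px);
every morphometric value can be overridden. Ground truth is computed from
the construction algebra, independently of the geometric measurement
engine, and the two agree to 1e-9 on exact corners — that cross-check,
not shared code, is what licenses using the generator as an oracle.

What the phantom does *not* emulate: intensity texture, ribs and shoulder
girdle occlusion, endplate curvature and osteophytes, pathological shapes,
and detection errors of a real segmenter. Passing the recovery tests
therefore demonstrates that the geometry engine is correct and that
rasterization costs are bounded (angles within 1.5 degrees, SVAs within
2.5 mm), not that any particular segmentation model is accurate.
Segmentation noise is approximated separately by seeded uniform jitter of
polygon vertices (`perturb()`), which degrades IoU monotonically in
expectation and is used to exercise the QC gate.

## Reliability statistics

`icc_2_1()` implements the two-way random-effects, absolute-agreement,
single-measurement intraclass correlation from the ANOVA mean squares,

```
ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)),
```

with the Shrout-Fleiss F-based 95% interval and the p value from
`MSR/MSE` on `(n-1), (n-1)(k-1)` degrees of freedom. The classification
uses the customary cut-points (poor < 0.40, fair 0.40-0.60, good
0.60-0.75, excellent 0.75-1.00); since the printed bins overlap at their
endpoints, a value equal to a cut-point takes the higher label — 0.40 is
fair, 0.60 good, 0.75 excellent. Note that narrative descriptions in the
literature do not always follow this scheme (0.62 is sometimes called
"moderate"); the cut-point scheme is authoritative here. Cases with any
missing rater value are dropped listwise with the count reported.
Bland-Altman limits are the mean difference ± 1.96 sample SD;
`error_stats()` adds MAE, SD of the absolute error, Pearson r and R².
`agreement_report()` assembles all of it pairwise against a designated
reference rater plus the pooled ICC.

The test-suite oracle for the ICC is an independent `stats::aov`
decomposition (and the implementation was additionally checked against a
reference implementation in another language during development); the two
routes agree to 1e-9 over random tables.

## Numerical choices and edge cases

* Angles are degrees everywhere in the interface; radians appear only
  inside trigonometric kernels. Signed angles are wrapped to (-180, 180].
* Slope resolution on a rasterized edge is limited by width: a near-flat
  64 px cervical endplate rises through a single pixel step, so its
  recovered slope can be off by about `atan(1/64) ≈ 0.9` degrees. This,
  not corner bias, dominates the observed worst-case C27L recovery error;
  wider thoracolumbar endplates recover to about 0.3 degrees.
* Degenerate geometry (zero-length directions, coincident corners,
  coincident femoral center and sacral midpoint) raises typed conditions;
  missing landmarks degrade the affected parameters to
  `missing-landmarks` status instead of failing the case.
* SVAs require a pixel spacing; without one they are refused (or reported
  as missing in `compute_all()`) rather than silently returned in pixels.
* Normal-range flags use inclusive bounds on magnitudes and stay
  `unevaluated` until the user supplies a range table; no population
  standard is bundled because reference ranges differ by population.
* Problem sizes in the validation suite: 500 random spines for the
  analytic identities, 200 rasterized spines for end-to-end recovery
  (about 1.3 s each end to end), 100 random tables for the ICC oracle,
  10^4 simulated differences for Bland-Altman coverage, a 12-case batch
  with a constructed 25% failure subset for the QC gate.

## Known limitations

* Level identification is positional; a scene missing a mid-thoracic body
  shifts every label below it (strict mode refuses such scenes, partial
  mode trusts the sacrum-adjacent anchor).
* The corner rule requires roughly quadrilateral convex bodies; severely
  wedged or fractured vertebrae are outside the model, as are bodies
  tilted beyond 45 degrees.
* Only isotropic pixel spacing is supported, and no magnification or
  perspective correction is attempted — parameters are measured in the
  image plane, as in routine clinical practice.
* DICOM is not read; spacing must arrive as metadata or a flag.
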