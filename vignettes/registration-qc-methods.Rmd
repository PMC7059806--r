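---
title: "Methods behind regqc: a standardized visual QC protocol for brain registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind regqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regqc)
```

## The problem

Group analyses of structural MRI depend on every individual T1 volume being
correctly registered to a stereotaxic template. Registration fails often
enough that results are reviewed visually, but visual review without a
protocol is subjective, slow to teach, and hard to compare across
laboratories. `regqc` implements a standardized protocol in which a rater
sees a fixed mosaic of nine slices from the registered individual and from
the template, with anatomical landmark regions drawn in transparent red, and
expresses judgement by *tagging* misplaced structures rather than by free
impression. The package covers the computable parts of that protocol
end-to-end: landmark-mask construction, mosaic rendering, the tag-to-rating
decision rule, consensus aggregation across raters, agreement statistics,
and the sample-size arithmetic for planning rating studies — plus simulators
(phantom volumes, confusion-matrix raters) so that every component is
testable without access to imaging data or human raters.

## Landmarks: the registration "confidence interval"

The only landmark with a fully computable definition is the brain outline.
`buildOutlineShell()` subtracts a 4 mm *eroded* template brain mask from a
4 mm *dilated* one, leaving a roughly 8 mm thick shell centred on the brain
outline. A structure that stays inside the shell is acceptably registered;
one that crosses it is tagged. Interior landmarks (central sulcus,
ventricles, calcarine fissure, ...) are hand-drawn objects in practice, so
the package consumes them as user-supplied NIfTI masks
(`readLandmarkMask()`) and only merges them (`mergeLandmarkMasks()`).

Morphology is millimetre-calibrated: radii are specified in mm and applied
through an exact anisotropic Euclidean distance transform, so "4 mm" means
4 mm whether the grid is 1 mm isotropic or 2 mm anisotropic. Both operations
use the closed-ball convention — dilation keeps voxels at distance
$\le r$ from the mask, erosion keeps mask voxels at distance $> r$ from the
background — which is symmetric and reproducible across resolutions. On a
synthetic sphere of radius 20 mm at 1 mm resolution the shell spans radii
(16, 24] mm within one voxel, and the test suite asserts exactly that; on
real template masks the voxel-level thickness depends on the mask's
resolution, which is why thickness is only asserted on phantoms.

## The nine-slice mosaic

The protocol's view is fixed: sagittal slices at x = −50, −8, 30 mm,
coronal at y = −65, −20, 54 mm, axial at z = −6, 13, 58 mm (the
x/y/z-to-view assignment follows the anatomical standard: x varies across
sagittal slices, y across coronal, z across axial). `buildMosaic()` renders
them as a 3 × 3 grid — axial, sagittal, coronal rows from top to bottom —
and `renderPair()` produces the individual/template pair with identical
geometry so that the two images can be flipped pixel-for-pixel.

Choices the protocol leaves open are fixed once, for determinism:

* **Sampling** is nearest-voxel, never interpolated: QC must show the
  registered data as stored, and interpolation could smooth away the very
  artefacts being reviewed.
* **Intensity windowing** maps the volume's 1st–99th intensity percentiles
  linearly to gray. Robust windowing is the standard way to display T1
  volumes with arbitrary intensity scales.
* **Overlay** voxels are tinted pure red at fixed alpha 0.4 ("red
  transparent outline"); exactly the overlay voxels intersecting the nine
  planes are tinted, a conservation property the tests check by counting.
* **Orientation** is neurological (subject's left on the viewer's left,
  superior up), assuming RAS-oriented axis-aligned grids; oblique affines
  are rejected rather than silently resampled.
* Panel size follows the grid; panels are padded to a common size with a
  2-pixel black gutter. Rendering twice yields byte-identical PNGs.

## From tags to a three-level rating

Raters click misregistered structures; each click is a sphere of radius
4 mm in world mm. `rateFromTags()` applies the protocol's decision rule:

* no tags → **OK**;
* tags present, but no two tag spheres overlap → **Maybe**;
* any two tag spheres overlap — centres strictly closer than 8 mm — →
  **Fail** (an extensive area is misplaced);
* a raised artifact flag (motion, ringing, excessive blur) → **Fail**,
  whatever the tags say.

Two geometric conventions are fixed deliberately. Overlap is *strict*:
spheres whose centres are exactly 8 mm apart touch but have disjoint
interiors, so they do not overlap and the rating stays Maybe. And distances
are always computed in world mm, never voxels, because the 4 mm radius is
an anatomical quantity. Duplicate clicks at one point are distance-0 pairs
and therefore force Fail; `validateTagSet()` flags them (and tags outside
the landmark mask) as warnings so pipelines can de-duplicate upstream, but
validation never changes a rating. A rater may both tag structures and
flag an artifact; artifact dominance applies.

The rule is monotone by construction — adding a tag can never improve a
rating — and the suite property-tests that over random tag clouds.

## Consensus panels

Ratings are ordinal with `Fail = 0 < Maybe = 1 < OK = 2` everywhere in the
package. `consensusVote()` takes plurality over a panel's votes; among
categories tied at the maximum the *worst* wins (a three-way tie is Fail).
Only observed votes count; images a panel never rated are omitted with a
warning rather than imputed. `partitionRaters()` reproduces the protocol's
"arbitrary" panels as seeded random splits, e.g. nine experts into three
panels of three, or 41 crowd raters into panels of 20 and 21.

## Agreement statistics

`weightedKappa()` implements weighted Cohen's kappa,
$\kappa = (p_o - p_e)/(1 - p_e)$, with agreement weights
$w_{ij} = 1 - |i-j|/(k-1)$ (linear, the default), $1 - (|i-j|/(k-1))^2$
(quadratic) or the identity (unweighted). Linear weights are the default
because the protocol reads OK-vs-Maybe and Maybe-vs-Fail as *partial*
disagreements and OK-vs-Fail as a *complete* one, which linear weights
encode exactly. Missing data are handled pairwise-complete — each pair of
raters is compared on the images both rated — and every report cell carries
the number of shared images so low-overlap pairs are visible. When both
raters are constant and identical, $p_e = 1$ and the formula's denominator
vanishes; the package returns an explicit flagged `NA` ("undefined") rather
than forcing 0 or 1.

`categoryDice()` computes, per rating category, the Sørensen–Dice
coefficient $2|X \cap Y|/(|X| + |Y|)$ between the image sets the two raters
assigned to that category — the natural per-category complement to kappa,
which is dominated by the majority category. `interpretStrength()` applies
the Landis–Koch bands with upper-closed intervals
((0, 0.20] slight, (0.20, 0.40] fair, (0.40, 0.60] moderate,
(0.60, 0.80] substantial, (0.80, 1] almost perfect; values $\le 0$ poor),
which closes the gap that the conventionally printed ranges leave between
0 and 0.01. `pairwiseReport()` assembles the full rater-by-rater (or
panel-by-rater) matrices.

## Kappa sample-size analysis

`minSampleSize()` answers the planning question "how many images must two
raters both rate to demonstrate that their kappa exceeds a baseline
$\kappa_0$, if the true kappa is $\kappa_1$?", following Flack, Afifi,
Lachenbruch and Schouten (1988). The large-sample variance of
$\hat\kappa$ (Fleiss, Cohen and Everitt, 1969) depends on the full joint
distribution of the two raters' categories, which is unknown at planning
time; the method therefore uses, for given margins and kappa, the joint
distribution that *maximizes* the variance. Because the variance is linear
in the cell probabilities once margins and kappa are fixed, that worst case
is a linear program over the 9-cell joint simplex; the package solves it
with a self-contained dense two-phase simplex, and the test suite
cross-checks the optimum against an independent vertex-enumeration oracle.
The sample size is then

$$ N = \left\lceil \left( \frac{z_{1-\alpha}\sqrt{Q(\kappa_0)} +
  z_{\mathrm{power}}\sqrt{Q(\kappa_1)}}{\kappa_1 - \kappa_0} \right)^2
  \right\rceil $$

with $Q(\kappa)$ the worst-case variance factor. Design decisions:

* The test is **one-sided** by default (the planning question is
  directional: an *improvement* over $\kappa_0$); two-sided is an option.
* The 1988 method addresses **unweighted** kappa. Applying it to a study
  whose observed agreement is a *weighted* kappa (as the three-level QC
  protocol's is) is therefore an approximation, inherited from standard
  practice; the package implements the method as defined rather than
  inventing a weighted-kappa variant.
* N is rounded up to an integer; infeasible inputs (a kappa no joint
  distribution with the stated margins can attain) raise an error instead
  of returning a number.

Under the protocol's published planning scenario — margins
(0.30, 0.35, 0.35) for both raters, $\kappa_0 = 0.5$, $\kappa_1 = 0.72$,
$\alpha = 0.05$ one-sided — the computation gives:

```{r power}
sc8 <- kappaPowerScenario(c(0.30, 0.35, 0.35), k0 = 0.5, k1 = 0.72,
                          alpha = 0.05, power = 0.8)
minSampleSize(sc8)
minSampleSize(kappaPowerScenario(c(0.30, 0.35, 0.35), k0 = 0.5, k1 = 0.72,
                                 alpha = 0.05, power = 0.9))
```

`empiricalPower()` closes the loop by Monte-Carlo: it draws rating pairs
from the worst-case joint at $\kappa_1$, applies the planning test (reject
when $\hat\kappa > \kappa_0 + z_{1-\alpha}\sqrt{Q(\kappa_0)/n}$, the test
the sample-size formula is built on), and reports the rejection fraction.
At the computed minimum N the empirical power sits near the nominal target
(slightly below it at these sample sizes, because $\hat\kappa$ is biased
downward in finite samples); the acceptance tests check the agreement at
three binomial standard errors of the target. Power checks run more
Monte-Carlo replicates than the minimum so that the check's own noise is
negligible relative to its stated tolerance.

## The simulators, and what passing tests do and do not show

`generatePhantom()` builds a deterministic ellipsoidal "brain" with smooth
internal structure and its binary mask, centred at the world origin so the
protocol's slice coordinates land in the field of view (the default grid is
64 × 76 × 64 voxels at 2 mm; geometry tests also use 1 mm grids around
48³–56³). `perturbRegistration()` resamples a volume through a smooth
random displacement field with an exact maximum-magnitude bound, emulating
the low-frequency residual of a failed registration. These phantoms
exercise geometry, rendering and I/O; they do **not** emulate tissue
contrast, noise, bias fields or real misregistration patterns, so passing
geometry tests says nothing about human rater behaviour on real scans.

Raters are simulated as confusion matrices over the true class
(`raterProfile()`, with Dirichlet jitter around a base matrix via
`jitterProfiles()` to mimic a heterogeneous pool; the concentration is
configurable because no behavioural model of volunteers is assumed).
`simulateCampaign()` reproduces the crowdsourcing workflow's bookkeeping:
each image collects ratings from a configurable number of distinct raters
before retirement (default 40), and raters contributing no more than the
retention threshold (default 15) are dropped. Defaults mirror the
protocol's validation conditions, including the 35/35/30
Fail/Maybe/OK class mix of the validation image set. The scheduler draws
raters uniformly; real platforms schedule adaptively, which the package
does not model.

Two calibration properties tie the simulator to the statistics: the
population weighted kappa of two confusion-matrix raters has a closed form
(`populationKappa()`), and the mean of simulated kappas must match it
within Monte-Carlo error (the acceptance suite uses 500 replicates of 100
images); and with honest-majority raters the consensus error against truth
must be non-increasing in panel size (checked at sizes 1, 3, 9, 21, 41,
averaged over 20 replicate campaigns of 200 images to keep the Monte-Carlo
noise below the effect).

## Numerical and interface conventions

* Volumes are S4 `BrainVolume` objects: a 3-D array plus a 4 × 4
  voxel-to-world affine in mm (NIfTI convention, 0-based indices on the
  file side). Grid compatibility means equal shapes and affines within
  1e-6 mm; all pairwise operations require it.
* Masks written to NIfTI are unsigned 8-bit.
* Rating tables travel as plain CSV (`image_id,rater_id,rating`,
  case-insensitive ratings on read, canonical case on write); tags as JSON
  with full-precision coordinates. Both round-trip losslessly, and both
  readers fail with the offending line/record rather than guessing.
* All stochastic helpers take explicit integer seeds and restore the
  caller's RNG state; identical seeds give identical outputs end-to-end.

## Known limitations

* Only the brain-outline landmark is computed; the eight interior
  anatomical landmarks must be supplied as masks.
* Slice extraction requires axis-aligned affines (standard for
  template-space data); oblique grids are rejected.
* The sample-size method is the unweighted-kappa worst-case construction;
  no weighted-kappa, ICC or multi-rater ($>2$) sample-size methods are
  provided.
* The consensus model is plurality with worst-category tie-break, as the
  protocol defines — no probabilistic label-aggregation models.
* The exact distance transform is computed in R; it is comfortable at the
  grid sizes the protocol uses (a few seconds at 1–2 mm phantom
  resolutions) but is not tuned for high-resolution whole-head masks.
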