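---
title: "Lesion-specific vessel wall mechanics and marker association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-specific vessel wall mechanics and marker association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquemech)
```

# The problem

Atherosclerotic plaques disrupt in at least two distinct ways: rupture of a
thin fibrous cap over a necrotic core, and erosion of an intact plaque
surface. A central question in plaque pathology is whether local tissue
mechanics (stress and strain in the vessel wall) co-localize with
inflammatory activity, and whether that coupling differs between lesion
phenotypes. `plaquemech` implements the full computational chain needed to
ask that question of stained histological cross-sections:

1. **Segmentation** of a pentachrome-like RGB image into tissue classes
   (fibrous, cellular, lipid/necrotic, calcified).
2. **Geometry**: contour handling, morphometry, rotation-only registration
   of serial sections by lumen radius signatures.
3. **Mechanics**: a lesion-specific 2D plane-strain finite-element model
   with rule-of-mixtures material properties, an iterative pre-inflation
   step that removes fixation artifacts, and Von Mises stress/strain
   *excursion* fields.
4. **Association**: element-level histogram statistics linking excursion to
   binary marker positivity.
5. **Phantoms**: a synthetic specimen generator with known ground truth, so
   the whole pipeline is testable without tissue.

# Mechanical model

## Constitutive assumptions

Each tissue class is linear, elastic and isotropic, with moduli
(defaults, Pa):

| class | modulus |
|---|---|
| lipid/necrotic core | 3.875e4 |
| cellular | 2.449e5 |
| fibrous | 1.821e6 |
| calcified | 1.066e7 |

Per-element moduli come from a *rule of mixtures*: the tissue-area-fraction
weighted mean of class moduli over the pixels inside the element
(background excluded). A single Poisson ratio of 0.49 is used for all
classes — soft tissue is nearly incompressible, and no class-specific
compressibility data exist for fixed tissue. Plane strain is assumed, as is
conventional for an axially tethered artery cross-section. Both are
configurable.

Because the tissue was pressure-fixed, no residual-stress state is
available and absolute stress magnitudes are not meaningful. All analysis
therefore uses the **excursion** of a field: `e = (x - median(x))/median(x)`
per element, a dimensionless, scale-invariant measure of how far each
element sits above or below the lesion median. The median element has
excursion exactly 0; doubling every modulus leaves the stress field (and
hence its excursion) unchanged.

## Discretization

The wall domain between the lumen and the outer border is meshed by a
structured polar scheme: angular rays from the lumen centroid crossed with
radial rings placed at equal-area subdivisions
(`r_j = sqrt(r_in^2 + (r_out^2 - r_in^2) j/n_r)`), each quad split along
its shorter diagonal (ties broken deterministically), then upgraded to
straight-sided 6-node quadratic triangles. Design notes:

* *Quadratic elements* avoid the volumetric locking that linear triangles
  suffer at nu = 0.49.
* *Equal-area rings* keep element footprints statistically comparable
  across the wall. This matters for the association statistic: an element
  is "positive" if any positive pixel falls in its footprint, so
  P(positive) grows with footprint size. If element area correlated with
  radius (as it does for uniform radial spacing), footprint size would
  correlate with excursion and bias the null. Equal-area rings remove that
  coupling; under incompressible inflation they also track material
  advection almost exactly, which stabilizes the pre-inflation loop.
* Both boundary contours must be star-shaped about the lumen centroid —
  true for vessel cross-sections, and checked at mesh time.
* *Quality selection*: the ratio of angular to radial resolution is chosen
  by evaluating a few aspect candidates and keeping the mesh with the best
  worst-case interior angle. For concentric and mildly eccentric walls
  this yields minimum angles of 21-26 degrees; for strongly eccentric
  walls (thickness varying 2x or more around the circumference) the
  equal-area grading necessarily deepens the first ring on the thick side
  and the attainable worst angle drops toward ~15 degrees. The mesh stays
  valid (positive areas, exact domain coverage); only worst-element
  quality degrades.
* Resolution is set by a target element area; tests and examples use 1k-20k
  elements, which places the inner-wall hoop stress of a homogeneous
  annulus within 2% of the thick-walled-cylinder closed form (the package's
  analytic validation fixture).

The luminal pressure (default +40 mmHg, the approximate
diastole-to-systole increment above the fixation pressure; 1 mmHg =
133.322 Pa) is applied as a consistent traction normal to the lumen edges;
the outer boundary is traction-free. A closed pressure load is
self-equilibrated, so the three rigid-body modes are removed by minimal
constraints on two deterministic outer-boundary nodes; element stresses are
insensitive to the constraint choice (verified to 0.1% by swapping the
constraint nodes) and the constraint reactions vanish to round-off.

Von Mises stress uses the plane-strain out-of-plane stress
`sigma_z = nu (sigma_x + sigma_y)`. "Von Mises strain" is taken as the
equivalent deviatoric strain `(2/3) sqrt(3 J2(eps_dev))`; whether a total
or deviatoric equivalent is meant is not decidable from the source
literature, and the deviatoric form is the standard equivalent measure.

## Pre-inflation artifact removal

Fixation and embedding can compress a section along one axis, leaving a
non-circular lumen and spurious stress concentrations. The pre-inflation
procedure finds the vessel's self-consistent conformation under the
incremental pressure by fixed-point iteration: solve on the current
conformation, set the new conformation to *reference geometry plus the
computed displacement*, remesh the deformed domain, and re-interpolate
per-element moduli from the previous deformed map (containing-element
lookup at the new centroid, nearest-neighbor fallback). Reference
coordinates are carried through each remesh the same way.

Because each iteration replaces rather than accumulates the inflation
displacement, the conformation converges geometrically (each step's
correction is of the order of the strain, a few percent, times the previous
correction). In the package's convergence tests the mean absolute
per-element change of stress and strain excursion falls below 0.01% within
10 iterations on a 0.7-compressed heterogeneous phantom, and lumen
circularity rises from the artifact value to a stable plateau. A
non-convergent variant of the loop (re-applying the full pressure increment
to each successive conformation) was evaluated and rejected: it inflates
the vessel indefinitely and its excursion fields never stabilize, which
contradicts the procedure's purpose of providing a converged starting
conformation.

Three numerical details: successive iterations are compared in a common
conformation (the earlier iteration's element centroids are carried forward
by the displacement before nearest-centroid matching), since matching raw
coordinates across conformations conflates advection with change; the
modulus re-interpolation is piecewise-constant, the simplest scheme
consistent with advecting a per-element material map; and the rigid-body
constraint nodes are selected in the reference frame so the pinned nodes
cannot flip between near-tied boundary nodes across iterations. One floor
effect is worth knowing: on a perfectly symmetric homogeneous annulus the
element stress values cluster in near-exact ties per ring, so the discrete
median (and hence every excursion value) can flip by a fraction of the
inter-ring gap between iterations — the excursion-change metric bottoms
out around 0.2-0.3 percentage points there even though node positions
converge to well below a hundredth of a micrometre. Heterogeneous lesions
have no such ties and converge to ~1e-6 percent.

# Association analysis

Elements — not pixels — are the statistical unit. For each stain, the
registered binary positivity raster is sampled over each element footprint;
an element is positive iff at least one unmasked positive pixel lies
inside, and elements whose footprint is entirely masked out are dropped.
Elements are then pooled into a *baseline* group (excursion < 0.25,
including all negative excursions) plus tertiles or deciles of equal count
over the remaining elements (remainder to the lowest bins). A chi-squared
test on the groups-by-positivity contingency table gates pooled-variance
two-proportion z-tests of each bin against baseline, Bonferroni-corrected
(default m = 11 for deciles, m = 4 for tertiles; both configurable, since
the exact comparison count convention is ambiguous in the source
literature). Phenotype-level scalar comparisons use one-way ANOVA with
Tukey HSD and an additional Bonferroni factor (6 for four phenotypes).

Spatial autocorrelation between neighboring elements is deliberately
ignored, matching the published procedure; p-values are therefore
anti-conservative for strongly autocorrelated fields and should be read as
descriptive at the single-specimen level. Registration is rotation-only
(serial sections share a center after acquisition); the registration angle
maximizes the circular cross-correlation of lumen radius signatures (360
one-degree bins by default, so precision is +-1 degree), with ties broken
toward the smallest absolute angle and a degeneracy flag for circular
lumens.

# The phantom generator

Phantoms emulate exactly the statistical structure the analysis assumes:

* an annular wall between a circular lumen (radius 1000 um by default) and
  outer border (2200 um), with the IEL at 1800 um;
* fibrous intima with a lipid/necrotic core arc (120 degrees by default)
  under a fibrous cap (250 um), an optionally calcified core subsector
  (15% of the core arc), and a cellular medial ring;
* an optional horizontal compression artifact (`compression_ratio`),
  applied to raster and contours alike;
* 8-bit RGB rendering under a configurable pentachrome-like palette with
  Gaussian color noise (`noise_sd`, 8-bit scale);
* binary stain maps drawn per-pixel Bernoulli, either uniform,
  region-restricted, or coupled to local strain excursion through
  `P(pos | e) = plogis(qlogis(p0) + beta e)`.

Default choices worth stating: the lumen is concentric by default
(`lumen_eccentricity_um = 0`) so that mechanical heterogeneity in the
association studies comes from tissue composition rather than wall-thickness
asymmetry — this keeps element areas uniform and the null calibration of
the element-level statistic clean; eccentric lumens are exercised in the
geometry tests. The default per-pixel baseline positivity is 0.02, a
sparse, IHC-like positivity level that keeps the per-element "any positive
pixel" statistic away from saturation at typical footprint sizes (tens of
pixels).

What phantoms do **not** emulate: thrombus, staining chemistry, stitching
artifacts, non-elliptical lumens, 3D anatomy, or realistic morphometric
distributions across phenotypes. A passing pipeline on phantoms
demonstrates computational correctness and statistical calibration, not
biological validity on real sections.

# Statistical behavior verified by the test suite

* *Power*: with strain-coupled staining (beta = 2) at ~5000 elements, the
  strain-decile analysis detects the association (significant chi-squared
  and positive Spearman trend across decile fractions) in at least 90% of
  50 seeds.
* *Type-I control*: with uncoupled staining (beta = 0) across 200 seeds at
  ~2500 elements, the chi-squared gate rejects at approximately the nominal
  alpha (bounded by alpha + 3 binomial SEs).
* *Dissociation*: at weak coupling (beta = 0.25) the strain association
  remains detectable while the stress association stays below the gate —
  the stress and strain excursion fields correlate only moderately in a
  heterogeneous lesion, so a strain-coupled marker needs not show a stress
  association. This reproduces, in miniature, the qualitative pattern of a
  marker tracking strain but not stress.

Problem sizes in the tests (128-512 pixel images, 400-20000 elements,
10-15 pre-inflation iterations, 50-200 seeds) are the package's chosen
desk-scale study conditions; all thresholds above are fixed in the test
code.

# Known limitations

* Linear, isotropic, single-phase elasticity; no residual stress, no
  anisotropy, no viscoelasticity. Only relative (excursion) fields are
  meaningful.
* The structured mesher requires star-shaped contours about the lumen
  centroid; extreme non-convex lumens would need a general mesher.
* Nearest-neighbor raster rotation is exact only at multiples of 90
  degrees; at other angles it introduces one-pixel resampling error,
  matching the precision of the 1-degree registration.
* Manual artifact correction is replaced by optional mask rasters; there is
  no interactive editing.
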