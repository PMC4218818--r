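# plaquemech

Histology-to-mechanics-to-inflammation analysis of atherosclerotic vessel
cross-sections, as an R package.

Plaque rupture is driven by focal mechanics — stress concentrating on a
thin fibrous cap over a soft necrotic core — and mechanosensitive
inflammation. `plaquemech` implements the complete computational pipeline
needed to study that coupling in stained histological sections:

* **Segmentation** of pentachrome-like RGB images into tissue classes
  (fibrous, cellular, lipid/necrotic, calcified) by k-means color
  clustering or nearest-prototype classification in LAB space, plus HSV
  thresholding of chromogen-stained marker images.
* **Geometry**: contour I/O, shortest-path contour tracing on a cost
  image, morphometry (plaque burden, eccentricity, minimum enclosing
  circle radius, media thickness), near-lumen band quantification via the
  exact signed distance function, and rotation-only registration of serial
  sections by circular cross-correlation of lumen radius signatures.
* **Mechanics**: lesion-specific 2D plane-strain finite elements
  (quadratic triangles on a structured equal-area polar mesh), per-element
  moduli by a rule of mixtures over the segmented tissue map
  (lipid/necrotic 3.875e4 Pa, cellular 2.449e5 Pa, fibrous 1.821e6 Pa,
  calcified 1.066e7 Pa; nu = 0.49), a +40 mmHg luminal pressure, an
  iterative pre-inflation step that removes fixation artifacts such as a
  compressed lumen, and per-element Von Mises stress and strain
  **excursion** fields, `e = (x - median x)/median x`.
* **Association**: per-element binary marker positivity pooled into a
  baseline group (excursion < 0.25) plus equal-count tertiles/deciles,
  chi-squared association testing with Bonferroni-corrected two-proportion
  post hocs, and ANOVA + Tukey HSD phenotype comparisons.
* **Phantoms**: a synthetic vessel generator (ground-truth label maps,
  contours, stain maps optionally coupled to strain excursion) so the
  entire pipeline is reproducible and testable with no tissue data.

## Worked example

Validate the solver against the thick-walled cylinder closed form, then
run a full phantom analysis:

```r
library(plaquemech)

## homogeneous annulus, a = 1 mm, b = 2 mm, +40 mmHg
lp   <- lame_phantom(1000, 2000, 1.821e6)
mesh <- mesh_domain(lp$geometry,
                    target_element_area_um2 = pi * 3e6 / 20000)
fem  <- solve_inflation(fe_model(mesh, rep(1.821e6, nrow(mesh$tri))))
inner_wall_hoop_stress(fem)$mean     # 8931.2 Pa
5332.9 * (1000^2 + 2000^2) / (2000^2 - 1000^2)  # closed form: 8888.2 Pa

## synthetic lesion with strain-coupled staining
cfg <- run_config(preinflate_iters = 0L, element_budget = 5000L)
ph  <- generate_phantom(phantom_spec(seed = 3, noise_sd = 8,
                                     coupling_beta = 2))
res <- plaquemech:::analyse_phantom(ph, cfg, coupling_beta = 2,
                                    stain_seed = 10)
res$associations$marker$strain
```

The first block prints the mean circumferential stress recovered at the
inner wall, 8931.2 Pa at ~20k elements, within 0.5% of the Lame closed
form 8888.2 Pa. The second prints the decile table for the strain-coupled
marker — positive fractions rising monotonically from 0.07 in the lowest
strain-excursion decile to 1.0 in the highest, with the chi-squared
association test and per-decile two-proportion post hocs (all deciles
above the fifth significantly enriched against baseline after Bonferroni
correction).

For real specimens, `run_specimen()` takes an image (PNG/TIFF), a contour
CSV (lumen/IEL/outer, micrometres) and optional binary stain rasters, and
writes per-element solution tables, morphometry, staining summaries and
association tables as CSV. `run_phantom_study()` runs multi-specimen
synthetic studies with a machine-readable manifest.

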