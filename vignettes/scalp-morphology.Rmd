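---
title: "Photogrammetric scalp morphology estimation: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photogrammetric scalp morphology estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Optical neuroimaging (fNIRS, HD-DOT) reconstructs cortical hemodynamics
through the scalp, so the accuracy of the head model directly limits the
accuracy of source localization. When participant MRI is unavailable, the
scalp surface must be estimated some other way — and a 3D scan of the head
does not show the scalp: it shows the *hair envelope*, a surface offset
outward by an unknown, spatially varying hair thickness.

`scalpmorph` implements a photogrammetric answer: the participant wears a
flexible cap carrying rigid modules whose thin feet comb through the hair and
rest on the skin, while each module's top carries a bright red right-triangle
fiducial that a color 3D scanner sees easily. Knowing the module geometry,
the pipeline detects each fiducial in the colored scan, recovers the module's
six-degree-of-freedom pose, projects its feet down to the scalp, and fits a
template head surface to the resulting sparse sample of true scalp points.

## Pipeline stages and their models

### Fiducial detection

Scan vertices are kept when `red >= 0.5`, HSV `saturation >= 0.7` and hue is
within `0.1` of the red origin of the hue circle. Two choices deserve
comment:

* *"Normalized color"* is read as the red channel itself on a `[0, 1]` scale,
  not a chromaticity ratio; saturation and hue follow the standard hexcone
  HSV model. The conversion is isolated in one place so a different reading
  can be swapped in.
* *Hue wraparound*: red sits at the origin of the hue circle, so the test
  accepts `hue <= 0.1` **or** `hue >= 0.9`. Without the wrap side, a fiducial
  photographed slightly toward magenta would lose half its vertices under
  lighting variation.

The surviving vertices are partitioned into one cluster per module by
k-means (seeded k-means++ initialization, Lloyd iterations) under the
physical constraint that all members of a cluster lie within 50 mm of each
other — the module top is about 3 cm across, while distinct modules sit
several centimetres apart. A converged partition that violates the bound, or
produces a cluster smaller than 3 points (a triangle cannot be oriented from
fewer), triggers a reseeded restart; persistent failure is an error rather
than a silent bad partition.

### Module pose

Each cluster is a filled triangular patch. Principal component analysis
gives the fiducial plane; the sign of its normal is fixed by pointing it
toward a rough head centre (the mean of all cluster centroids — the modules
cover the upper scalp, so their centroid mean falls safely inside the head;
it is used *only* for this sign decision). The in-plane orientation uses the
fiducial's deliberate asymmetry: the triangle has a 20 mm and a 15 mm leg, so
matching observed corner distances to the model resolves the 180° ambiguity
that a symmetric marker would leave. The three extremal corners give a
closed-form rigid fit (least-squares over the three correspondences), which
is then refined by least squares of *all* patch vertices against the posed
model triangle — the corners are the noisiest members of the patch, and the
whole-patch refinement roughly halves the pose noise at realistic scanner
noise levels. A fit whose corner residual exceeds 2 mm, or whose observed
leg ratio is within 10% of 1, is rejected (the module is skipped with a
warning rather than contributing wrong feet).

The module feet sit at `z = -25` mm in the module frame; their exact in-plane
positions default to the corners of a 14 x 14 mm square centred under the
triangle and are configurable, because the downstream surface fit is
insensitive to in-plane placement at the few-millimetre scale.

### Template fitting

The projected feet form the sparse scalp sample (68 points for the default
17-module cap). A template head surface — in practice an atlas scalp such as
the MNI152 scalp surface; in all tests a synthetic head — is fitted to the
sample by iterated closest-surface-point: each round finds the closest point
on the transformed template for every sample point, then re-estimates the
transform minimizing the summed squared correspondence distances. Four
transform families are supported: rigid, rigid + isotropic scale, rigid +
per-axis scale (the default; the factorization order is fixed as
`R %*% diag(s)`, scale in template axes then rotation), and full affine
(used for the volumetric gold-standard comparison). The objective — mean
squared point-to-surface distance — is non-increasing by construction
(each half-step is an exact minimization), and iteration stops when it
improves by less than `1e-4` mm².

Point-to-point ICP over a smooth, sparsely sampled head converges slowly and
can stall when started far from the solution, so the fit is initialised from
the four cranial landmarks (rigid + isotropic scale over
nasion/inion/preauriculars) whenever both landmark sets are available. This
replaces the manual atlas alignment of an interactive workflow; with that
initialisation, a known rotation + per-axis-scale transform of the template
is recovered to well within 1% scale and 1° rotation from a 68-point sample.

### Geodesic montages

Validation uses EEG-style electrode systems placed by surface geodesics.
A "geodesic" here is a plane-slice curve: the intersection of the mesh with
the plane through the two endpoints and a reference point, restricted to the
arc passing nearest the reference. This construction is deterministic, fast,
and exactly rigid-equivariant; it is not a shortest path, but on head-like
(convex, smooth) surfaces the two coincide closely, and it is the
construction the field's montage tools use.

Cz is found by alternating refinement: midpoint of the nasion-inion curve,
then midpoint of the preauricular curve through that point, iterated to
0.5 mm (it converges in a handful of rounds on ellipsoids with axis ratios
0.7-1.3). The midline carries fractions of the nasion-inion curve; the
ear-level ring passes through Fpz, T7, Oz, T8 (least-squares plane through
the four anchors); each transverse row runs from a left ring point through
its midline point to the mirrored right ring point, with the ring anchor at
the same arc fraction as the midline level — the classical correspondence
(the F row ends at F7, the ring point at the Fz level). Row positions are
placed per half-row, so left/right asymmetry of a real head does not push
midline electrodes off the sagittal curve.

The error montage is the **modified 10-5 set restricted to positions at or
above the ear-level ring**. Its membership is frozen in this package as the
17 x 17 grid — 17 midline levels (10%..90% in 5% steps) by 17 columns per
row (eighths of each half-row) — which has exactly 289 labels on any valid
head and contains the 21 standard 10-20 sites as grid cells. The registry
ships as `inst/extdata/ten5_labels.txt`; the only externally anchored fact
about the subset is its cardinality, so the explicit frozen list is what
makes results reproducible. Labels follow the extended 10-10/10-5 naming
with the classical temporal-region exceptions; the dense interior of the Fp
and O rows (where the classical system has no electrodes) uses lettered
step codes (`Fp1a` ... `Fp1g`) documented in the registry.

### Error assessment

An estimate is compared against a reference surface by computing both
montages, rigidly aligning estimate to reference via the 21 shared 10-20
labels (rotation and translation only — the montage is constructed without
reference to the cap, so it is an independent correspondence), and taking
per-label Euclidean distances over the 289 sites. Summaries use the
population (divide-by-n) convention for standard deviation and variance,
both within a scan and across participants; the participant count is always
recorded alongside. Grand summaries are means of the per-participant
columns; the global per-label extremes are kept as attributes since both
readings of a "grand minimum/maximum" are defensible.

## The phantom generator

Synthetic study conditions are produced by `phantom_spec()` /
`make_head()` / `make_cap_scan()`:

* **Head**: an ellipsoid (default semi-axes 90/110/95 mm — an adult head
  with the long axis anterior-posterior) plus a smooth seeded bump field
  (sum of 12 spherical Gaussians, peak amplitude 3 mm by default) standing
  in for idiosyncratic skull shape. Landmarks sit at the anterior/posterior
  poles and the lateral extremes, the preauriculars slightly anterior and
  inferior as on a real head — which also keeps the four landmarks
  non-coplanar, as the four-point affine comparison requires.
* **Hair**: a uniform outward offset of the scalp along vertex normals
  (default 8 mm). The scanner sees the hair envelope; a scalar offset
  captures the bias that the cap corrects. Real uncapped hair is *worse*
  than this model — uneven, compressible, scanned as fluff — which matters
  when interpreting the comparison experiment (below).
* **Modules**: 17 placements, quasi-uniform above ear level (spherical
  Fibonacci). Each module is seated on the analytic surface by a small
  least-squares pose fit (height offset and two tilts) so its four rigid
  feet rest on the scalp to within a tenth of a millimetre; the recorded
  ground truth feet are the surface projections of the seated feet. The
  scan shows each module as a black top plate with a short skirt and the
  red fiducial triangle; the feet are deliberately *not* rendered — the
  scanner cannot see them under hair, which is the entire premise.
* **Noise**: i.i.d. Gaussian vertex displacement (default sigma 0.3 mm,
  a typical structured-light scanner figure). All randomness derives from
  the spec seed; identical spec implies bit-identical output.

What the phantom does **not** emulate: hair strand geometry and its
scan artifacts, the face (the phantom head is closed and hairless below the
cap region), cap fabric deformation, fiducial color variation with
lighting, and non-affine anatomy differences beyond the smooth bump field.
Passing phantom tests therefore demonstrates the geometry and algebra of
the pipeline, not robustness to every scanner artifact.

## The comparison experiment

`compare_methods()` simulates a cohort (default 10 participants: seeded
per-axis size factors in 0.94-1.06, seeded bumps, default hair and noise)
and evaluates six scalp estimates against each true surface:
the cap-based estimation; a **volumetric gold standard**; the "basic 4"
four-point affine from nasion/inion/preauriculars; the unscaled rigid atlas
placement; the bare scan (hair envelope) without the cap; and the cap
pipeline with the module leg length ignored.

Two design notes:

* The gold standard is realized as an *affine fit of the atlas to a dense
  sample (400 points) of the full true head surface*. A volumetric
  registration is an optimal fit given the whole head; realizing it instead
  as "the transform that generated the phantom" would ignore the seeded
  bump field and make the gold standard artifactually worse than the
  68-point cap fit.
* With uniform hair, the degraded variants order differently than in vivo:
  ignoring the 25 mm legs inflates the fitted template by roughly a leg
  length of scale, which outweighs the 8 mm uniform hair envelope, so the
  no-cap estimate beats the no-legs estimate on phantoms. On real heads the
  no-cap scan is degraded by everything the uniform-offset hair model leaves
  out, and the in-vivo ordering flips. The acceptance suite asserts the
  in-vivo ordering and documents this expected failure rather than bending
  the phantom toward it.

The hair-thickness sweep (`hair_robustness_sweep()`) restates the central
claim at phantom level: sweeping hair from 0 to 15 mm moves the cap-based
grand-mean error by well under 1.5 mm, while the bare-scan error grows
monotonically at roughly the hair thickness scaled by the head's angular
spread.

## Numerical choices and degenerate inputs

* Plane slicing nudges exact-zero signed distances by 1e-12 so every crossed
  face has exactly two crossed edges; slice curves are chained into closed
  loops and an interrupted loop (open surface) is an error, not a partial
  answer.
* Cluster diameter uses exact pairwise distances (clusters are small);
  the k-means restart budget is 10.
* `surface_from_binary_mask` uses the cuberille construction (boundary faces
  of foreground voxels): the result is exactly closed and volume-exact for
  a single voxel, at the cost of voxel staircase on oblique surfaces
  (vertex deviation up to about one voxel diagonal on a digitized sphere).
  Optional Taubin smoothing is available but off by default, because it
  collapses features at the single-voxel scale.
* "Normalized thresholding" of an intensity volume scales by the 99.9th
  percentile, thresholds at 0.1 by default (the step's parameters are not
  externally specified; both are configurable), keeps the largest
  6-connected component and fills interior holes.
* Collinear landmark sets, equilateral (ambiguous) fiducials, coplanar
  basic-4 source points, and samples confined to one octant are all
  rejected with specific errors rather than producing garbage transforms.

## Problem sizes

Default phantom meshes target a 4 mm edge length (10,242 vertices), which
keeps montage geodesics within a few hundredths of a millimetre of
closed-form sphere positions while a full six-method participant evaluation
runs in well under a minute; the shipped cohort experiment uses 10
participants and the hair sweep four thicknesses. All are package choices
made to keep the test suite fast while leaving every observed effect at
least an order of magnitude above mesh resolution artifacts.

## Known limitations

* The template fit is a similarity/affine family: non-affine head shape
  (the bump field, real anatomy) is explicitly out of reach and is exactly
  what the residual errors of the gold standard and cap estimates measure.
  Deformable registration is out of scope.
* Only positions at or above the ear-level ring are assessed; cheek and
  neck coverage is absent by design.
* The frozen 289-label registry is this package's definition of the
  above-ear 10-5 subset; other tools freeze different membership lists of
  different cardinality, and only the 21-label 10-20 core can be assumed
  portable across tools.
* Saturation thresholds may need manual adjustment per participant
  (skin-tone variation); only a configuration override is provided, no
  automatic adaptation.
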