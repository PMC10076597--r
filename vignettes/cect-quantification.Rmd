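---
title: "Quantitative CECT analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CECT analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cectquant)
```

## The problem

Contrast-enhanced computed tomography (CECT) images soft tissue by soaking a
fixed specimen — here, murine brain hemispheres — in an X-ray attenuating
staining agent and scanning it at micrometer resolution. Three quantitative
questions drive the analyses in this package:

1. **How fast does a staining agent penetrate the tissue?** The stained
   shell advances inward over days; its depth over time characterizes the
   agent's diffusion behavior.
2. **How well does an agent separate gray from white matter?** Measured as
   a contrast-to-noise ratio between two anatomical regions.
3. **Can white-matter pathology be quantified in 3D?** In a
   cuprizone-demyelination model, myelin loss changes stain uptake, fiber
   bundle geometry and image texture; the package measures fiber volume
   fraction, bundle thickness, gradient-based fractional anisotropy and
   normalized regional gray values.

Volumes are 16-bit TIFF slice stacks with isotropic voxels (6 µm in the
motivating experiments), where gray value 0 means no attenuation (air) and
65535 the strongest attenuation. Arrays are stored `[y, x, z]`; the third
index is the slice, and after `reorient()` the coronal plane is the xy
plane. All quantitative analyses run on the 16-bit data; 8-bit conversion
(`auto_window()` / `apply_window()`) exists for visualization and BMP
export only.

## Gray-value normalization

Absolute gray values are not comparable across scans. Every dataset
contains two reference materials — a ceramic alumina bead (`G_B`) and the
polypropylene sample tube (`G_E`) — plus air. Two mechanisms use them:

* `normalized_gray()` computes the dimensionless `g = (G − G_E) / (G_B −
  G_E)`, which is 0 at the tube, 1 at the bead, and invariant under any
  affine distortion of the scanner's gray scale.
* `normalize_to_references()` maps whole volumes onto a designated anchor
  dataset's scale by the affine transform that aligns their tube and air
  reference means.

"Automatic histogram windowing" for 8-bit conversion is implemented as
percentile windowing with defaults (0.1, 99.9); percentiles rather than
min/max make the window robust to isolated hot or dead voxels. The mapping
rounds half-up and clips at the window bounds.

## Staining kinetics

The specimen is approximated as a sphere from measured volumes: with total
tissue volume $V_e$ and unstained volume $V_u$,

$$R_e = \left(\frac{3V_e}{4\pi}\right)^{1/3},\quad
  r_u = \left(\frac{3V_u}{4\pi}\right)^{1/3},\quad
  r_p = R_e - r_u,$$

and the penetration depth over time is fitted with the exponential-decay
model $r_p(t) = R_e\,(1 - e^{-kt})$, which passes through the origin and
saturates at the asymptote $R_e$ (mm); $k$ (1/day) is the growth rate. The
fit (`fit_penetration_decay()`) is bounded Levenberg–Marquardt initialized
at $R_e = \max r_p$, $k = 1/\mathrm{median}(t)$. A series in which the
front has already saturated at the first time point leaves $k$
unidentifiable; such fits are flagged (`at_bound`), not raised as errors.

`run_kinetics_study()` automates what interactive segmentation tools did in
the original workflow, with three deliberate choices:

* **Denoising** (`smooth_sigma`, default 1 voxel Gaussian) stands in for
  the median/volume filters a scanner's reconstruction pipeline applies.
* **Interior erosion** (`erode_vox`, default 3 voxels) removes
  partial-volume surface voxels before classifying stained vs unstained;
  surface voxels are mixtures of tissue and solution and otherwise
  masquerade as unstained tissue.
* **Stain threshold rule.** The `"final-percentile"` rule implements the
  classic protocol — the threshold is a low percentile (default 1st) of
  interior tissue gray values at the final, fully stained time point, i.e.
  the least-attenuating stained tissue. With Gaussian noise this rule
  leaves its percentile mass below threshold at *every* time point, which
  floors the measured unstained volume and biases late penetration depths
  low. The default `"interior-otsu"` rule instead places the threshold
  between the unstained and stained gray modes of the first time point
  (Otsu on interior tissue), which localizes the blurred front at its
  midpoint and is unbiased. The unstained volume is measured as the
  largest connected unstained component, so isolated noise voxels never
  count as core.

Total-volume change over time (`volume_change_series()`) is reported in
percent relative to the first time point — the swelling/shrinkage readout.

## Contrast-to-noise ratio

`cnr()` implements
$\mathrm{CNR} = |\mu_1 - \mu_2| / \tfrac{1}{2}(\sigma_1 + \sigma_2)$
between two ROIs (e.g. corpus callosum vs cerebral cortex). ROI statistics
use the population SD (divide by $n$); this is configurable
(`sample_sd`). CNR is invariant under joint affine rescaling, which ties
it to the reference normalization: normalized datasets give the same CNR
as raw ones. Ease of segmentation is probed by `otsu_binarize()`, an
exhaustive 256-bin between-class-variance maximization.

## White-matter microstructure

**Structure tensor and FA.** `structure_tensor()` computes
Gaussian-derivative gradients at scale `sigma_grad`, smooths the gradient
outer products at `sigma_tensor` into a local orientation tensor, and
aggregates once more at `sigma_fiber` to the fiber-bundle scale. The three
scales default to (0.5, 0.5, 5) voxels — the mouse-brain settings — and are
interpreted as Gaussian σ in voxels throughout. Because image gradients
are perpendicular to fiber axes, the fiber direction is the eigenvector of
the *smallest* eigenvalue. `fractional_anisotropy()` applies the standard
DTI formula to the sorted eigenvalues of the fiber-scale tensor,
$FA = \sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert / \lVert\lambda\rVert
\in [0, 1]$, and reports the radial-diffusivity analog
$(\lambda_2 + \lambda_3)/2$. Voxels whose tensor trace falls below
`energy_floor` (default `1e-8`, suppressing numerically-zero tensors in
flat regions) get FA 0. On an isotropic noise phantom the VOI-mean FA is
≈ 0.04; on a perfectly laminar phantom it is ≈ 1.

**Volume fraction.** `volume_fraction()` counts the VOI fraction on the
fiber side of a fixed gray threshold. Polarity matters: a negatively
charged, myelin-repelled agent renders fibers hypointense (`"hypo"`,
fiber = gray ≤ threshold); a positively charged one renders them weakly
hyperintense (`"hyper"`). The threshold is derived once from healthy-tissue
gray levels and held constant between datasets.

**Fiber detection, labeling, thickness.** `detect_fibers()` runs
normalized cross-correlation of oriented cylindrical templates (radius,
length, orientation set configurable; orientations default to a Fibonacci
hemisphere at the requested angular step, plus the pole). The volume is
edge-replicate padded so tubes crossing the VOI border do not produce
spurious end responses. Voxels whose best correlation reaches the cutoff
form the detection *core*; the returned mask additionally paints the
best-matching template footprint at every core voxel, reconstructing the
full tube cross-section around the high-correlation centerline (a raw
correlation threshold only covers the inner ~50% of a matched tube).
`label_fibers()` places markers at regional maxima of the correlation map
(minimum separation defaulting to the template radius; plateau ties break
toward the lowest linear voxel index, and the score is quantized at 1e-6 so
exact plateaus survive FFT round-off) and floods a marker-based watershed
on the inverted correlation inside the mask. `fiber_thickness()` assigns
each voxel the diameter of the largest inscribed sphere containing it,
computed from the exact Euclidean distance transform; a sphere with EDT
radius $r$ spans $2\lceil r\rceil - 1$ voxels ($2r-1$ for integral $r$),
which makes digitized balls of odd diameter evaluate exactly and a single
voxel evaluate to 1. Bundle thickness is the mean local thickness over the
bundle; the study-level summary is the median across bundles, in µm.

In `run_cuprizone_study()` the thickness is measured on the intersection
of the painted detection mask with the fixed-threshold fiber mask. This
matters scientifically: the thickness readout should respond to myelin
loss (bundles thin as their strongly myelinated, stain-repelling core
shrinks), and a purely template-shaped mask has constant thickness by
construction. Each module operation keeps its own contract; the gating is
a pipeline composition choice.

The VOI placement rule "start 50 slices below where fibers first appear"
is operationalized as: the first slice on which `detect_fibers()` yields a
label, plus 50 slices.

## The phantom generator

`phantom_spec()` / `make_scene()` / `make_timeseries()` /
`make_fiber_phantom()` generate fully ground-truthed scenes; every test
and the acceptance script validate the pipeline against their manifests.

What the generator emulates: a quasi-spherical hemisphere in a sample tube
with staining solution, tube wall, ceramic bead and air in the field of
view; a stained shell whose depth follows $R_e(1-e^{-kt})$ with the 1, 2,
4, 9-day design; volume-based swelling per day; parallel fiber bundles at
a target volume fraction (default 0.20, radius 30 µm) with hypo- or
hyperintense polarity; demyelination as a factor $d \in [0,1]$ moving
fiber gray toward background ($d{=}0$ healthy, $d{=}1$ contrast erased);
finite PSF as a 1-voxel Gaussian blur; and i.i.d. Gaussian acquisition
noise (default 700 gray values ≈ 5% of the stained/unstained contrast),
clipped to the bit range with the clipped fraction recorded.

Two geometry decisions are deliberate. The hemisphere is modeled as a
*full* tri-axial ellipsoid: an anatomical hemisphere is a convex blob, and
a literal half-ellipsoid would expose the unstained core at its flat face,
which cannot happen for an immersed specimen. The unstained core is the
concentric similar ellipsoid whose sphere-equivalent radius is
$R_e(t) - r_p(t)$, so the spherical volume relations hold exactly by
construction while the specimen itself is non-spherical — the same model
misfit the sphere approximation faces on real data acts on the shell
geometry, not the volumes.

What the generator does **not** emulate: beam hardening, scatter and ring
artifacts; diffusion-PDE concentration profiles (the front is sharp with
optional blur, because the downstream model assumes a front); anatomical
heterogeneity (cortex layers, hippocampus); curved or branching fibers;
spatially correlated noise. Passing tests therefore demonstrate that the
algorithms recover known ground truth under the stated imaging model, not
that they are robust to every artifact of real scans.

Determinism: a fixed seed makes scenes bit-identical; time series offset
the seed per time point so noise is independent across acquisitions.

## Numerical conventions

* VOIs are 1-based with inclusive bounds; box or sphere, with optional
  slice slabs.
* Rounding in gray-value mappings is half-up; values clip at window/bit
  bounds.
* Percentiles are "smallest observed value with cumulative frequency ≥ p".
* Otsu uses 256 equal-width bins over the full bit range; the returned
  threshold is the lower edge of the upper class, and `gray >= threshold`
  selects the bright class.
* Connected components use 26-connectivity; hole filling floods the
  background with 6-connectivity; watershed floods with 26-connectivity
  and FIFO tie-breaking.
* Reorientation resamples trilinearly by default (nearest-neighbor
  available; exact for 90° multiples on cubic grids) and fills
  out-of-field voxels with 0, the attenuation of air.
* Degenerate inputs fail loudly (constant volumes for Otsu/windowing,
  empty ROIs, overlapping reference VOIs, `G_B = G_E`), except
  non-convergence of the decay fit, which is flagged in the result.

## Problem sizes

The validation suite runs staining scenes on a 128×128×96 grid at 40 µm
voxels (so the tube scene fits a compact lattice) and fiber phantoms on
72³ at 6 µm; the decay-fit Monte Carlo uses 200 replicates at 0.05 mm
noise. These sizes were chosen so the full suite exercises every pipeline
end-to-end in well under a minute of compute while keeping voxelization
error far below the tolerances being tested.

## Known limitations

* The cylinder-correlation defaults (radius 5 voxels, length 15, 30°
  angular step, cutoff 0.5) are package defaults, exposed in full; the
  original interactive software's parameter set is not public.
* Fractional anisotropy from structure tensors is comparable *within* this
  package's runs but not numerically interchangeable with diffusion-MRI FA
  or with other vendors' gradient-FA implementations.
* Group-level inference (ANOVA, multiple-comparison tests) is out of
  scope; study functions report descriptive means ± SD and per-dataset
  metrics that standard R tools can test directly.
* `read_volume()` infers slice order lexicographically; scanners that
  export unpadded numeric names need renaming first.
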