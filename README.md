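# cectquant

Quantitative analysis of contrast-enhanced microCT (CECT) volumes of soft
tissue, built for ex vivo brain imaging with contrast-enhancing staining
agents (CESAs). The package is aimed at imaging scientists who have
reconstructed 16-bit TIFF slice stacks and want reproducible, scriptable
versions of the measurements usually done interactively: staining
penetration kinetics, gray/white-matter contrast, and 3D white-matter
microstructure readouts in demyelination models.

## What it computes

**Staining kinetics.** The specimen is approximated as a sphere from its
total volume V_e and unstained volume V_u:

    R_e = (3 V_e / 4π)^(1/3),   r_u = (3 V_u / 4π)^(1/3),   r_p = R_e − r_u

and the penetration depth over staining time is fitted with the
exponential-decay model

    r_p(t) = R_e (1 − exp(−k t))

giving the asymptote R_e (mm) and growth rate k (1/day). Total-volume
change over time quantifies staining-induced swelling or shrinkage.

**Contrast.** CNR = |μ₁ − μ₂| / ((σ₁ + σ₂)/2) between two regions of
interest, plus Otsu binarization (exhaustive 256-bin between-class
variance) as the ease-of-segmentation readout.

**Normalization.** Reference materials present in every scan (ceramic
bead G_B, sample tube G_E) anchor the dimensionless normalized gray value
g = (G − G_E)/(G_B − G_E) and the affine rescaling of whole datasets onto
a common gray scale.

**Microstructure.** Gradient structure tensors at three Gaussian scales
(defaults 0.5, 0.5, 5 voxels) yield a DTI-like fractional anisotropy
FA = √(3/2)·‖λ − λ̄‖/‖λ‖ and a radial-diffusivity analog ((λ₂+λ₃)/2);
fiber volume fraction at a fixed normalized threshold; cylinder-correlation
fiber detection; marker-based watershed bundle labeling; and
inscribed-sphere local thickness (Thickness3D-style), summarized as the
median bundle thickness in µm.

**Phantoms.** A deterministic generator (`phantom_spec()`, `make_scene()`,
`make_timeseries()`, `make_fiber_phantom()`) produces scenes with full
ground-truth manifests — staining front geometry, reference materials,
fiber systems with hypo-/hyperintense polarity and a demyelination factor,
Gaussian noise — that back every test in the package.

## Worked example

Generate a staining time series at 1, 2, 4 and 9 days and recover the
front kinetics:

```r
library(cectquant)
spec <- phantom_spec(seed = 1)                    # k = 0.5/day ground truth
series <- make_timeseries(spec, times = c(1, 2, 4, 9))
man <- series[[1]]$manifest
report <- run_kinetics_study(
  lapply(series, `[[`, "volume"), times = c(1, 2, 4, 9),
  tissue_threshold = (spec$grays$solution + spec$grays$stained) / 2,
  exclude = list(man$vois$bead, man$vois$tube))
round(report$kinetics, 4)
#>   t     V_e    V_u    R_e    r_u    r_p
#> 1 1 17.0751 3.8142 1.5974 0.9693 0.6282
#> 2 2 17.0749 0.8486 1.5974 0.5873 1.0101
#> 3 4 17.0756 0.0350 1.5975 0.2029 1.3945
#> 4 9 17.0747 0.0000 1.5974 0.0000 1.5974
report$fit[c("R_e_hat", "k")]
#> $R_e_hat
#> [1] 1.618230
#> $k
#> [1] 0.4912179
```

Columns are per time point: total and unstained volume (mm³), the
sphere-equivalent radii (mm) and the penetration depth r_p (mm). The
fitted asymptote 1.618 mm and rate 0.491/day recover the generator's
truth (1.598 mm, 0.5/day) within ~2% at 5% acquisition noise — the same
segmentation → sphere approximation → decay fit chain one would run on
real scans via `read_volume()`.

The demyelination workflow is analogous: `make_fiber_phantom()` for a
healthy and a treated scene (or two real datasets), then
`run_cuprizone_study()` returns fiber volume fraction, median bundle
thickness, VOI-mean FA and the four-position normalized gray report with
percent change against the healthy baseline.

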