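---
title: "Estimating the statistical technical variation of SUV metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the statistical technical variation of SUV metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative FDG-PET reports uptake through SUV metrics: SUVMax (the
hottest voxel of a lesion), SUVMean (the average over a volume of
interest) and SUVPeak (the average over a 1 cm^3 ball centered on the
hottest voxel). Deciding whether a change between two scans is real
requires knowing how much of the observed difference is irreducible
measurement noise. Part of that noise is *statistical technical
variation*: radioactive decay is a Poisson process, so even two
reconstructions of exactly the same acquisition geometry and activity
differ. This package implements a method to quantify that floor, per SUV
metric and per lesion size, from a single acquisition.

## The method

A single acquisition of duration $T$ (here 150 s, one bed position of a
NEMA image-quality phantom) is re-framed into subsets of shorter
reconstruction length (RL): disjoint half-open intervals
$[k\,\mathrm{RL}, (k+1)\,\mathrm{RL})$, $k = 0 \ldots
\lfloor T/\mathrm{RL}\rfloor - 1$. Because the intervals never share a
coincidence, the frames of a subset are statistically independent
samples of the same object at a shorter counting time. Fourteen subsets
are built with RL from 4 s (37 frames) to 30 s (5 frames).

For each subset, each sphere and each metric, the coefficient of
variation across the frames is

$$\mathrm{CoV} = 100 \cdot \frac{s}{\bar{x}} \,[\%],$$

with $s$ the sample standard deviation ($n-1$ denominator; the small
subsets, down to $n = 5$, make the unbiased choice matter). Under a
random-sampling model with independent counts, standard deviations at
two reconstruction lengths are related by the inverse square-root law

$$\mathrm{SD}_2 = \mathrm{SD}_1 \sqrt{\mathrm{RL}_1 / \mathrm{RL}_2},$$

so each subset's CoV yields one estimate of the CoV at the full length
$\mathrm{RL}_2 = 150$ s. The 14 estimates are summarised by their mean
and SD (`estimate_at_full_length()`); each subset can also be
cross-estimated from the 13 others (`cross_estimate_matrix()`). The law
is applied to the CoV rather than the raw SD: the ratio form is
identical for both, and the CoV is the scale-free quantity a clinic
would use.

Welch two-sample t-tests (unequal variances, two-sided, $\alpha = 0.05$)
compare the estimate populations between adjacent sphere sizes and
between metrics; a Kolmogorov-Smirnov check (raw and log-transformed) is
run on every subset population. No multiple-testing correction is
applied to the significance flags, matching common practice for this
kind of exploratory table; a Holm-adjusted column is emitted alongside
so readers can apply the stricter view.

## The phantom simulator

The simulator replaces scanner and reconstruction so the whole chain is
testable. It models the NEMA IQ phantom: an elliptical torso
cross-section (semi-axes 150 x 110 mm) filled with background activity,
a cold cylindrical insert (radius 25 mm) on the axis, and six spheres of
10/13/17/22/28/37 mm diameter on a 57.2 mm ring in one axial plane.
Default concentrations at scan start are 2.10 MBq/ml (background) and
20.04 MBq/ml (spheres), a nominal 10:1 ratio; the simulator stores the
two concentrations and reports the computed ratio (about 9.54:1) rather
than forcing a rounded value. The grid is 144 x 144 in-plane with 4 mm
isotropic voxels; the axial extent defaults to 48 slices (192 mm), enough
to hold the sphere plane with generous margin. Ground truth is rasterized
with sub-voxel supersampling of the sphere boundaries (default $3^3$
points for voxels straddling a surface), so partial-volume fractions are
explicit; the torso edge and the cold insert use the plain center-in
rule, since the sphere analysis never reads those interfaces.

Noise follows counting statistics. A single calibration constant - the
effective sensitivity, in expected counts per (kBq/ml x ml x s) -
converts truth concentration, voxel volume and frame duration into a
Poisson mean per voxel, so the per-voxel CoV is $1/\sqrt{\mu}$ and
scales exactly as $\mathrm{RL}^{-1/2}$. Frames are decay-corrected to
acquisition start using the frame-averaged decay factor
$\frac{1}{\mathrm{RL}}\int 2^{-t/T_{1/2}}\,dt$ over the frame (F-18,
$T_{1/2} = 109.7$ min); the integral form is exact, and at these frame
lengths differs negligibly from a midpoint rule.

Two modelling choices deserve emphasis:

* **Correlated noise.** By default an 8 mm FWHM Gaussian point-spread
  blur is applied *after* the noise draw. The blur is linear, so the
  expectation remains the blurred truth and every voxel's SD still
  scales as $\mathrm{RL}^{-1/2}$; what changes is that the noise
  acquires the spatial correlation length of the PSF, the texture that
  iteratively reconstructed PET images actually have. This matters for
  the max-seeking metrics: with independent white voxel noise the
  hottest voxel of a large uniform sphere is an arbitrary interior
  voxel, the 1 cm^3 peak ball wanders across the sphere edge, and
  SUVPeak's variation no longer falls with sphere size - a behaviour
  real reconstructions do not show. A `psf_apply = "pre"` mode (blur the
  truth, keep voxel noise independent) is retained for experiments. The
  8 mm width is a typical effective resolution for accreditation-style
  whole-body reconstructions on 4 mm voxels.
* **Sensitivity.** The default, 2e-4 counts/(kBq s), is calibrated so
  that the 10 mm sphere's SUVMax CoV at RL = 4 s falls in the 20-30%
  band - the level reported for small objects at very short frame
  lengths. One constant absorbs scanner sensitivity, randoms/scatter
  losses and reconstruction noise amplification; none of those are
  modelled individually.

Randomness is controlled by one master seed; every frame draws from its
own deterministic substream indexed by (schedule, frame), mirroring the
statistical independence of disjoint list-mode intervals. Identical
seeds give bit-identical volumes.

A fixed multiplicative "fill texture" field (`apply_fill_texture()`) can
emulate percent-level fill inhomogeneity: it is constant across frames,
so it adds no frame-to-frame variance, but it anchors the argmax of
max-seeking metrics the way a real, imperfectly mixed fill does. The
pipeline default leaves it off.

## Regions of interest and metrics

Spheres are located either from the known geometry (centers refined by
the intensity center of mass within the nominal sphere - the default for
simulated data) or automatically: light Gaussian smoothing, the six
strongest local maxima separated by at least 20 mm (with non-maximum
suppression wide enough that the halo of the 37 mm sphere cannot
resurface as a spurious candidate), equivalent diameters from the
50%-of-local-max isocontour volume, and rank matching of estimated to
expected sizes.

Masks use the center-in rule: a voxel belongs to a sphere ROI iff its
center lies within the nominal radius. On 4 mm voxels this gives 7
voxels for the 10 mm sphere (19 for 13 mm), 5 in its central plane, and
19 voxels for the 1 cm^3 peak ball (radius
$(3 \cdot 1000/4\pi)^{1/3} \approx 6.2$ mm). SUVMean uses the full mask
with no thresholding. SUVMax 2D/3D are maxima over the central-plane
disk and the full sphere mask; the SUVMax search is deliberately
restricted to the nominal mask. SUVPeak averages the peak ball centered
on the sphere's argmax; ties break at the lexicographically lowest
index, and a ball clipped by the grid edge is used as-is with a
warning - background spill-in near small spheres is inherent to the
metric as defined. ROIs are detected once on a reference image and
reused for every frame of every subset, so the measured variation
isolates counting statistics rather than ROI placement. Values are
reported as activity concentration (kBq/ml); a phantom has no body
weight or injected dose to normalise by, and a constant scale factor
would cancel from every CoV anyway.

Degenerate cases are pinned down deterministically: a sphere center
exactly between two slices takes the lower slice as its central plane;
remainder seconds of the acquisition (e.g. 150 mod 4) are dropped rather
than pooled into a shorter frame, keeping every frame of a subset at the
same RL so the equal-variance premise of the extrapolation holds.
Indices are 1-based with the voxel-center convention
(position = origin + (index - 1) x spacing), the idiomatic choice for R
arrays.

## What the validation does and does not show

The test suite validates the chain in three tiers. Exact facts
(partition counts, mask cardinalities against exhaustive lattice
enumeration, the extrapolation algebra and its round trip) are asserted
to machine precision. Distributional properties of the simulator (voxel
CoV $= 1/\sqrt{\mu}$, the $\mathrm{RL}^{-1/2}$ scaling exponent, mean
preservation, decay-correction invariance) are checked on small grids
with fixed seeds. Finally, the full default study is simulated once - all
14 subsets plus 100 independent 150 s frames, about a million voxels per
frame - and the extrapolated estimates are compared with the directly
measured full-length CoV for every metric and sphere, together with the
qualitative structure: CoV falls with RL and with sphere diameter;
short frames inflate the mean of SUVMax and SUVPeak (for the larger
spheres, where the effect is unambiguous) but not SUVMean; SUVMean3D
varies less than SUVMax3D on the large spheres.

Two caveats frame these results. First, the simulator emulates counting
statistics, resolution and noise correlation, but not scatter,
attenuation, randoms, reconstruction non-linearity, or fill
inhomogeneity; passing tests demonstrate the estimator's behaviour under
ideal counting noise, not scanner-specific accuracy, and absolute CoV
values remain scanner- and protocol-specific. Second, the mean
inflation of max-seeking metrics at short RL sits in the denominator of
the CoV, so extrapolation from short subsets carries a downward bias for
SUVMax and SUVPeak that is invisible for SUVMean - the two facts are two
faces of the same order-statistics effect. In this simulator the bias is
a modest fraction of the spread of the 14 estimates and shows up as a
predominance of negative deviations between the extrapolated and the
directly measured full-length CoV; users extrapolating max-type metrics
across large RL ratios should expect mild underestimation of the
full-length CoV, most visibly for SUVPeak on the largest spheres.

Problem sizes in the routine tests are chosen to keep a full run
comfortable on one CPU: unit tests use 20-80 voxel grids, and the
end-to-end validation uses the full default grid with 166 subset frames
plus 100 reference frames. The CSV/JSON tables are the pipeline's
contract; figures analogous to the usual CoV-versus-RL plots are easy to
produce from `cov_by_subset()` output but are deliberately not part of
the artifact set.
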