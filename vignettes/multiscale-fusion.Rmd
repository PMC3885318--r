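---
title: "Multiscale wavelet-domain fusion of multimodal medical images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale wavelet-domain fusion of multimodal medical images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavefuse)
```

## The problem

Different medical imaging modalities see different tissue: CT renders
bone and sharp anatomical boundaries with high contrast, MRI renders
soft-tissue variation that CT misses. When the two acquisitions are
co-registered — pixel (x, y) corresponds to the same anatomical location
in both — pixel-level fusion can combine them into a single image
carrying both kinds of information, which is cheaper to store, read and
process than the pair.

`wavefuse` fuses in the wavelet domain. The discrete wavelet transform
(DWT) concentrates salient structure — edges, boundaries, contours —
into few large coefficients, localized in space and scale and split into
three orientations (horizontal, vertical, diagonal). That makes a very
simple rule effective: decompose both sources, keep at every coefficient
position whichever source's coefficient has the larger absolute value,
and invert.

## The transform

The analysis bank is an orthogonal Daubechies filter pair: the scaling
filter `l(k)` (normalized to sum to √2) and its quadrature-mirror
high-pass `h(k) = (−1)^k l(N−1−k)`. The default mother wavelet is db3 —
6 taps, three vanishing moments — a short filter that keeps edge energy
compact without excessive ringing; `haar`, `db2` and `db4` are also
available (Haar is required by the shift-invariant baseline). The filter
coefficients are the standard published constants; the test suite
asserts the defining invariants (normalization, orthonormality over even
shifts, the quadrature-mirror relation, vanishing moments) rather than
trusting them.

Conventions, fixed once for bit-stable reproducibility:

* separable order: rows (width axis) first, then columns;
* analysis phase: "filter, then keep the even-indexed samples of the
  full convolution", `a[i] = Σ_k filt[k] · x[2i − k]`;
* synthesis is the exact adjoint of analysis, which for an orthonormal
  bank is its exact inverse — reconstruction error is machine precision
  (~1e-13), far inside the 1e-8 contract the tests assert.

### Boundary handling

The default mode is **periodic** (circular) extension. It preserves the
orthonormal energy identity, keeps every subband at `ceil(n/2)` samples,
and lets the recursion run all the way down to a 1 × 1 approximation —
which is what makes level 8 reachable on a 256 × 256 image. An
odd-length axis is padded by replicating its last sample and cropped
back at synthesis. The level capacity is therefore the pure dyadic rule

```r
max_decomposition_level(256, 256)   # floor(log2(min(H, W))) = 8
```

deliberately *not* the filter-length-aware rule
`floor(log2(n / (filterlen − 1)))` often used elsewhere, which would cap
db3 on 256 × 256 at level 5 and forbid the deepest scales of the sweep.
At those depths the filter is longer than the band it convolves and
wraps around it; periodic extension makes that well defined and exactly
invertible.

A **symmetric** (half-point reflection) mode is available behind a flag
for users who dislike wrap-around artifacts at image borders. It extends
each axis by `filterlen − 1` reflected samples and applies the
zero-extension transform to the extended signal; synthesis is again the
exact adjoint followed by a center crop, so perfect reconstruction holds
at machine precision in this mode too. The price is redundancy: subbands
hold `ceil((n + 3(filterlen − 1))/2)` samples per axis instead of
`ceil(n/2)`, and the energy identity no longer holds (the reflected
samples are counted twice). Fusion results with either mode are
deterministic; no randomness exists anywhere in the fusion path.

## The fusion rule

All detail coefficients are fused by maximum absolute value, ties going
to the first source (the rule's `>=` gives source A priority on exact
ties, and the near-symmetry property — fuse(A,B) and fuse(B,A) differ
only at exact-tie positions — is tested). Two decisions were genuinely
open:

* **Approximation band.** The selection rule is stated for wavelet
  coefficients without excluding the final approximation band; the most
  faithful reading applies max-absolute selection there too, and that is
  the default. Because coefficient-max on a low-pass band can produce
  patchy luminance when the sources have similar large-scale brightness,
  `approximation_rule = "average"` switches that one band to the
  arithmetic mean. All tests of the headline properties run with the
  default.
* **Range handling.** Inputs must share a declared intensity range for
  the max rule to compare like with like; mismatched ranges trigger a
  warning and both images are rescaled to [0, 1]. Reconstructed
  intensities may slightly overshoot the declared range; they are
  clipped only at export time, never inside the pipeline, so metric
  computation sees the floating-point image.

The multiscale driver simply repeats decompose–select–reconstruct for
every level in the requested range (2 up to capacity by default),
returning one fused image per scale. Deeper levels route more
coarse-scale content through the selection rule — visible as rising
entropy in the comparison table — and the choice of working scale is
left to the user.

## Quality metrics

The seven non-reference metrics follow their standard literature
definitions; where the literature leaves a constant or stencil open, the
choice is fixed here and documented:

* **E** — Shannon entropy of the intensity histogram, 256 equal-width
  bins over the declared range (the 8-bit convention; configurable).
* **SD** — population standard deviation (divide by N, not N − 1).
* **SF** — spatial frequency `sqrt(RF² + CF²)`, RF/CF the RMS of
  horizontal/vertical first differences.
* **AG** — average gradient: mean over the (H−1) × (W−1) interior of
  `sqrt((Δx² + Δy²)/2)` with forward differences.
* **MI** — fusion mutual information `I(F;A) + I(F;B)` from 256 × 256
  joint histograms, in bits (the sum convention, not a normalized
  variant).
* **Q** — the Xydeas–Petrovic gradient-preservation score: Sobel
  magnitude and orientation per pixel, per-source preservation ratios
  through sigmoids with the published gains/slopes/offsets
  (`q_constants()`), combined as a gradient-magnitude-weighted average.
  One deliberate normalization: each sigmoid is scaled to equal exactly
  1 at perfect preservation, so that a fused image identical to both
  sources scores Q = 1 (the raw published constants saturate near 0.975,
  which makes the perfect-transfer anchor fuzzy). Fully constant sources
  make the weighted average 0/0; the metric then returns `NA` with a
  warning rather than propagating NaN.
* **BSSIM** — blind structural similarity: SSIM of the fused image
  against each source over sliding 8 × 8 uniform windows (unit stride,
  K1 = 0.01, K2 = 0.03 on the declared dynamic range), combined per
  window by the unweighted mean of the two SSIM values. A window larger
  than the image degenerates to one global window.

Every metric is checked against an independently written brute-force
oracle (explicit loops, explicit histograms) on seeded inputs, plus
analytic anchors: a constant image has E = SD = SF = AG = 0, a
half-and-half two-value image has E = 1 bit, a 0/1 checkerboard has
SD = 0.5 and SF = √2, and F = A = B gives Q = 1, BSSIM = 1, MI = 2·H(A).

## Baseline methods

The comparison methods are implemented from their standard
constructions: pixel averaging; PCA fusion (weights from the leading
eigenvector of the 2 × 2 covariance of the flattened images, normalized
to sum to one — two constant inputs fall back to 0.5/0.5, and negatively
correlated inputs, where no convex weighting can follow the eigenvector,
are clamped with a message); pyramid fusion on a Gaussian backbone with
the 5-tap binomial kernel (1,4,6,4,1)/16; and shift-invariant
undecimated (à trous) Haar fusion with periodic boundaries, whose
fusion pipeline commutes exactly with circular shifts of the inputs.

Two pyramid decisions are worth spelling out. The contrast and ratio
variants divide by the expanded next-coarser level; the denominator is
clamped at 1e-6 of the declared range, which keeps dark regions finite
(strictly positive images are unaffected). The gradient variant departs
from the classic construction deliberately: the classic
gradient/FSD-pyramid reconstruction is only approximate, but this
package holds every baseline to the exact identity fuse(I, I) = I. The
band layers are therefore the exactly invertible band-pass differences
`G_k − expand(G_{k+1})`, and the 4-orientation directional-derivative
energy — the gradient pyramid's activity measure — decides, per pixel,
which source's band coefficient is selected. The biorthogonal
spline-wavelet comparison variant is not implemented (its exact filter
choice is ambiguous); the comparison table simply has no such row.

No numeric equivalence with any third-party tool's output is claimed for
the baselines.

## Synthetic phantoms

Real co-registered CT/MRI pairs cannot ship with the package, so all
tests and demos run on generated phantoms that emulate the structure of
the problem: a shared elliptical head (background 20, interior 90,
bright rim 150, on a [0, 255] float scale chosen to give non-degenerate
histograms), plus complementary exclusive features — thin high-contrast
line segments (intensity 230, width 1–2 px) in the left half for the
CT-like modality, smooth Gaussian blobs (σ between 2 and 6 px at the
reference 128-px size, peak near 230) in the right half for the MRI-like
modality. Placing the two feature families in disjoint halves guarantees
disjoint exclusivity masks by construction. The pixelwise maximum of the
two modalities is the ideal composite, and the headline fixture property
— tested over 10 seeds at 128 × 128, level 3 — is that the fused image
is closer (RMSE) to that composite than either input, overall and within
each exclusive region.

Generation is fully deterministic for a fixed (size, seed, n_features)
and restores the caller's RNG state. What the phantoms do *not* emulate:
anatomical realism, acquisition noise and artifacts (only an optional
additive Gaussian noise flag), intensity inhomogeneity, or
mis-registration. Passing the phantom suite therefore demonstrates the
algorithmic contracts — feature transfer, scale behavior, determinism —
not clinical performance on real scanners.

## Problem sizes and numerical choices

The test suite runs on 8–128 px images (50 reconstruction cases, 10-seed
phantom batches, 10-triple metric-oracle batches) and the end-to-end
driver test on one 256 × 256 pair swept to level 8 plus five baselines —
sizes chosen so the whole suite completes in seconds while still
exercising every level of the dyadic recursion. Tolerances: transforms
are asserted to 1e-10 against oracles and 1e-8 for reconstruction
(observed ~1e-13); metrics to 1e-9 (1e-6 for Q, whose Sobel/atan
pipeline accumulates more rounding); exact identities (selection
closure, tie-breaking, shift-equivariance, byte-stable reports) are
asserted with no tolerance at all.

## Limitations

* Inputs must be pre-registered; no registration is attempted.
* Two source images only; no region-based or energy-weighted rules.
* Grayscale only; color inputs are collapsed to luminance on read.
* PNG export is 8-bit (TIFF/PGM carry 16-bit); DICOM/NIfTI are out of
  scope.
* Published benchmark tables for this method were produced on external
  image collections that are not redistributable, so the package verifies
  properties and self-consistency rather than reproducing third-party
  numbers.
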