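---
title: "Quantifying nuclear rim localization and morphometry with nucrim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear rim localization and morphometry with nucrim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(nucrim)
library(dplyr)
```

## The problem

Lamins shape the nuclear envelope, and laminopathies (HGPS, EDMD2) as well
as many tumors deform it: nuclei wrinkle, bleb, and lose their smooth
elliptical outline. Proteins that normally decorate the nuclear rim as
discrete foci — the motivating case is a telomere- and rim-associated
factor imaged together with lamin A/C or lamin B1 — can be displaced by
these alterations. Quantifying that displacement from multi-channel
fluorescence images requires a chain of measurements:

1. segment nuclei from the DNA stain;
2. detect punctate foci (bandpass filter, moment-preserving threshold,
   watershed, particle analysis);
3. measure nuclear shape (circularity, roundness, solidity, blebs) and
   condense it into an aberration score against a wild-type reference;
4. classify each focus as *rim* (< 0.5 µm from the lamina) or
   *nucleoplasmic*, and measure how much of the rim is decorated;
5. quantify colocalization with lamina channels (masked Pearson);
6. relate the per-condition summaries to expression levels by ordinary
   least squares.

nucrim implements this chain as composable functions over tibbles, plus a
synthetic image generator with per-object ground truth so every stage is
testable without external data.

## Measurement model and definitions

**Shape descriptors.** For a binary nucleus mask with area $A$, perimeter
$P$, and second-moment major axis $L$:

$$\text{circularity} = \frac{4\pi A}{P^2}, \qquad
  \text{roundness} = \frac{4A}{\pi L^2}, \qquad
  \text{solidity} = \frac{A}{A_{\text{hull}}}.$$

The perimeter estimator matters: counting boundary pixels inflates $P$ by
up to ~27% on smooth shapes and deflates circularity accordingly. nucrim
uses a Crofton-type estimator (intercept counts in four directions,
weighted by $\pi/8$), which is unbiased for discs; a rasterized disc of
radius 50 px scores circularity ≈ 0.99 and roundness ≈ 1.00. The convex
hull is taken over pixel centres, which undershoots the pixel-count area
by a half-pixel rind on convex shapes; indices are therefore clamped at 1,
and convex shapes score solidity 1 within rasterization error. The major
axis comes from the second-moment ellipse fit with the standard +1/12
pixel-variance correction, so roundness of an ellipse equals its axis
ratio $b/a$.

**Aberration.** Per nucleus, with reference means
$(\bar c, \bar s, \bar r)$ from a designated wild-type-like condition:

$$\text{index} = (\bar c - c) + (\bar s - s) + (r - \bar r),$$

oriented so that larger = more aberrant, and
$\text{aberrant} = (c < \bar c) \wedge (s < \bar s) \wedge (r > \bar r)$
— the simultaneous three-way deviation. The three indices share a 0–1
scale, so the deviations are summed unnormalized. Reference means are
pooled over all reference nuclei. The fraction of aberrant nuclei is the
population-level dysmorphism readout; by construction the reference
population itself can only have a minority flagged.

**Bleb counting.** The count is the number of connected components of
(mask − opening(mask, disc of radius `r_open_um`)) that reach the mask
boundary and exceed `min_bleb_area_um2` (defaults 1 µm and 0.5 µm²). A
geometric caveat documented here because it constrains valid parameters:
morphological opening retains any lobe that can inscribe the opening
disc, regardless of how narrow its neck is, so **only blebs with radius
smaller than `r_open_um` are detectable** by this definition. The
synthetic generator therefore renders 0.75 µm blebs by default, and they
are recovered 3/3 with zero false positives from wrinkles.

**Foci detection.** The chain is bandpass → threshold → watershed →
particle analysis. The bandpass is the classical FFT filter,
$H = (1 - G_\ell)\,G_s$ with $G_c(r) = \exp(-4 (c r)^2)$ for cutoff size
$c$ px at frequency $r$ cycles/px; with the canonical 4 px / 4 px setting
the pass band is a narrow ring around that scale, the DC component is
preserved, and stripe suppression is off. The threshold is the
moment-preserving (Tsai) criterion, implemented directly in its discrete
form: among all candidate thresholds on the 256-bin histogram, choose the
one whose two-level representative image — levels chosen to preserve the
first two gray-level moments — minimises the third-moment mismatch. This
is the optimum the classical percentile rule targets, and the discrete
argmin form agrees *exactly* with an exhaustive search, which the test
suite verifies against an independently coded oracle on 100 random
histograms.

Touching foci are split by watershed on the Euclidean distance transform
with an h-maxima tolerance of 0.5 px. The choice is deliberate: spot
pairs at the resolution floor (3σ separation) merge into a single
component whose distance-map saddle is less than 1 px below its maxima,
so a 1 px tolerance never splits them, while 0.5 px splits them without
fragmenting single spots in our recovery experiments.

Particle analysis discards particles below `min_area_px` (default 2 px).
Because bandpassed noise is spatially *correlated*, its threshold
exceedances arrive as multi-pixel blobs; when the imaging PSF is known,
`psf_min_area_px(sigma)` = ⌈π(1.177σ)²⌉ — the half-maximum footprint of
the PSF, ~18 px at σ = 2 px — is the physically motivated floor no
genuine focus can undercut, and it is what the recovery experiments use.

**Rim classification.** The rim reference is the lamina-channel intensity
ridge when that channel is supplied (found by scanning inward along the
normal at each contour sample), else the DNA-mask boundary. A focus is
*rim* when its centroid is strictly closer than `cutoff_um` (default
0.5 µm) to the reference; a distance exactly at the cutoff is
nucleoplasm. *Percent positive rim* samples the boundary contour at
pixel resolution and marks a sample positive when any detected-foci pixel
lies within `occupancy_radius_um` (default 0.25 µm, half the cutoff).
Rim intensity profiles average each channel over a disc (default radius
0.2 µm) at every contour sample against cumulative arc length.

**Colocalization.** Plain sample Pearson over masked pixels — no Costes
thresholding, no background subtraction by default — matching what the
common commercial colocalization modules report. Compartment-resolved
variants restrict the mask to the rim band or its complement inside the
nucleus; profile correlation is Pearson over two rim profiles on the same
arc grid.

**Statistics layer.** Expression fold changes use the standard
$2^{-\Delta\Delta C_q}$ construction; population doublings use
$\log_{10}(n_t/n_0) \times 3.33$ (base 10, with 3.33 ≈ 1/log₁₀2, so PD
counts doublings). Two-sample comparisons use the classical
equal-variance Student t (Welch behind a flag), annotated with the
conventional star mapping (*, **, *** at 0.05, 0.01, 0.001; "ns" above).
Condition-level relations are simple OLS on per-condition means, with the
slope p-value (identical to the correlation-test p-value in simple OLS).
No multiple-testing correction is applied anywhere, matching the
reporting conventions of the field this package serves; users running
many panels should correct downstream. The merged predictor available in
`build_correlation_table()` is z(lamin A / lamin C) + z(aberration
index), both standardized across conditions; the construction is a
declared interpretation since ratio-with-morphometry merges are not
standardized in the literature.

## The synthetic generator: what it emulates, and what it does not

`synthetic_spec()` renders one nucleus in three channels: a filled DNA
mask, a lamina-like rim band of configurable width just inside the
boundary (optionally interrupted by one contiguous gap arc sized by arc
length), and a punctate channel. The boundary is an ellipse modulated by
random low-order Fourier wrinkles (per-mode amplitudes summing to
`wrinkle_amplitude`, so the total radial deviation is bounded) and
decorated with circular bleb lobes. Foci land in the rim band with
probability `rim_fraction`, else uniformly in the interior, with a 3σ
minimum separation enforced by rejection sampling so that counting
recovery is well posed — a simulation assumption, not a biological claim.
Rim foci are co-placed with the *rendered* rim signal: if the band has a
gap, foci avoid it, mirroring a factor that follows the lamina. All
channels are blurred by a Gaussian PSF and degraded by Poisson photon
noise then Gaussian read noise, the standard camera model.

Defaults are chosen once as a realistic SIM-sampled fibroblast-scale
cross-section: 0.04 µm/px (so the 0.5 µm cutoff spans 12 px), a
5 × 3.8 µm semi-axis ellipse in a 384-px field (sized to hold blebbed and
wrinkled phenotypes), 20 foci of σ = 0.08 µm, background 0.1 with Poisson
scale 200 and read noise 0.01. `shape_class_specs()` bundles the three
phenotype presets: *wt* (smooth, elongated), *hgps* (rounder, strongly
wrinkled, 3 blebs — progeria nuclei lose elongation while gaining
boundary irregularity, which is exactly what the three-way aberration
flag keys on), and *mcf7* (elongated, strongly wrinkled, rim
interruptions).

What the generator does **not** emulate: chromatin texture inside the
nucleus, intensity heterogeneity of the lamina, 3-D optical sectioning
and reconstruction artifacts, multiple touching nuclei, illumination
gradients. Passing recovery tests on these synthetics therefore
demonstrates the correctness of the measurement chain, not robustness to
every pathology of real micrographs. Real stacks should be
maximum-intensity projected (which `read_nucleus_image()` does for
z-stacks, with a notice) and inspected.

```{r example}
spec <- shape_class_specs(n_foci = 12, seed = 3)$hgps
nuc <- simulate_nucleus(spec)
seg <- segment_nuclei(nuc$channels$dna, spec$pixel_size_um)
foci <- detect_foci(nuc$channels$foci, seg, min_area_px = psf_min_area_px(2))
rim <- rim_geometry(seg$mask[[1]], spec$pixel_size_um, rim_width_um = 0.4)
classify_foci(foci, rim, cutoff_um = 0.5) |> rim_counts()
shape_descriptors(seg$mask[[1]], spec$pixel_size_um)
```

## Numerical choices and degenerate inputs

- **Coordinates**: 0-based pixel centres, x = column, y = row; physical
  distances via `pixel_size_um`. Centroids are intensity-weighted
  (sub-pixel), since a 0.5 µm classification is distance-sensitive.
- **Thresholding** errors out on constant images ("degenerate
  histogram"); detection treats that as zero particles inside a nucleus.
- **Ties** in the threshold search resolve to the smallest candidate.
- **Clamping** of the three shape indices at 1 absorbs rasterization
  overshoot; degenerate line-like masks raise "axis undefined".
- **Equal bandpass cutoffs** are permitted (the band degenerates to a
  ring); non-positive cutoffs are errors.
- **Zero pooled variance** in the t-test returns p = 1 for identical
  constant samples and errors when the constant samples differ.
- **Regression** needs ≥ 3 points and a non-constant predictor; a
  constant response returns slope ≈ 0, r² = 0, p = 1.
- **Seeding**: `generate_population()` derives per-nucleus seeds from the
  master seed and the condition name, so each condition is reproducible
  in isolation; identical spec + seed is bit-identical.

## Study conditions used by the automated checks

The test suite and `scripts/acceptance.R` exercise the chain end to end
at fixed sizes chosen as the package's documented study conditions:
30 nuclei × 30 foci at SNR 8 (peak/read-noise = 8, σ = 2 px, 6 px
minimum separation) for counting recovery (mean absolute error ≤ 5%);
50 nuclei per rim fraction ∈ {0.2, 0.5, 0.9} with a 0.4 µm band and the
0.5 µm cutoff for rim-fraction recovery (±7 points; the residual upward
bias at low fractions comes from interior foci that legitimately fall
inside the 0.5 µm shell); 30 + 30 nuclei for the WT/HGPS aberration
contrast; 10 nuclei per arm for the colocalization contrast (dense rim
decoration — 110 foci on a 0.3 µm band — versus a pore-like punctate
channel paired with independently, uniformly placed foci); and a
6-condition regression layer with predictor spread 0–1.5, slope −0.5 and
noise SD 0.1, which gives the slope test ≈ 99.5% analytic power at the
5% level, plus 1000 null replicates for the type-I error (≤ 7%
observed). Runtimes stay within a few minutes on one CPU.

## Known limitations

- 2-D only. The motivating measurements were made on 3-D SIM stacks;
  every formula implemented here is well defined on 2-D projections, and
  the projection bridge is documented, but 3-D shell distances and 3-D
  watershed are out of scope.
- The opening-residue bleb counter cannot see blebs larger than the
  opening radius (see above); choose `r_open_um` above the expected bleb
  radius.
- The moment-preserving threshold lands inside the noise tail when the
  bright class is a tiny fraction of pixels; pair it with a PSF-informed
  particle-size floor, as the recovery experiments do.
- Pearson colocalization is reported without thresholding or
  correction; values are comparable within this package, not across
  software that applies automatic thresholds.
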