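# nucrim

Quantification of nuclear-rim protein localization and nuclear
morphometry from multi-channel fluorescence microscopy.

Laminopathic and tumor cells deform their nuclei — wrinkles, blebs, rim
interruptions — and these deformations can displace proteins that
normally decorate the nuclear rim as discrete foci. nucrim implements the
full measurement chain needed to quantify that displacement and relate it
to lamin expression and nuclear shape:

- **Segmentation & detection** — nuclei from the DNA stain
  (moment-preserving threshold), punctate foci via the classical chain
  *FFT bandpass (4 px/4 px) → moments threshold → watershed → particle
  analysis*, with sub-pixel intensity-weighted centroids.
- **Morphometry** — circularity `4πA/P²` (Crofton perimeter), roundness
  `4A/(πL²)` (second-moment major axis; equals b/a for an ellipse),
  solidity `A/A_hull`, opening-residue bleb counts, and a per-nucleus
  **aberration index** `(c̄−c) + (s̄−s) + (r−r̄)` against a wild-type
  reference, with the simultaneous three-way deviation flag and its
  population fraction.
- **Rim topology** — distance of each focus to the lamina (channel ridge
  or mask boundary), rim/nucleoplasm classification at a strict 0.5 µm
  cutoff, percent of the rim decorated by foci, and rim intensity
  profiles along arc length.
- **Colocalization** — masked Pearson, compartment-resolved (rim vs
  nucleoplasm), colocalizing-foci fractions, profile correlation.
- **Statistics** — 2^−ΔΔCq fold changes, population doublings
  `log10(nt/n0) × 3.33`, equal-variance Student t with star annotation,
  and the condition-level OLS correlation layer (including the merged
  lamin-ratio × morphometry predictor).
- **Synthetic ground truth** — a generator of three-channel nucleus
  images (wrinkled/blebbed shape classes, gapped rim band, rim-enriched
  foci, PSF blur, Poisson + read noise) with per-object truth tables, so
  the entire chain is testable end to end.

Everything is tidyverse-native: record-level functions take and return
tibbles, results chain with the pipe, fitted regressions have
`tidy()`/`glance()`/`autoplot()` methods, and `plot_morphometry()` /
`plot_rim_profile()` give ggplot2 graphics.

## Worked example

Simulate one HGPS-like nucleus (rounder, strongly wrinkled, 3 blebs, 12
rim-enriched foci), then quantify it:

```r
library(nucrim)

spec <- shape_class_specs(n_foci = 12, seed = 3)$hgps
nuc  <- simulate_nucleus(spec)

seg  <- segment_nuclei(nuc$channels$dna, spec$pixel_size_um)
foci <- detect_foci(nuc$channels$foci, seg, min_area_px = psf_min_area_px(2))
rim  <- rim_geometry(seg$mask[[1]], spec$pixel_size_um, rim_width_um = 0.4)

classify_foci(foci, rim, cutoff_um = 0.5) |> rim_counts()
#>   nucleus n_rim n_nucleoplasm n_total pct_rim pct_nucleoplasm
#> 1       1     8             4      12    66.7            33.3

shape_descriptors(seg$mask[[1]], spec$pixel_size_um)
#>   area_um2 perimeter_um major_axis_um convex_hull_area_um2 circularity roundness solidity
#> 1   65.781       32.265         9.772               68.486       0.794     0.877     0.96
```

All 12 simulated foci are found; 8 of 12 (66.7%) sit within 0.5 µm of
the rim, exactly matching the generator's truth table (8 rim-placed
foci). The wrinkled, blebbed outline depresses circularity (0.79) and
solidity (0.96) while the near-equal axes keep roundness high (0.88) —
the signature the aberration flag keys on. Feeding populations of such
nuclei through `aberration()` / `build_correlation_table()` reproduces
the group-level contrasts, and `run_pipeline()` drives the whole chain
from a manifest of TIFF files to a CSV bundle with a report and
provenance log.

## Package layout

- `R/synthdata.R` — synthetic nucleus generator and truth tables
- `R/segment.R` — thresholding, bandpass, segmentation, foci detection
- `R/morpho.R` — shape descriptors, blebs, aberration metrics
- `R/rimloc.R` — rim geometry, classification, occupancy, profiles
- `R/coloc.R` — masked Pearson colocalization
- `R/statistics.R` — ΔΔCq, growth, t-tests, regression layer
- `R/pipeline.R` — config (YAML), TIFF I/O, end-to-end driver
- `vignettes/nucrim-methods.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
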