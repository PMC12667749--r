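# mirspec

Analysis of mid-infrared spectrochemical imaging (MIRSI) data for
quantifying how tissue preparation — fresh-frozen (FF) versus
formalin-fixed paraffin-embedded (FFPE) — alters the biochemical
information in hyperspectral absorbance cubes. It is written for
spectroscopists and image analysts working with quantum-cascade-laser or
FTIR microscopes over the fingerprint region (950–1800 cm⁻¹).

## What it computes

For each region of interest (an H×W×426 absorbance cube) the pipeline
runs:

* **Tissue segmentation** by Otsu thresholding of the 1608 cm⁻¹ band
  image; the discarded off-tissue pixels define the background spectrum
  and the noise scale σ (standard deviation of its Savitzky–Golay second
  derivative).
* **Rubberband baseline correction**: subtraction of the lower convex
  hull of each spectrum, removing broad scattering backgrounds.
* **Second-derivative sub-band analysis**: Savitzky–Golay differentiation
  (window 13, order 2; 26 edge points trimmed), significance testing of
  derivative dips by the 3σ rule, per-band **peak occurrence** —
  the number of sampled pixel spectra per ROI containing a significant dip
  within ±2 cm⁻¹ of a reference band center — and consistent-band counts
  (median ROI occurrence ≥ 50%).
* **Band quantification**: composite-Simpson integrals over reference
  windows and the percent reduction of FFPE integrals relative to FF,

  $$ \mathrm{reduction} = 100\cdot\frac{I_{FF} - I_{FFPE}}{I_{FF}}, $$

  plus Gaussian sub-band fitting of mean spectra.
* **Discrimination**: ROI correlation matrices, per-spectrum Z-score
  normalization, PCA → UMAP embedding, and ridge logistic regression
  ranking the top-40 most discriminative wavenumbers.

Because no acquisitions ship with the package, a first-class synthetic
generator (`default_config()`, `simulate_study()`) produces four-class
kidney/liver × FF/FFPE studies with Gaussian band structure, scattering
baselines, spatial amplitude fields, detector noise, FFPE amide
attenuation and the FFPE-specific 1026 cm⁻¹ crosslinking artifact, so the
whole pipeline is exercised as a parameter-recovery problem with known
targets. Cubes can also be read from and written to ENVI header/binary
pairs (`read_cube()`/`write_cube()`).

## Worked example

```r
library(mirspec)

report <- run_study(run_config(seed = 0, run_discriminate = FALSE))
report
#> <run_report> consistent bands per class:
#>   kidney_FF kidney_FFPE    liver_FF  liver_FFPE
#>          13           8          13           7
#> Amide I percent reduction (FFPE vs FF):
#> kidney  liver
#>   66.2   46.1
```

The counts say that 13 vibrational bands are consistently observed across
the 8 fresh-frozen kidney ROIs but only 8 survive FFPE processing (13 vs 7
for liver), and the Amide I band integral drops by ~66% (kidney) and ~46%
(liver) after fixation — the FFPE-attenuation structure the generator was
parameterized with. Individual stages are available as plain functions
(`tissue_mask()`, `background_stats()`, `rubberband_correct()`,
`second_derivative()`, `detect_significant_peaks()`, `peak_occurrence()`,
`band_integral()`, `embed_spectra()`, `feature_importance()`, ...); see the
vignette in `vignettes/mirspec-methods.Rmd` for the model and every
numerical choice.

The `analysis/` directory holds the numbered study drivers
(`01_simulate_study.R` … `04_replicates.R`), thin scripts over the package
that write their tables under `results/`.

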