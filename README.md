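# bundlerepro

Reproducibility analysis of diffusion-MRI tractography bundle segmentations.

When the same subject's white-matter pathways are segmented from scans taken
in different sessions, on different scanners, from different vendors, or with
different acquisition protocols (spatial resolution, gradient directions,
b-value), the resulting bundles — and every shape or microstructure measure
extracted inside them — vary. `bundlerepro` quantifies that variability for
paired study designs, where each comparison holds the subject fixed and
changes exactly one acquisition factor (a *confound contrast*: RESCAN, SCAN,
VEN, RES, DIR, BVAL).

For researchers running multi-site or longitudinal diffusion studies, it
answers: how much does each acquisition factor move my bundle segmentations,
where in the bundle does the disagreement live, which shape features are
robust, and how much extra variance does the tractography step itself add to
FA/MD estimates?

## What it computes

All comparisons operate on a common currency: the **binary bundle mask at
1 mm isotropic resolution** in the subject's reference space. Streamline
bundles (TRK/TCK) are binarized at streamline density ≥ 1; probabilistic
visitation maps at an inclusive threshold of 2.5×10⁻⁴; both are resampled
nearest-neighbour onto the reference grid.

- **Dice overlap** per bundle pair: `dice = 2|A∩B| / (|A|+|B|)`.
- **Agreement/disagreement maps**: per voxel, the fraction of subject pairs
  where both masks contain the voxel (agreement) vs exactly one
  (disagreement) — localizing random boundary noise vs consistent bias.
- **Twelve shape descriptors**: mean length, span, diameter, end radius
  (mm); surface area, end area (mm²); total, trunk, branch volume (mm³);
  curl = length/span, elongation = length/diameter,
  irregularity = surface area / (π · diameter · length).
- **Paired statistics**: MAPE = 100·|x₁−x₂| / mean(x₁,x₂), its signed form
  MPV for bias detection, and paired Wilcoxon signed-rank tests between
  confounds with Bonferroni correction computed from the actual number of
  comparisons.
- **Microstructure**: diffusion tensor fit by iteratively reweighted linear
  least squares (log-linear fit, weights = squared predicted signals, 2
  passes), FA/MD means extracted with a *fixed* reference ROI (isolates the
  acquisition effect) versus each dataset's *native* ROI (adds tractography
  variance); the MAPE gap between the two is the tractography-added variance.
- **Quality control**: bundles removed below 200 streamlines or more than
  3 SD below the per-pathway mean count; subjects dropped per method when
  more than 20% of pathways fail.
- **Synthetic study generator** with known ground truth (centerlines,
  core/branch labels, true tensors) so the entire pipeline is testable
  without patient data.

## Worked example

```r
library(bundlerepro)
library(dplyr)

dir <- tempfile("study")
manifest <- simulate_study(dir, n_subjects = 2, seed = 11, dwi = TRUE)
res <- run_study(manifest, out_dir = file.path(dir, "results"))

summarize_study(res)$dice_by_confound
#> # A tibble: 3 × 5
#>   confound     n median_dice iqr_dice mean_dice
#>   <chr>    <int>       <dbl>    <dbl>     <dbl>
#> 1 RESCAN       4       0.815   0.0549     0.815
#> 2 SCAN1        4       0.750   0.0305     0.748
#> 3 RES1         4       0.706   0.0109     0.705
```

Scan-rescan (0.5 mm streamline jitter) reproduces best, cross-scanner
(1.0 mm jitter) next, and a 2.4 mm-resolution acquisition worst — Dice
ranks the confounds by their effective perturbation size. The
microstructure table separates the two variance sources:

```r
res$microstructure |>
  group_by(metric) |>
  summarise(fixed = mean(mape_fixed_roi), native = mean(mape_native_roi))
#> # A tibble: 2 × 3
#>   metric fixed native
#>   <chr>  <dbl>  <dbl>
#> 1 fa     0.135   4.99
#> 2 md     0.329   0.291
```

With the ROI held fixed, FA varies by ~0.1% across these contrasts (pure
acquisition + noise effect); letting each dataset's own tractography define
the ROI raises that to ~5% — the added variance of the segmentation step.
`autoplot(res)` draws the per-confound Dice boxes, `plot_feature_mape(res)`
the per-feature MAPE panels, and `autoplot(res$agreement[[1]])` an
agreement/disagreement slice.

Individual stages are ordinary functions on tibbles and light S3 containers:
`read_tractogram()`, `streamlines_to_density()`, `density_to_mask()`,
`dice()`, `shape_features()`, `fit_tensor_irwlls()`, `paired_wilcoxon()`,
`qc_filter()` — see the vignette in `vignettes/bundle-reproducibility.Rmd`
for the model definitions and numerical conventions.

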