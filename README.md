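# artifactlab

Respiratory motion corrupts four-dimensional CT (4DCT) of the lung in two
characteristic ways. **Phase-binning artifacts** arise when a stack of axial
slices is reconstructed from the wrong breathing phase, leaving duplicated,
overlapping or cut-off anatomy, typically near the diaphragm. **Interpolation
artifacts** arise when missing projection data is papered over by linearly
interpolating between valid neighbouring slices, smearing everything in
between. Both derail downstream lung segmentation and dose calculation in
radiotherapy planning.

`artifactlab` is a desk-scale R toolkit for studying these artifacts without
clinical data or trained networks. It provides:

- a **seedable multi-phase breathing phantom** (two ellipsoidal lungs in a
  soft-tissue torso with a spine proxy; the diaphragm rises sinusoidally from
  end-inspiration T00 to end-expiration T50) with paired left/right lung
  masks;
- an analytical **phase-binning artifact generator**: a binary slice mask
  `Mg` over the inferior lung half is feathered into `M̂g` by a Gaussian of
  sd σg (the *artifact visibility*), the secondary phase is shifted in-plane,
  the pairing is accepted only when the weighted difference
  `C = M̂g ⊙ (I − Ĩg)` is majority-negative, and the composite
  `Î = I ⊙ (1 − M̂g) + M̂g ⊙ Ĩg` is blended; the ground-truth mask comes from
  thresholding `|I − Î|` at λ ∝ σg followed by morphological closing and
  connected-component filtering;
- an **interpolation artifact generator**: interior slices of perturbed
  intervals `[z0, z1]` are replaced by
  `Îz = ((z1−z)/(z1−z0)) Iz0 + ((z−z0)/(z1−z0)) Iz1`;
- a **rule-based interpolation detector**: simulate the artifact over every
  sliding interval of lengths 3 and 4, flag intervals whose maximum
  voxel-wise difference falls below a per-axial-segment threshold, then apply
  a non-containment rule and merging. Thresholds are fitted per segment by
  minimizing the mean Dice loss `1 − 2TP/(2TP+FP+FN)` within bounds
  (0.2, 0.3) via grid search or bounded Brent optimization, with k-fold
  cross-validation (`fit_interp_detector()` returns a classed model object
  with `print`/`summary`/`coef`/`predict`/`plot` methods);
- a **localized correction** that camouflages phase-binning artifact voxels
  with the mean surrounding lung intensity to rescue intensity-based lung
  segmentation;
- **multi-level metrics**: Dice, accuracy/sensitivity/specificity at
  voxel/slice/stack/region level, weighted-by-volume averages, Youden's
  J = sensitivity + specificity − 1, the overfitting index
  `ϕ = (DL_train − DL_test)/(DL_train + DL_test) + 1 ∈ [0, 2]`, and
  boundary smoothness `β = S/V` with the surface area summed over a
  marching-tetrahedra mesh via Heron's formula;
- **artifact-omics**: 14 morphological features per connected artifact
  component (volume, bounding-box volume, solidity, extent, equivalent
  diameter, PCA axis lengths, elongations, flatness, sphericity,
  compactness) compared between groups with Mann-Whitney U tests plus TOST
  equivalence tests (±0.2 after z-scoring) under Benjamini-Hochberg FDR.

## Worked example

```r
library(artifactlab)

# 10-phase breathing phantom
series <- generate_phase_series(phantom_spec(grid_shape = c(40, 40, 40), seed = 3))
head(phantom_summary(series)[, 1:3], 3)
#>   phase lung_voxels lung_volume_ml
#> 1   T00        6536         52.288
#> 2   T10        6500         52.000
#> 3   T20        6316         50.528

# infuse a phase-binning artifact from the opposite phase
I  <- truncate_and_normalize(series$phases$T00$volume)
S  <- truncate_and_normalize(series$phases$T50$volume)
pb <- infuse_phase_binning(I, S, series$phases$T00$mask,
                           pb_params(h = 6, n_stacks = 1, sigma_g = 1, seed = 5))
pb$accepted
#> [1] TRUE

# infuse and then detect interpolation artifacts
iv  <- list(slice_interval(10, 17))
inf <- infuse_interpolation(I, iv)
det <- detect_interpolation(inf$volume, threshold_profile(rep(1e-3, 10)))
det$intervals
#>   z_start z_end
#> 1      10    17
```

The detector recovers the infused interval `[10, 17]` exactly: the generator
and the detector share the same linear interpolation, so genuinely
interpolated intervals reproduce themselves (difference 0) while the
phantom's voxel noise keeps every artifact-free interval above threshold.

The full demonstration pipeline (phantom → dataset → threshold fitting →
detection → correction → omics) runs in a few seconds at demo sizes:

```r
rep <- run_pipeline(n_series = 3, grid_shape = c(32, 32, 32), seed = 3)
rep
#> <pipeline_report>
#>   3 phantom series, grid 32x32x32, seed 3
#>   mean slice-level detection Dice: 1.000
#>   correction: median Dice 0.834 -> 0.955
#>   omics components: 6
```

A thin command-line front end is installed at `inst/cli/artifactlab.R`
(subcommands `phantom`, `inject-pb`, `inject-interp`, `detect-interp`,
`correct`, `run`).

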