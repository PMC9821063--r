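# ramanphen

Label-free phenotyping of single macrophages from Raman hyperspectral
image scans: spectral preprocessing, N-FINDR unmixing into biochemical
component maps, lipid band-ratio scoring, and PCA-LDA discrimination of
pro-inflammatory (M1) versus non-pro-inflammatory (M0/M2) phenotypes under
leave-one-donor-out cross-validation. A synthetic hyperspectral scene
generator with exact ground truth stands in for raw single-cell data and
drives all quantitative validation.

The package is for spectroscopists and computational biologists who work
with single-cell Raman images (cube `h × w × channels` plus a cell mask
and donor/phenotype metadata) and want a tested, scriptable version of
this analysis chain.

## The methods in brief

* **Preprocessing.** Cell masking; neighbor-median cosmic-ray despiking
  (variance-stabilized residual, 8 robust-sd threshold, ≤3-channel runs);
  exclusion of spectra whose mean SNIP baseline exceeds the in-image
  median by >3 MAD (high fluorescence); removal of the silent region
  1800–2650 cm⁻¹; SNIP baseline subtraction per region — 200 clipping
  iterations on 350–1800 cm⁻¹, 50 on 2650–3100 cm⁻¹, with
  `b_i ← min(b_i, (b_{i−p}+b_{i+p})/2)`, `p = 1..iterations`.
* **Unmixing.** N-FINDR: PCA-project pooled cell spectra to `p−1`
  dimensions and find the `p = 15` pixels whose simplex
  `V = |det[1; v_1 … v_p]|/(p−1)!` has maximal volume (strictly improving
  swaps, 10 seeded restarts); endmembers grouped into
  lipid/protein/nucleus/environment by template correlation; per-pixel
  abundances by non-negative least squares `min ‖y − Eᵀa‖₂, a ≥ 0`;
  false-color rendering (red = lipid, green = protein, blue = nucleus,
  white = environment); per-cell class fractions compared within donors
  by an exact two-sided Mann–Whitney U test (M1 vs M0+M2).
* **Lipid bands.** Abundance-weighted lipid spectrum per cell; trapezoidal
  band integrals with linear-endpoints local background; unsaturation
  ratio `A(1655)/A(1444)`, plus `A(1260)/A(1300)` and the 1740 cm⁻¹ ester
  band.
* **Classification.** Per image: mean-normalize every retained spectrum
  and average; covariance PCA (2 components, training folds only) then
  two-class LDA with equal priors; leave-one-donor-out cross-validation;
  sensitivity, specificity, balanced accuracy, plain accuracy and
  Mann–Whitney ROC AUC pooled over all test folds; LDA coefficients
  back-projected to the wavenumber axis with cross-fold cosine stability.

## Worked example

```r
library(ramanphen)

bench <- generate_benchmark_set(scene_config())   # 66 synthetic cells, seed 42
pp    <- preprocess_set(bench$images)
pp
#> <preprocessed_set> 66 images, 634 channels, 17690 spectra retained
#>   (113 excluded, 9759 spike events)

sel <- select_balanced(set_metadata(bench$images))  # 7 M0, 6 M1, 7 M2
em  <- common_endmembers(pp, sel, p = 15, seed = 1042)
refs <- do.call(rbind, lapply(endmember_templates(), function(tm)
  build_endmember_spectrum(tm, pp$axis)$intensities))
em   <- group_endmembers(em, refs)
maps <- lapply(pp$images, unmix_image, endmembers = em)
comp <- do.call(rbind, lapply(maps, cell_composition))

aggregate(lipid ~ phenotype, comp, mean)
#>   phenotype      lipid
#> 1        M0 0.08428312
#> 2        M1 0.19959093
#> 3        M2 0.10308327
compare_lipid_fraction(comp, "donor1")
#> [1] 0.0002871859

cv <- lodo_cv(build_feature_table(pp), n_components = 2, task = "M1_vs_rest")
cv
#> <cv_report> M1_vs_rest, 3 folds, 66 pooled test predictions
#>   balanced accuracy 67.5%, sensitivity 60.0%, specificity 75.0%,
#>   accuracy 68.2%, ROC AUC 80.6%
#>   coefficient stability (pairwise cosine): 0.384..0.984
```

The M1 cells carry roughly twice the estimated lipid fraction of M0/M2
cells (significant within every donor), and the cross-validated model
separates them with ROC AUC ≈ 0.81 under the benchmark's donor-level
nuisance effects. The vignette
(`vignettes/raman-macrophage-phenotyping.Rmd`) explains each model, every
tunable default, and why the 2-component model is fragile under the
simulated donor wavenumber miscalibration.

`run_pipeline(pipeline_config(out_dir = "run"))` executes all stages and
writes false-color PNGs, composition/profile CSVs, CV JSONs and a
manifest; `inst/scripts/run_pipeline.R` wraps it for the shell with a YAML
config.

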