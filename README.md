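# hipporad

Hippocampal functional radiomics for separating cognitively impaired (CI)
from cognitively preserved (CP) Parkinson's disease patients.

Cognitive impairment in Parkinson's disease is hard to diagnose from
conventional imaging, but the texture of resting-state fMRI derivative maps
of the hippocampus carries discriminative signal. This package implements
the full analysis chain as tested, reusable R code, for neuroimaging
researchers who want to apply or scrutinise the method:

1. **Derivative maps.** From a 4D BOLD volume (detrended, 0.01–0.1 Hz
   band-passed, 6 mm FWHM smoothed — except for ReHo and DC, which use
   unsmoothed data and are smoothed after z-scoring) it computes
   - **ALFF** — mean over in-band frequency bins of √(power spectral
     density) of each voxel's series,
   - **ReHo** — Kendall's coefficient of concordance
     W = 12·S / (m²(n³−n) − m·ΣTⱼ) over a voxel and its 26 neighbours,
   - **VMHC** — Pearson correlation r between a voxel's series and its
     mirror across the x mid-plane,
   - **DC** — weighted degree Σᵤ r(v,u)·1[r(v,u) > 0.25] over all brain
     voxels.
2. **Radiomics.** 819 features per map over the bilateral hippocampus ROI:
   18 first-order + 73 texture (GLCM 22, GLRLM 16, GLSZM 16, NGTDM 5,
   GLDM 14) on the original map, plus the same 91 on each of 8 undecimated
   3D wavelet sub-bands (`wavelet-LLL` … `wavelet-HHH`, coif1), named
   `wavelet-<S>_<family>_<Feature>`.
3. **Selection and models.** Min–max normalisation on training statistics,
   greedy Spearman pruning at |ρ| > 0.9, LASSO (λ by 10-fold CV) → a
   **rad-score** (linear combination of selected features) with a Youden
   cut-off, and a SMOTE-balanced logistic model, evaluated with
   ROC/AUC (DeLong CIs), accuracy/sensitivity/specificity (Wilson CIs),
   DeLong AUC comparisons, decision-curve analysis, and exact linear SHAP
   attribution — over all 15 combinations of the four metrics.
4. **Clinical associations.** Age-adjusted partial correlations between
   selected features and clinical scales (MoCA, UPDRS-III, NMSS, PDQ-39,
   HAMA, HAMD, …) within each group, Bonferroni-corrected (p × n < 0.05).

Because no patient data are distributable, the package ships a **synthetic
cohort generator** that plants group effects as attenuations of the locally
shared and homotopic BOLD components inside the hippocampus mask, with
clinical scores correlated to the injected effect — so the whole chain is
exercised end to end and recovery of known effects is testable.

## Worked example

```r
library(hipporad)
cfg <- run_config(n_ci = 12, n_cp = 12,
                  effect_synchrony = 0.8, effect_homotopy = 0.8,
                  metrics = c("ReHo", "VMHC"),
                  combinations = list(c("ReHo", "VMHC")), seed = 42)
res <- run_pipeline(cfg)
res$summary[, c("combination", "cohort", "auc_rad", "auc_lr",
                "acc_lr", "sen_lr", "spe_lr")]
#>   combination     cohort auc_rad auc_lr acc_lr sen_lr spe_lr
#> 1   ReHo+VMHC      train       1      1      1      1      1
#> 2   ReHo+VMHC validation       1      1      1      1      1
length(res$results[[1]]$selection$selected)   # LASSO kept 4 features
res$results[[1]]$radscore$model$youden_threshold  # 0.22
sort(abs(colMeans(res$results[[1]]$logistic$shap$shap)), decreasing = TRUE)[1:3]
#>                     VMHC_wavelet-HLL_firstorder_Mean
#>                                               1.1138
#> VMHC_wavelet-LHL_glrlm_ShortRunHighGrayLevelEmphasis
#>                                               0.9154
#>                  VMHC_wavelet-HHH_firstorder_Maximum
#>                                               0.1417
```

A strong planted effect (80% attenuation of both shared components in the
CI hippocampus) is fully separable even at 24 subjects: both the rad-score
and the logistic model reach AUC 1 on the held-out validation third, the
LASSO needs only 4 of the 1,638 candidate features, and the SHAP ranking
points at VMHC wavelet features — the attenuated component. With
`effect_synchrony = effect_homotopy = 0` the same pipeline hovers at
chance (AUC ≈ 0.5).

Lower-level entry points: `generate_atlas_mask()`, `generate_bold()`,
`derive_maps()`, `extract_all()`, `spearman_prune()`, `lasso_cv()`,
`delong_test()`, `decision_curve()`, `linear_shap()`,
`partial_correlation()`, `group_compare()`. A thin command-line wrapper
lives in `inst/cli/hipporad.R` (`simulate`, `derive`, `extract`, `run`).

## Limitations

The synthetic generator produces band-limited stationary signals on a small
grid; it emulates the correlation structure the derivatives measure, not
haemodynamics, head motion, registration error, or anatomy. Passing
recovery tests demonstrate that the implementation measures what it claims
to measure — not clinical performance on real cohorts. See the methods
vignette (`vignettes/hippocampal-functional-radiomics.Rmd`) for the model,
conventions and design decisions.
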