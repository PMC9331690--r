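# strokefeat

Does the volume of a stroke lesion tell you everything the image knows
about the patient's outcome? `strokefeat` is an R package for studying
that question at desk scale. It re-implements, end to end, a
feature-set comparison for predicting favorable functional outcome
(the modified Rankin Scale 0–2 analogue) from follow-up
diffusion-weighted MRI after acute ischemic stroke:

1. **FIV** — the follow-up infarct volume, one number per patient;
2. **CAE** — the 100-dimensional latent code of a 3D convolutional
   autoencoder trained to reconstruct the volumes;
3. **Radiomics** — a pinned catalog of exactly 100 features
   (18 first-order, 14 shape, 22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM)
   computed from first principles.

Each feature set feeds an identical protocol: robust scaling by
training-set median/IQR, an SVM tuned by 5-fold cross-validated AUC
over 144 kernel × C × gamma combinations, evaluation on a held-out 20%
test set, pairwise DeLong tests against the best AUC, and Kernel-SHAP
feature attributions for the radiomics model.

Because clinical trial images cannot ship with a package, the first
module is a **seeded synthetic cohort generator**: DWI-like volumes
with a dominant white-matter intensity mode (so white-stripe
normalization is well-posed), one connected hyperintense lesion whose
volume `V` and within-lesion heterogeneity `h ∈ [0,1]` are controlled,
and outcomes drawn from

```
P(favorable) = plogis(5.2 − 3·h − log V + ε),   ε ~ N(0, 0.5)
```

so that heterogeneity — a texture property — carries more weight than
volume. The pipeline's job is to recover that planted structure.

All numerics the analysis depends on are implemented in the package
and tested against independent brute-force oracles: the texture
matrices (co-occurrence, run-length, size-zone, dependence; 26-connected,
direction-averaged over the 13 unique 3D directions), a
marching-tetrahedra mesh volume, the Mann–Whitney AUC
`θ = (1/n₊n₋) Σ Σ [s₊ > s₋] + ½[s₊ = s₋]`, DeLong's placement-value
test for paired AUCs, and Kernel SHAP with exact local accuracy
`Σφᵢ = f(x) − E[f]`. The 3D convolution engine behind the autoencoder
is compiled (RcppArmadillo/BLAS) and gradient-checked.

## Worked example

```r
library(strokefeat)

cfg <- run_config(out_dir = "demo_run", n_subjects = 60, grid = "small",
                  seed = 7, cae_epochs = 2, cae_train_max = 8,
                  shap_subjects = 3, shap_samples = 256)
report <- run_all(cfg, verbose = FALSE)
print(report$metrics[, c("feature_set", "train_accuracy", "test_accuracy",
                         "auc", "precision", "recall", "kernel", "C",
                         "delong_p_vs_best")])
head(report$shap[, c("feature", "mean_abs_phi", "rank")], 5)
```

```
  feature_set train_accuracy test_accuracy       auc precision recall kernel     C delong_p_vs_best
1         fiv         0.6875     0.5833333 0.2285714 0.5833333      1    rbf 1e+03      0.000363343
2   radiomics         0.6250     0.5833333 0.9428571 0.5833333      1    rbf 1e-02               NA
3         cae         0.6250     0.5833333 0.8857143 0.5833333      1    rbf 1e-02      0.698535358

                                                                          feature mean_abs_phi rank
glcm_ClusterShade                                               glcm_ClusterShade 0.0015420675    1
glszm_LargeAreaHighGrayLevelEmphasis         glszm_LargeAreaHighGrayLevelEmphasis 0.0006170890    2
gldm_LargeDependenceLowGrayLevelEmphasis gldm_LargeDependenceLowGrayLevelEmphasis 0.0005856825    3
glszm_LargeAreaLowGrayLevelEmphasis           glszm_LargeAreaLowGrayLevelEmphasis 0.0005257696    4
firstorder_Minimum                                             firstorder_Minimum 0.0004977020    5
```

One row per feature set: accuracy at the decision threshold, the
Mann–Whitney AUC of the continuous decision scores on the 12 held-out
subjects, precision and recall for the favorable class, the selected
hyperparameters, and the two-sided DeLong p-value against the best
feature set (here radiomics, which is why its own entry is `NA`). At
this demo size (60 subjects, 12 test scans, a 2-epoch autoencoder) the
point estimates are very noisy — note the FIV AUC of 0.23 — which is
exactly why the packaged experiments repeat the comparison over 10
cohorts of 206 subjects. The SHAP ranking already shows the planted
structure: size-zone large-area and texture features on top, with the
mesh- and voxel-volume features far down the list.

Per-stage functions are exported too (`generate_cohort()`,
`white_stripe_normalize()`, `segment_threshold()`,
`extract_features()`, `build_cae()`/`train_cae()`/`encode()`,
`grid_search_svm()`, `delong_test()`, `kernel_shap()`, ...), and a thin
command-line wrapper lives at `inst/cli/strokefeat.R`. The methods
vignette (`vignettes/strokefeat-methods.Rmd`) documents the generative
model, every numerical convention, and the design decisions.

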