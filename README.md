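# nirspa

Chemometric classification of near-infrared (NIR) tissue spectra, built for
the question a diagnostic spectroscopist actually faces: can a handful of
wavenumbers separate malignant from normal tissue as well as a
full-spectrum model? The package implements the complete two-class
workflow — synthetic spectrum simulation, SNV and Savitzky–Golay derivative
preprocessing, PCA exploration, **SPA-LDA** variable selection with a
pooled-covariance Mahalanobis discriminant, a **PLS-DA** full-spectrum
baseline, and sensitivity/specificity evaluation over a
training/validation/test design (class 1 = cancerous, 2 = normal).

## The method in brief

**SPA-LDA.** Phase 1 builds, from the class-mean-centred training matrix
*X* (*N* × *K*), one chain of up to *L* ≤ *N* − *C* variables per channel by
successive orthogonal projections: each step appends the column with the
largest residual norm outside the span of those already chosen, so selected
variables are minimally collinear. Phase 2 scores every chain prefix — up to
*K* × *L* candidate subsets — on the validation set by the average
misclassification risk

    G_cost = (1/N_val) Σ_n g_n,
    g_n = MD²(x_n, true-class mean) / min over wrong classes MD²(x_n, wrong mean)

with MD²(x, x̄) = (x − x̄) S⁻¹ (x − x̄)ᵀ and S the pooled within-class
covariance (denominator *N* − *C*) of the training set restricted to the
candidate. The minimising subset defines an LDA that assigns new spectra to
the nearest class mean in Mahalanobis distance.

**PLS-DA baseline.** NIPALS PLS1 regression of mean-centred spectra on the
dummy class code (1/2), thresholded at 1.5; latent-variable count chosen by
a quota-design 5-fold cross-validation (5 cancerous + 7 normal per fold
under the 26 + 36 design, remainder in the fifth fold).

Because clinical NIR spectra of this kind are not public, a synthetic
generator (`synthetic_config()`, `generate_spectra()`) supplies two-class
spectra with the structure the analysis assumes — broad overlapping Gaussian
bands, >0.99 adjacent-channel correlation, multiplicative scatter and
offset, planted class-difference bands — with a closed-form Bayes accuracy
(`bayes_accuracy()`) available as ground truth whenever scatter is off.

## Worked example

```r
library(nirspa)

cfg <- pipeline_config()   # 3 subsets x (26 cancerous + 36 normal),
                           # 4000-10000 cm^-1 at 4 cm^-1 (1501 channels)
res <- run_pipeline(cfg)
#> generate: seed 1
#> split: seed 2
#> preprocess: snv=TRUE derivative=TRUE window=11 polyorder=2
#> pca: first 3 components explain 15.0% of variance
#> spa_lda: selected 1 variable(s) at 4204 cm^-1
#> pls_da: cross-validation chose 1 LV(s)
#> training: SPA-LDA sens 96.2% spec 88.9% | PLS-DA sens 100.0% spec 100.0%
#> validation: SPA-LDA sens 100.0% spec 100.0% | PLS-DA sens 100.0% spec 100.0%
#> test: SPA-LDA sens 84.6% spec 97.2% | PLS-DA sens 100.0% spec 100.0%

tidy(res$spa)
#> # A tibble: 1 × 4
#>   index wavenumber mean_class_1 mean_class_2
#>   <int>      <dbl>        <dbl>        <dbl>
#> 1    52       4204       0.0312       0.0371
```

Reading this: under the default generator the three planted
class-difference bands sit at 4065, 4173 and 5758 cm⁻¹; SPA-LDA picked a
single channel at 4204 cm⁻¹ — inside the derivative signature of the
4173 cm⁻¹ band — and classifies the held-out test subset with 84.6%
sensitivity (22/26 cancerous found) and 97.2% specificity (35/36 normal
cleared), while the full-spectrum PLS-DA baseline, using all 1501 channels
through one latent variable, is error-free on this synthetic draw. The
trade parsimony buys interpretability: one wavenumber versus a 1501-channel
regression vector. `autoplot(res$spa)` draws the validation cost curve,
`autoplot(res$pca)` the PC1/PC2 scores, and `run_pipeline(cfg, out_dir =
"run1")` persists every intermediate table, both model reports and a run
log as plain text.

Lower-level verbs compose with the pipe if you want the stages individually:

```r
subs <- synthetic_config() |> generate_spectra() |> split_subsets(seed = 2)
train <- preprocess(subs$training)
fit   <- spa_lda(train, preprocess(subs$validation), l_max = 10)
predict(fit, preprocess(subs$test))
```

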