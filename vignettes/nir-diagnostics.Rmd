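---
title: "Variable-selection diagnostics for NIR tissue spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-selection diagnostics for NIR tissue spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirspa)
```

## The problem

Near-infrared (NIR) diffuse-reflectance spectroscopy probes overtones and
combination bands of molecular vibrations in the 4000–10000 cm⁻¹ region.
Because malignant and normal tissue differ in composition (proteins, lipids,
carbohydrates, water), their log(1/R) spectra differ subtly — but NIR bands
are broad, overlapping, and strongly collinear across neighbouring channels,
so a usable diagnostic must be a multivariate model. `nirspa` implements a
complete two-class classification workflow for this setting: spectral
preprocessing, unsupervised exploration, a parsimonious variable-selection
classifier (SPA-LDA), a full-spectrum baseline (PLS-DA), and
sensitivity/specificity evaluation over a training / validation / test
design. Class codes follow the clinical convention used throughout the
package: **1 = cancerous, 2 = normal**, with cancer as the positive class.

Clinical spectra of this kind are rarely public, so the package ships a
synthetic-spectrum generator whose statistical structure matches what the
analysis assumes; every claim the test suite makes is against data with
known ground truth.

## The SPA-LDA method

SPA-LDA couples the successive projections algorithm (SPA) with a
pooled-covariance Mahalanobis linear discriminant.

**Phase 1 — chains.** The $N \times K$ training matrix $X$ is first centred
on its class means (so class separation does not masquerade as
collinearity). For each of the $K$ channels as an initialiser, a chain of up
to $L$ variables is grown: at each step every remaining column is projected
onto the orthogonal complement of the span of the columns already selected,
and the column with the largest residual norm joins the chain. Chains are
therefore maximally *non*-collinear by construction. The chain length is
bounded by $N - C$ ($C$ = number of classes), the residual degrees of
freedom after class-mean centring.

**Phase 2 — cost.** Each chain contributes one candidate subset per prefix
length, up to $K \times L$ candidates. A candidate $I$ is scored on the
*validation* set by the average misclassification risk

$$G_\mathrm{cost} = \frac{1}{N_\mathrm{val}} \sum_{n=1}^{N_\mathrm{val}} g_n,
\qquad
g_n = \frac{\mathrm{MD}^2(x_n, \bar x_{I_n})}
           {\min_{j \ne I_n} \mathrm{MD}^2(x_n, \bar x_{I_j})},$$

where $\mathrm{MD}^2(x, \bar x) = (x-\bar x)\,S^{-1}(x-\bar x)^\top$ and $S$
is the pooled within-class covariance $\sum_c \sum_{i \in c}
(x_i-\bar x_c)(x_i-\bar x_c)^\top / (N-C)$, estimated on the training set
restricted to $I$. $g_n$ is zero when a sample sits on its own class mean
and grows past 1 as it nears a wrong class. The subset minimising
$G_\mathrm{cost}$ defines the final classifier: assign a new spectrum to the
class with the smallest Mahalanobis distance.

Design points that the literature leaves open, fixed here:

* **Chain criterion.** The construction is the classic maximal-residual-norm
  orthogonal projection scheme; "minimal correlation" phrasings found in
  applied papers are treated as an informal description of the same
  operation.
* **Candidate identity.** A candidate is the *set* of its variables: the
  cost is mathematically invariant to the order in which a prefix listed
  them, so prefixes are canonicalised to sorted index order before
  de-duplication and scoring. Ties in cost are broken toward fewer
  variables, then the lexicographically smallest index sequence — output is
  fully deterministic.
* **Singularity.** A pooled covariance with reciprocal condition number
  below $10^{-12}$ is a hard error (or an infinite cost during
  enumeration), never silently ridge-regularised; invertibility genuinely
  requires fewer variables than $N - C + 1$.
* **Indices.** Variables are 1-based column indices, the native R
  convention; results also carry the corresponding wavenumbers in cm⁻¹,
  which is what one reports.

## The PLS-DA baseline

The full-spectrum reference classifier regresses the mean-centred spectra on
the mean-centred dummy class code $y \in \{1, 2\}$ with NIPALS PLS1. A
threshold at 1.5 — the midpoint of the codes — converts the continuous
prediction into a class; a prediction exactly at the threshold goes to
class 2 ("at or above"), a convention the package logs when it fires. The
number of latent variables is chosen by 5-fold cross-validation with the
quota fold design: four folds hold $\lfloor n_c/5 \rfloor$ samples of each
class (5 cancerous + 7 normal under the 26 + 36 design), the remainder forms
the fifth fold, and membership within quotas is randomised by an explicit
seed. The LV count with the lowest held-out misclassification ratio wins,
ties toward fewer LVs.

## Preprocessing

Spectra are preprocessed per sample in a fixed single pass: **SNV first,
then a Savitzky–Golay first derivative** (listing order of the usual
protocol; the reverse order is configurable but not default). SNV maps each
spectrum to zero mean and unit standard deviation ($n-1$ denominator),
removing multiplicative scatter and baseline offset; a constant spectrum is
a hard error naming the sample. The derivative uses window 11 and
polynomial order 2 — standard chemometric defaults, exposed as arguments —
in absorbance-per-channel units, with boundary values from the edge-window
polynomial fits so output length equals input length. Running the
derivative stage twice would differentiate twice; the pipeline driver
therefore applies preprocessing exactly once to raw spectra.

PCA (mean-centring only, no variance scaling, as is standard for spectra)
is exploratory. Component signs follow a fixed convention — the
largest-magnitude loading element is positive — so score plots are
reproducible. Both raw and preprocessed spectra can be sent to
`pca_spectra()`; the pipeline reports PCA of the preprocessed training set.
On derivative-preprocessed synthetic spectra the leading components capture
far less variance than they would on raw spectra, because differentiation
suppresses the broad shared bands and baseline that dominate raw variance.

## The synthetic generator

`synthetic_config()` describes a two-class population on a uniform
inclusive grid (default 4000–10000 cm⁻¹ at 4 cm⁻¹, i.e. 1501 channels).
Each spectrum is

$$x = \Big(\textstyle\sum_b \text{band}_b + [\text{class}=1]
\sum_d \text{band}_d\Big)(1 + s\,t) + o + \varepsilon,$$

with Gaussian bands in wavenumber, a per-sample multiplicative ramp of
slope $s \sim N(0, 0.05^2)$ over the normalised grid coordinate $t$, an
additive offset $o \sim N(0, 0.05^2)$, and i.i.d. channel noise
$\varepsilon \sim N(0, 0.005^2)$ absorbance units. Defaults plant five
broad shared bands (widths 250–600 cm⁻¹, so neighbouring channels correlate
above 0.99, as in real NIR) and three narrow class-difference bands of
20–30 m-absorbance amplitude, and draw three subsets of 26 cancerous + 36
normal spectra — the clinical study design this workflow mirrors. Gaussian
line shapes were chosen because NIR tissue bands are broad and featureless;
nothing downstream depends on the exact shape. With both scatter terms off
the two classes are Gaussian with common isotropic covariance, so
`bayes_accuracy()` returns the closed-form optimal accuracy
$\pi_1\Phi(\Delta/2 - \ln(\pi_2/\pi_1)/\Delta) + \pi_2\Phi(\Delta/2 +
\ln(\pi_2/\pi_1)/\Delta)$, $\Delta = \lVert d \rVert/\sigma$ — the analytic
yardstick the test suite holds both classifiers against.

What the generator deliberately does **not** emulate: instrument physics
(detector response, probe geometry, photon penetration depth), wavelength-
dependent noise, and — importantly — patient-level grouping. Real subsets
drawn from different patients share within-patient correlation that
stratified random splitting of i.i.d. samples cannot reproduce, so passing
tests demonstrate algorithmic correctness and statistical behaviour under
the stated model, not clinical performance.

## Study problem sizes

The shipped experiments use two scales, chosen so every property is
exercised at the size where it is informative: the full 1501-channel,
3 × 62-sample design for the end-to-end pipeline, and a reduced 251-channel
grid (4000–5000 cm⁻¹) with three planted bands of 8 cm⁻¹ width for the
selection-behaviour experiments — band recovery across three SNR levels
(noise 0.05 / 0.01 / 0.002 a.u., 20 replicates each), Bayes-gap checks with
a 500-sample test set, and a signal-free null. Oracle-equivalence checks run
at $K \le 10$, $N \le 12$, where brute-force enumeration is exact and
instant.

## Known limitations

* Two classes are assumed throughout the tested surface; the formulas are
  generic in $C$ but multi-class behaviour is not validated.
* The average-risk cost uses the validation set only; with very small
  validation sets the selected subset can overfit it, which is inherent to
  the method, not a defect of the implementation.
* SNV requires non-constant spectra; derivative preprocessing assumes a
  uniform grid.
* The generator's scatter model is linear in the grid coordinate; curved
  baselines are not simulated.
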