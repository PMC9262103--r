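---
title: "Domain-driven dimension reduction and CCA: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-driven dimension reduction and CCA: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Studies that relate a high-dimensional behavioural battery (subject measures,
SM) to a high-dimensional imaging-derived block (brain measures, BM, typically
functional-connectivity edges) usually compress each block before canonical
correlation analysis, because CCA is ill-posed when the number of variables
approaches the number of subjects. A single whole-block PCA does that job but
produces components that mix unrelated measurement domains and are hard to
interpret. This package implements the alternative: **domain-driven dimension
reduction (DDR)**, where PCA is applied separately within functionally
coherent variable sub-domains (cognition, tobacco use, one parcellation
region's edges, ...), the dimensionality of every sub-domain is estimated
automatically, and the per-domain rotated components are concatenated into
the reduced space fed to CCA.

## Dimension selection by two-way cross-validated PRESS

For a sub-domain block $X$ ($N$ subjects $\times$ $P$ variables), subjects are
split into $F$ folds. For each fold, the SVD of the held-in rows
$X^{in} = U \Sigma V'$ provides principal loadings $V$; the naive held-out
reconstruction error

$$\sum_i \lVert x_i^{out} - x_i^{out} V_k V_k' \rVert^2$$

decreases monotonically in $k$ because the held-out rows participate in their
own reconstruction, so it cannot select a dimensionality. The two-way scheme
therefore adds a variable-wise direction: the $j$-th held-out column is
predicted *without itself*,

$$\tilde X^{out} = X^{out}_{-j}\,[V_{-j,k}']^{+}\,V_k',$$

where $V_{-j,k}$ drops row $j$ of the first $k$ loadings and $[\cdot]^{+}$ is
the Moore–Penrose pseudo-inverse (needed because deleting a row of an
orthonormal matrix breaks orthogonality). PRESS$(k)$ sums the squared error of
these self-blind predictions over all columns and folds, attains an interior
minimum on signal-plus-noise data, and the smallest $k$ at the minimum is
chosen. Because fold assignment is random, the scan is repeated
(`n_repeats`, default 50; repeat $i$ uses seed `rng_seed + i`) and the modal
$k$ is kept, ties resolved towards the smaller (more parsimonious) dimension.

Numerical notes, all of which are pinned by tests:

* **Squared norms.** The per-fold PRESS is a sum of *squared* column errors,
  so the total is a predicted residual error *sum of squares*; the naive and
  two-way curves are therefore on the same scale.
* **Search range.** $k$ runs over $1,\dots,\min(P-1,\ N_{in}-1)$: the
  leave-one-column-out reconstruction is undefined at $k = P$, and the SVD
  rank caps at the held-in row count.
* **Fast path.** For orthonormal $V_k$ with row leverages
  $h_j = \lVert v_j \rVert^2 < 1$, the Sherman–Morrison identity collapses the
  pseudo-inverse so that the prediction of column $j$ is
  $(S v_j - h_j x_j)/(1 - h_j)$ with $S = X^{out} V_k$. This is algebraically
  identical to the definition and makes the scan vectorisable; columns with
  $1 - h_j < 10^{-6}$ fall back to the explicit SVD pseudo-inverse.
* **No per-fold recentring by default.** Blocks arrive from the preprocessing
  pipeline already near mean zero (the inverse-normal transform and
  de-confounding both centre), and the SVD model decomposes $X^{in}$ directly;
  `center_folds = TRUE` recentres held-in/held-out rows by held-in means for
  raw inputs.
* **Degenerate domains.** A one-variable sub-domain bypasses the scan with
  $k = 1$ and contributes its (already standardised) variable unchanged.

As a convergence diagnostic — never a selector — `null_eigenspectrum()`
compares the covariance eigenvalues with the mean spectrum after permuting
each column independently; where the null first meets the actual spectrum,
background noise takes over, and on clean low-rank data that crossing falls
within one component of the PRESS choice.

## Preprocessing

The pipeline order is fixed: quality control, median imputation, rank-based
inverse-normal transformation, de-confounding, benchmark sign alignment.

* **Quality control** removes variables with more than 50% missing entries,
  zero standard deviation, or more than 95% identical non-missing values —
  in that order of precedence, evaluated on the raw values.
* **Imputation.** Residual missingness is filled with the column median, a
  rank-stable choice that cannot disturb the subsequent rank-based transform
  for observed entries.
* **Inverse-normal (Blom) transform.**
  $\Phi^{-1}((r - 3/8)/(n + 1/4))$ on average ranks, making every column
  marginally Gaussian while preserving rank order.
* **De-confounding** replaces every variable by its OLS residual on an
  intercept plus (z-scored) confounds; squared, re-centred copies of selected
  confounds can be appended (`square =`) for curvilinear nuisance effects.
  Confounds are z-scored purely for conditioning — residuals are unchanged.
* **Sign alignment.** Variables negatively correlated with a chosen benchmark
  are negated (so "higher is better" reads consistently), with a manual
  override list applied on top. Sign flips change neither covariance
  eigenvalues nor any PRESS curve, chosen dimension, or canonical
  correlation; only loadings flip on the flipped rows. This invariance is
  asserted to $10^{-10}$ in the tests.

## CCA, significance, and interpretation

CCA is solved by whitening each centred block with the inverse square root of
its covariance (eigendecomposition; a relative eigenvalue below $10^{-10}$ is
a hard error advising further reduction rather than a silent ridge) and
taking the SVD of the whitened cross-covariance. Canonical variables have
unit variance; weight signs follow a deterministic largest-entry-positive
convention. Varimax rotation of the per-domain loadings (Kaiser-normalised,
criterion tolerance $10^{-6}$) is an orthogonal — hence CCA-invariant —
transformation applied purely for interpretability, and when the reduced BM
block still exceeds the subject count, one further PCA (`reduce_block_pca`)
brings it to a configurable dimension.

Significance uses a **max-statistic permutation scheme**: rows of one block
are permuted, the *first* canonical correlation of each permuted refit forms
a common null, and every observed correlation is compared against it,

$$p_i = \frac{1 + \#\{r^{null}_1 \ge r_i\}}{1 + n_{perm}},$$

giving family-wise control and monotone p-values; the number of significant
pairs is counted sequentially from the first component. A per-component null
is available via `per_component = TRUE`. Families can be respected either by
whole-block exchange (equal-sized families) or within-block permutation.

Interpretation relies on canonical loadings (structure coefficients):
correlations of each canonical variable with the observed variables and,
separately, with the DDR factors — the latter expose each sub-domain's
contribution directly. Variance explained is the mean squared observed
loading per component, in percent, computed against the post-preprocessing
variables (those are what CCA saw). For connectivity blocks,
`edge_loading_matrix()` symmetrises the two column copies of each undirected
edge and `cca_strength()` summarises each region by the mean of its top
sign-modulated positive and negative edge loadings.

## Cross-validated stability

`run_stability()` wraps the whole pipeline in a family-respecting k-fold
cross-validation: whole families are assigned greedily (largest first into
the currently smallest fold, seeded random tie-breaks), and for each fold the
sub-domain dimensions, loadings, rotations, any extra PCA, and canonical
weights are re-estimated on training subjects only. Held-out subjects are
projected through the training rotated loadings and weights
($\tilde P = X^{out} A^{in}$, $\tilde Q = Y^{out} B^{in}$), yielding
cross-validated canonical correlations that are deliberately left signed.
Both training and held-out correlations are permutation-tested.

Across folds, canonical components are matched by index and sign-aligned to
fold 1 via the correlation of their SM loading vectors (without this,
means and SDs across folds would cancel under the inherent sign
indeterminacy). Stability is then summarised by occurrence counts — how many
folds placed an item in the top `top_T` absolute loadings — with per-item
means and SDs over the folds where it occurred.

Two phenomena reproduce robustly on synthetic data and are asserted in the
acceptance tests: a strongly planted mode survives to held-out data (with the
held-out estimate close to the attenuated population value, free of the
upward training bias), while under weak signal and study-scale input
dimensionality (dozens of factors per block) training correlations inflate
to the null level and held-out correlations collapse towards zero — the
training/held-out gap is driven by input dimensionality, which is why the
weak-signal check uses ~30 factors per side rather than a toy 4-factor block.

## The synthetic-data generator

`make_domain_block()` draws `block = scores %*% t(loadings) + noise` with
random orthonormal (optionally sparsified) loadings; `make_linked_dataset()`
plants cross-block modes by giving one carrier factor per block a
$\sqrt\rho$-weighted share of a shared latent variable, so the *factor-level*
population canonical correlation is exactly $\rho$. Observed variables add
measurement noise, which attenuates the observable canonical correlation by
a closed-form reliability factor per block — $s/\sqrt{s^2+\sigma^2}$ for an
SM carrier with signal sd $s$ and noise sd $\sigma$, and
$\sqrt{S/(S+\sigma^2)}$ with $S = (\lVert w\rVert^4 - \sum_a w_a^4)/2$ for a
connectivity factor with region pattern $w$ — both reported in the returned
`truth` object. Connectivity matrices are synthesised symmetrically as
$M_i = \sum_k f_{ik}\, w_k w_k' + E_i$ (symmetric noise, unit diagonal), so
every region sub-domain has known low-rank structure; the compact
`bm_spec` list (regions, factors, pattern norms, noise) replaces hundreds of
redundant per-region specifications.

The reference simulation (`simulate_study()`) fixes the study conditions used
throughout the tests: 14 SM sub-domains whose sizes and latent ranks follow
the spread of a real behavioural battery (218 variables, 62 factors, ranks 1
to 14), a 20-region connectivity block with 8 latent patterns, 3 linear
confounds, sibling-sized families with a family intercept of sd 0.3, signal
sd 4 against noise sd 1, and two planted modes at factor-level canonical
correlations 0.85 and 0.70. The mode strengths were set by a design-stage
power calculation: at the resulting CCA input dimensions (~62 SM factors
against a 20-dimensional BM reduction, N = 500) the null first canonical
correlation simulates to ≈ 0.52, so the attenuated observed modes
(≈ 0.80 / 0.65) are clearly detectable without being trivial. What the
generator does **not** emulate: temporal autocorrelation of fMRI,
heavy-tailed or ordinal measurement scales, structured (non-ignorable)
missingness, and non-linear brain–behaviour coupling — passing tests
demonstrate correctness of the machinery under the stated model, not
robustness to those features of real data.

## Problem sizes used in tests and the acceptance script

Dimension-recovery checks use rank-3 blocks of 12 variables at N = 250 with
11-repeat, 5-fold scans over 20 replicates; the type-I simulation uses 300
replicates of independent 5 + 5 blocks at N = 200 with 199 permutations; the
cross-validation recovery run uses one planted mode at ρ = 0.7, N = 2000,
five folds; the end-to-end run uses the reference simulation at N = 500 with
499 permutations. These sizes make the whole suite run in about a minute and
a half while leaving every statistical margin wide.

## Known limitations

* Dimension estimates for very deep domains (rank approaching the variable
  count) are conservative: the leave-one-column-out scheme loses power as
  $k \to P - 1$.
* The permutation scheme treats de-confounding as fixed (done once before
  testing); a fold-wise refit is available for the cross-validation but not
  re-derived inside each permutation.
* Canonical components are matched across folds by index; genuinely swapped
  neighbouring modes (near-equal correlations) will blur the stability
  summaries rather than being re-paired optimally.
* The max-statistic null is conservative for later components, which is the
  price of family-wise control when counting significant pairs.
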