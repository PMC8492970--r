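---
title: "Homotopic functional connectivity in white and gray matter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homotopic functional connectivity in white and gray matter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemifc)
```

## The measurement

Voxel-mirrored homotopic connectivity (VMHC) quantifies the functional
coupling between the two cerebral hemispheres: for every voxel $v$ inside a
mirror-symmetric mask, the Pearson correlation $r_v$ between the BOLD time
series at $v$ and at its left–right mirrored counterpart $v'$ is computed and
variance-stabilized with the Fisher transform $z_v = \operatorname{atanh}(r_v)$.
Because the same $r$ is assigned to both members of each pair, every map the
package emits satisfies $z(v) = z(v')$ exactly.

The package applies this measurement separately within white-matter (WM) and
gray-matter (GM) compartments. The WM BOLD signal is weak and historically
treated as noise; restricting smoothing and correlation to a strict WM mask
(group threshold 0.8, versus 0.2 for GM) limits contamination of WM series by
partial-volume GM signal, which is the main methodological hazard of
WM-functional analysis.

## The synthetic phantom

Real cohort data cannot support desk-scale verification, so the package
generates phantoms with known ground truth. Each subject lives on a
midline-aligned grid (default $24 \times 28 \times 24$ voxels at 3 mm,
emulating a 3 mm normalized space at toy scale) with 164 time points at
TR = 2.2 s. The first grid axis is even, so the mirror map has no self-paired
midline voxels.

**Tissue layout.** Concentric compartments — CSF core, WM shell, GM rind —
defined by a normalized radial coordinate, exactly mirror-symmetric;
probability maps assign 0.92 to the home tissue and 0.04 to each other
tissue. An optional perturbation (`tissue_asymmetry`) breaks the symmetry to
exercise mask symmetrization.

**Planted correlations.** For a mirrored pair with target correlation
$\rho$, the generator draws a shared unit-variance Gaussian series $s$ and
independent noises $e_1, e_2, e_3$ and sets

$$x = s + \sigma e_1, \qquad y = \rho s + \sqrt{1-\rho^2}\, e_2 + \sigma e_3,$$

so both series have variance $1 + \sigma^2$ and the population correlation is
$\rho / (1 + \sigma^2)$ (`effective_rho()`). With the default $\sigma = 0$ the
planted and effective values coincide. Voxels outside parcels are independent
noise, so the null distribution of $z$ is centred at 0 with sd
$\approx 1/\sqrt{T-3}$. Two mirrored parcels are planted by default — one in
the deep WM shell, one in the GM rind — with per-group correlations declining
NC $>$ VMCI $>$ MCI (defaults 0.8/0.6/0.4 in WM). The magnitudes are design
choices, not empirical values: group-level homotopic correlation magnitudes
are not available for this design, so round, well-separated levels were fixed
once to make ordered recovery measurable.

Because each pair has its own latent series, linear filtering applied
identically to both members leaves the pair correlation unchanged, and
*uniform* smoothing inside a parcel would too; at parcel *boundaries*,
however, smoothing mixes in independent neighbours and attenuates the
correlation. This is a real property of within-mask smoothing, not an
artifact: recovery of the planted $\rho$ is therefore assessed on unsmoothed
series, while the smoothing operator has its own direct-convolution oracle.

**What the phantom does not emulate.** No hemodynamic convolution, slice
timing, susceptibility distortion, scanner drift beyond a linear trend, or
spatial autocorrelation of noise. Passing tests demonstrate the correctness
of the pipeline's arithmetic and inference machinery on data with known
truth; they do not certify performance on real acquisitions.

**Covariates.** Age, sex, education and MMSE are drawn per group from
normal/Bernoulli models matched to published cohort summaries (e.g. MMSE
means 28.86 / 25.99 / 22.08 for NC / VMCI / MCI), rounded and clamped to
plausible ranges. They are synthetic; only their first two moments are
meaningful.

**Motion.** Six rigid-body parameters as low-frequency sinusoids plus mild
jitter (max FD well below 1 mm by default). Requested spike frames add a
sustained 2 mm translation step, so Power framewise displacement
$\mathrm{FD}(t) = \sum |\Delta d_i| + 50\,\mathrm{mm} \cdot \sum |\Delta
\theta_i|$ exceeds the 1 mm scrubbing threshold exactly at those frames. The
FD definition is the Power convention, the dominant one in this toolchain.

**Diffusion.** Single-tensor signals $S(b, g) = S_0 \exp(-b\, g^\top D g)$
on a deterministic 24-direction Fibonacci-sphere scheme at
$b = 1000\ \mathrm{s/mm^2}$ plus one $b = 0$. WM tensors are prolate
$(1.7, 0.3, 0.3) \times 10^{-3}\ \mathrm{mm^2/s}$; the MCI group's WM parcel
carries $(2.6, 0.35, 0.35) \times 10^{-3}$, raising MD
($1.1$ vs $0.767 \times 10^{-3}$) and FA ($0.850$ vs $0.799$) as the planted
anatomical abnormality. Default Gaussian signal noise sd is 1 against
$S_0 = 100$; a noiseless phantom would make within-group ROI means exactly
constant and degenerate the group t-tests.

## Preprocessing chain

The stages run in a fixed order, recorded in each run's provenance:

1. **Drop** the first 5 volumes (T1 saturation).
2. **Detrend**: per-voxel least-squares removal of intercept and slope.
3. **Nuisance regression**: OLS residuals against intercept + Friston-24
   motion expansion ($p$, lagged $p$ with $p(0)=0$, and their squares) + the
   CSF mean signal + one indicator column per frame with FD > 1 mm
   (scrubbing). Indicator columns zero their own frame's residual without
   altering correlations among the remaining frames. The CSF mean is
   extracted from the dropped + detrended series — the alternative (before
   detrending) differs only by an affine component the regression removes
   anyway. Rank-deficient designs drop collinear columns with a warning.
4. **Bandpass** 0.01–0.1 Hz: an ideal rectangular filter in the discrete
   Fourier domain (bins with $|f|$ in band retained, DC removed). The ideal
   filter is deterministic and matches the conventional resting-state
   implementation; it has no roll-off parameters to document.
5. **Tissue-restricted smoothing** (4 mm FWHM): normalized masked Gaussian
   $\mathrm{sm}(x \cdot m)/\mathrm{sm}(m)$ within the subject's WM and GM
   masks (probability > 0.5) separately, with the same truncated separable
   kernel (radius $3\sigma$) in numerator and denominator; denominators below
   $10^{-6}$ are zeroed. Outside-mask voxels never influence inside values,
   and constants inside the mask are preserved exactly.

Head-motion *estimation* is not implemented: phantoms supply their motion
traces directly, and motion-related signal change is handled by the
regression stage.

## Symmetric masks and the mirror map

Group masks are built by averaging subject probability maps, flip-averaging
the group mean ($(\bar m + \mathrm{flip}(\bar m))/2$), and binarizing at
$\ge$ threshold (0.2 GM / 0.8 WM; `>=` because strictness is a free choice
and `>=` keeps exact-threshold voxels). An optional exclusion mask (e.g. for
subcortical nuclei, supplied by the user) is subtracted and the result
re-symmetrized by intersection with its own mirror. The mirror map pairs
in-mask voxels across the first axis; phantoms are midline-aligned by
construction, so the registration-to-symmetric-template step used with real
data is replaced by the shared grid (recorded in provenance). On an odd
first axis, midsagittal voxels are excluded from the map: their homotopic
correlation is identically 1 and carries no information.

Degenerate inputs: pairs with a zero-variance member get $r = 0$ plus a QA
count (rather than NaN); $|r|$ is clipped at $1 - 10^{-7}$ before
$\operatorname{atanh}$ so degenerate perfect correlations stay finite.

## Group statistics

Per voxel, group differences are tested with the partial F for the group
factor in the GLM $z \sim \text{group} + \text{age} + \text{sex} +
\text{education}$ — a joint ANCOVA fit rather than
residualize-then-test, which keeps the degrees of freedom
$(g-1,\, n-g-c)$ exact. With no covariates this reduces to the classical
one-way ANOVA F (tested against a hand-computed table). F p-values are
upper-tail: an F test is inherently one-sided, so no separate "one-tailed"
option exists. Voxel-wise correction is Benjamini–Hochberg at $q = 0.05$
(implemented over `stats::p.adjust`, verified against brute-force
enumeration). Post-hoc pairwise comparisons use the t statistic of the group
indicator in the covariate-adjusted GLM, two-tailed, Bonferroni-controlled at
$0.05/m$ with $m$ an explicit parameter ($m = 6$ for GM, $m = 9$ for WM in
the companion analyses — plausibly ROIs $\times$ contrasts, but since that
derivation is not certain, $m$ is never inferred automatically).

Rejected voxels are grouped into clusters by flood-fill connected components
(26-connectivity by default, 6/18 configurable; the choice only matters for
diagonal adjacency and is recorded). No cluster-extent threshold is applied.
Exactly mirrored left–right component pairs are merged into one bilateral
record whose size sums both sides and whose peak x coordinate is reported as
$\pm|x|$; sizes are always `n_voxels` $\times$ voxel volume.

## Diffusion tensor analysis

Tensors are fit per voxel by log-linear least squares,
$\ln S = \ln S_0 - b\, g^\top D g$, the simplest estimator that is exact on
noiseless single-tensor data (verified to machine precision); weighted or
nonlinear variants would only change noise propagation, which the phantom
does not model realistically anyway. Non-positive signals are clamped to a
small positive value before the log and counted. Eigenvalues come from the
closed-form trigonometric solution for symmetric $3\times3$ matrices
(cross-checked against `eigen()`); slightly negative values from noise are
clamped to 0 and counted. Metrics: AD $= \lambda_1$ (the standard reading of
axial diffusivity), MD $= \bar\lambda$, FA $= \sqrt{3/2}\,
\|\lambda - \bar\lambda\| / \|\lambda\|$. ROI means inside the abnormal-VMHC
clusters are compared between groups with pooled two-sample t-tests at
$0.05/9$. ROIs live on the shared phantom grid; real-data space
transformations are out of scope.

## Classification

The multiclass (NC/VMCI/MCI) classifier follows the libsvm protocol
(`e1071`): features are the Fisher-z values at every voxel of the abnormal-WM
clusters plus age, sex (M = 1), education and MMSE. Feature optimization
keeps a feature only if all three pairwise pooled t-tests (NC–VMCI, NC–MCI,
VMCI–MCI) have $p < 0.05$; by default the filter sees training rows only
(`select_on = "train"`), with `"all"` available to reproduce the laxer
variant since published descriptions of such filters are often ambiguous on
this point. Features are z-scored by training statistics (centering is
harmless for a linear SVM with bias and improves conditioning); validation
rows are always transformed with training statistics — never their own. The
cost parameter is tuned over $C = 2^e$, $e \in \{-8, -7.75, \dots, 3\}$
(45 candidates; the grid convention cmin, cmax, cstep $= 2^{-8}, 2^3,
2^{-2}$ read as a log2 exponent step of 0.25) by stratified 5-fold
cross-validated accuracy with a deterministic fold assignment; ties take the
smallest C. One one-vs-one linear SVM is trained on the full training set and
applied unchanged to the external validation cohort. Reports contain the
confusion matrix, per-class precision/recall/F1, accuracy, and the $1/3$
chance baseline; a never-predicted class gets precision 0 and a flag.

## Problem sizes and defaults

The default pipeline run uses a training cohort of 10 subjects per group and
an external validation cohort of 7/9/4 (NC/VMCI/MCI — half of a published
validation cohort's 14/18/8, preserving its imbalance) on the
$24 \times 28 \times 24$ grid; this completes in roughly a minute on one CPU
and is the configuration exercised end-to-end by the test suite, twice, to
confirm bit-identical manifest hashes. Unit tests use a
$16 \times 14 \times 16$ grid with 60–164 time points. All randomness flows
from a single integer seed through per-subject, per-stage streams, so any
subject can be regenerated in isolation.

## Known limitations

- The phantom's noise is white in space and time; spatially correlated
  physiological noise would lower the effective degrees of freedom of the
  correlation estimates in ways the phantom does not probe.
- Smoothing-induced boundary attenuation means parcel-mean recovery of the
  planted $\rho$ holds for unsmoothed series; after smoothing the recovered
  group ordering survives but magnitudes shrink toward zero near parcel
  edges.
- The FDR correction is voxel-wise; no cluster-level or permutation
  inference is provided.
- Registration, segmentation, eddy-current correction and atlas lookup are
  explicitly out of scope: phantoms are born on a common midline-aligned
  grid.

## A minimal session

```{r example, eval = FALSE}
cfg <- default_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "hemifc_run")
res$stats$wm$clusters            # bilateral abnormal-VMHC clusters
res$dti[res$dti$significant, ]   # AD/FA/MD group differences in those ROIs
res$classification$report        # external-validation confusion and metrics
```
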