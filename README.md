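# hemifc

Homotopic functional connectivity analysis of white- and gray-matter BOLD
signals, with a synthetic phantom generator so that every stage of the
pipeline is verifiable at desk scale.

## The problem

The two cerebral hemispheres are strongly functionally coupled: a voxel's
resting-state BOLD time series correlates with that of its left–right
mirrored counterpart. This *voxel-mirrored homotopic connectivity* (VMHC) is
a sensitive marker of disease, and recent work extends it from gray matter
(GM) into white matter (WM), whose BOLD signal was long discarded as noise.
Group comparisons of WM homotopic connectivity — between normal cognition
(NC), very mild cognitive impairment (VMCI) and mild cognitive impairment
(MCI) — together with diffusion-tensor anatomy in the abnormal regions and an
SVM classifier over the abnormal-connectivity features, form a complete
analysis whose every step this package implements in testable form.

For each voxel $v$ with mirror $v'$ inside a mirror-symmetric tissue mask:

$$r_v = \mathrm{corr}\big(x_v(t),\, x_{v'}(t)\big), \qquad
z_v = \operatorname{atanh}(r_v)$$

after a standard preprocessing chain (drop 5 volumes, linear detrend,
Friston-24 + CSF + FD>1 mm spike-regressor nuisance regression, 0.01–0.1 Hz
bandpass, 4 mm FWHM smoothing restricted separately to WM and GM). Group
effects are tested voxel-wise with covariate-adjusted ANOVA (age, sex,
education) under Benjamini–Hochberg FDR, post-hoc pairwise t-tests under
Bonferroni control (0.05/6 GM, 0.05/9 WM), clusters are reported bilaterally
(± x), ROI-mean AD/FA/MD from log-linear tensor fits are compared between
groups, and a one-vs-one linear SVM (libsvm via `e1071`) with a
three-pairwise-t feature filter and a $2^{-8} \ldots 2^3$ cost grid is
validated on an external cohort.

Who is it for: methods developers and students who need a fully inspectable,
deterministic implementation of the WM/GM homotopic-connectivity workflow
with ground-truth phantoms, not a clinical tool.

## Worked example

```r
library(hemifc)
cfg <- default_config(seed = 1)          # 10/10/10 training, 7/9/4 validation
res <- run_pipeline(cfg, out_dir = "hemifc_run")
as.data.frame(res$stats$wm$clusters)[1, ]
#>   cluster n_voxels size_mm3 peak_stat peak_x_mm peak_y_mm peak_z_mm bilateral
#> 1       1      144     3888   102.477      16.5       1.5      -1.5      TRUE
res$classification$report
#> Accuracy 100.00% (baseline 33.33%)
```

The phantom plants a mirrored WM parcel whose homotopic correlation declines
0.8 / 0.6 / 0.4 across NC / VMCI / MCI. The run above recovers it as one
bilateral cluster of 144 voxels (3888 mm³ at 3 mm, peak F = 102.5 at
x = ±16.5 mm), finds the planted MCI diffusion abnormality in that ROI
(higher FA, MD and AD, e.g. FA 0.851 vs 0.799, p ≈ 1e-29 at the 0.05/9
threshold), and classifies the external validation cohort well above the
33.33% baseline — the phantom's planted effects are deliberately strong, so
perfect separation is expected there, unlike on real data. Every output file
gets a provenance sidecar carrying the configuration hash, and
`manifest.json` lists md5 hashes that reproduce bit-for-bit across reruns
with the same seed.

See `vignettes/wm-homotopic-connectivity.Rmd` for the generative model of
the phantom, all stage conventions and their rationale.

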