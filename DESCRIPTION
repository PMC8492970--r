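Package: hemifc
Title: Homotopic Functional Connectivity Analysis of White and Gray Matter BOLD Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for voxel-mirrored homotopic
    functional connectivity (VMHC) analysis of resting-state BOLD signals within
    white and gray matter. Provides a synthetic phantom generator with known
    ground truth (mirrored BOLD correlations, tissue compartments, rigid-body
    motion traces, single-tensor diffusion signals, and a clinical covariate
    table), the standard functional preprocessing chain (volume dropping, linear
    detrending, Friston-24 + CSF + motion-spike nuisance regression, 0.01-0.1 Hz
    bandpass filtering, tissue-restricted Gaussian smoothing), symmetric group
    mask construction, per-subject Fisher-z homotopic correlation maps,
    covariate-adjusted mass-univariate group statistics with FDR and Bonferroni
    control plus cluster reporting, diffusion tensor fitting with AD/MD/FA
    metrics and ROI group comparisons, and a multiclass linear support vector
    machine with t-test filter feature selection and external validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
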