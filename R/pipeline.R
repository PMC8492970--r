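# Pipeline orchestration: a single validated configuration drives
# phantom -> preprocess -> masks -> VMHC -> group stats -> DTI -> SVM,
# with NIfTI/TSV outputs, per-file provenance sidecars and a hashed manifest.

#' Default run configuration
#'
#' All stage parameters at their standard values: drop 5 volumes, FD spike
#' threshold 1 mm, 0.01-0.1 Hz bandpass, 4 mm FWHM tissue-restricted
#' smoothing, group-mask thresholds GM 0.2 / WM 0.8, FDR q 0.05, Bonferroni
#' divisors 6 (GM: 2 ROIs x 3 contrasts) and 9 (WM: 3 ROIs x 3 contrasts),
#' and a C grid 2^-8..2^3 in steps of 2^0.25. The phantom block defines the
#' cohort: a training cohort of 10 subjects per group and an external
#' validation cohort of 7/9/4 (NC/VMCI/MCI) generated with an independent
#' seed stream, emulating a second scanner.
#'
#' @param seed master integer seed.
#' @return nested configuration list (class `run_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    phantom = list(grid_shape = c(24L, 28L, 24L), voxel_size_mm = 3,
                   n_timepoints = 164L, tr_s = 2.2,
                   groups = c(NC = 10L, VMCI = 10L, MCI = 10L),
                   validation_groups = c(NC = 7L, VMCI = 9L, MCI = 4L),
                   noise_sd = 0, dwi_noise_sd = 1, tissue_asymmetry = 0),
    preprocess = list(drop = 5L, fd_threshold_mm = 1, band = c(0.01, 0.1),
                      fwhm_mm = 4, subject_threshold = 0.5),
    masks = list(gm_threshold = 0.2, wm_threshold = 0.8),
    stats = list(fdr_q = 0.05, bonferroni_m_gm = 6L, bonferroni_m_wm = 9L,
                 connectivity = 26L),
    dti = list(m_comparisons = 9L),
    classify = list(alpha = 0.05, c_exponents = seq(-8, 3, by = 0.25),
                    n_folds = 5L, select_on = "train")
  ), class = "run_config")
}

#' Build and validate a run configuration
#'
#' Merges user overrides into [default_config()]; unknown keys are rejected,
#' and cross-field constraints (bandpass below Nyquist, thresholds in (0,1))
#' are checked before any computation.
#'
#' @param overrides nested list of settings to override, or a path to a YAML
#'   file with the same structure.
#' @param seed master seed (overridden by `overrides$seed` when given).
#' @return validated `run_config`.
#' @export
run_config <- function(overrides = list(), seed = 1L) {
  if (is.character(overrides)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    overrides <- yaml::read_yaml(overrides)
  }
  cfg <- unclass(default_config(seed))
  merge_block <- function(base, over, path) {
    bad <- setdiff(names(over), names(base))
    if (length(bad))
      stop("unknown config key(s): ", paste(paste0(path, bad), collapse = ", "))
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_block(base[[nm]], over[[nm]], paste0(path, nm, "$"))
      else over[[nm]]
    }
    base
  }
  cfg <- merge_block(cfg, overrides, "")
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  band <- cfg$preprocess$band
  nyq <- 1 / (2 * cfg$phantom$tr_s)
  if (band[1] >= band[2]) stop("config invalid: band low >= high")
  if (band[2] >= nyq)
    stop("config invalid: band high ", band[2], " Hz is at or above Nyquist (",
         signif(nyq, 4), " Hz) for TR ", cfg$phantom$tr_s, " s")
  for (th in c(cfg$masks$gm_threshold, cfg$masks$wm_threshold))
    if (th <= 0 || th >= 1) stop("config invalid: mask thresholds must lie in (0,1)")
  if (cfg$stats$fdr_q <= 0 || cfg$stats$fdr_q >= 1)
    stop("config invalid: fdr_q must lie in (0,1)")
  if (cfg$phantom$n_timepoints <= cfg$preprocess$drop)
    stop("config invalid: drop >= n_timepoints")
  cfg
}

config_hash <- function(cfg) object_md5(unclass(cfg))

write_provenance <- function(path, cfg_hash, stage, extra = list()) {
  side <- paste0(path, ".json")
  jsonlite::write_json(c(list(file = basename(path), stage = stage,
                              config_md5 = cfg_hash,
                              package = "hemifc",
                              version = as.character(utils::packageVersion("hemifc"))),
                         extra),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

write_nifti_out <- function(vol, path, voxel_size_mm) {
  RNifti::writeNifti(RNifti::asNifti(vol * 1,
                                     pixdim = rep(voxel_size_mm, 3)), path)
  invisible(path)
}

#' Run the full phantom-to-classification pipeline
#'
#' Generates training and external-validation phantom cohorts, preprocesses
#' every subject, builds the group symmetric GM/WM masks, computes per-subject
#' Fisher-z homotopic connectivity maps for both tissues, runs the
#' covariate-adjusted ANOVA with FDR correction plus post-hoc pairwise t-tests
#' and cluster extraction, fits diffusion tensors and compares ROI AD/FA/MD
#' between groups, and trains/validates the multiclass linear SVM on the
#' abnormal-WM-connectivity features. All artifacts (NIfTI maps, TSV tables, a
#' JSON manifest with md5 hashes) are written under `out_dir`; a rerun with
#' the same configuration reproduces the hashes bit for bit.
#'
#' @param config a [run_config()] / [default_config()] object.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `masks`, `vmhc` (per-tissue z matrices),
#'   `anova`, `clusters`, `posthoc`, `dti`, `classification`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  ch <- config_hash(cfg)
  ph <- cfg$phantom
  vs <- ph$voxel_size_mm

  make_spec <- function(groups, seed) {
    phantom_spec(grid_shape = ph$grid_shape, voxel_size_mm = vs,
                 n_timepoints = ph$n_timepoints, tr_s = ph$tr_s,
                 groups = groups, noise_sd = ph$noise_sd,
                 tissue_asymmetry = ph$tissue_asymmetry,
                 dwi_noise_sd = ph$dwi_noise_sd, seed = seed)
  }
  spec_tr <- make_spec(ph$groups, cfg$seed)
  spec_vl <- make_spec(ph$validation_groups, cfg$seed + 101L)

  say("phantom: generating covariates and ground truth")
  coh_tr <- generate_cohort(spec_tr, materialize = FALSE)
  coh_vl <- generate_cohort(spec_vl, materialize = FALSE)

  say("masks: building group symmetric GM/WM masks")
  tissues_tr <- lapply(coh_tr$subjects$id, function(id) generate_tissue(spec_tr, id))
  gm_mask <- group_symmetric_mask(lapply(tissues_tr, `[[`, "gm"), cfg$masks$gm_threshold)
  wm_mask <- group_symmetric_mask(lapply(tissues_tr, `[[`, "wm"), cfg$masks$wm_threshold)
  gm_map <- build_mirror_map(gm_mask)
  wm_map <- build_mirror_map(wm_mask)

  process_cohort <- function(spec, coh) {
    subj <- coh$subjects
    z_wm <- vector("list", nrow(subj))
    z_gm <- vector("list", nrow(subj))
    for (s in seq_len(nrow(subj))) {
      id <- subj$id[s]
      say("preprocess + VMHC: ", id)
      bold <- generate_bold(spec, id, subj$group[s])
      motion <- generate_motion(spec, id)
      tissue <- generate_tissue(spec, id)
      pp <- preprocess_subject(bold, motion, tissue,
                               drop = cfg$preprocess$drop,
                               fd_threshold_mm = cfg$preprocess$fd_threshold_mm,
                               band = cfg$preprocess$band,
                               fwhm_mm = cfg$preprocess$fwhm_mm,
                               subject_threshold = cfg$preprocess$subject_threshold)
      z_wm[[s]] <- vmhc_subject(pp$wm, wm_mask, wm_map, "WM", id)
      z_gm[[s]] <- vmhc_subject(pp$gm, gm_mask, gm_map, "GM", id)
    }
    list(wm = z_wm, gm = z_gm)
  }
  maps_tr <- process_cohort(spec_tr, coh_tr)
  maps_vl <- process_cohort(spec_vl, coh_vl)

  say("group statistics: ANOVA + FDR + clusters + post-hoc")
  covs <- coh_tr$subjects[, c("age", "sex", "education")]
  groups <- coh_tr$subjects$group
  run_stats <- function(maps, mask, m_bonf) {
    an <- glm_group_f(maps, groups, covs, mask)
    rej <- fdr_bh(an$p, cfg$stats$fdr_q)
    rej_map <- unmask(rej, an$voxels, an$dim, fill = FALSE)
    fmap <- unmask(an$stat, an$voxels, an$dim)
    cl <- extract_clusters(rej_map, fmap, vs, cfg$stats$connectivity)
    pairs <- utils::combn(unique(groups), 2, simplify = FALSE)
    ph_t <- lapply(pairs, function(pr)
      posthoc_t(maps, groups, pr, covs, m_bonf, mask = mask))
    list(anova = an, reject = rej_map, fmap = fmap, clusters = cl, posthoc = ph_t)
  }
  stats_wm <- run_stats(maps_tr$wm, wm_mask, cfg$stats$bonferroni_m_wm)
  stats_gm <- run_stats(maps_tr$gm, gm_mask, cfg$stats$bonferroni_m_gm)

  say("DTI: tensor fits and ROI comparisons")
  dti_tbl <- NULL
  if (nrow(stats_wm$clusters) > 0) {
    metrics <- lapply(seq_len(nrow(coh_tr$subjects)), function(s) {
      id <- coh_tr$subjects$id[s]
      tf <- make_tensor_field(spec_tr, coh_tr$subjects$group[s])
      dwi <- generate_dwi(spec_tr, tf, noise_sd = ph$dwi_noise_sd, subject_id = id)
      tensor_metrics(fit_tensor(dwi))
    })
    dti_tbl <- roi_dti_compare(metrics, groups, stats_wm$clusters,
                               m_comparisons = cfg$dti$m_comparisons)
  }

  say("classification: multiclass linear SVM with external validation")
  cls <- NULL
  if (nrow(stats_wm$clusters) > 0) {
    roi_vox <- sort(unique(unlist(attr(stats_wm$clusters, "voxels"))))
    x_tr <- feature_matrix(maps_tr$wm, roi_vox, coh_tr$subjects)
    x_vl <- feature_matrix(maps_vl$wm, roi_vox, coh_vl$subjects)
    cls <- hfc_classifier(x_tr, coh_tr$subjects$group, x_vl,
                          coh_vl$subjects$group,
                          alpha = cfg$classify$alpha,
                          exponents = cfg$classify$c_exponents,
                          n_folds = cfg$classify$n_folds,
                          seed = cfg$seed,
                          select_on = cfg$classify$select_on)
  }

  say("writing artifacts to ", out_dir)
  files <- character(0)
  emit <- function(path, stage, extra = list()) {
    files <<- c(files, path, write_provenance(path, ch, stage, extra))
  }
  p <- function(...) file.path(out_dir, paste0(...))
  write_nifti_out(gm_mask, p("mask_gm_symmetric.nii"), vs); emit(p("mask_gm_symmetric.nii"), "masks")
  write_nifti_out(wm_mask, p("mask_wm_symmetric.nii"), vs); emit(p("mask_wm_symmetric.nii"), "masks")
  for (tg in c("wm", "gm")) {
    maps <- maps_tr[[tg]]
    for (m in maps) {
      f <- p("vmhc_", tg, "_", m$subject_id, ".nii")
      write_nifti_out(m$z, f, vs); emit(f, "vmhc", list(subject = m$subject_id))
    }
    smap <- if (tg == "wm") stats_wm else stats_gm
    write_nifti_out(smap$fmap, p("anova_F_", tg, ".nii"), vs)
    emit(p("anova_F_", tg, ".nii"), "group_stats")
    write_nifti_out(smap$reject, p("anova_reject_", tg, ".nii"), vs)
    emit(p("anova_reject_", tg, ".nii"), "group_stats")
    ctab <- smap$clusters
    utils::write.table(as.data.frame(ctab), p("clusters_", tg, ".tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    emit(p("clusters_", tg, ".tsv"), "group_stats")
  }
  utils::write.table(coh_tr$subjects, p("covariates_train.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  emit(p("covariates_train.tsv"), "phantom")
  utils::write.table(coh_vl$subjects, p("covariates_validation.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  emit(p("covariates_validation.tsv"), "phantom")
  if (!is.null(dti_tbl)) {
    utils::write.table(dti_tbl, p("dti_roi_comparisons.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    emit(p("dti_roi_comparisons.tsv"), "dti")
  }
  if (!is.null(cls)) {
    rep_tab <- data.frame(class = rownames(cls$report$confusion),
                          precision = cls$report$precision,
                          recall = cls$report$recall,
                          f1 = cls$report$f1)
    utils::write.table(rep_tab, p("classification_report.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    emit(p("classification_report.tsv"), "classify")
    utils::write.table(as.data.frame(cls$report$confusion),
                       p("classification_confusion.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    emit(p("classification_confusion.tsv"), "classify",
         list(C = cls$C, n_features = cls$n_features))
  }
  data_files <- setdiff(files, grep("\\.json$", files, value = TRUE))
  manifest <- list(seed = cfg$seed, config_md5 = ch,
                   package_version = as.character(utils::packageVersion("hemifc")),
                   files = data.frame(file = basename(data_files),
                                      md5 = unname(tools::md5sum(data_files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = cfg,
                 masks = list(gm = gm_mask, wm = wm_mask),
                 cohorts = list(train = coh_tr, validation = coh_vl),
                 vmhc = list(train = maps_tr, validation = maps_vl),
                 stats = list(wm = stats_wm, gm = stats_gm),
                 dti = dti_tbl, classification = cls, manifest = manifest))
}
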