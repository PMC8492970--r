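# Maps in these tests are tiny 3D arrays; "subjects" are lists of such arrays.

make_maps <- function(values_by_subject, d = c(2, 2, 2)) {
  lapply(values_by_subject, function(v) array(v, d))
}

test_that("partial F reduces to classical one-way ANOVA without covariates", {
  # hand-computed toy table: groups (1,2,3), (2,3,4), (6,7,8)
  # grand mean 4; SSB = 3*(4+1+9) = 42, df 2; SSW = 6, df 6; F = 21
  y <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  maps <- make_maps(as.list(y), d = c(1, 1, 1))
  an <- glm_group_f(maps, g)
  expect_equal(unname(an$stat), 21, tolerance = 1e-12)
  expect_equal(unname(an$df), c(2, 6))
  expect_equal(unname(an$p), pf(21, 2, 6, lower.tail = FALSE))

  # identical groups: F = 0, p = 1
  maps0 <- make_maps(rep(list(c(1, 5, 2, 7, 3, 1, 2, 8)), 6))
  an0 <- glm_group_f(maps0, rep(c("a", "b"), each = 3))
  expect_equal(unname(an0$stat), rep(0, 8))
  expect_equal(unname(an0$p), rep(1, 8))
})

test_that("covariate-adjusted partial F agrees with the lm/anova oracle", {
  set.seed(17)
  n <- 18
  g <- rep(c("NC", "VMCI", "MCI"), each = 6)
  covs <- data.frame(age = rnorm(n, 74, 8), sex = sample(c("M", "F"), n, TRUE),
                     education = rnorm(n, 14, 2))
  nvox <- 10
  Y <- matrix(rnorm(n * nvox), n)
  Y[, 1] <- Y[, 1] + 2 * (g == "MCI")           # one voxel with a real effect
  maps <- lapply(seq_len(n), function(i) array(Y[i, ], c(nvox, 1, 1)))
  an <- glm_group_f(maps, g, covs)
  for (v in seq_len(nvox)) {
    fit0 <- lm(Y[, v] ~ age + sex + education, covs)
    fit1 <- lm(Y[, v] ~ age + sex + education + factor(g), covs)
    tab <- anova(fit0, fit1)
    expect_equal(an$stat[v], tab$F[2], tolerance = 1e-8)
    expect_equal(an$p[v], tab$`Pr(>F)`[2], tolerance = 1e-8)
  }
  expect_equal(unname(an$df), c(2, 18 - 3 - 3))
})

test_that("BH-FDR matches brute-force enumeration on exhaustive small inputs", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(fdr_bh(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(fdr_bh(0.04, 0.05), TRUE)
  expect_equal(fdr_bh(0.06, 0.05), FALSE)
  set.seed(19)
  for (m in 1:12) {
    for (rep_i in 1:25) {
      p <- round(runif(m), 3)
      expect_equal(fdr_bh(p, 0.05), brute_bh(p, 0.05))
      expect_equal(fdr_bh(p, 0.2), brute_bh(p, 0.2))
    }
  }
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.3)), "\\[0,1\\]")
})

test_that("post-hoc covariate-adjusted t matches lm and applies alpha/m", {
  set.seed(23)
  n <- 20
  g <- rep(c("NC", "MCI"), each = 10)
  covs <- data.frame(age = rnorm(n, 74, 8), education = rnorm(n, 14, 2))
  Y <- matrix(rnorm(n * 6), n)
  Y[, 3] <- Y[, 3] + 3 * (g == "NC")
  maps <- lapply(seq_len(n), function(i) array(Y[i, ], c(6, 1, 1)))
  ph <- posthoc_t(maps, g, c("NC", "MCI"), covs, m_comparisons = 9)
  expect_equal(ph$threshold, 0.05 / 9)
  for (v in 1:6) {
    sm <- summary(lm(Y[, v] ~ I(g == "NC") + age + education, covs))$coefficients
    expect_equal(ph$stat[v], sm[2, "t value"], tolerance = 1e-8)
    expect_equal(ph$p[v], sm[2, "Pr(>|t|)"], tolerance = 1e-8)
  }
  expect_true(ph$significant[3])
  ph6 <- posthoc_t(maps, g, c("NC", "MCI"), covs, m_comparisons = 6)
  expect_equal(ph6$threshold, 0.05 / 6)

  # identical groups: t ~ 0, nothing significant
  maps_same <- maps[c(1:10, 1:10)]
  ph0 <- posthoc_t(maps_same, g, c("NC", "MCI"), m_comparisons = 9)
  expect_equal(max(abs(ph0$stat)), 0, tolerance = 1e-8)
  expect_false(any(ph0$significant))
  expect_error(posthoc_t(maps, g, c("NC", "MCI"), covs, m_comparisons = 0),
               "positive")
})

test_that("cluster extraction sizes, peaks and bilateral merging are correct", {
  d <- c(12, 10, 10)
  rej <- array(FALSE, d)
  stat <- array(0, d)

  # one 78-voxel component at 3 mm -> 2106 mm^3
  comp <- cbind(rep(2:3, length.out = 78),
                rep(rep(1:8, each = 2), length.out = 78),
                rep(1:5, each = 16, length.out = 78))
  rej[comp] <- TRUE
  stat[comp] <- runif(78)
  stat[3, 4, 2] <- 9.5; rej[3, 4, 2] <- TRUE
  tab <- extract_clusters(rej, stat, voxel_size_mm = 3, merge_mirrored = FALSE)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$size_mm3, 2106)
  expect_equal(tab$peak_stat, 9.5)
  expect_true(all(tab$size_mm3 %% 27 == 0))

  # empty rejection map
  tab0 <- extract_clusters(array(FALSE, d), stat, 3)
  expect_equal(nrow(tab0), 0L)

  # two mirrored components merge into one bilateral +-x record
  rej2 <- array(FALSE, d); stat2 <- array(0, d)
  rej2[2:3, 4:5, 4:5] <- TRUE; rej2[10:11, 4:5, 4:5] <- TRUE
  stat2[rej2] <- 1; stat2[2, 4, 4] <- 7; stat2[11, 4, 4] <- 7
  tab2 <- extract_clusters(rej2, stat2, 3)
  expect_equal(nrow(tab2), 1L)
  expect_true(tab2$bilateral)
  expect_equal(tab2$n_voxels, 16L)
  expect_gt(tab2$peak_x_mm, 0)                  # reported as +-|x|
  expect_equal(length(attr(tab2, "voxels")[[1]]), 16L)

  # connectivity: diagonal neighbours connect at 26 but not at 6
  rej3 <- array(FALSE, d); rej3[2, 2, 2] <- TRUE; rej3[3, 3, 3] <- TRUE
  expect_equal(nrow(extract_clusters(rej3, stat, 3, connectivity = 26,
                                     merge_mirrored = FALSE)), 1L)
  expect_equal(nrow(extract_clusters(rej3, stat, 3, connectivity = 6,
                                     merge_mirrored = FALSE)), 2L)
})

test_that("planted group effects are localized by ANOVA + FDR", {
  spec <- tiny_spec(groups = c(NC = 8L, VMCI = 8L, MCI = 8L), seed = 27,
                    n_timepoints = 120L)
  coh <- generate_cohort(spec, materialize = FALSE)
  wm_mask <- generate_tissue(spec)$wm > 0.5
  mm <- build_mirror_map(wm_mask)
  maps <- lapply(seq_len(nrow(coh$subjects)), function(s) {
    b <- detrend_linear(drop_initial(
      generate_bold(spec, coh$subjects$id[s], coh$subjects$group[s]), 5))
    fisher_z(homotopic_correlation(b, mm))
  })
  an <- glm_group_f(maps, coh$subjects$group,
                    coh$subjects[, c("age", "sex", "education")], wm_mask)
  rej <- fdr_bh(an$p, 0.05)
  rejected_vox <- an$voxels[rej]
  parcel <- parcel_linear_index(spec, both_sides = TRUE)
  expect_gt(length(rejected_vox), 0)
  expect_gte(mean(rejected_vox %in% parcel), 0.9)
  # and most of the parcel is recovered
  expect_gt(mean(parcel %in% rejected_vox), 0.9)
})
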