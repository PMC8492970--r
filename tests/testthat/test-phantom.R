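test_that("phantom spec validation rejects degenerate definitions", {
  expect_error(phantom_spec(grid_shape = c(15, 14, 16)), "even")
  expect_error(phantom_spec(n_timepoints = 5), ">= 10")
  expect_error(tiny_spec(groups = c(NC = 0L, VMCI = 2L, MCI = 2L)) |>
                 generate_cohort(), "at least one subject")
  expect_error(generate_bold(tiny_spec(), "X01", "AD"), "unknown group")
})

test_that("generation is deterministic bit for bit under a fixed seed", {
  spec <- tiny_spec()
  b1 <- generate_bold(spec, "NC01", "NC")
  b2 <- generate_bold(spec, "NC01", "NC")
  expect_identical(b1, b2)
  expect_identical(generate_motion(spec, "MCI02"), generate_motion(spec, "MCI02"))
  c1 <- generate_cohort(spec, materialize = FALSE)
  c2 <- generate_cohort(spec, materialize = FALSE)
  expect_identical(c1$subjects, c2$subjects)
  # different subjects get different data
  expect_false(identical(generate_bold(spec, "NC01", "NC"),
                         generate_bold(spec, "NC02", "NC")))
})

test_that("planted homotopic correlation has the advertised population value", {
  # rho = 1, no noise: mirrored series identical
  spec1 <- tiny_spec(groups = c(NC = 1L))
  spec1$parcels[[1]]$rho["NC"] <- 1
  b <- generate_bold(spec1, "NC01", "NC")
  d <- spec1$grid_shape
  v <- spec1$parcels[[1]]$voxels[1, ]
  expect_equal(b[v[1], v[2], v[3], ], b[d[1] + 1 - v[1], v[2], v[3], ])

  # rho = 0: sample r inside the Fisher 99% null CI at T = 164
  spec0 <- phantom_spec(grid_shape = c(16, 14, 16), n_timepoints = 164,
                        groups = c(NC = 1L), seed = 11)
  spec0$parcels <- lapply(spec0$parcels, function(p) { p$rho[] <- 0; p })
  b0 <- generate_bold(spec0, "NC01", "NC")
  v <- spec0$parcels[[1]]$voxels[1, ]
  x <- b0[v[1], v[2], v[3], ]
  y <- b0[spec0$grid_shape[1] + 1 - v[1], v[2], v[3], ]
  expect_lt(abs(atanh(cor(x, y))), 2.576 / sqrt(164 - 3))

  # rho = 0.6: mean Fisher z over pooled pairs within 3 SEM of atanh(0.6)
  spec6 <- phantom_spec(grid_shape = c(16, 14, 16), n_timepoints = 164,
                        groups = c(NC = 6L), seed = 5)
  spec6$parcels <- lapply(spec6$parcels, function(p) { p$rho[] <- 0.6; p })
  zs <- unlist(lapply(sprintf("NC%02d", 1:6), function(id) {
    b <- generate_bold(spec6, id, "NC")
    m <- t(matrix(b, prod(spec6$grid_shape[1:3]), 164))
    unlist(lapply(seq_along(spec6$parcels), function(pi) {
      left <- parcel_linear_index(spec6, pi)
      vright <- spec6$parcels[[pi]]$voxels
      vright[, 1] <- spec6$grid_shape[1] + 1 - vright[, 1]
      right <- vright[, 1] + (vright[, 2] - 1) * 16 + (vright[, 3] - 1) * 16 * 14
      vapply(seq_along(left),
             function(i) atanh(cor(m[, left[i]], m[, right[i]])), numeric(1))
    }))
  }))
  expect_gt(length(zs), 100)  # pooled independent pairs
  sem <- sd(zs) / sqrt(length(zs))
  expect_lt(abs(mean(zs) - atanh(0.6)), 3 * sem)

  # additive noise attenuates the correlation to rho / (1 + sd^2)
  expect_equal(effective_rho(0.8, 1), 0.4)
})

test_that("motion traces honour amplitude and spike requests", {
  spec <- tiny_spec()
  fd <- compute_fd(generate_motion(spec, "NC01"))
  expect_true(all(fd < 1))

  quiet <- tiny_spec(motion_amp_mm = 0, motion_rot_amp = 0)
  expect_equal(compute_fd(generate_motion(quiet, "NC01")), rep(0, 60))

  spiked <- tiny_spec(motion_amp_mm = 0, motion_rot_amp = 0,
                      motion_spike_frames = list(NC01 = 50L))
  fd_s <- compute_fd(generate_motion(spiked, "NC01"))
  expect_gte(fd_s[50], 2)
  expect_equal(sum(fd_s > 1), 1L)

  bad <- tiny_spec(motion_spike_frames = list(NC01 = 1000L))
  expect_error(generate_motion(bad, "NC01"), "out of range")
})

test_that("DWI signals follow the single-tensor decay law", {
  spec <- tiny_spec()
  tf <- make_tensor_field(spec, "NC")
  dwi <- generate_dwi(spec, tf)
  head_vox <- which(tf$S0 > 0)

  # b = 0 volume returns S0 exactly
  s0_vol <- as.vector(dwi$data[, , , 1])
  expect_equal(s0_vol[head_vox], tf$S0[head_vox])

  # isotropic voxel: identical signal in every direction at fixed b
  csf_vox <- which(phantom_compartments_equal(spec, 1L))[1]
  sig <- matrix(dwi$data, ncol = length(dwi$bvals))[csf_vox, dwi$bvals > 0]
  expect_equal(max(sig) - min(sig), 0)

  # closed form: D = diag(1.7,.3,.3)e-3, b=1000, g=(1,0,0) -> S/S0 = exp(-1.7)
  spec_x <- tiny_spec()
  spec_x$dwi_scheme <- list(bvals = c(0, 1000), bvecs = rbind(c(0, 0, 0), c(1, 0, 0)))
  dwi_x <- generate_dwi(spec_x, tf)
  wm_vox <- which(phantom_compartments_equal(spec_x, 2L))[1]
  m <- matrix(dwi_x$data, ncol = 2)
  expect_equal(m[wm_vox, 2] / m[wm_vox, 1], exp(-1.7))

  # noiseless log-signal linearity: ln(S/S0) = -b g' D g for every volume
  S <- matrix(dwi$data, ncol = length(dwi$bvals))
  v <- head_vox[1]
  for (j in which(dwi$bvals > 0)) {
    g <- dwi$bvecs[j, ]
    Dm <- matrix(c(tf$D[v, "xx"], tf$D[v, "xy"], tf$D[v, "xz"],
                   tf$D[v, "xy"], tf$D[v, "yy"], tf$D[v, "yz"],
                   tf$D[v, "xz"], tf$D[v, "yz"], tf$D[v, "zz"]), 3)
    expect_equal(log(S[v, j] / tf$S0[v]), -dwi$bvals[j] * drop(g %*% Dm %*% g))
  }

  # invalid schemes rejected
  bad <- tiny_spec()
  bad$dwi_scheme$bvecs[2, ] <- c(2, 0, 0)
  expect_error(generate_dwi(bad, tf), "unit norm")
  bad2 <- tiny_spec()
  bad2$dwi_scheme$bvals[2] <- -5
  expect_error(generate_dwi(bad2, tf), "negative")
})

test_that("cohorts carry the expected structure and covariate ordering", {
  spec <- tiny_spec(groups = c(NC = 5L, VMCI = 5L, MCI = 5L))
  coh <- generate_cohort(spec, materialize = FALSE)
  expect_equal(nrow(coh$subjects), 15L)
  expect_setequal(unique(coh$subjects$group), c("NC", "VMCI", "MCI"))
  expect_true(all(c("age", "sex", "education", "mmse") %in% names(coh$subjects)))

  # MMSE severity gradient NC > VMCI > MCI at the default cohort size
  spec_big <- phantom_spec(grid_shape = c(16, 14, 16), n_timepoints = 60,
                           groups = c(NC = 10L, VMCI = 10L, MCI = 10L), seed = 1)
  mm <- tapply(generate_cohort(spec_big, materialize = FALSE)$subjects$mmse,
               generate_cohort(spec_big, materialize = FALSE)$subjects$group, mean)
  expect_gt(mm[["NC"]], mm[["VMCI"]])
  expect_gt(mm[["VMCI"]], mm[["MCI"]])

  # default grid: per-subject BOLD shape is the full acquisition
  dspec <- phantom_spec(groups = c(NC = 1L), seed = 3)
  expect_equal(dim(generate_bold(dspec, "NC01", "NC")), c(24, 28, 24, 164))

  # ground truth is stored alongside the cohort
  expect_identical(coh$ground_truth$parcels, spec$parcels)
  expect_equal(unname(coh$ground_truth$labels[coh$subjects$id]),
               coh$subjects$group)
})
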