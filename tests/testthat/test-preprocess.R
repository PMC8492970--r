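test_that("initial volume dropping truncates data and motion identically", {
  spec <- phantom_spec(grid_shape = c(16, 14, 16), n_timepoints = 164,
                       groups = c(NC = 1L), seed = 2)
  b <- generate_bold(spec, "NC01", "NC")
  m <- generate_motion(spec, "NC01")
  b5 <- drop_initial(b, 5)
  expect_equal(dim(b5)[4], 159)
  expect_equal(attr(b5, "tr_s"), 2.2)
  expect_equal(nrow(drop_initial(m, 5)), 159)
  expect_equal(b5[3, 4, 5, 1], b[3, 4, 5, 6])
  expect_identical(drop_initial(m, 0), m)
  expect_error(drop_initial(m, 164), "cannot drop")
})

test_that("linear detrending removes exactly the affine-in-time component", {
  tt <- 1:50
  m <- cbind(2 + 0.5 * tt, rep(7, 50))         # line and constant
  out <- detrend_linear(m)
  expect_equal(max(abs(out)), 0, tolerance = 1e-10)

  set.seed(3)
  r <- matrix(rnorm(50 * 4), 50)
  dr <- detrend_linear(r)
  X <- cbind(1, tt)
  coefs <- qr.coef(qr(X), dr)
  expect_lt(max(abs(coefs)), 1e-10)
  expect_error(detrend_linear(matrix(1:4, 2)), "at least 3")
})

test_that("framewise displacement matches the Power formula on hand cases", {
  z <- matrix(0, 10, 6)
  expect_equal(compute_fd(z), rep(0, 10))

  m <- z; m[5:10, 1] <- 1                       # 1 mm sustained x step at frame 5
  fd <- compute_fd(m)
  expect_equal(fd[5], 1)
  expect_equal(fd[-5], rep(0, 9))

  m2 <- z; m2[7:10, 4] <- 0.02                  # rotation arc: 50 mm * 0.02 rad
  expect_equal(compute_fd(m2)[7], 1)

  # hand-computed mixed frame: |dx|+|dy|+|dz| + 50*(|drx|+|dry|+|drz|)
  m3 <- z; m3[3, ] <- c(0.2, -0.1, 0.05, 0.001, -0.002, 0.004)
  expect_equal(compute_fd(m3)[3], 0.35 + 50 * 0.007)
  expect_equal(compute_fd(m3)[4], 0.35 + 50 * 0.007)  # return step, same cost
  expect_error(compute_fd(matrix(0, 5, 4)), "6 columns")
})

test_that("Friston-24 expansion has the documented lag/square structure", {
  z <- matrix(0, 8, 6)
  expect_equal(friston24(z), matrix(0, 8, 24), ignore_attr = TRUE)
  m <- z; m[, 2] <- 1:8
  f <- friston24(m)
  expect_equal(ncol(f), 24)
  expect_equal(f[, 6 + 2], c(0, 1:7))           # lagged copy, zero-padded
  expect_equal(f[, 12 + 2], (1:8)^2)            # square
  expect_equal(f[, 18 + 2], c(0, 1:7)^2)        # lagged square
})

test_that("spike regressors are one-hot columns above the FD threshold", {
  fd <- c(0, 0.3, 2, 0.1, 1.5, 0.2)
  s <- spike_regressors(fd, 1)
  expect_equal(dim(s), c(6, 2))
  expect_equal(colSums(s), c(spike_3 = 1, spike_5 = 1))
  expect_equal(which(s[, 1] == 1), 3L)
  expect_equal(ncol(spike_regressors(rep(0.3, 6), 1)), 0)
  expect_equal(ncol(spike_regressors(fd, 0)), sum(fd > 0))
})

test_that("nuisance regression produces orthogonal residuals and scrubs spikes", {
  set.seed(9)
  t_len <- 40
  X <- cbind(1, rnorm(t_len), rnorm(t_len))
  y <- X[, 2]
  expect_equal(max(abs(regress_nuisance(matrix(y), X))), 0, tolerance = 1e-12)

  Y <- matrix(rnorm(t_len * 5), t_len)
  res <- regress_nuisance(Y, X)
  expect_lt(max(abs(crossprod(X, res))), 1e-8)

  # intercept-only design demeans
  expect_equal(regress_nuisance(Y, matrix(1, t_len)),
               sweep(Y, 2, colMeans(Y)), tolerance = 1e-12)

  # spike indicator zeroes its own frame and leaves other frames' correlations intact
  spikes <- matrix(0, t_len, 1); spikes[13, 1] <- 1
  res_s <- regress_nuisance(Y, cbind(1, spikes))
  expect_equal(res_s[13, ], rep(0, 5), tolerance = 1e-12)
  keep <- setdiff(seq_len(t_len), 13)
  expect_equal(cor(res_s[keep, 1], res_s[keep, 2]),
               cor(Y[keep, 1], Y[keep, 2]), tolerance = 1e-12)

  # collinear design: warning, residuals still orthogonal to the column space
  Xc <- cbind(X, X[, 2] * 2)
  expect_warning(res_c <- regress_nuisance(Y, Xc), "rank deficient")
  expect_lt(max(abs(crossprod(X, res_c))), 1e-8)
})

test_that("FFT bandpass keeps in-band energy and removes out-of-band energy", {
  t_len <- 159; tr <- 2.2
  tt <- (seq_len(t_len) - 1) * tr
  inband <- sin(2 * pi * 0.05 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  bp <- function(x) bandpass(matrix(x), 0.01, 0.1, tr_s = tr)
  expect_gt(sum(bp(inband)^2) / sum(inband^2), 0.95)
  expect_lt(sum(bp(outband)^2) / sum(outband^2), 0.05)
  expect_equal(max(abs(bp(rep(3, t_len)))), 0, tolerance = 1e-10)
  expect_error(bandpass(matrix(inband), 0.1, 0.01, tr_s = tr), "low cutoff")
  expect_error(bandpass(matrix(inband), 0.01, 0.25, tr_s = tr), "Nyquist")
})

test_that("masked smoothing matches the brute-force truncated kernel oracle", {
  d <- c(9, 9, 9)
  set.seed(21)
  mask <- array(FALSE, d); mask[2:8, 2:8, 2:8] <- TRUE
  mask[4, 4, ] <- FALSE                          # irregular hole
  vol <- array(rnorm(prod(d)), d)

  sm <- masked_smooth(vol, mask, fwhm_mm = 4, voxel_size_mm = 3)
  oracle <- brute_masked_smooth(vol, mask, 4, 3)
  expect_equal(sm, oracle, tolerance = 1e-12)

  # impulse response at an interior voxel
  imp <- array(0, d); imp[5, 5, 5] <- 1
  expect_equal(masked_smooth(imp, mask, 4, voxel_size_mm = 3),
               brute_masked_smooth(imp, mask, 4, 3), tolerance = 1e-12)

  # constant field inside the mask is preserved exactly
  cvol <- array(0, d); cvol[mask] <- 5.5
  smc <- masked_smooth(cvol, mask, 4, voxel_size_mm = 3)
  expect_equal(smc[mask], rep(5.5, sum(mask)), tolerance = 1e-12)
  expect_equal(smc[!mask], rep(0, sum(!mask)))

  # voxels outside the mask never influence inside values
  vol2 <- vol; vol2[!mask] <- 1e6
  expect_equal(masked_smooth(vol2, mask, 4, voxel_size_mm = 3)[mask], sm[mask])

  expect_error(masked_smooth(vol, mask, fwhm_mm = 0, voxel_size_mm = 3), "positive")
  expect_error(masked_smooth(vol, array(FALSE, d), 4, voxel_size_mm = 3), "empty")
})

test_that("the full preprocessing chain runs in the documented stage order", {
  spec <- tiny_spec(groups = c(NC = 1L),
                    motion_spike_frames = list(NC01 = 30L))
  b <- generate_bold(spec, "NC01", "NC")
  m <- generate_motion(spec, "NC01")
  ti <- generate_tissue(spec)
  pp <- preprocess_subject(b, m, ti, drop = 5)
  expect_equal(dim(pp$wm)[4], 55)
  expect_equal(pp$params$order,
               c("drop", "detrend", "nuisance", "bandpass", "masked_smooth"))
  expect_equal(pp$spike_frames, 30L - 5L)        # spike index after dropping
  wm_mask <- ti$wm > 0.5
  expect_equal(sum(abs(pp$wm[!wm_mask])), 0)     # smoothing restricted to WM
})
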