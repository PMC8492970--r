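# Shared fixtures: small phantom specs and brute-force oracles used across
# module tests. Everything is generated in code at test time.

tiny_spec <- function(groups = c(NC = 3L, VMCI = 3L, MCI = 3L), seed = 42L,
                      n_timepoints = 60L, ...) {
  phantom_spec(grid_shape = c(16L, 14L, 16L), n_timepoints = n_timepoints,
               groups = groups, seed = seed, ...)
}

parcel_linear_index <- function(spec, which_parcel = 1L, both_sides = FALSE) {
  d <- spec$grid_shape
  p <- spec$parcels[[which_parcel]]
  lin <- function(v) v[, 1] + (v[, 2] - 1L) * d[1] + (v[, 3] - 1L) * d[1] * d[2]
  left <- lin(p$voxels)
  if (!both_sides) return(left)
  right <- p$voxels
  right[, 1] <- d[1] + 1L - right[, 1]
  c(left, lin(right))
}

# Direct 3D truncated-Gaussian masked smoothing: for every in-mask voxel, a
# windowed weighted mean over in-mask neighbours with the separable product
# kernel, renormalized over the window. Independent of the separable
# band-matrix implementation under test.
brute_masked_smooth <- function(vol, mask, fwhm_mm, voxel_size_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k1 <- exp(-0.5 * ((-r:r) / sigma)^2)
  k1 <- k1 / sum(k1)
  d <- dim(vol)
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      if (!mask[ii, jj, kk]) next
      w <- k1[di + r + 1] * k1[dj + r + 1] * k1[dk + r + 1]
      num <- num + w * vol[ii, jj, kk]
      den <- den + w
    }
    out[i, j, k] <- num / den
  }
  out
}

# Brute-force Benjamini-Hochberg: k = max{i : p_(i) <= i * q / m}, reject the
# k smallest p-values.
brute_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# Logical vector over voxels of the compartment with the given code
# (1 = CSF, 2 = WM, 3 = GM), recovered from the unperturbed tissue maps.
phantom_compartments_equal <- function(spec, code) {
  t <- generate_tissue(spec)
  m <- switch(code, t$csf, t$wm, t$gm)
  as.vector(m == 0.92)
}

# Labels reconstructing a given 3x3 confusion matrix (rows = true classes).
labels_from_confusion <- function(cm, classes) {
  y_true <- rep(classes, rowSums(cm))
  y_pred <- unlist(lapply(seq_len(nrow(cm)), function(i) rep(classes, cm[i, ])))
  list(true = y_true, pred = y_pred)
}
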