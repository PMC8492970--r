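# Functional preprocessing chain: volume dropping, linear detrending,
# Friston-24 + CSF + motion-spike nuisance regression, FFT bandpass and
# tissue-restricted Gaussian smoothing. Stage order is drop -> detrend ->
# nuisance/spike regression -> bandpass -> masked smoothing.

# Internal: view a 4D BOLD array (or a T x V matrix) as a T x V matrix plus a
# closure restoring the original shape and attributes.
as_ts_matrix <- function(x) {
  if (is.matrix(x)) {
    return(list(m = x, restore = function(m) m))
  }
  d <- dim(x)
  if (length(d) != 4L) stop("expected a 4D array or a T x V matrix")
  at <- attributes(x)
  list(m = t(matrix(x, nrow = prod(d[1:3]), ncol = d[4])),
       restore = function(m) {
         out <- array(t(m), dim = c(d[1:3], nrow(m)))
         for (nm in setdiff(names(at), c("dim", "dimnames")))
           attr(out, nm) <- at[[nm]]
         out
       })
}

n_frames <- function(x) if (is.matrix(x)) nrow(x) else dim(x)[length(dim(x))]

#' Drop initial volumes
#'
#' Removes the first `k` frames (T1 saturation period) from a 4D BOLD array or
#' from any per-frame matrix (e.g. a motion trace), so that both stay aligned.
#'
#' @param x 4D array (time last) or T x k matrix.
#' @param k number of initial frames to drop (default 5).
#' @return same type as `x` with `k` fewer frames.
#' @export
drop_initial <- function(x, k = 5L) {
  t_len <- n_frames(x)
  if (k >= t_len) stop("cannot drop ", k, " of ", t_len, " frames")
  if (k == 0L) return(x)
  keep <- (k + 1L):t_len
  if (is.matrix(x)) return(x[keep, , drop = FALSE])
  ts <- as_ts_matrix(x)
  ts$restore(ts$m[keep, , drop = FALSE])
}

#' Remove per-voxel linear trends
#'
#' Least-squares removal of intercept and slope from every voxel time series;
#' the output is orthogonal to both the constant and the linear ramp.
#'
#' @param x 4D array or T x V matrix, T >= 3.
#' @return detrended data, same shape as input.
#' @export
detrend_linear <- function(x) {
  ts <- as_ts_matrix(x)
  t_len <- nrow(ts$m)
  if (t_len < 3L) stop("need at least 3 frames to detrend")
  X <- cbind(1, seq_len(t_len))
  ts$restore(qr.resid(qr(X), ts$m))
}

#' Power framewise displacement
#'
#' FD(t) = sum of absolute backward differences of the three translations plus
#' `sphere_radius_mm` times the summed absolute rotation differences (arc
#' length on a sphere approximating the head); FD(1) = 0.
#'
#' @param motion T x 6 matrix (tx, ty, tz in mm; rx, ry, rz in rad).
#' @param sphere_radius_mm head-sphere radius converting rotations to mm.
#' @return numeric vector of length T, all values >= 0.
#' @export
compute_fd <- function(motion, sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion trace must have 6 columns")
  if (nrow(motion) < 1L) stop("motion trace is empty")
  d <- rbind(rep(0, 6), abs(diff(motion)))
  rowSums(d[, 1:3, drop = FALSE]) +
    sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' Friston 24-parameter motion regressor set
#'
#' Columns are `[p(t), p(t-1), p(t)^2, p(t-1)^2]` for the six rigid-body
#' parameters, with the zero-padded convention p(0) = 0 for the first frame.
#'
#' @param motion T x 6 matrix.
#' @return T x 24 matrix.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion trace must have 6 columns")
  lag1 <- rbind(rep(0, 6), motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_lag"),
                     paste0("p", 1:6, "_sq"), paste0("p", 1:6, "_lagsq"))
  out
}

#' Motion-spike indicator regressors
#'
#' One indicator column per frame whose framewise displacement exceeds the
#' threshold; scrubbing those frames through the nuisance regression removes
#' their influence without altering correlations among the remaining frames.
#'
#' @param fd per-frame FD vector (see [compute_fd()]).
#' @param threshold_mm spike threshold in mm (default 1).
#' @return T x S 0/1 matrix; S may be 0.
#' @export
spike_regressors <- function(fd, threshold_mm = 1) {
  idx <- which(fd > threshold_mm)
  out <- matrix(0, nrow = length(fd), ncol = length(idx))
  if (length(idx)) {
    out[cbind(idx, seq_along(idx))] <- 1
    colnames(out) <- paste0("spike_", idx)
  }
  out
}

#' Assemble the nuisance design matrix
#'
#' Intercept + Friston-24 motion expansion + optional CSF mean signal +
#' optional per-spike indicator columns.
#'
#' @param motion T x 6 motion trace (already aligned to the BOLD frames).
#' @param csf_mean optional length-T CSF mean signal.
#' @param fd optional FD vector enabling spike regressors.
#' @param fd_threshold_mm spike threshold in mm.
#' @return T x K design matrix.
#' @export
nuisance_design <- function(motion, csf_mean = NULL, fd = NULL, fd_threshold_mm = 1) {
  X <- cbind(intercept = 1, friston24(motion))
  if (!is.null(csf_mean)) X <- cbind(X, csf = csf_mean)
  if (!is.null(fd)) X <- cbind(X, spike_regressors(fd, fd_threshold_mm))
  X
}

#' Regress nuisance signals from a BOLD series
#'
#' Per-voxel OLS residuals against the design; collinear columns are dropped
#' (QR pivoting) with a warning. Residuals are orthogonal to every retained
#' design column; frames carrying their own spike indicator have residual 0.
#'
#' @param x 4D array or T x V matrix.
#' @param design T x K nuisance design (see [nuisance_design()]).
#' @return residual series, same shape as input.
#' @export
regress_nuisance <- function(x, design) {
  ts <- as_ts_matrix(x)
  design <- as.matrix(design)
  if (nrow(design) != nrow(ts$m))
    stop("design has ", nrow(design), " rows but data has ", nrow(ts$m), " frames")
  q <- qr(design)
  if (q$rank < ncol(design))
    warning("nuisance design is rank deficient (rank ", q$rank, " of ",
            ncol(design), "); collinear columns dropped")
  ts$restore(qr.resid(q, ts$m))
}

#' Ideal FFT bandpass filter
#'
#' Rectangular retention in the discrete Fourier domain: frequency bins with
#' |f| in `[low, high]` are kept, all others (including DC) are zeroed.
#'
#' @param x 4D array or T x V matrix.
#' @param low,high passband edges in Hz (0.01-0.1 by default).
#' @param tr_s repetition time in seconds (taken from the `tr_s` attribute when
#'   present).
#' @return filtered series, same shape as input.
#' @export
bandpass <- function(x, low = 0.01, high = 0.1, tr_s = attr(x, "tr_s")) {
  if (is.null(tr_s)) stop("tr_s is required")
  nyq <- 1 / (2 * tr_s)
  if (low >= high) stop("low cutoff must be below high cutoff")
  if (high >= nyq) stop("high cutoff ", high, " Hz is at or above Nyquist (",
                        signif(nyq, 4), " Hz)")
  ts <- as_ts_matrix(x)
  t_len <- nrow(ts$m)
  k <- 0:(t_len - 1)
  f <- pmin(k, t_len - k) / (t_len * tr_s)
  keep <- f >= low & f <= high
  xf <- stats::mvfft(ts$m)
  xf[!keep, ] <- 0
  ts$restore(Re(stats::mvfft(xf, inverse = TRUE)) / t_len)
}

# Truncated, normalized 1D Gaussian kernel in voxel units.
gaussian_kernel1d <- function(fwhm_mm, voxel_size_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

band_matrix <- function(n, kern) {
  r <- (length(kern) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n - abs(o))
    if (o >= 0) K[cbind(idx, idx + o)] <- kern[o + r + 1L]
    else K[cbind(idx - o, idx)] <- kern[o + r + 1L]
  }
  K
}

smooth3d <- function(vol, fwhm_mm, voxel_size_mm) {
  kern <- gaussian_kernel1d(fwhm_mm, voxel_size_mm)
  d <- dim(vol)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    v <- aperm(vol, perm)
    v <- array(band_matrix(d[axis], kern) %*% matrix(v, nrow = d[axis]),
               dim = d[perm])
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Gaussian smoothing restricted to a tissue mask
#'
#' Normalized masked smoothing: `smooth(data * mask) / smooth(mask)` evaluated
#' inside the mask and 0 outside, with the same truncated separable Gaussian
#' kernel in numerator and denominator. Voxels outside the mask never influence
#' values inside, and a constant field inside the mask is preserved exactly.
#' Denominator values below 1e-6 are zeroed.
#'
#' @param x 3D volume or 4D series.
#' @param mask logical/0-1 3D array on the same grid; must be non-empty.
#' @param fwhm_mm kernel full width at half maximum in mm (default 4).
#' @param voxel_size_mm isotropic voxel size in mm (taken from the
#'   `voxel_size_mm` attribute when present).
#' @return smoothed data, same shape as `x`; zero outside the mask.
#' @export
masked_smooth <- function(x, mask, fwhm_mm = 4,
                          voxel_size_mm = attr(x, "voxel_size_mm")) {
  if (is.null(voxel_size_mm)) stop("voxel_size_mm is required")
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  mask <- array(as.numeric(mask != 0), dim = dim(mask))
  if (!any(mask > 0)) stop("mask is empty")
  den <- smooth3d(mask, fwhm_mm, voxel_size_mm)
  inside <- mask > 0 & den > 1e-6
  one <- function(vol) {
    num <- smooth3d(vol * mask, fwhm_mm, voxel_size_mm)
    out <- array(0, dim = dim(vol))
    out[inside] <- num[inside] / den[inside]
    out
  }
  d <- dim(x)
  if (length(d) == 3L) return(one(x))
  if (length(d) != 4L) stop("expected a 3D or 4D array")
  at <- attributes(x)
  out <- array(0, dim = d)
  for (t in seq_len(d[4])) out[, , , t] <- one(x[, , , t])
  for (nm in setdiff(names(at), c("dim", "dimnames"))) attr(out, nm) <- at[[nm]]
  out
}

#' Full per-subject functional preprocessing
#'
#' Applies the chain drop -> detrend -> nuisance regression (Friston-24 + CSF
#' mean + FD spike indicators) -> bandpass -> masked smoothing separately
#' within the subject's WM and GM (probability > `subject_threshold`). The CSF
#' mean regressor is extracted from the dropped + detrended series.
#'
#' @param bold 4D BOLD array with `tr_s` and `voxel_size_mm` attributes.
#' @param motion T x 6 motion trace aligned to the *undropped* series.
#' @param tissue list with `gm`, `wm`, `csf` probability maps.
#' @param drop number of initial volumes to discard.
#' @param fd_threshold_mm spike threshold in mm.
#' @param band passband in Hz, `c(low, high)`.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param subject_threshold tissue probability cut identifying a subject's own
#'   WM/GM/CSF voxels.
#' @return list with smoothed `wm` and `gm` series, `unsmoothed` residual
#'   series, `fd`, `spike_frames`, and a `params` provenance record.
#' @export
preprocess_subject <- function(bold, motion, tissue, drop = 5L,
                               fd_threshold_mm = 1, band = c(0.01, 0.1),
                               fwhm_mm = 4, subject_threshold = 0.5) {
  tr_s <- attr(bold, "tr_s")
  b <- drop_initial(bold, drop)
  m <- drop_initial(motion, drop)
  b <- detrend_linear(b)
  fd <- compute_fd(m)
  csf_mask <- tissue$csf > subject_threshold
  ts <- as_ts_matrix(b)
  csf_mean <- rowMeans(ts$m[, as.vector(csf_mask), drop = FALSE])
  X <- nuisance_design(m, csf_mean, fd, fd_threshold_mm)
  b <- regress_nuisance(b, X)
  b <- bandpass(b, band[1], band[2], tr_s)
  wm_mask <- tissue$wm > subject_threshold
  gm_mask <- tissue$gm > subject_threshold
  list(wm = masked_smooth(b, wm_mask, fwhm_mm),
       gm = masked_smooth(b, gm_mask, fwhm_mm),
       unsmoothed = b,
       fd = fd,
       spike_frames = which(fd > fd_threshold_mm),
       params = list(order = c("drop", "detrend", "nuisance", "bandpass", "masked_smooth"),
                     drop = drop, fd_threshold_mm = fd_threshold_mm,
                     band = band, fwhm_mm = fwhm_mm,
                     subject_threshold = subject_threshold, tr_s = tr_s))
}
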