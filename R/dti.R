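# Diffusion tensor fitting (log-linear least squares), AD/MD/FA metrics via
# closed-form symmetric 3x3 eigenvalues, and ROI-level group comparisons.

#' Fit single diffusion tensors by log-linear least squares
#'
#' Solves, per voxel, `ln S(b, g) = ln S0 - b * g' D g` in least squares over
#' all volumes. Requires at least one b = 0 volume and >= 6 non-collinear
#' gradient directions. Non-positive signals are clamped to a small positive
#' value before the log (counted in `n_clamped`). On noiseless single-tensor
#' data the generator is inverted to machine precision.
#'
#' @param dwi a `dwi_series` (see [generate_dwi()]) or 4D array.
#' @param bvals,bvecs scheme vectors (taken from `dwi` when it is a
#'   `dwi_series`).
#' @return `tensor_field`: `D` (nvox x 6), `S0`, `dim`, `mask` (voxels with
#'   positive b0 signal), `n_clamped`.
#' @export
fit_tensor <- function(dwi, bvals = NULL, bvecs = NULL) {
  if (inherits(dwi, "dwi_series")) {
    if (is.null(bvals)) bvals <- dwi$bvals
    if (is.null(bvecs)) bvecs <- dwi$bvecs
    arr <- dwi$data
  } else arr <- dwi
  d <- dim(arr)
  stopifnot(length(d) == 4L)
  nvol <- d[4]
  if (length(bvals) != nvol || nrow(bvecs) != nvol)
    stop("scheme does not match the number of volumes")
  if (sum(bvals == 0) < 1L) stop("at least one b = 0 volume is required")
  dw <- bvals > 0
  if (sum(dw) < 6L) stop("at least 6 diffusion-weighted directions are required")
  g <- bvecs
  X <- cbind(1, -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
             -2 * bvals * g[, 1] * g[, 2], -2 * bvals * g[, 1] * g[, 3],
             -2 * bvals * g[, 2] * g[, 3])
  if (qr(X)$rank < 7L)
    stop("gradient directions are collinear; the tensor is not identifiable")
  nvox <- prod(d[1:3])
  S <- matrix(arr, nrow = nvox, ncol = nvol)
  b0_mean <- rowMeans(S[, !dw, drop = FALSE])
  mask <- b0_mean > 0
  eps <- .Machine$double.eps * pmax(b0_mean, 1)
  n_clamped <- sum(S[mask, ] <= 0)
  logS <- log(pmax(S[mask, , drop = FALSE], eps[mask]))
  beta <- solve(crossprod(X), crossprod(X, t(logS)))
  D <- matrix(0, nrow = nvox, ncol = 6,
              dimnames = list(NULL, c("xx", "yy", "zz", "xy", "xz", "yz")))
  D[mask, ] <- t(beta[2:7, , drop = FALSE])
  S0 <- numeric(nvox)
  S0[mask] <- exp(beta[1, ])
  structure(list(D = D, S0 = S0, dim = d[1:3], mask = mask,
                 n_clamped = n_clamped), class = "tensor_field")
}

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorized over rows of a
# nvox x 6 matrix (xx, yy, zz, xy, xz, yz). Returns a nvox x 3 matrix with
# columns sorted descending.
sym_eigenvalues <- function(D) {
  a <- D[, 1]; b <- D[, 2]; c_ <- D[, 3]
  d <- D[, 4]; e <- D[, 5]; f <- D[, 6]
  q <- (a + b + c_) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c_ - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(p2 / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > .Machine$double.eps * pmax(abs(q), 1)
  if (any(nz)) {
    pn <- p[nz]
    B11 <- (a[nz] - q[nz]) / pn; B22 <- (b[nz] - q[nz]) / pn
    B33 <- (c_[nz] - q[nz]) / pn
    B12 <- d[nz] / pn; B13 <- e[nz] / pn; B23 <- f[nz] / pn
    detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
      B13 * (B12 * B23 - B22 * B13)
    phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
    l1[nz] <- q[nz] + 2 * pn * cos(phi)
    l3[nz] <- q[nz] + 2 * pn * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3)
}

#' Tensor-derived diffusivity metrics
#'
#' From the eigenvalues l1 >= l2 >= l3 of each voxel's tensor:
#' axial diffusivity AD = l1, mean diffusivity MD = (l1 + l2 + l3) / 3, and
#' fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((l - MD)^2)) / sqrt(sum(l^2))` in \[0, 1\].
#' Slightly negative eigenvalues (noise) are clamped to 0 before the metric
#' computation and counted; all-zero tensors get FA = 0.
#'
#' @param tensor_field a `tensor_field` (see [fit_tensor()]).
#' @return list with 3D arrays `ad`, `md`, `fa`, eigenvalue matrix
#'   `eigenvalues` (nvox x 3), and QA counts `n_negative_clamped`, `n_zero`.
#' @export
tensor_metrics <- function(tensor_field) {
  stopifnot(inherits(tensor_field, "tensor_field"))
  ev <- sym_eigenvalues(tensor_field$D)
  n_neg <- sum(ev < 0)
  ev <- pmax(ev, 0)
  md <- rowMeans(ev)
  ss <- rowSums(ev^2)
  zero <- ss <= 0
  num <- rowSums((ev - md)^2)
  fa <- sqrt(1.5) * sqrt(num / ifelse(zero, 1, ss))
  fa[zero] <- 0
  fa <- pmin(fa, 1)
  d <- tensor_field$dim
  list(ad = array(ev[, 1], dim = d), md = array(md, dim = d),
       fa = array(fa, dim = d), eigenvalues = ev,
       n_negative_clamped = n_neg, n_zero = sum(zero))
}

#' Compare ROI diffusivity metrics between groups
#'
#' For every ROI x metric x group pair, the mean metric within the ROI is
#' computed per subject and compared with a pooled two-sample t-test; a cell is
#' significant when its two-tailed p falls below `alpha / m_comparisons`
#' (the companion analysis uses m = 9: 3 ROIs x 3 contrasts).
#'
#' @param metrics_by_subject list (one element per subject) of
#'   [tensor_metrics()] outputs (or any list with `ad`, `md`, `fa` arrays).
#' @param groups group label per subject.
#' @param rois a `cluster_table` (voxel lists are taken from its attribute) or
#'   a named list of linear voxel index vectors.
#' @param m_comparisons Bonferroni divisor (default 9).
#' @param alpha family-wise level before division (default 0.05).
#' @return data.frame with columns roi, metric, group_a, group_b, mean_a,
#'   mean_b, t, df, p, significant.
#' @export
roi_dti_compare <- function(metrics_by_subject, groups, rois,
                            m_comparisons = 9L, alpha = 0.05) {
  if (m_comparisons <= 0) stop("m_comparisons must be positive")
  if (inherits(rois, "cluster_table")) {
    vx <- attr(rois, "voxels")
    names(vx) <- paste0("cluster_", rois$cluster)
    rois <- vx
  }
  if (any(vapply(rois, length, 0L) == 0L)) stop("empty ROI")
  lv <- unique(groups)
  pairs <- utils::combn(lv, 2)
  rows <- list()
  for (rn in names(rois)) {
    vox <- rois[[rn]]
    for (metric in c("ad", "fa", "md")) {
      vals <- vapply(metrics_by_subject,
                     function(m) mean(m[[metric]][vox]), numeric(1))
      for (pc in seq_len(ncol(pairs))) {
        ga <- pairs[1, pc]; gb <- pairs[2, pc]
        xa <- vals[groups == ga]; xb <- vals[groups == gb]
        tt <- stats::t.test(xa, xb, var.equal = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          roi = rn, metric = toupper(metric), group_a = ga, group_b = gb,
          mean_a = mean(xa), mean_b = mean(xb),
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value, significant = tt$p.value < alpha / m_comparisons)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- alpha / m_comparisons
  out
}
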