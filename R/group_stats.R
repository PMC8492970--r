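# Mass-univariate group comparison of VMHC maps: covariate-adjusted one-way
# ANOVA (partial F via nested GLMs), Benjamini-Hochberg FDR, post-hoc
# covariate-adjusted two-sample t with Bonferroni control, and connected-
# component cluster reporting with mirrored-pair merging.

# Internal: stack per-subject maps (vmhc_map objects or 3D arrays) into a
# subjects x voxels matrix over the mask (or over all voxels when mask NULL).
stack_maps <- function(maps, mask = NULL) {
  vols <- lapply(maps, function(m) if (inherits(m, "vmhc_map")) m$z else m)
  d <- dim(vols[[1]])
  vox <- if (is.null(mask)) seq_len(prod(d)) else which(as.vector(mask != 0))
  Y <- do.call(rbind, lapply(vols, function(v) as.vector(v)[vox]))
  list(Y = Y, voxels = vox, dim = d)
}

# Internal: covariate model matrix (numeric age/education, sex as 0/1 factor),
# dropping collinear columns with a warning.
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || length(covariates) == 0L)
    return(matrix(numeric(0), nrow = n, ncol = 0))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  q <- qr(cbind(1, X))
  if (q$rank < ncol(X) + 1L) {
    keep <- q$pivot[seq_len(q$rank)] - 1L
    keep <- keep[keep > 0L]
    warning("collinear covariates dropped: ",
            paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X
}

new_stat_map <- function(stat, p, df, voxels, dim, type) {
  structure(list(stat = stat, p = p, df = df, voxels = voxels, dim = dim,
                 type = type), class = "stat_map")
}

# Internal: expand a masked per-voxel vector into a 3D array (fill elsewhere).
unmask <- function(values, voxels, dim, fill = 0) {
  out <- array(fill, dim = dim)
  out[voxels] <- values
  out
}

#' Voxel-wise covariate-adjusted one-way ANOVA
#'
#' Per voxel, the partial F for the group factor in the GLM
#' `y ~ group + covariates + intercept`, i.e. the nested-model comparison of
#' residual sums of squares with and without the group dummies. With no
#' covariates this reduces exactly to the classical one-way ANOVA F.
#' Degrees of freedom are (g - 1, n - g - c).
#'
#' @param maps list of per-subject [vmhc_subject()] maps or 3D arrays.
#' @param groups vector of group labels, one per map (>= 2 groups, each n >= 2).
#' @param covariates optional data.frame (e.g. age, sex, education).
#' @param mask optional 3D mask restricting the analysis.
#' @return object of class `stat_map` with per-voxel `stat` (F), `p`
#'   (upper-tail), `df`, masked voxel indices and grid dimensions.
#' @export
glm_group_f <- function(maps, groups, covariates = NULL, mask = NULL) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs n >= 2")
  st <- stack_maps(maps, mask)
  n <- nrow(st$Y)
  if (length(g) != n) stop("groups length does not match number of maps")
  C <- covariate_matrix(covariates, n)
  X0 <- cbind(1, C)
  X1 <- cbind(X0, stats::model.matrix(~ g)[, -1, drop = FALSE])
  q0 <- qr(X0); q1 <- qr(X1)
  rss0 <- colSums(qr.resid(q0, st$Y)^2)
  rss1 <- colSums(qr.resid(q1, st$Y)^2)
  df1 <- q1$rank - q0$rank
  df2 <- n - q1$rank
  if (df2 <= 0) stop("no residual degrees of freedom")
  num <- pmax(rss0 - rss1, 0)
  Fv <- (num / df1) / (rss1 / df2)
  # voxels constant across subjects (both RSS at floating-point zero): F = 0
  tol <- 1e-10 * (colSums(st$Y^2) + 1)
  degen <- rss1 <= tol
  Fv[degen] <- ifelse(num[degen] <= tol[degen], 0, Inf)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  new_stat_map(Fv, p, c(df1 = df1, df2 = df2), st$voxels, st$dim, "F")
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Rejects the k smallest p-values where `k = max{i : p_(i) <= i * q / m}`,
#' via the equivalent adjusted-p formulation.
#'
#' @param pvals vector of p-values in \[0,1\].
#' @param q false-discovery-rate level (default 0.05).
#' @return logical rejection vector of the same length.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Post-hoc covariate-adjusted two-sample t-test map
#'
#' Per voxel, the t statistic of the group-indicator coefficient in the GLM
#' `y ~ indicator + covariates + intercept` fitted on the two groups' subjects,
#' with two-tailed p-values and Bonferroni-style significance at
#' `alpha / m_comparisons`.
#'
#' @param maps list of per-subject maps (all subjects; the pair is subset here).
#' @param groups group label per map.
#' @param pair character(2): the two group labels to compare (contrast is
#'   `pair[1] - pair[2]`).
#' @param covariates optional data.frame for all subjects.
#' @param m_comparisons Bonferroni divisor m (> 0); the paper's analyses use
#'   6 for GM (2 ROIs x 3 contrasts) and 9 for WM (3 ROIs x 3 contrasts).
#' @param alpha family-wise level before division (default 0.05).
#' @param mask optional 3D mask.
#' @return `stat_map` with `stat` (t), `p`, `df`, plus `significant` flags and
#'   the `threshold` used.
#' @export
posthoc_t <- function(maps, groups, pair, covariates = NULL,
                      m_comparisons = 1L, alpha = 0.05, mask = NULL) {
  if (m_comparisons <= 0) stop("m_comparisons must be positive")
  sel <- groups %in% pair
  if (sum(groups == pair[1]) < 2L || sum(groups == pair[2]) < 2L)
    stop("both groups need n >= 2")
  st <- stack_maps(maps[sel], mask)
  gsel <- groups[sel]
  ind <- as.numeric(gsel == pair[1])
  C <- covariate_matrix(if (is.null(covariates)) NULL else covariates[sel, , drop = FALSE],
                        length(gsel))
  X <- cbind(1, ind = ind, C)
  q <- qr(X)
  n <- nrow(X)
  df2 <- n - q$rank
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, st$Y)
  rss <- colSums((st$Y - X %*% B)^2)
  se <- sqrt(rss / df2 * XtXinv[2, 2])
  tval <- B[2, ] / pmax(se, .Machine$double.xmin)
  tval[se == 0] <- 0
  p <- 2 * stats::pt(-abs(tval), df2)
  out <- new_stat_map(tval, p, c(df = df2), st$voxels, st$dim, "t")
  out$threshold <- alpha / m_comparisons
  out$significant <- p < out$threshold
  out$pair <- pair
  out
}

#' @export
print.stat_map <- function(x, ...) {
  cat("Voxel-wise ", x$type, " map over ", length(x$voxels), " voxels, df = (",
      paste(x$df, collapse = ", "), "), min p = ", signif(min(x$p), 3), "\n",
      sep = "")
  invisible(x)
}

neighbour_offsets <- function(connectivity = 26L) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lim <- switch(as.character(connectivity), "6" = 1L, "18" = 2L, "26" = 3L,
                stop("connectivity must be 6, 18 or 26"))
  offs[rowSums(abs(offs)) <= lim, , drop = FALSE]
}

#' Label connected components of a binary 3D map
#'
#' Flood-fill labeling under 6-, 18- or 26-neighbour connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity one of 6, 18, 26 (default 26).
#' @return integer 3D array; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- neighbour_offsets(connectivity)
  labels <- array(0L, dim = d)
  todo <- which(mask != 0)
  lab <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    stack <- seed
    labels[seed] <- lab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- arrayInd(cur, d)
      nb <- sweep(offs, 2, as.integer(ci), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- lin[mask[lin] != 0 & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- lab
        stack <- c(stack, lin)
      }
    }
  }
  labels
}

# Voxel index -> mm coordinate with the origin at the grid centre; the
# left-right axis changes sign under mirroring.
voxel_to_mm <- function(vox, dim, voxel_size_mm) {
  sweep(vox, 2, (dim + 1) / 2) * voxel_size_mm
}

#' Extract suprathreshold clusters into a report table
#'
#' Labels connected components of the rejection map, records size (mm^3), peak
#' statistic and peak coordinate, and merges exactly mirrored left-right
#' component pairs into a single bilateral record whose x coordinate is
#' reported as +-|x|. Cluster sizes are always voxel multiples of the voxel
#' volume.
#'
#' @param reject logical 3D rejection map.
#' @param stat 3D statistic map (peaks are located by max |stat|).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param merge_mirrored merge mirror-image component pairs (default TRUE).
#' @return data.frame of class `cluster_table` with columns `cluster`,
#'   `n_voxels`, `size_mm3`, `peak_stat`, `peak_x_mm`, `peak_y_mm`,
#'   `peak_z_mm`, `bilateral`; per-record voxel indices in attribute `voxels`.
#' @export
extract_clusters <- function(reject, stat, voxel_size_mm = 3,
                             connectivity = 26L, merge_mirrored = TRUE) {
  d <- dim(reject)
  labels <- label_components(reject, connectivity)
  n_lab <- max(labels)
  empty <- data.frame(cluster = integer(0), n_voxels = integer(0),
                      size_mm3 = numeric(0), peak_stat = numeric(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0), bilateral = logical(0))
  if (n_lab == 0L) {
    attr(empty, "voxels") <- list()
    class(empty) <- c("cluster_table", class(empty))
    return(empty)
  }
  sets <- lapply(seq_len(n_lab), function(l) which(labels == l))
  mirror_lin <- function(lin) {
    v <- arrayInd(lin, d)
    v[, 1] <- d[1] + 1L - v[, 1]
    sort(v[, 1] + (v[, 2] - 1L) * d[1] + (v[, 3] - 1L) * d[1] * d[2])
  }
  merged <- rep(FALSE, n_lab)
  records <- list()
  for (l in seq_len(n_lab)) {
    if (merged[l]) next
    vox <- sets[[l]]
    bilateral <- FALSE
    if (merge_mirrored) {
      mir <- mirror_lin(vox)
      if (identical(mir, sort(vox))) {
        bilateral <- TRUE     # single component straddling the midline
      } else {
        for (l2 in seq_len(n_lab)) {
          if (l2 == l || merged[l2]) next
          if (identical(mir, sort(sets[[l2]]))) {
            vox <- c(vox, sets[[l2]])
            merged[l2] <- TRUE
            bilateral <- TRUE
            break
          }
        }
      }
    }
    peak <- vox[which.max(abs(stat[vox]))]
    pc <- voxel_to_mm(arrayInd(peak, d), d, voxel_size_mm)
    records[[length(records) + 1L]] <- list(
      n_voxels = length(vox), peak_stat = stat[peak],
      x = if (bilateral) abs(pc[1]) else pc[1], y = pc[2], z = pc[3],
      bilateral = bilateral, voxels = vox)
  }
  ord <- order(-vapply(records, `[[`, 0L, "n_voxels"))
  records <- records[ord]
  out <- data.frame(
    cluster = seq_along(records),
    n_voxels = vapply(records, `[[`, 0L, "n_voxels"),
    size_mm3 = vapply(records, `[[`, 0L, "n_voxels") * voxel_size_mm^3,
    peak_stat = vapply(records, `[[`, 0, "peak_stat"),
    peak_x_mm = vapply(records, `[[`, 0, "x"),
    peak_y_mm = vapply(records, `[[`, 0, "y"),
    peak_z_mm = vapply(records, `[[`, 0, "z"),
    bilateral = vapply(records, `[[`, FALSE, "bilateral"))
  attr(out, "voxels") <- lapply(records, `[[`, "voxels")
  class(out) <- c("cluster_table", class(out))
  out
}
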