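# Voxel-mirrored homotopic connectivity: Pearson correlation between every
# pair of symmetric interhemispheric voxels, Fisher-z transformed. The pair's
# correlation is assigned to both voxels, so every map is exactly symmetric.

#' Homotopic correlation map
#'
#' Pearson correlation between each mirrored voxel pair of the map; the value
#' is written to both members, so `r(v) == r(mirror(v))` exactly. Pairs where
#' either series has zero variance get r = 0 and are counted in the
#' `n_zero_variance` attribute rather than propagating NaN.
#'
#' @param bold 4D BOLD array (or T x V matrix matching the map's grid).
#' @param mirror_map a [build_mirror_map()] pairing.
#' @return 3D array of r values in \[-1, 1\] (0 outside the mask), with
#'   attribute `n_zero_variance`.
#' @export
homotopic_correlation <- function(bold, mirror_map) {
  stopifnot(inherits(mirror_map, "mirror_map"))
  ts <- as_ts_matrix(bold)
  if (ncol(ts$m) != prod(mirror_map$dim))
    stop("BOLD grid does not match the mirror map")
  if (nrow(ts$m) < 3L) stop("need at least 3 time points")
  X <- ts$m[, mirror_map$left, drop = FALSE]
  Y <- ts$m[, mirror_map$right, drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  sx <- colSums(X^2)
  sy <- colSums(Y^2)
  flat <- sx <= 0 | sy <= 0
  denom <- sqrt(sx * sy)
  denom[flat] <- 1
  r <- colSums(X * Y) / denom
  r[flat] <- 0
  r <- pmin(pmax(r, -1), 1)
  out <- array(0, dim = mirror_map$dim)
  out[mirror_map$left] <- r
  out[mirror_map$right] <- r
  attr(out, "n_zero_variance") <- sum(flat)
  out
}

#' Fisher z transform
#'
#' `z = atanh(r)` with clipping of |r| to `1 - eps` beforehand so degenerate
#' perfect correlations stay finite. Odd and strictly increasing.
#'
#' @param r correlations, |r| <= 1 (anything else is rejected).
#' @param eps clipping margin (default 1e-7).
#' @return z values, same shape as `r`.
#' @export
fisher_z <- function(r, eps = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1")
  at <- attributes(r)
  z <- atanh(pmin(pmax(r, -1 + eps), 1 - eps))
  attributes(z) <- at
  z
}

#' Per-subject VMHC map
#'
#' Computes the homotopic correlation over a symmetric mask and Fisher-z
#' transforms it. Provenance records the mask checksum and parameters so maps
#' from different mask versions are never silently mixed.
#'
#' @param bold preprocessed 4D BOLD series.
#' @param mask symmetric binary mask defining the tissue compartment.
#' @param mirror_map optional precomputed [build_mirror_map()] for `mask`.
#' @param tissue tag, "WM" or "GM".
#' @param subject_id subject identifier carried into the map.
#' @return object of class `vmhc_map` with 3D `z` and `r` maps,
#'   `n_zero_variance`, `tissue`, `subject_id` and `provenance`.
#' @export
vmhc_subject <- function(bold, mask, mirror_map = NULL,
                         tissue = c("WM", "GM"), subject_id = NA_character_) {
  tissue <- match.arg(tissue)
  if (is.null(mirror_map)) mirror_map <- build_mirror_map(mask)
  r <- homotopic_correlation(bold, mirror_map)
  z <- fisher_z(r)
  structure(list(z = z, r = r,
                 n_zero_variance = attr(r, "n_zero_variance"),
                 tissue = tissue, subject_id = subject_id,
                 provenance = list(mask_md5 = object_md5(mask),
                                   n_pairs = mirror_map$n_pairs,
                                   n_timepoints = n_frames(bold))),
            class = "vmhc_map")
}

#' @export
print.vmhc_map <- function(x, ...) {
  cat("VMHC map (", x$tissue, ") subject ", x$subject_id, ": ",
      x$provenance$n_pairs, " pairs, mean z ",
      signif(mean(x$z[x$z != 0]), 4), "\n", sep = "")
  invisible(x)
}

# md5 of an R object's serialized bytes (used for provenance records).
# Arrays are reduced to content + dim so incidental metadata attributes do
# not perturb the hash.
object_md5 <- function(x) {
  if (is.array(x)) attributes(x) <- attributes(x)["dim"]
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}
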