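# Symmetric template / mask construction and the voxel mirror map. The mirror
# axis is the first voxel axis of the canonical midline-aligned grid; phantoms
# are generated already aligned, so no registration step is needed.

#' Mirror a volume across the left-right axis
#'
#' Flips a 3D volume along axis 1; an involution (`mirror(mirror(v)) == v`).
#'
#' @param vol 3D array.
#' @return flipped array of the same shape.
#' @export
mirror_volume <- function(vol) {
  if (length(dim(vol)) != 3L) stop("expected a 3D volume")
  vol[rev(seq_len(dim(vol)[1])), , , drop = FALSE]
}

#' Symmetrize a volume by flip-averaging
#'
#' `(vol + mirror(vol)) / 2`; the output is exactly invariant under
#' [mirror_volume()].
#'
#' @param vol 3D array.
#' @return mirror-symmetric array.
#' @export
symmetric_average <- function(vol) (vol + mirror_volume(vol)) / 2

#' Binary group symmetric tissue mask
#'
#' Averages the subjects' probability maps, flip-averages the group mean, and
#' binarizes at `>= threshold`. The conventional thresholds are 0.2 for gray
#' matter and 0.8 for white matter (strict, to limit partial-volume
#' contamination of WM by GM signal).
#'
#' @param prob_maps list of per-subject 3D probability maps (values in \[0,1\])
#'   on a common grid.
#' @param threshold binarization threshold in (0, 1).
#' @return logical 3D array, exactly mirror-symmetric.
#' @export
group_symmetric_mask <- function(prob_maps, threshold) {
  if (length(prob_maps) == 0L) stop("no probability maps supplied")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  d <- dim(prob_maps[[1]])
  mean_map <- Reduce(`+`, prob_maps) / length(prob_maps)
  if (any(mean_map < -1e-9 | mean_map > 1 + 1e-9))
    stop("probability maps must have values in [0, 1]")
  symmetric_average(mean_map) >= threshold
}

#' Remove a region from a mask, keeping symmetry
#'
#' Intersects the mask with the complement of the exclusion mask (e.g. a
#' user-supplied subcortical-nucleus mask), then re-symmetrizes by intersecting
#' the result with its own mirror, so an asymmetric exclusion still yields a
#' mirror-symmetric mask.
#'
#' @param mask logical 3D array.
#' @param exclusion_mask logical 3D array on the same grid.
#' @return logical mirror-symmetric 3D array.
#' @export
exclude_region <- function(mask, exclusion_mask) {
  if (!identical(dim(mask), dim(exclusion_mask))) stop("grids differ")
  m <- mask & !exclusion_mask
  m & mirror_volume(m)
}

#' Build the homotopic voxel pairing for a symmetric mask
#'
#' Pairs every in-mask voxel (i, j, k) with its counterpart
#' (Nx + 1 - i, j, k). The mask must be mirror-symmetric (offending voxels are
#' reported otherwise). On an odd first axis the midsagittal plane is excluded
#' from the pairing, since a voxel's correlation with itself is uninformative.
#'
#' @param mask logical 3D array, mirror-symmetric.
#' @return object of class `mirror_map` with linear index vectors `left` and
#'   `right` (one entry per pair), `dim`, and `n_pairs`.
#' @export
build_mirror_map <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stop("expected a 3D mask")
  flip <- mirror_volume(mask)
  bad <- which(mask != flip)
  if (length(bad)) {
    coords <- arrayInd(utils::head(bad, 10L), d)
    stop("mask is not mirror-symmetric; ", length(bad),
         " unmatched voxels, e.g. (",
         paste(apply(coords, 1, paste, collapse = ","), collapse = "), ("), ")")
  }
  nx <- d[1]
  half <- nx %/% 2L
  if (nx %% 2L == 1L && any(mask[half + 1L, , ]))
    message("odd left-right axis: ", sum(mask[half + 1L, , ]),
            " midsagittal voxels excluded from the mirror map")
  idx <- which(mask, arr.ind = TRUE)
  idx <- idx[idx[, 1] <= half, , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  right_idx <- idx
  right_idx[, 1] <- nx + 1L - right_idx[, 1]
  lin <- function(v) v[, 1] + (v[, 2] - 1L) * d[1] + (v[, 3] - 1L) * d[1] * d[2]
  structure(list(left = lin(idx), right = lin(right_idx), dim = d,
                 n_pairs = nrow(idx)),
            class = "mirror_map")
}

#' @export
print.mirror_map <- function(x, ...) {
  cat("Mirror map:", x$n_pairs, "homotopic voxel pairs on a",
      paste(x$dim, collapse = "x"), "grid\n")
  invisible(x)
}
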