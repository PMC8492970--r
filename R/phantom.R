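# Synthetic phantom cohorts with known ground truth: mirrored BOLD correlations,
# concentric tissue compartments, rigid-body motion traces, single-tensor DWI
# signals and a clinical covariate table. Everything is deterministic given the
# spec seed; per-subject streams are derived from (seed, subject id, stage).

#' Phantom specification
#'
#' Describes a synthetic cohort: voxel grid, acquisition timing, group sizes,
#' mirrored parcels with planted homotopic correlations, noise levels, motion
#' spikes and the diffusion gradient scheme. Defaults emulate the acquisition
#' this pipeline targets (164 time points at TR 2.2 s; 24 diffusion directions
#' at b = 1000 s/mm^2 plus one b = 0) on a midline-aligned 3 mm grid reduced to
#' desk scale.
#'
#' @param grid_shape integer(3), voxel counts per axis. The first (left-right)
#'   axis must be even so the mirror map has no self-paired midline voxels.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param n_timepoints number of BOLD volumes (>= 10).
#' @param tr_s repetition time in seconds.
#' @param groups named integer vector, subjects per group (e.g.
#'   `c(NC = 10, VMCI = 10, MCI = 10)`).
#' @param parcels list of mirrored parcel definitions; each element has `name`,
#'   `tissue` ("WM" or "GM"), `rho` (named per-group homotopic correlation in
#'   \[0,1\]) and `voxels` (n x 3 matrix of left-hemisphere voxel indices).
#'   Defaults are placed inside the phantom's WM shell and GM rind.
#' @param noise_sd additive independent Gaussian noise on each member of a
#'   mirrored pair, on top of the unit-variance shared signal. The population
#'   correlation of a pair with planted `rho` is then
#'   `rho / (1 + noise_sd^2)`; see [effective_rho()].
#' @param motion_spike_frames named list (by subject id) of frame indices that
#'   receive a sustained translation step exceeding 1 mm framewise displacement.
#' @param motion_amp_mm,motion_rot_amp amplitudes of the smooth background
#'   motion (mm / radians). Set to 0 for identically zero motion.
#' @param spike_mm translation step size (mm) used for motion spikes.
#' @param tissue_asymmetry sd of an optional asymmetric perturbation added to
#'   the tissue probability maps (exercises mask symmetrization); 0 = exactly
#'   mirror-symmetric maps.
#' @param dwi_scheme list with `bvals` (s/mm^2) and `bvecs` (unit rows); see
#'   [default_dwi_scheme()].
#' @param dwi_noise_sd sd of Gaussian noise added to DWI signals (signal units;
#'   phantom S0 is 100 inside the head).
#' @param seed integer master seed; a fixed seed yields bit-identical cohorts.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 28L, 24L),
                         voxel_size_mm = 3,
                         n_timepoints = 164L,
                         tr_s = 2.2,
                         groups = c(NC = 10L, VMCI = 10L, MCI = 10L),
                         parcels = default_parcels(grid_shape, names(groups)),
                         noise_sd = 0,
                         motion_spike_frames = list(),
                         motion_amp_mm = 0.05,
                         motion_rot_amp = 5e-4,
                         spike_mm = 2,
                         tissue_asymmetry = 0,
                         dwi_scheme = default_dwi_scheme(),
                         dwi_noise_sd = 1,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L))
  if (grid_shape[1] %% 2L != 0L)
    stop("grid_shape[1] (the left-right axis) must be even for an unambiguous midline")
  if (n_timepoints < 10L) stop("n_timepoints must be >= 10")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector")
  for (p in parcels) {
    if (!all(names(groups) %in% names(p$rho)))
      stop("parcel '", p$name, "' must define rho for every group")
    if (any(p$rho < 0 | p$rho > 1)) stop("parcel rho values must lie in [0, 1]")
    if (any(p$voxels[, 1] > grid_shape[1] %/% 2L))
      stop("parcel voxels must lie in the left hemisphere (i <= nx/2)")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
                 groups = groups, parcels = parcels, noise_sd = noise_sd,
                 motion_spike_frames = motion_spike_frames,
                 motion_amp_mm = motion_amp_mm, motion_rot_amp = motion_rot_amp,
                 spike_mm = spike_mm, tissue_asymmetry = tissue_asymmetry,
                 dwi_scheme = dwi_scheme, dwi_noise_sd = dwi_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Deterministic per-subject, per-stage RNG stream; stays below 2^31.
subject_seed <- function(seed, subject_id, salt = 0L) {
  u <- utf8ToInt(as.character(subject_id))
  h <- sum(u * seq_along(u)) %% 100000L
  (abs(as.integer(seed)) %% 100000L) * 20011L + h * 131L + as.integer(salt) * 7L
}

#' Diffusion gradient scheme
#'
#' One b = 0 volume plus `n_directions` unit gradients laid out on a Fibonacci
#' sphere (deterministic, pairwise non-collinear).
#'
#' @param n_directions number of diffusion-weighted directions.
#' @param b b-value in s/mm^2 for the weighted volumes.
#' @return list with `bvals` (length n+1) and `bvecs` ((n+1) x 3; zero row for b0).
#' @export
default_dwi_scheme <- function(n_directions = 24L, b = 1000) {
  i <- seq_len(n_directions)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i - 1) / n_directions
  rad <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (i - 1)
  dirs <- cbind(rad * cos(th), rad * sin(th), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(bvals = c(0, rep(b, n_directions)), bvecs = rbind(c(0, 0, 0), dirs))
}

# Normalized coordinates: u = 0 at the midplane of each axis, +-1 at the faces.
# With an even first axis, u_x is antisymmetric under i -> nx+1-i, so every
# construct built from |u| is exactly mirror-symmetric.
phantom_geometry <- function(grid_shape) {
  ax <- lapply(1:3, function(a) {
    n <- grid_shape[a]
    ((seq_len(n)) - 0.5 - n / 2) / (0.5 * n)
  })
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  list(u = ax, r = sqrt(r2))
}

# Compartment codes: 0 background, 1 CSF core, 2 WM shell, 3 GM rind.
phantom_compartments <- function(grid_shape) {
  r <- phantom_geometry(grid_shape)$r
  comp <- array(0L, dim = grid_shape)
  comp[r <= 0.30] <- 1L
  comp[r > 0.30 & r <= 0.62] <- 2L
  comp[r > 0.62 & r <= 0.95] <- 3L
  comp
}

#' Default mirrored parcels for a phantom grid
#'
#' One parcel in the deep white-matter shell and one in the gray-matter rind,
#' each selected geometrically (so they scale with the grid) and restricted to
#' the left hemisphere; the right-hemisphere counterpart is implied by the
#' mirror map. Planted per-group correlations decline NC > VMCI > MCI,
#' emulating the homotopic-connectivity ordering the pipeline is designed to
#' detect.
#'
#' @param grid_shape integer(3) voxel counts.
#' @param group_names character vector of group labels (defaults NC/VMCI/MCI).
#' @return list of parcel definitions (see [phantom_spec()]).
#' @export
default_parcels <- function(grid_shape, group_names = c("NC", "VMCI", "MCI")) {
  geo <- phantom_geometry(grid_shape)
  comp <- phantom_compartments(grid_shape)
  u <- geo$u
  ii <- slice.index(comp, 1); jj <- slice.index(comp, 2); kk <- slice.index(comp, 3)
  ux <- u[[1]][ii]; uy <- u[[2]][jj]; uz <- u[[3]][kk]
  pick <- function(sel) {
    w <- which(sel & ux < 0, arr.ind = TRUE)
    w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
  }
  rho_of <- function(levels) {
    stats::setNames(levels[seq_along(group_names)], group_names)
  }
  wm_vox <- pick(comp == 2L & abs(ux) > 0.35 & abs(ux) < 0.55 &
                   abs(uy) <= 0.2 & abs(uz) <= 0.2)
  gm_vox <- pick(comp == 3L & abs(ux) > 0.70 & abs(ux) < 0.85 &
                   abs(uy) <= 0.25 & abs(uz) <= 0.25)
  parcels <- list()
  if (nrow(wm_vox) > 0)
    parcels <- c(parcels, list(list(name = "wm_central", tissue = "WM",
                                    rho = rho_of(c(0.8, 0.6, 0.4, 0.3, 0.2)),
                                    voxels = wm_vox)))
  if (nrow(gm_vox) > 0)
    parcels <- c(parcels, list(list(name = "gm_lateral", tissue = "GM",
                                    rho = rho_of(c(0.75, 0.55, 0.35, 0.25, 0.15)),
                                    voxels = gm_vox)))
  parcels
}

#' Effective population correlation of a planted mirrored pair
#'
#' The generator uses a shared-latent construction: with unit-variance shared
#' signal s and independent unit-variance noises e1, e2, e3,
#' `x = s + noise_sd * e1` and `y = rho * s + sqrt(1 - rho^2) * e2 +
#' noise_sd * e3`. Both members have variance `1 + noise_sd^2` and covariance
#' `rho`, so the population correlation is `rho / (1 + noise_sd^2)`.
#'
#' @param rho planted correlation of the noiseless pair.
#' @param noise_sd additive noise sd (see [phantom_spec()]).
#' @return effective population correlation after noise attenuation.
#' @export
effective_rho <- function(rho, noise_sd = 0) rho / (1 + noise_sd^2)

linear_index <- function(vox, d) {
  vox[, 1] + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2]
}

#' Generate a subject's 4D BOLD series
#'
#' Voxels outside the planted parcels are independent unit-variance Gaussian
#' noise. Each mirrored parcel voxel pair shares a latent signal so that its
#' population correlation equals [effective_rho()] of the parcel's per-group
#' rho. Attributes `tr_s` and `voxel_size_mm` carry acquisition metadata.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id character id (drives the per-subject RNG stream).
#' @param group group label; must be present in `spec$groups`.
#' @return 4D array (x, y, z, t) of class `bold_series`.
#' @export
generate_bold <- function(spec, subject_id, group) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!group %in% names(spec$groups)) stop("unknown group: ", group)
  set.seed(subject_seed(spec$seed, subject_id, salt = 1L))
  d <- spec$grid_shape
  t_len <- spec$n_timepoints
  nvox <- prod(d)
  m <- matrix(stats::rnorm(nvox * t_len), nrow = nvox, ncol = t_len)
  for (p in spec$parcels) {
    rho <- unname(p$rho[[group]])
    left <- linear_index(p$voxels, d)
    right_vox <- p$voxels
    right_vox[, 1] <- d[1] + 1L - right_vox[, 1]
    right <- linear_index(right_vox, d)
    np <- length(left)
    s <- matrix(stats::rnorm(np * t_len), nrow = np)
    e2 <- matrix(stats::rnorm(np * t_len), nrow = np)
    x <- s
    y <- rho * s + sqrt(1 - rho^2) * e2
    if (spec$noise_sd > 0) {
      x <- x + spec$noise_sd * matrix(stats::rnorm(np * t_len), nrow = np)
      y <- y + spec$noise_sd * matrix(stats::rnorm(np * t_len), nrow = np)
    }
    m[left, ] <- x
    m[right, ] <- y
  }
  out <- array(m, dim = c(d, t_len))
  attr(out, "tr_s") <- spec$tr_s
  attr(out, "voxel_size_mm") <- spec$voxel_size_mm
  attr(out, "subject_id") <- subject_id
  attr(out, "group") <- group
  class(out) <- c("bold_series", class(out))
  out
}

#' Generate a subject's rigid-body motion trace
#'
#' Smooth low-amplitude sinusoidal drift plus small jitter on the six
#' rigid-body parameters (3 translations in mm, 3 rotations in rad). Frames
#' listed in `spec$motion_spike_frames[[subject_id]]` receive a sustained
#' `spec$spike_mm` translation step on x, so Power framewise displacement at
#' that frame exceeds 1 mm.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id character id.
#' @return T x 6 matrix (columns tx, ty, tz, rx, ry, rz).
#' @export
generate_motion <- function(spec, subject_id) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(subject_seed(spec$seed, subject_id, salt = 2L))
  t_len <- spec$n_timepoints
  tt <- seq_len(t_len) * spec$tr_s
  one <- function(amp) {
    if (amp == 0) return(numeric(t_len))
    f <- stats::runif(1, 0.005, 0.02)
    ph <- stats::runif(1, 0, 2 * pi)
    amp * sin(2 * pi * f * tt + ph) + stats::rnorm(t_len, sd = amp / 10)
  }
  m <- cbind(one(spec$motion_amp_mm), one(spec$motion_amp_mm), one(spec$motion_amp_mm),
             one(spec$motion_rot_amp), one(spec$motion_rot_amp), one(spec$motion_rot_amp))
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  spikes <- spec$motion_spike_frames[[subject_id]]
  for (f in spikes) {
    if (f < 1L || f > t_len) stop("spike frame ", f, " out of range 1..", t_len)
    m[f:t_len, 1] <- m[f:t_len, 1] + spec$spike_mm
  }
  m
}

#' Generate a subject's tissue probability maps
#'
#' Concentric compartments (CSF core, WM shell, GM rind) on the phantom grid,
#' exactly mirror-symmetric; the compartment a voxel belongs to gets
#' probability 0.92 and the other two tissues 0.04 each (background 0). With
#' `spec$tissue_asymmetry > 0` an independent Gaussian perturbation (clipped to
#' \[0,1\]) breaks the symmetry mildly, to exercise mask symmetrization.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id character id (only used when maps are perturbed).
#' @return list with 3D arrays `gm`, `wm`, `csf`.
#' @export
generate_tissue <- function(spec, subject_id = "template") {
  comp <- phantom_compartments(spec$grid_shape)
  prob <- function(code) {
    p <- array(0, dim = spec$grid_shape)
    p[comp != 0L] <- 0.04
    p[comp == code] <- 0.92
    p
  }
  maps <- list(gm = prob(3L), wm = prob(2L), csf = prob(1L))
  if (spec$tissue_asymmetry > 0) {
    set.seed(subject_seed(spec$seed, subject_id, salt = 3L))
    maps <- lapply(maps, function(p) {
      pmin(pmax(p + array(stats::rnorm(length(p), sd = spec$tissue_asymmetry),
                          dim = dim(p)), 0), 1)
    })
  }
  maps
}

#' Ground-truth diffusion tensor field for a phantom subject
#'
#' Single tensors per voxel (mm^2/s): prolate WM tensor (1.7, 0.3, 0.3)e-3
#' aligned with x, isotropic GM 0.8e-3 and free-water CSF 3.0e-3; S0 = 100
#' inside the head and 0 in the background. For the group named by
#' `affected_group` the WM parcel carries an altered tensor
#' (2.6, 0.35, 0.35)e-3 — higher MD (1.1e-3 vs 0.767e-3) and FA (0.850 vs
#' 0.799) — providing a planted anatomical effect for the ROI comparisons.
#'
#' @param spec a [phantom_spec()].
#' @param group group label of the subject.
#' @param affected_group group whose WM-parcel tensors are altered
#'   (default "MCI"; set to NA for no planted effect).
#' @return list of class `tensor_field`: `D` (nvox x 6 matrix, columns
#'   xx, yy, zz, xy, xz, yz), `S0` (nvox vector), `dim`.
#' @export
make_tensor_field <- function(spec, group, affected_group = "MCI") {
  comp <- phantom_compartments(spec$grid_shape)
  nvox <- length(comp)
  D <- matrix(0, nrow = nvox, ncol = 6,
              dimnames = list(NULL, c("xx", "yy", "zz", "xy", "xz", "yz")))
  S0 <- numeric(nvox)
  head_vox <- comp != 0L
  S0[head_vox] <- 100
  D[comp == 1L, c("xx", "yy", "zz")] <- 3.0e-3
  D[comp == 3L, c("xx", "yy", "zz")] <- 0.8e-3
  wm <- comp == 2L
  D[wm, "xx"] <- 1.7e-3
  D[wm, c("yy", "zz")] <- 0.3e-3
  if (!is.na(affected_group) && identical(group, affected_group)) {
    for (p in spec$parcels) {
      if (!identical(p$tissue, "WM")) next
      left <- linear_index(p$voxels, spec$grid_shape)
      right_vox <- p$voxels
      right_vox[, 1] <- spec$grid_shape[1] + 1L - right_vox[, 1]
      idx <- c(left, linear_index(right_vox, spec$grid_shape))
      D[idx, "xx"] <- 2.6e-3
      D[idx, c("yy", "zz")] <- 0.35e-3
    }
  }
  structure(list(D = D, S0 = S0, dim = spec$grid_shape), class = "tensor_field")
}

#' Generate diffusion-weighted volumes from a tensor field
#'
#' Single-tensor signal model: `S(b, g) = S0 * exp(-b * g' D g)`, one volume
#' per (b, g) in the scheme; optional additive Gaussian noise.
#'
#' @param spec a [phantom_spec()] (supplies the scheme and grid).
#' @param tensor_field a `tensor_field` (see [make_tensor_field()]).
#' @param noise_sd Gaussian noise sd in signal units (0 = noiseless).
#' @param subject_id id used to derive the noise RNG stream.
#' @return list of class `dwi_series` with `data` (4D array, volumes last),
#'   `bvals`, `bvecs`.
#' @export
generate_dwi <- function(spec, tensor_field, noise_sd = 0, subject_id = "dwi") {
  stopifnot(inherits(spec, "phantom_spec"), inherits(tensor_field, "tensor_field"))
  bvals <- spec$dwi_scheme$bvals
  bvecs <- spec$dwi_scheme$bvecs
  if (any(bvals < 0)) stop("negative b-value")
  nb <- sqrt(rowSums(bvecs^2))
  if (any(bvals > 0 & abs(nb - 1) > 1e-6)) stop("gradient directions must be unit norm")
  d <- tensor_field$dim
  nvox <- prod(d)
  nvol <- length(bvals)
  D <- tensor_field$D
  S <- matrix(0, nrow = nvox, ncol = nvol)
  for (v in seq_len(nvol)) {
    g <- bvecs[v, ]
    quad <- D[, "xx"] * g[1]^2 + D[, "yy"] * g[2]^2 + D[, "zz"] * g[3]^2 +
      2 * (D[, "xy"] * g[1] * g[2] + D[, "xz"] * g[1] * g[3] + D[, "yz"] * g[2] * g[3])
    S[, v] <- tensor_field$S0 * exp(-bvals[v] * quad)
  }
  if (noise_sd > 0) {
    set.seed(subject_seed(spec$seed, subject_id, salt = 4L))
    S <- S + matrix(stats::rnorm(length(S), sd = noise_sd), nrow = nvox)
  }
  structure(list(data = array(S, dim = c(d, nvol)), bvals = bvals, bvecs = bvecs),
            class = "dwi_series")
}

# Covariate distributions used by generate_cohort: per-group mean/sd of age,
# education and MMSE, and the male fraction. MMSE means decline NC > VMCI > MCI.
cohort_norms <- list(
  NC   = list(age = c(74.41, 8.227), edu = c(14.32, 1.757), mmse = c(28.86, 1.318), male = 50 / 100),
  VMCI = list(age = c(74.76, 7.668), edu = c(14.59, 3.016), mmse = c(25.99, 2.882), male = 48 / 90),
  MCI  = list(age = c(75.89, 8.554), edu = c(14.75, 3.204), mmse = c(22.08, 4.057), male = 33 / 53)
)

#' Generate a full synthetic cohort
#'
#' Builds the subject table (id, group, age, sex, education, MMSE) and, when
#' `materialize = TRUE`, every subject's BOLD series, motion trace, tissue maps
#' and (optionally) DWI volumes. Data generation is per-subject deterministic,
#' so a non-materialized cohort can be re-materialized subject by subject with
#' [generate_bold()] etc. and yields identical arrays.
#'
#' @param spec a [phantom_spec()].
#' @param materialize generate and store per-subject arrays (memory-heavy for
#'   large cohorts); if FALSE only covariates and ground truth are returned.
#' @param with_dwi also generate diffusion data per subject.
#' @return list of class `phantom_cohort`: `spec`, `subjects` (data.frame),
#'   `ground_truth` (parcels with per-group rho, spike frames, labels), and
#'   `data` (named per-subject lists) when materialized.
#' @export
generate_cohort <- function(spec, materialize = TRUE, with_dwi = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$groups <= 0L)) stop("every requested group needs at least one subject")
  ids <- unlist(lapply(names(spec$groups), function(g)
    sprintf("%s%02d", g, seq_len(spec$groups[[g]]))))
  grp <- rep(names(spec$groups), times = spec$groups)
  set.seed(subject_seed(spec$seed, "covariates", salt = 5L))
  draw <- function(g, what) {
    nm <- if (g %in% names(cohort_norms)) cohort_norms[[g]] else cohort_norms[["NC"]]
    stats::rnorm(1, nm[[what]][1], nm[[what]][2])
  }
  age <- round(vapply(grp, draw, numeric(1), what = "age"), 1)
  edu <- pmax(6, round(vapply(grp, draw, numeric(1), what = "edu")))
  mmse <- pmin(30, pmax(0, round(vapply(grp, draw, numeric(1), what = "mmse"))))
  male_p <- vapply(grp, function(g)
    if (g %in% names(cohort_norms)) cohort_norms[[g]]$male else 0.5, numeric(1))
  sex <- ifelse(stats::runif(length(grp)) < male_p, "M", "F")
  subjects <- data.frame(id = ids, group = grp, age = age, sex = sex,
                         education = edu, mmse = mmse, stringsAsFactors = FALSE)
  gt <- list(parcels = spec$parcels,
             labels = stats::setNames(grp, ids),
             spike_frames = spec$motion_spike_frames,
             noise_sd = spec$noise_sd)
  out <- list(spec = spec, subjects = subjects, ground_truth = gt)
  if (materialize) {
    out$data <- stats::setNames(lapply(seq_along(ids), function(s) {
      el <- list(bold = generate_bold(spec, ids[s], grp[s]),
                 motion = generate_motion(spec, ids[s]),
                 tissue = generate_tissue(spec, ids[s]))
      if (with_dwi) {
        tf <- make_tensor_field(spec, grp[s])
        el$dwi <- generate_dwi(spec, tf, noise_sd = spec$dwi_noise_sd,
                               subject_id = ids[s])
        el$tensor_truth <- tf
      }
      el
    }), ids)
  }
  class(out) <- "phantom_cohort"
  out
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("Phantom cohort:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(x$spec$groups), x$spec$groups), collapse = ", "),
      ")\n")
  cat("  grid", paste(x$spec$grid_shape, collapse = "x"),
      "at", x$spec$voxel_size_mm, "mm,", x$spec$n_timepoints,
      "time points, TR", x$spec$tr_s, "s\n")
  cat("  parcels:", paste(vapply(x$spec$parcels, `[[`, "", "name"), collapse = ", "), "\n")
  invisible(x)
}
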