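#' Rigid (rotation + translation) spatial transform
#'
#' Maps a point `p` (um, world coordinates) to
#' `R (p - center) + center + translation`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation_um Numeric 3-vector (um).
#' @param center_um Rotation centre (um).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation_um = c(0, 0, 0),
                            center_um = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation,
                 translation_um = as.numeric(translation_um),
                 center_um = as.numeric(center_um)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) um\n",
              ang, x$translation_um[1], x$translation_um[2], x$translation_um[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param t A [rigid_transform()].
#' @param pts n x 3 matrix of points (um).
#' @return n x 3 matrix of transformed points (um).
#' @export
transform_points <- function(t, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(pts, 2, t$center_um) %*% t(t$rotation) +
    matrix(t$center_um + t$translation_um, nrow(pts), 3, byrow = TRUE)
}

#' Compose two rigid transforms (`a` after `b`)
#'
#' @param a,b [rigid_transform()] objects; the result maps `p` to `a(b(p))`.
#' @return A [rigid_transform()] with centre at the origin.
#' @export
compose_rigid <- function(a, b) {
  # fold centres into the translations: t(p) = R p + d
  da <- a$center_um + a$translation_um - a$rotation %*% a$center_um
  db <- b$center_um + b$translation_um - b$rotation %*% b$center_um
  R <- a$rotation %*% b$rotation
  d <- a$rotation %*% db + da
  rigid_transform(R, as.numeric(d), c(0, 0, 0))
}

#' Invert a rigid transform
#'
#' @param t A [rigid_transform()].
#' @return The inverse [rigid_transform()] (centre at the origin).
#' @export
invert_rigid <- function(t) {
  d <- t$center_um + t$translation_um - t$rotation %*% t$center_um
  Rt <- t(t$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% d), c(0, 0, 0))
}

#' Rotation matrix from extrinsic XYZ Euler angles (degrees)
#'
#' @param angles_deg Numeric 3-vector: rotations about x, y, z in degrees,
#'   applied in that order (`Rz %*% Ry %*% Rx`).
#' @return 3x3 rotation matrix.
#' @export
euler_rotation <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

mask_centroid_um <- function(mask) {
  w <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("mask is empty")
  mask$origin_um + (colMeans(w) - 1) * mask$voxel_size_um
}

#' Centre-of-mass rigid pre-alignment
#'
#' Identity rotation; the translation moves the centroid of the moving mask
#' onto the centroid of the fixed mask.
#'
#' @param moving,fixed Non-empty [binary_mask()] objects.
#' @return A [rigid_transform()] centred at the moving centroid.
#' @export
align_centers_of_mass <- function(moving, fixed) {
  cm <- mask_centroid_um(moving)
  cf <- mask_centroid_um(fixed)
  rigid_transform(diag(3), cf - cm, cm)
}

#' Describe the sampling lattice of a volume
#'
#' @param img A [volume_image()] or [binary_mask()].
#' @return List with `dims`, `origin_um`, `voxel_size_um`.
#' @export
lattice_of <- function(img) {
  d <- if (inherits(img, "binary_mask")) dim(img$voxels) else dim(img$intensities)
  list(dims = d, origin_um = img$origin_um, voxel_size_um = img$voxel_size_um)
}

# Affine (A, b) sending target voxel indices to source voxel coordinates
# under the pull-back of `t` (target world -> source world via inverse of t).
pullback_affine <- function(t, src_lattice, dst_lattice) {
  Rt <- t(t$rotation)
  d <- t$center_um + t$translation_um - t$rotation %*% t$center_um
  A <- Rt * dst_lattice$voxel_size_um / src_lattice$voxel_size_um
  b <- (Rt %*% (dst_lattice$origin_um - d) - src_lattice$origin_um) /
    src_lattice$voxel_size_um
  list(A = A, b = as.numeric(b))
}

#' Resample a volume onto a target lattice with a Lanczos-3 kernel
#'
#' Pull-back resampling: each target voxel centre is mapped through the
#' inverse of `transform` into the source volume and interpolated with a
#' separable Lanczos kernel (window a = 3). Samples outside the source extent
#' fade to 0 (background) and interpolation undershoot is clamped at 0.
#'
#' @param img Source [volume_image()].
#' @param transform A [rigid_transform()] mapping source world coordinates to
#'   target world coordinates; `NULL` for identity.
#' @param target Target lattice, as returned by [lattice_of()], or a
#'   [bounding_box()] interpreted on the source lattice.
#' @return A [volume_image()] on the target lattice.
#' @export
resample_lanczos <- function(img, transform = NULL, target = lattice_of(img)) {
  if (is.null(transform)) transform <- rigid_transform()
  if (inherits(target, "bounding_box")) {
    target <- list(dims = target$hi_voxel - target$lo_voxel,
                   origin_um = img$origin_um + target$lo_voxel * img$voxel_size_um,
                   voxel_size_um = img$voxel_size_um)
  }
  ab <- pullback_affine(transform, lattice_of(img), target)
  out <- cpp_resample_affine_lanczos(img$intensities, dim(img$intensities),
                                     as.integer(target$dims), ab$A, ab$b)
  volume_image(array(out, target$dims), target$voxel_size_um,
               origin_um = target$origin_um, stage_label = img$stage_label,
               specimen_id = img$specimen_id)
}

#' Apply a rigid transform to a volume, resampling onto a target lattice
#'
#' Establishes the common lattice shared by all specimens of one anatomical
#' site: every moving image is mapped with its own rigid transform and
#' resampled (Lanczos-3) onto the same target.
#'
#' @inheritParams resample_lanczos
#' @param t A [rigid_transform()].
#' @return A [volume_image()] on the target lattice.
#' @export
apply_rigid <- function(img, t, target) resample_lanczos(img, t, target)

#' Normalised mutual information of a rigidly mapped image pair
#'
#' Studholme NMI, `(H(fixed) + H(moving)) / H(joint)`, computed from a
#' `bins` x `bins` joint histogram over the fixed-image foreground.
#'
#' @param moving,fixed [volume_image()] objects.
#' @param t A [rigid_transform()] mapping moving world to fixed world.
#' @param fixed_mask Optional [binary_mask()] selecting the fixed-image
#'   foreground; default: every voxel strictly above the fixed minimum.
#' @param bins Histogram bins per image (default 32).
#' @return List with `nmi` and `overlap` (fraction of foreground voxels that
#'   land inside the moving extent).
#' @export
nmi_rigid <- function(moving, fixed, t = rigid_transform(), fixed_mask = NULL,
                      bins = 32L) {
  fg <- if (is.null(fixed_mask)) fixed$intensities > min(fixed$intensities)
        else fixed_mask$voxels
  idx <- which(fg, arr.ind = TRUE) - 1
  if (nrow(idx) == 0L) stop("fixed foreground is empty")
  vals <- fixed$intensities[fg]
  ab <- pullback_affine(t, lattice_of(moving), lattice_of(fixed))
  r <- cpp_nmi_rigid(moving$intensities, dim(moving$intensities), vals,
                     idx * 1.0, ab$A, ab$b, as.integer(bins),
                     min(fixed$intensities), max(fixed$intensities),
                     min(moving$intensities), max(moving$intensities))
  list(nmi = r[1], overlap = r[2])
}

#' Automatic orientation refinement by mutual-information search
#'
#' Replaces the interactive orientation adjustment of the original protocol
#' with a deterministic derivative-free local search: coordinate descent over
#' three Euler angles and three translations, maximising NMI
#' ([nmi_rigid()]), started at `init`.
#'
#' @param moving,fixed [volume_image()] objects.
#' @param init Initial [rigid_transform()] (e.g. from
#'   [align_centers_of_mass()]).
#' @param fixed_mask Optional foreground mask for the NMI histogram.
#' @param bins Histogram bins (default 32).
#' @param max_sweeps Maximum number of coordinate-descent sweeps.
#' @param angle_bound_deg,trans_bound_voxels Search bounds around `init`.
#' @param angle_step_deg,trans_step_voxels Initial step sizes.
#' @return A [rigid_transform()] with attributes `nmi` (final objective) and
#'   `converged` (FALSE if the sweep budget was exhausted).
#' @export
refine_orientation <- function(moving, fixed, init, fixed_mask = NULL,
                               bins = 32L, max_sweeps = 60L,
                               angle_bound_deg = 30, trans_bound_voxels = 20,
                               angle_step_deg = 4, trans_step_voxels = 2) {
  vs <- fixed$voxel_size_um
  tb_um <- trans_bound_voxels * vs
  # perturbations rotate about the moving image's centre (a rotation about
  # a distant point is mostly a translation and defeats the angle search)
  ctr <- moving$origin_um + (dim(moving$intensities) - 1) / 2 *
    moving$voxel_size_um
  make_t <- function(p) {
    # p = (rx, ry, rz deg, tx, ty, tz um) composed on top of init
    pert <- rigid_transform(euler_rotation(p[1:3]), p[4:6], ctr)
    compose_rigid(pert, init)
  }
  obj <- function(p) nmi_rigid(moving, fixed, make_t(p), fixed_mask, bins)
  p <- rep(0, 6)
  r0 <- obj(p)
  if (r0$overlap <= 0)
    stop("images do not overlap after the initial transform")
  best <- r0$nmi
  steps <- c(rep(angle_step_deg, 3), rep(trans_step_voxels * vs, 3))
  min_steps <- c(rep(0.05, 3), rep(0.05 * vs, 3))
  lo <- c(rep(-angle_bound_deg, 3), rep(-tb_um, 3))
  hi <- -lo
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (d in 1:6) {                      # fixed evaluation order
      for (sgn in c(1, -1)) {
        cand <- p
        cand[d] <- min(max(cand[d] + sgn * steps[d], lo[d]), hi[d])
        if (cand[d] == p[d]) next
        v <- obj(cand)$nmi
        if (v > best + 1e-12) {
          best <- v; p <- cand; improved <- TRUE
          break
        }
      }
    }
    if (!improved) {
      if (all(steps <= min_steps)) { converged <- TRUE; break }
      steps <- pmax(steps / 2, min_steps)
    }
  }
  if (!converged)
    warning("orientation refinement: sweep budget exhausted, returning best so far")
  out <- make_t(p)
  attr(out, "nmi") <- best
  attr(out, "converged") <- converged
  out
}

#' Serialize a rigid transform to a 12-number JSON record
#'
#' Row-major rotation (9 numbers) followed by the effective translation in um
#' (rotation centre folded in, so the record alone reproduces the mapping).
#'
#' @param t A [rigid_transform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rigid <- function(t, path) {
  d <- t$center_um + t$translation_um - t$rotation %*% t$center_um
  rec <- list(rotation = as.numeric(t(t$rotation)), translation_um = as.numeric(d))
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a rigid transform written by [write_rigid()]
#'
#' @param path JSON path.
#' @return A [rigid_transform()] with centre at the origin.
#' @export
read_rigid <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(rec$rotation, 3, 3, byrow = TRUE), rec$translation_um)
}
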