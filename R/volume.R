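#' Construct a 3D scalar volume
#'
#' A `volume_image` is the package's basic container for a reconstructed
#' optical projection tomography (OPT) stack or any other 3D grayscale image
#' with isotropic voxels.
#'
#' @param intensities 3D numeric array (dims = x, y, z); must be finite.
#' @param voxel_size_um Positive scalar, isotropic voxel size in micrometres.
#'   The protocol's reference data use 14.63 um.
#' @param origin_um Numeric 3-vector, position of the first voxel centre (um).
#' @param stage_label One of `"TS23"`, `"TS24"`, `"other"` (Theiler stage).
#' @param specimen_id Character scalar identifying the specimen.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(intensities, voxel_size_um,
                         origin_um = c(0, 0, 0),
                         stage_label = c("other", "TS23", "TS24"),
                         specimen_id = "unnamed") {
  stage_label <- match.arg(stage_label)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (any(dim(intensities) < 2L))
    stop("all three dimensions must be >= 2")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a positive scalar")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("intensities must be finite (no NA/NaN/Inf)")
  storage.mode(intensities) <- "double"
  structure(list(
    intensities = intensities,
    voxel_size_um = as.numeric(voxel_size_um),
    origin_um = as.numeric(origin_um),
    stage_label = stage_label,
    specimen_id = as.character(specimen_id)
  ), class = "volume_image")
}

#' Construct a binary mask
#'
#' @param voxels 3D logical array on the same lattice as its source volume.
#' @param voxel_size_um Positive scalar, voxel size (um).
#' @param origin_um Numeric 3-vector (um).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, voxel_size_um, origin_um = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1))) stop("voxels must be logical or 0/1")
    voxels <- array(voxels != 0, dim(voxels))
  }
  if (anyNA(voxels)) stop("mask may not contain NA")
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a positive scalar")
  structure(list(
    voxels = voxels,
    voxel_size_um = as.numeric(voxel_size_um),
    origin_um = as.numeric(origin_um)
  ), class = "binary_mask")
}

#' Construct a half-open bounding box in voxel indices
#'
#' @param lo_voxel Integer 3-vector, inclusive 0-based lower corner.
#' @param hi_voxel Integer 3-vector, exclusive upper corner.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(lo_voxel, hi_voxel) {
  lo_voxel <- as.integer(lo_voxel); hi_voxel <- as.integer(hi_voxel)
  if (length(lo_voxel) != 3L || length(hi_voxel) != 3L)
    stop("lo_voxel and hi_voxel must be 3-vectors")
  if (any(lo_voxel < 0L)) stop("lo_voxel must be >= 0")
  if (any(lo_voxel >= hi_voxel)) stop("lo_voxel must be < hi_voxel on every axis")
  structure(list(lo_voxel = lo_voxel, hi_voxel = hi_voxel),
            class = "bounding_box")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume_image> %dx%dx%d voxels @ %.4g um, stage %s, specimen '%s'\n",
              d[1], d[2], d[3], x$voxel_size_um, x$stage_label, x$specimen_id))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%.4g, %.4g, %.4g) um\n",
              min(x$intensities), max(x$intensities),
              x$origin_um[1], x$origin_um[2], x$origin_um[3]))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %dx%dx%d voxels @ %.4g um, %d foreground\n",
              d[1], d[2], d[3], x$voxel_size_um, sum(x$voxels)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$intensities)

#' @export
dim.binary_mask <- function(x) dim(x$voxels)

check_box_within <- function(box, dims) {
  if (any(box$hi_voxel > dims))
    stop(sprintf("bounding box [%s)-[%s) exceeds image extent %s",
                 paste(box$lo_voxel, collapse = ","),
                 paste(box$hi_voxel, collapse = ","),
                 paste(dims, collapse = "x")))
  invisible(TRUE)
}

#' Crop a volume or mask to a bounding box
#'
#' Returns the sub-volume copy; the origin is shifted by
#' `lo_voxel * voxel_size_um` so world coordinates are preserved.
#'
#' @param x A `volume_image` or `binary_mask`.
#' @param box A [bounding_box()] lying within the extent of `x`.
#' @param ... Unused.
#' @return Object of the same class as `x`.
#' @export
crop <- function(x, box, ...) UseMethod("crop")

#' @rdname crop
#' @export
crop.volume_image <- function(x, box, ...) {
  check_box_within(box, dim(x$intensities))
  idx <- lapply(1:3, function(a) seq.int(box$lo_voxel[a] + 1L, box$hi_voxel[a]))
  volume_image(x$intensities[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               x$voxel_size_um,
               origin_um = x$origin_um + box$lo_voxel * x$voxel_size_um,
               stage_label = x$stage_label, specimen_id = x$specimen_id)
}

#' @rdname crop
#' @export
crop.binary_mask <- function(x, box, ...) {
  check_box_within(box, dim(x$voxels))
  idx <- lapply(1:3, function(a) seq.int(box$lo_voxel[a] + 1L, box$hi_voxel[a]))
  binary_mask(x$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
              x$voxel_size_um,
              origin_um = x$origin_um + box$lo_voxel * x$voxel_size_um)
}

#' Tight bounding box of a mask, with optional margin
#'
#' @param mask A `binary_mask` with at least one foreground voxel.
#' @param margin_voxels Non-negative integer margin added on every side
#'   (clipped at the image extent).
#' @return A [bounding_box()].
#' @export
mask_bounding_box <- function(mask, margin_voxels = 0L) {
  w <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("mask is empty")
  lo <- pmax(apply(w, 2, min) - 1L - margin_voxels, 0L)
  hi <- pmin(apply(w, 2, max) + margin_voxels, dim(mask$voxels))
  bounding_box(lo, hi)
}
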