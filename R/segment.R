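#' Single-level threshold segmentation with largest-component retention
#'
#' Marks every voxel with intensity greater than or equal to `level` as
#' foreground and keeps only the largest connected component, a deterministic
#' surrogate for the interactive clean-up of a manual segmentation.
#'
#' @param img A [volume_image()].
#' @param level Threshold on the image's own gray-value scale; must lie within
#'   the intensity range of `img`.
#' @param connectivity 6 (face-adjacent, default) or 26 for the component
#'   labelling.
#' @return A [binary_mask()].
#' @export
threshold_segment <- function(img, level, connectivity = 6L) {
  rng <- range(img$intensities)
  if (level < rng[1] || level > rng[2])
    stop(sprintf("threshold level %g outside intensity range [%g, %g]",
                 level, rng[1], rng[2]))
  raw <- img$intensities >= level
  if (!any(raw)) stop("no foreground at this level")
  keep <- cpp_largest_component(raw, dim(img$intensities), as.integer(connectivity))
  binary_mask(array(keep, dim(img$intensities)), img$voxel_size_um, img$origin_um)
}

#' Morphological erosion of a binary mask
#'
#' Applies a 1-voxel erosion `radius_voxels` times. The structuring element is
#' 6-connected (face-adjacent) by default; voxels outside the image are
#' treated as background, so the mask also erodes at the image faces.
#'
#' @param mask A [binary_mask()].
#' @param radius_voxels Integer >= 1, number of erosion passes.
#' @param connectivity 6 (default) or 26.
#' @return The eroded [binary_mask()].
#' @export
erode_mask <- function(mask, radius_voxels = 1L, connectivity = 6L) {
  radius_voxels <- as.integer(radius_voxels)
  if (radius_voxels < 1L) stop("radius_voxels must be >= 1")
  out <- cpp_erode(mask$voxels, dim(mask$voxels), radius_voxels,
                   as.integer(connectivity))
  binary_mask(array(out, dim(mask$voxels)), mask$voxel_size_um, mask$origin_um)
}

#' Apply a mask to a volume (background set to zero)
#'
#' @param img A [volume_image()].
#' @param mask A [binary_mask()] on the same lattice.
#' @return A [volume_image()] equal to `img` inside the mask, 0 outside.
#' @export
mask_volume <- function(img, mask) {
  if (!identical(dim(img$intensities), dim(mask$voxels)))
    stop("image and mask lattices differ")
  volume_image(img$intensities * ifelse(mask$voxels, 1, 0), img$voxel_size_um,
               origin_um = img$origin_um, stage_label = img$stage_label,
               specimen_id = img$specimen_id)
}

#' Morphological dilation of a binary mask
#'
#' Dual of [erode_mask()]: dilation by the same structuring element.
#'
#' @inheritParams erode_mask
#' @return The dilated [binary_mask()].
#' @export
dilate_mask <- function(mask, radius_voxels = 1L, connectivity = 6L) {
  inv <- cpp_erode(!mask$voxels, dim(mask$voxels), as.integer(radius_voxels),
                   as.integer(connectivity))
  binary_mask(array(!inv, dim(mask$voxels)), mask$voxel_size_um, mask$origin_um)
}

#' Registration domain from stage masks
#'
#' The deformable solver is driven only by voxels inside the registration
#' domain: the union of the early- and late-stage masks, dilated a few
#' voxels, mirroring the protocol where the late-stage binary image is an
#' input of the registration. Restricting the domain keeps the empty
#' background (pure noise) from influencing the field.
#'
#' @param early_mask A [binary_mask()].
#' @param late_mask Optional [binary_mask()] on the same lattice.
#' @param dilate_voxels Dilation radius (default 3).
#' @return A [binary_mask()].
#' @export
registration_domain <- function(early_mask, late_mask = NULL,
                                dilate_voxels = 3L) {
  vox <- early_mask$voxels
  if (!is.null(late_mask)) {
    if (!identical(dim(late_mask$voxels), dim(vox)))
      stop("masks live on different lattices")
    vox <- vox | late_mask$voxels
  }
  dilate_mask(binary_mask(vox, early_mask$voxel_size_um,
                          early_mask$origin_um), dilate_voxels)
}
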