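# Volume file I/O: MetaImage (.mhd + .raw) and NIfTI-1 (.nii / .nii.gz).
# Both are simple fixed layouts, written and read with readBin/writeBin; no
# imaging I/O package for R is assumed. Data are always little-endian.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L),
  `512`= list(what = "integer", size = 2L, signed = FALSE, bitpix = 16L)
)

met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

is_isotropic <- function(sp, tol = 1e-4) {
  max(sp) - min(sp) <= tol * max(sp)
}

#' Read a 3D volume from disk
#'
#' Supports MetaImage (`.mhd` header + raw block) and NIfTI-1
#' (`.nii`, `.nii.gz`). Anisotropic voxel metadata is rejected: the whole
#' protocol assumes isotropic voxels.
#'
#' @param path Path to a `.mhd`, `.nii` or `.nii.gz` file.
#' @param voxel_size_um Optional override of the voxel size (um). If `NULL`,
#'   the size stored in the file is used (assumed to be in um).
#' @param stage_label,specimen_id Passed to [volume_image()].
#' @return A [volume_image()].
#' @export
read_volume <- function(path, voxel_size_um = NULL,
                        stage_label = "other", specimen_id = NULL) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  if (is.null(specimen_id))
    specimen_id <- sub("\\.(mhd|nii|nii\\.gz)$", "", basename(path))
  lower <- tolower(path)
  if (grepl("\\.mhd$", lower)) {
    vol <- read_mhd(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- read_nifti(path)
  } else {
    stop("unsupported volume format (expected .mhd, .nii or .nii.gz): ", path)
  }
  if (!is_isotropic(vol$spacing))
    stop(sprintf("anisotropic voxels unsupported (spacing %s) in %s",
                 paste(signif(vol$spacing, 6), collapse = " x "), path))
  vs <- if (is.null(voxel_size_um)) vol$spacing[1] else voxel_size_um
  if (anyNA(vol$data) || any(!is.finite(vol$data)))
    stop("volume contains non-finite values: ", path)
  volume_image(vol$data, vs, origin_um = vol$origin,
               stage_label = stage_label, specimen_id = specimen_id)
}

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)\\s*$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop("malformed MetaImage header ", path,
                         ": missing ", paste(miss, collapse = ", "))
  if (as.integer(kv$NDims) != 3L) stop("only 3D MetaImage volumes supported")
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  if (!is.null(kv$ElementByteOrderMSB) &&
      toupper(kv$ElementByteOrderMSB) == "TRUE")
    stop("big-endian MetaImage not supported")
  tp <- met_types[[kv$ElementType]]
  if (is.null(tp)) stop("unsupported MetaImage ElementType: ", kv$ElementType)
  raw_path <- file.path(dirname(path), kv$ElementDataFile)
  if (!file.exists(raw_path)) stop("MetaImage data file missing: ", raw_path)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  data <- readBin(con, tp$what, n = n, size = tp$size, signed = tp$signed,
                  endian = "little")
  if (length(data) != n) stop("truncated MetaImage data file: ", raw_path)
  list(data = array(as.double(data), dims), spacing = spacing, origin = origin)
}

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path)
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = "big")
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  dims <- readBin(hdr[41:56], "integer", n = 8, size = 2, endian = endian)
  datatype <- readBin(hdr[71:72], "integer", n = 1, size = 2, endian = endian)
  pixdim <- readBin(hdr[77:108], "double", n = 8, size = 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "double", n = 1, size = 4, endian = endian)
  scl_slope <- readBin(hdr[113:116], "double", n = 1, size = 4, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", n = 1, size = 4, endian = endian)
  ndim <- dims[1]
  if (ndim < 3L) stop("NIfTI volume must be 3D: ", path)
  d3 <- dims[2:4]
  if (ndim > 3L && any(dims[5:(1 + ndim)] > 1L))
    stop("only single-frame 3D NIfTI volumes supported: ", path)
  tp <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(tp)) stop("unsupported NIfTI datatype code ", datatype)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d3)
  data <- readBin(con, tp$what, n = n, size = tp$size, signed = tp$signed,
                  endian = endian)
  if (length(data) != n) stop("truncated NIfTI data: ", path)
  data <- as.double(data)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, d3), spacing = abs(pixdim[2:4]), origin = c(0, 0, 0))
}

#' Write a 3D volume to disk
#'
#' Format is chosen from the file extension: `.mhd` (MetaImage header plus a
#' sibling `.raw` block) or `.nii` / `.nii.gz` (NIfTI-1). Intensities are
#' stored as little-endian float32 by default; use `type = "uint8"` for
#' masks stored as 0/255 volumes.
#'
#' @param vol A [volume_image()].
#' @param path Output path.
#' @param type `"float32"`, `"float64"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, type = c("float32", "float64", "uint8")) {
  type <- match.arg(type)
  lower <- tolower(path)
  if (grepl("\\.mhd$", lower)) write_mhd(vol, path, type)
  else if (grepl("\\.nii(\\.gz)?$", lower)) write_nifti(vol, path, type)
  else stop("unsupported output format (expected .mhd, .nii or .nii.gz): ", path)
  invisible(path)
}

io_payload <- function(vol, type) {
  x <- vol$intensities
  switch(type,
    float32 = list(data = as.double(x), size = 4L, what = "double",
                   met = "MET_FLOAT", nifti = 16L, bitpix = 32L),
    float64 = list(data = as.double(x), size = 8L, what = "double",
                   met = "MET_DOUBLE", nifti = 64L, bitpix = 64L),
    uint8   = list(data = as.integer(pmin(pmax(round(x), 0), 255)), size = 1L,
                   what = "integer", met = "MET_UCHAR", nifti = 2L, bitpix = 8L))
}

write_mhd <- function(vol, path, type) {
  pl <- io_payload(vol, type)
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  d <- dim(vol$intensities)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g", vol$voxel_size_um,
            vol$voxel_size_um, vol$voxel_size_um),
    sprintf("Offset = %.10g %.10g %.10g", vol$origin_um[1], vol$origin_um[2],
            vol$origin_um[3]),
    sprintf("ElementType = %s", pl$met),
    sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(pl$data, con, size = pl$size, endian = "little")
}

write_nifti <- function(vol, path, type) {
  pl <- io_payload(vol, type)
  d <- dim(vol$intensities)
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")                     # sizeof_hdr
  writeBin(raw(36), con)                                               # unused
  writeBin(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), con, size = 2,
           endian = "little")                                          # dim[8]
  writeBin(raw(14), con)                                               # intent etc.
  writeBin(as.integer(pl$nifti), con, size = 2, endian = "little")     # datatype
  writeBin(as.integer(pl$bitpix), con, size = 2, endian = "little")    # bitpix
  writeBin(0L, con, size = 2, endian = "little")                       # slice_start
  writeBin(c(1, rep(vol$voxel_size_um, 3), 0, 0, 0, 0), con, size = 4,
           endian = "little")                                          # pixdim[8]
  writeBin(c(352, 1, 0), con, size = 4, endian = "little")             # vox_offset, scl
  writeBin(raw(224), con)                                              # bytes 120..343
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)               # magic
  writeBin(raw(4), con)                                                # extension
  writeBin(pl$data, con, size = pl$size, endian = "little")
}

#' Read a binary mask stored as an 8-bit volume
#'
#' @param path Volume path as in [read_volume()].
#' @param voxel_size_um Optional voxel size override (um).
#' @return A [binary_mask()]; foreground where the stored intensity is > 0.
#' @export
read_mask <- function(path, voxel_size_um = NULL) {
  v <- read_volume(path, voxel_size_um)
  binary_mask(v$intensities > 0, v$voxel_size_um, v$origin_um)
}

#' Write a binary mask as an 8-bit 0/255 volume
#'
#' @param mask A [binary_mask()].
#' @param path Output path (`.mhd`, `.nii`, `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  v <- volume_image(array(ifelse(mask$voxels, 255, 0), dim(mask$voxels)),
                    mask$voxel_size_um, origin_um = mask$origin_um)
  write_volume(v, path, type = "uint8")
}
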