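test_that("volume and mask constructors enforce their invariants", {
  expect_error(volume_image(array(0, c(1, 4, 4)), 1), "dimensions")
  expect_error(volume_image(array(NA_real_, c(4, 4, 4)), 1), "finite")
  expect_error(volume_image(array(0, c(4, 4, 4)), -1), "positive")
  v <- volume_image(array(0, c(4, 4, 4)), 14.63, stage_label = "TS23")
  expect_s3_class(v, "volume_image")
  expect_identical(dim(v), c(4L, 4L, 4L))
  expect_error(binary_mask(array(2, c(4, 4, 4)), 1), "logical")
  expect_error(bounding_box(c(0, 0, 0), c(0, 4, 4)))
  expect_error(bounding_box(c(2, 2, 2), c(2, 4, 4)))  # lo == hi on an axis
})

test_that("volume I/O round-trips through MetaImage and NIfTI", {
  set.seed(7)
  v <- volume_image(array(rnorm(64), c(4, 4, 4)), 14.63,
                    origin_um = c(1, 2, 3), specimen_id = "rt")
  for (ext in c("mhd", "nii", "nii.gz")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_volume(v, path, type = "float64")
    r <- read_volume(path)
    expect_identical(r$intensities, v$intensities, label = ext)
    expect_equal(r$voxel_size_um, 14.63, tolerance = 1e-5)
    if (ext == "mhd") expect_equal(r$origin_um, c(1, 2, 3))
  }
  # a 4x4x4 all-zero volume reads back as written
  z <- volume_image(array(0, c(4, 4, 4)), 1)
  p <- file.path(tempdir(), "zero.mhd")
  write_volume(z, p)
  expect_true(all(read_volume(p)$intensities == 0))
  expect_error(read_volume(file.path(tempdir(), "missing.mhd")), "no such file")
})

test_that("masks round-trip as 8-bit 0/255 volumes", {
  set.seed(8)
  m <- binary_mask(array(runif(64) > 0.5, c(4, 4, 4)), 14.63)
  p <- file.path(tempdir(), "mask.mhd")
  write_mask(m, p)
  expect_identical(read_mask(p)$voxels, m$voxels)
})

test_that("anisotropic voxel metadata is rejected", {
  v <- volume_image(array(0, c(4, 4, 4)), 14.63)
  p <- file.path(tempdir(), "aniso.nii")
  write_volume(v, p, type = "float32")
  # patch pixdim[3] (z spacing, float32 at byte offset 84) to twice the size
  con <- file(p, "r+b")
  seek(con, 84, rw = "write")
  writeBin(29.26, con, size = 4, endian = "little")
  close(con)
  expect_error(read_volume(p), "anisotropic voxels unsupported")
})

test_that("threshold segmentation keeps the largest connected component", {
  a <- array(0, c(10, 10, 10))
  a[2:6, 2:6, 2:5] <- 10          # 100-voxel blob
  a[9, 9, 8:10] <- 10             # 3-voxel blob
  img <- volume_image(a, 1)
  m <- threshold_segment(img, 5)
  expect_equal(sum(m$voxels), 100)
  expect_true(all(m$voxels[2:6, 2:6, 2:5]))
  # binary image: mask exactly where intensity >= level
  b <- array(0, c(4, 4, 4)); b[2:3, , ] <- 10
  mb <- threshold_segment(volume_image(b, 1), 5)
  expect_identical(mb$voxels, b >= 5)
  expect_error(threshold_segment(img, 99), "outside intensity range")
  expect_error(threshold_segment(volume_image(a, 1), 10.5), "outside")
})

test_that("threshold output is monotone non-increasing in the level", {
  set.seed(11)
  img <- volume_image(array(runif(1000), c(10, 10, 10)), 1)
  m_lo <- threshold_segment(img, 0.3)
  m_hi <- threshold_segment(img, 0.6)
  expect_true(all(m_lo$voxels | !m_hi$voxels))  # hi subset of lo
  m_all <- threshold_segment(img, min(img$intensities))
  expect_true(all(m_all$voxels))
})

test_that("erosion matches the spec examples", {
  d <- c(7, 7, 7)
  single <- array(FALSE, d); single[4, 4, 4] <- TRUE
  expect_equal(sum(erode_mask(binary_mask(single, 1))$voxels), 0)
  cube <- array(FALSE, d); cube[2:6, 2:6, 2:6] <- TRUE
  e <- erode_mask(binary_mask(cube, 1))
  expect_equal(sum(e$voxels), 27)
  expect_true(all(e$voxels[3:5, 3:5, 3:5]))
  empty <- binary_mask(array(FALSE, d), 1)
  expect_equal(sum(erode_mask(empty)$voxels), 0)
})

test_that("erosion agrees with a brute-force oracle and is anti-extensive", {
  set.seed(21)
  for (rep in 1:4) {
    d <- c(6, 7, 5)
    m <- array(runif(prod(d)) > 0.4, d)
    for (conn in c(6L, 26L)) {
      got <- erode_mask(binary_mask(m, 1), connectivity = conn)$voxels
      expect_identical(got, brute_erode(m, conn))
      expect_true(all(m | !got))   # output subset of input
    }
  }
})

test_that("erosion commutes with translation away from the borders", {
  set.seed(22)
  d <- c(9, 9, 9)
  m <- array(FALSE, d)
  m[3:6, 3:6, 3:6] <- array(runif(64) > 0.3, c(4, 4, 4))
  shift <- function(a, s) {
    out <- array(FALSE, dim(a))
    out[(1 + s[1]):d[1], (1 + s[2]):d[2], (1 + s[3]):d[3]] <-
      a[1:(d[1] - s[1]), 1:(d[2] - s[2]), 1:(d[3] - s[3])]
    out
  }
  s <- c(1, 2, 1)
  a <- erode_mask(binary_mask(shift(m, s), 1))$voxels
  b <- shift(erode_mask(binary_mask(m, 1))$voxels, s)
  expect_identical(a, b)
})

test_that("crop returns the expected sub-volume and shifts the origin", {
  v <- ramp_volume(c(4, 4, 4), vs = 2)
  full <- crop(v, bounding_box(c(0, 0, 0), c(4, 4, 4)))
  expect_identical(full$intensities, v$intensities)
  sub <- crop(v, bounding_box(c(1, 1, 1), c(3, 3, 3)))
  expect_identical(sub$intensities, v$intensities[2:3, 2:3, 2:3])
  expect_equal(sub$origin_um, c(2, 2, 2))
  expect_error(crop(v, bounding_box(c(1, 1, 1), c(5, 3, 3))), "exceeds")
  m <- binary_mask(array(TRUE, c(4, 4, 4)), 2)
  expect_identical(dim(crop(m, bounding_box(c(0, 0, 0), c(2, 4, 4)))),
                   c(2L, 4L, 4L))
})

test_that("mask_bounding_box is tight and clipped", {
  m <- array(FALSE, c(6, 6, 6)); m[2:3, 3, 4:5] <- TRUE
  bb <- mask_bounding_box(binary_mask(m, 1))
  expect_equal(bb$lo_voxel, c(1L, 2L, 3L))
  expect_equal(bb$hi_voxel, c(3L, 3L, 5L))
  bb2 <- mask_bounding_box(binary_mask(m, 1), margin_voxels = 10)
  expect_equal(bb2$lo_voxel, c(0L, 0L, 0L))
  expect_equal(bb2$hi_voxel, c(6L, 6L, 6L))
})

test_that("Lanczos resampling is exact on lattice points and constants", {
  set.seed(31)
  v <- volume_image(array(runif(12^3), c(12, 12, 12)), 1)
  same <- resample_lanczos(v, NULL, lattice_of(v))
  expect_lt(max(abs(same$intensities - v$intensities)), 1e-9)
  # integer translation: interior voxels shift exactly
  t1 <- rigid_transform(diag(3), c(1, 0, 0))
  sh <- resample_lanczos(v, t1, lattice_of(v))
  expect_lt(max(abs(sh$intensities[2:12, , ] - v$intensities[1:11, , ])), 1e-9)
  # constants survive arbitrary rigid motion in the interior
  cst <- volume_image(array(5, c(12, 12, 12)), 1)
  rot <- rigid_transform(euler_rotation(c(0, 0, 20)), c(0.3, -0.2, 0.1),
                         center_um = c(5.5, 5.5, 5.5))
  w <- resample_lanczos(cst, rot, lattice_of(cst))
  expect_lt(max(abs(w$intensities[5:8, 5:8, 5:8] - 5)), 1e-6)
  expect_true(all(w$intensities >= 0))   # undershoot clamped
})
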