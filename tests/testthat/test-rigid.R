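test_that("rigid transform algebra: composition, inversion, points", {
  t1 <- rigid_transform(euler_rotation(c(10, -5, 30)), c(3, -2, 1),
                        center_um = c(4, 4, 4))
  t2 <- rigid_transform(euler_rotation(c(0, 15, -10)), c(-1, 0, 2))
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(transform_points(compose_rigid(t1, t2), p),
               transform_points(t1, transform_points(t2, p)), tolerance = 1e-9)
  id <- compose_rigid(invert_rigid(t1), t1)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(id$translation_um)), 1e-9)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
})

test_that("rigid transforms survive JSON serialization", {
  t1 <- rigid_transform(euler_rotation(c(7, 13, -22)), c(10.5, -3, 0.25),
                        center_um = c(100, 50, 25))
  p <- file.path(tempdir(), "t.json")
  write_rigid(t1, p)
  t2 <- read_rigid(p)
  pts <- matrix(rnorm(15), 5, 3)
  expect_equal(transform_points(t1, pts), transform_points(t2, pts),
               tolerance = 1e-9)
})

test_that("centre-of-mass alignment matches centroid arithmetic", {
  d <- c(10, 10, 10)
  a <- array(FALSE, d); a[2:4, 2:4, 2:4] <- TRUE
  b <- array(FALSE, d); b[4:6, 2:4, 2:4] <- TRUE    # shifted +2 voxels in x
  ma <- binary_mask(a, VS); mb <- binary_mask(b, VS)
  t <- align_centers_of_mass(ma, mb)
  expect_equal(t$translation_um, c(2 * VS, 0, 0))
  expect_identical(t$rotation, diag(3))
  expect_equal(align_centers_of_mass(ma, ma)$translation_um, c(0, 0, 0))
  # single-voxel masks: translation = index difference x voxel size
  s1 <- array(FALSE, d); s1[2, 3, 4] <- TRUE
  s2 <- array(FALSE, d); s2[5, 3, 9] <- TRUE
  t2 <- align_centers_of_mass(binary_mask(s1, VS), binary_mask(s2, VS))
  expect_equal(t2$translation_um, c(3, 0, 5) * VS)
  expect_error(align_centers_of_mass(binary_mask(array(FALSE, d), VS), ma),
               "empty")
})

test_that("apply_rigid: forward then inverse translation restores the interior", {
  d <- 24L
  co <- devomap:::voxel_coordinate_arrays(c(d, d, d))
  blob <- exp(-((co$X - 11.5)^2 + (co$Y - 11.5)^2 + (co$Z - 11.5)^2) / (2 * 16))
  v <- volume_image(blob, VS)
  i <- 8:17
  # integer translations round-trip exactly (lattice points, delta kernel)
  ti <- rigid_transform(diag(3), c(2, -1, 3) * VS)
  back_i <- apply_rigid(apply_rigid(v, ti, lattice_of(v)), invert_rigid(ti),
                        lattice_of(v))
  expect_lt(max(abs(back_i$intensities[i, i, i] - v$intensities[i, i, i])), 1e-6)
  # fractional translations accumulate the finite-window (a = 3) truncation
  # error of the kernel, about 1e-3 of the dynamic range on smooth data
  t <- rigid_transform(diag(3), c(2.5 * VS, -1.25 * VS, 0.75 * VS))
  fwd <- apply_rigid(v, t, lattice_of(v))
  back <- apply_rigid(fwd, invert_rigid(t), lattice_of(v))
  expect_lt(max(abs(back$intensities[i, i, i] - v$intensities[i, i, i])), 2e-3)
  # two different specimens resampled to one target share the lattice
  v2 <- make_early_specimen(phantom_spec(dims = c(30, 26, 28), g_c = 0, g_n = 0,
                                         noise_sd = 0, perturb_sd = 0), 2)$image
  out2 <- apply_rigid(v2, rigid_transform(), lattice_of(v))
  expect_identical(dim(out2), dim(v))
})

test_that("orientation refinement recovers identity and small rotations", {
  sp <- phantom_spec(dims = c(28, 28, 28), g_c = 0, g_n = 0, noise_sd = 0,
                     perturb_sd = 0)
  fixed <- make_early_specimen(sp, 1)$image
  fm <- threshold_segment(fixed, sp$intensity_max / 2)
  # self-registration from identity stays at identity
  t_self <- refine_orientation(fixed, fixed, rigid_transform(), fixed_mask = fm)
  ang <- acos(pmin((sum(diag(t_self$rotation)) - 1) / 2, 1)) * 180 / pi
  expect_lt(ang, 0.5)
  expect_lt(max(abs(t_self$translation_um)), 0.1 * VS)

  # moving = fixed rotated 10 degrees about z -> recovered within 1 degree
  ctr <- (dim(fixed$intensities) - 1) / 2 * VS
  t_true <- rigid_transform(euler_rotation(c(0, 0, 10)), c(0, 0, 0), ctr)
  moving <- apply_rigid(fixed, invert_rigid(t_true), lattice_of(fixed))
  t_rec <- refine_orientation(moving, fixed, rigid_transform(), fixed_mask = fm)
  err <- t_rec$rotation %*% t(t_true$rotation)
  ang_err <- acos(pmin((sum(diag(err)) - 1) / 2, 1)) * 180 / pi
  expect_lt(ang_err, 1)

  # the optimizer never worsens its own objective
  nmi0 <- nmi_rigid(moving, fixed, rigid_transform(), fixed_mask = fm)$nmi
  expect_gte(attr(t_rec, "nmi"), nmi0 - 1e-12)
})

test_that("disjoint images are rejected", {
  d <- c(16, 16, 16)
  a <- array(0, d); a[2:5, 2:5, 2:5] <- 100
  b <- array(0, d); b[11:14, 11:14, 11:14] <- 100
  va <- volume_image(a, VS); vb <- volume_image(b, VS)
  far <- rigid_transform(diag(3), c(1000 * VS, 0, 0))
  expect_error(refine_orientation(va, vb, far), "overlap")
})
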