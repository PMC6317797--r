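test_that("phantom generation is deterministic and well formed", {
  sp <- phantom_spec(dims = c(24, 24, 24), g_c = 40, g_n = 16)
  a <- make_early_specimen(sp, 3)
  b <- make_early_specimen(sp, 3)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$mask$voxels, b$mask$voxels)
  # noise-free, unperturbed generation is also bit-reproducible
  sp0 <- phantom_spec(dims = c(24, 24, 24), g_c = 40, g_n = 16,
                      noise_sd = 0, perturb_sd = 0)
  expect_identical(make_early_specimen(sp0, 1)$image$intensities,
                   make_early_specimen(sp0, 1)$image$intensities)
  # the mask is a single 6-connected component
  expect_equal(devomap:::cpp_n_components(a$mask$voxels, dim(a$mask$voxels), 6L), 1L)
  expect_error(phantom_spec(g_c = 10, g_n = 20), "g_c >= g_n")
  # shape too large for the lattice
  big <- phantom_spec(dims = c(24, 24, 24), base_semiaxes = c(14, 14, 14),
                      g_c = 0, g_n = 0)
  expect_error(make_early_specimen(big, 1), "exceeds the lattice")
})

test_that("foreground volume varies within 10% across specimens", {
  sp <- phantom_spec(dims = c(24, 24, 24), g_c = 40, g_n = 16)
  vols <- vapply(0:4, function(s) sum(make_early_specimen(sp, s)$mask$voxels), 0)
  expect_true(all(abs(vols - mean(vols)) / mean(vols) < 0.10))
})

test_that("zero growth leaves the specimen unchanged with zero ground truth", {
  sp <- phantom_spec(dims = c(20, 20, 20), g_c = 0, g_n = 0,
                     noise_sd = 0, perturb_sd = 0)
  e <- make_early_specimen(sp, 1)
  gr <- grow_specimen(e$image, e$mask, sp, 1)
  expect_lt(max(abs(gr$image$intensities - e$image$intensities)), 1e-9)
  expect_identical(gr$mask$voxels, e$mask$voxels)
  expect_true(all(gr$ground_truth$u == 0))
})

test_that("a uniform forward field reproduces a pure translation", {
  set.seed(91)
  v <- array(0, c(16, 16, 16))
  v[5:11, 5:11, 5:11] <- runif(343, 50, 100)
  v <- devomap:::cpp_gaussian_blur(v, c(16L, 16L, 16L), 1)
  f <- matrix(rep(c(2, 0, 0), each = 16^3), ncol = 3)   # +2 voxels in x
  warped <- devomap:::cpp_warp_inverse_fixedpoint(v, c(16L, 16L, 16L), f, 10L)
  expect_lt(max(abs(array(warped, c(16, 16, 16))[7:13, , ] - v[5:11, , ])), 1e-6)
})

test_that("the ground-truth field peaks at g_c on the rudiment", {
  sp <- phantom_spec(dims = c(32, 32, 32), g_c = 100, g_n = 40,
                     noise_sd = 0, perturb_sd = 0)
  e <- make_early_specimen(sp, 1)
  gr <- grow_specimen(e$image, e$mask, sp, 1)
  gt <- gr$ground_truth
  # NS = 1: nodes coincide with voxels
  expect_identical(gt$grid$ns, 1L)
  mask_nodes <- as.vector(e$mask$voxels)
  mags <- sqrt(rowSums(gt$u[mask_nodes, ]^2))
  expect_equal(max(mags), sp$g_c, tolerance = 1e-6)
  # condylar growth exceeds intercondylar growth
  pos <- node_positions_um(gt$grid)[mask_nodes, ]
  w <- phantom_condyle_weight(sp, pos)
  r <- sqrt(rowSums(sweep(pos / sp$voxel_size_um, 2,
                          devomap:::phantom_center(sp))^2))
  shell <- r > 0.8 * max(r)
  expect_gt(mean(mags[shell & w > 0.7]), mean(mags[shell & w < 0.3]))
})

test_that("the growth mapping has positive Jacobian determinant (no folding)", {
  sp <- phantom_spec(dims = c(32, 32, 32), g_c = 100, g_n = 40)
  vs <- sp$voxel_size_um
  co <- devomap:::voxel_coordinate_arrays(sp$dims)
  pts <- cbind(as.numeric(co$X), as.numeric(co$Y), as.numeric(co$Z)) * vs
  u <- phantom_growth_field(sp, pts) / vs        # voxel units
  dims <- sp$dims
  arr <- function(m) array(m, dims)
  ux <- arr(u[, 1]); uy <- arr(u[, 2]); uz <- arr(u[, 3])
  i <- 2:(dims[1] - 1); j <- 2:(dims[2] - 1); k <- 2:(dims[3] - 1)
  dd <- function(a, ax) switch(ax,
    (a[i + 1, j, k] - a[i - 1, j, k]) / 2,
    (a[i, j + 1, k] - a[i, j - 1, k]) / 2,
    (a[i, j, k + 1] - a[i, j, k - 1]) / 2)
  J11 <- 1 + dd(ux, 1); J12 <- dd(ux, 2); J13 <- dd(ux, 3)
  J21 <- dd(uy, 1); J22 <- 1 + dd(uy, 2); J23 <- dd(uy, 3)
  J31 <- dd(uz, 1); J32 <- dd(uz, 2); J33 <- 1 + dd(uz, 3)
  det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
  expect_true(all(det > 0))
})

test_that("populations are seeded, sized and reproducible", {
  sp <- phantom_spec(dims = c(20, 20, 20), g_c = 30, g_n = 12)
  pop <- make_population(sp, 5, 5)
  expect_length(pop$early$members, 5)
  expect_length(pop$late$members, 5)
  expect_equal(nrow(enumerate_pairs(pop$early, pop$late)), 25)
  pop2 <- make_population(sp, 5, 5)
  expect_identical(pop$early$members$e03$image$intensities,
                   pop2$early$members$e03$image$intensities)
  expect_identical(pop$late$members$l05$image$intensities,
                   pop2$late$members$l05$image$intensities)
  mini <- make_population(sp, 1, 1)
  expect_equal(nrow(enumerate_pairs(mini$early, mini$late)), 1)
  expect_error(make_population(sp, 0, 1), ">= 1")
})
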