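# small fast phantoms for solver tests
defo_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- phantom_spec(dims = c(24, 24, 24), g_c = 40, g_n = 16,
                        noise_sd = 0, perturb_sd = 0)
      e <- make_early_specimen(sp, 1)
      gr <- grow_specimen(e$image, e$mask, sp, 1)
      cache <<- list(spec = sp, early = e, late = gr)
    }
    cache
  }
})

test_that("registration grids cover the image lattice", {
  g <- registration_grid(c(10, 13, 8), 4, VS)
  expect_equal(g$n_node, c(4L, 4L, 3L))
  # last node at or beyond the last voxel on every axis
  expect_true(all((g$n_node - 1) * g$ns >= g$dims - 1))
  expect_error(registration_grid(c(10, 10, 10), 0), ">= 1")
  expect_equal(nrow(node_positions_um(g)), prod(g$n_node))
})

test_that("displacement interpolation is exact at nodes and cell centres", {
  g <- registration_grid(c(5, 5, 5), 2, VS)
  nn <- prod(g$n_node)
  set.seed(71)
  u <- matrix(rnorm(nn * 3), nn, 3)
  f <- displacement_field(g, u)
  pos <- node_positions_um(g)
  expect_equal(interpolate_displacement(f, pos), u, tolerance = 1e-12)
  # centre of the first cell: mean of its 8 corner values
  centre <- matrix(c(1, 1, 1) * VS, 1, 3)
  id <- function(i, j, k) i + g$n_node[1] * (j - 1 + g$n_node[2] * (k - 1))
  corners <- c(id(1,1,1), id(2,1,1), id(1,2,1), id(2,2,1),
               id(1,1,2), id(2,1,2), id(1,2,2), id(2,2,2))
  expect_equal(as.numeric(interpolate_displacement(f, centre)),
               colMeans(u[corners, ]), tolerance = 1e-12)
  # uniform field: same vector everywhere
  fu <- displacement_field(g, matrix(rep(c(1, 2, 3), each = nn), nn, 3))
  expect_equal(as.numeric(interpolate_displacement(fu, matrix(c(3.3, 1.7, 5.1), 1, 3))),
               c(1, 2, 3), tolerance = 1e-12)
  expect_error(interpolate_displacement(f, matrix(c(-5, 0, 0), 1, 3)),
               "outside grid")
})

test_that("displacement precision follows the population-SD closed forms", {
  g <- registration_grid(c(5, 5, 4), 1, VS)   # even node count
  nn <- prod(g$n_node)
  zero <- displacement_field(g, matrix(0, nn, 3))
  expect_equal(unname(displacement_precision(zero)), c(0, 0, 0))
  a <- 7.5
  ux <- rep(c(-a, a), length.out = nn)
  f <- displacement_field(g, cbind(ux, 0, 0))
  expect_equal(unname(displacement_precision(f)), c(a, 0, 0), tolerance = 1e-12)
})

test_that("self-registration yields a negligible field and zero offset", {
  d <- defo_pair()
  f <- register_deformable(d$early$image, d$early$image, ns = 4)
  expect_lt(max(abs(f$u)) / VS, 0.05)
  expect_lt(max(abs(f$intensity_offset)), 1)
  expect_true(f$converged)
})

test_that("a 1.5-voxel translation is recovered within 0.2 voxel", {
  d <- defo_pair()
  img <- d$early$image
  t <- rigid_transform(diag(3), c(1.5 * VS, 0, 0))
  late <- resample_lanczos(img, t, lattice_of(img))
  f <- register_deformable(img, late, ns = 4)
  keep <- as.vector(devomap:::nodes_of_valid_cells(
    filter_cells(f$grid, d$early$mask)))
  mean_u <- colMeans(f$u[keep, ]) / VS
  expect_lt(max(abs(mean_u - c(1.5, 0, 0))), 0.2)
})

test_that("a smooth 3-voxel growth field is recovered under 0.5 voxel RMSE", {
  d <- defo_pair()
  f <- register_deformable(d$early$image, d$late$image, ns = 4)
  keep <- as.vector(devomap:::nodes_of_valid_cells(
    filter_cells(f$grid, d$early$mask)))
  pos <- node_positions_um(f$grid)[keep, ]
  gt <- phantom_growth_field(d$spec, pos)
  rmse <- sqrt(mean(rowSums((f$u[keep, ] - gt)^2)))
  expect_lt(rmse / VS, 0.5)
})

test_that("registration is equivariant under common integer translation", {
  # a 24-scale rudiment centred in a 40^3 lattice, so the shifted copies
  # keep full margins and boundary truncation does not enter the comparison
  base <- 24
  sp <- phantom_spec(dims = c(40, 40, 40),
                     base_semiaxes = base * c(0.24, 0.18, 0.20),
                     condyle_offset = c(0.11, 0, 0) * base,
                     condyle_radius = 0.11 * base,
                     g_c = 40, g_n = 16, noise_sd = 0, perturb_sd = 0)
  e <- make_early_specimen(sp, 1)
  gr <- grow_specimen(e$image, e$mask, sp, 1)
  f1 <- register_deformable(e$image, gr$image, ns = 4)
  sh <- c(4, 4, 0)                      # one nodal spacing per shifted axis
  t <- rigid_transform(diag(3), sh * VS)
  e2 <- resample_lanczos(e$image, t, lattice_of(e$image))
  l2 <- resample_lanczos(gr$image, t, lattice_of(gr$image))
  f2 <- register_deformable(e2, l2, ns = 4)
  # compare u at interior mask nodes: u2(x + sh) should equal u1(x)
  keep <- as.vector(devomap:::nodes_of_valid_cells(
    filter_cells(f1$grid, erode_mask(e$mask, 2))))
  pos <- node_positions_um(f1$grid)[keep, ]
  u1 <- interpolate_displacement(f1, pos)
  u2 <- interpolate_displacement(f2, sweep(pos, 2, -sh * VS))
  expect_lt(max(abs(u2 - u1)) / VS, 0.05)
})

test_that("stronger smoothing never increases field roughness", {
  d <- defo_pair()
  rough <- vapply(c(5, 50, 500), function(lam) {
    f <- register_deformable(d$early$image, d$late$image, ns = 4,
                             lambda_s = lam)
    field_roughness(f)
  }, 0)
  expect_true(all(diff(rough) <= 1e-9 + 1e-9 * abs(rough[-3])))
})

test_that("registration quality never falls below the unregistered NMI", {
  d <- defo_pair()
  rng <- range(c(d$early$image$intensities, d$late$image$intensities))
  e_n <- (d$early$image$intensities - rng[1]) / diff(rng)
  l_n <- (d$late$image$intensities - rng[1]) / diff(rng)
  nmi0 <- devomap:::cpp_nmi(as.numeric(e_n), as.numeric(l_n), 32L, 0, 1, 0, 1)
  f <- register_deformable(d$early$image, d$late$image, ns = 4)
  expect_gte(f$quality, nmi0 - 1e-9)
})

test_that("degenerate inputs are rejected", {
  cst <- volume_image(array(3, c(8, 8, 8)), VS)
  expect_error(register_deformable(cst, cst, ns = 4),
               "no intensity gradient")
  a <- volume_image(array(runif(512), c(8, 8, 8)), VS)
  b <- volume_image(array(runif(729), c(9, 9, 9)), VS)
  expect_error(register_deformable(a, b, ns = 4), "same lattice")
})

test_that("repeated-scan precision stays below 0.2 voxel at 5% noise", {
  sp <- phantom_spec(dims = c(24, 24, 24), g_c = 0, g_n = 0,
                     noise_sd = 10, perturb_sd = 0)
  scan1 <- make_early_specimen(sp, 1, scan_seed = 0L)
  scan2 <- make_early_specimen(sp, 1, scan_seed = 1L)  # same specimen, new noise
  f <- register_deformable(scan1$image, scan2$image, ns = 4,
                           domain_mask = registration_domain(scan1$mask,
                                                             scan2$mask))
  f$grid <- filter_cells(f$grid, scan1$mask)
  sds <- displacement_precision(f)
  expect_true(all(sds / VS < 0.2))
})
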