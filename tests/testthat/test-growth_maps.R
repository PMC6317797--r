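test_that("cell filtering follows the all-nodes-outside rule", {
  dims <- c(5, 5, 5)
  g <- registration_grid(dims, 2, VS)   # 3x3x3 nodes, 8 cells
  empty <- binary_mask(array(FALSE, dims), VS)
  expect_equal(sum(filter_cells(g, empty)$cell_valid), 0)
  full <- binary_mask(array(TRUE, dims), VS)
  expect_equal(sum(filter_cells(g, full)$cell_valid), 8)
  # mask true only at the (0,0,0) corner node's voxel -> exactly 1 valid cell
  corner <- array(FALSE, dims); corner[1, 1, 1] <- TRUE
  expect_equal(sum(filter_cells(g, binary_mask(corner, VS))$cell_valid), 1)
  expect_error(filter_cells(g, binary_mask(array(TRUE, c(4, 4, 4)), VS)),
               "does not match")
})

test_that("cell filtering matches the brute-force oracle", {
  set.seed(81)
  for (rep in 1:6) {
    dims <- sample(5:12, 3, replace = TRUE)
    ns <- sample(1:3, 1)
    m <- array(runif(prod(dims)) > 0.6, dims)
    g <- filter_cells(registration_grid(dims, ns, VS), binary_mask(m, VS))
    expect_equal(sum(g$cell_valid), brute_valid_cells(dims, ns, m))
  }
})

dummy_group <- function(ids, stage, dims = c(6, 6, 6)) {
  members <- lapply(ids, function(i)
    list(image = volume_image(array(1, dims), VS), mask = NULL))
  names(members) <- ids
  specimen_group("tibia_proximal", stage, members)
}

test_that("pair enumeration reproduces the cohort bookkeeping", {
  e5 <- dummy_group(sprintf("e%02d", 1:5), "TS23")
  l5 <- dummy_group(sprintf("l%02d", 1:5), "TS24")
  expect_equal(nrow(enumerate_pairs(e5, l5)), 25)
  e4 <- dummy_group(sprintf("e%02d", 1:4), "TS23")
  expect_equal(nrow(enumerate_pairs(e4, l5)), 20)
  expect_equal(nrow(enumerate_pairs(e5, l5, exclude_control = "e03")), 20)
  e1 <- dummy_group("a", "TS23"); l1 <- dummy_group("b", "TS24")
  expect_equal(nrow(enumerate_pairs(e1, l1)), 1)
  # deterministic lexicographic order
  p <- enumerate_pairs(e4, l5)
  expect_identical(p$early_id, rep(sprintf("e%02d", 1:4), each = 5))
  expect_identical(p$late_id, rep(sprintf("l%02d", 1:5), times = 4))
  expect_error(enumerate_pairs(e1, l1, exclude_control = "a"), "non-empty")
  expect_error(enumerate_pairs(e1, l1, exclude_control = "zz"), "not in")
})

rand_field <- function(grid, seed) {
  set.seed(seed)
  nn <- prod(grid$n_node)
  displacement_field(grid, matrix(rnorm(nn * 3), nn, 3))
}

test_that("field averaging is a node-wise mean over the valid-cell intersection", {
  g <- registration_grid(c(7, 7, 7), 2, VS)
  nn <- prod(g$n_node)
  f <- rand_field(g, 1)
  same <- average_fields(list(f, f, f), "single")
  expect_equal(same$mean_u, f$u)
  expect_equal(same$n_contributing, 3L)
  f0 <- displacement_field(g, matrix(0, nn, 3))
  f10 <- displacement_field(g, matrix(rep(c(10, 0, 0), each = nn), nn, 3))
  m <- average_fields(list(f0, f10), "developmental")
  expect_true(all(m$mean_u[, 1] == 5))
  # 20 random fields vs a per-node loop oracle
  fields <- lapply(1:20, rand_field, grid = g)
  got <- average_fields(fields, "developmental")$mean_u
  exp_u <- matrix(0, nn, 3)
  for (f_ in fields) exp_u <- exp_u + f_$u
  expect_equal(got, exp_u / 20, tolerance = 1e-12)
  # permutation invariance
  perm <- average_fields(fields[sample(20)], "developmental")$mean_u
  expect_equal(perm, got, tolerance = 1e-12)
})

test_that("averaging intersects cell validity and rejects mismatches", {
  g <- registration_grid(c(7, 7, 7), 2, VS)
  f1 <- rand_field(g, 2); f2 <- rand_field(g, 3)
  f1$grid$cell_valid[1:2, , ] <- FALSE
  f2$grid$cell_valid[, 1:2, ] <- FALSE
  m <- average_fields(list(f1, f2), "developmental")
  expect_identical(m$grid$cell_valid,
                   f1$grid$cell_valid & f2$grid$cell_valid)
  mu <- average_fields(list(f1, f2), "developmental", validity = "union")
  expect_identical(mu$grid$cell_valid,
                   f1$grid$cell_valid | f2$grid$cell_valid)
  g2 <- registration_grid(c(9, 9, 9), 2, VS)
  expect_error(average_fields(list(f1, rand_field(g2, 4)), "single"),
               "share one lattice")
  f3 <- rand_field(g, 5); f3$grid$cell_valid[] <- FALSE
  expect_error(average_fields(list(f1, f3), "single"), "empty intersection")
})

test_that("identical specimens give identical developmental and single maps", {
  sp <- phantom_spec(dims = c(20, 20, 20), g_c = 30, g_n = 12,
                     noise_sd = 0, perturb_sd = 0, texture_amp = 0)
  pop <- make_population(sp, 2, 2)
  maps <- build_site_maps(pop$early, pop$late, "e01", ns = 4)
  expect_equal(maps$developmental$n_contributing, 2L)  # (2-1) early x 2 late
  expect_equal(maps$single$n_contributing, 2L)
  keep <- devomap:::common_valid_nodes(maps$developmental, maps$single)
  expect_lt(max(abs(maps$developmental$mean_u[keep, ] -
                    maps$single$mean_u[keep, ])) / VS, 0.05)
  expect_error(build_site_maps(pop$early, pop$late, "nope", ns = 4),
               "not found")
})
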