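test_that("directed and symmetrised distances match closed forms", {
  A <- matrix(c(0, 0, 0), 1, 3)
  B <- matrix(c(3, 4, 0), 1, 3)
  expect_equal(directed_distance(A, B, "max"), 5)
  expect_equal(directed_distance(A, B, "mean"), 5)
  A2 <- rbind(c(0, 0, 0), c(2, 0, 0))
  B2 <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(directed_distance(A2, B2, "mean"), 1)
  expect_equal(modified_hausdorff(A2, B2), 1)
  expect_equal(modified_hausdorff(A2, A2), 0)
  # asymmetry of the directed means, symmetrised by the max
  A3 <- matrix(c(0, 0, 0), 1, 3)
  B3 <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(directed_distance(A3, B3, "mean"), 0)
  expect_equal(directed_distance(B3, A3, "mean"), 5)
  expect_equal(modified_hausdorff(A3, B3), 5)
  expect_equal(hausdorff_distance(A3, B3), 10)
  expect_error(directed_distance(A, matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("k-d tree distances agree with the all-pairs oracle", {
  set.seed(51)
  for (rep in 1:20) {
    A <- random_point_set(sample(1:400, 1))
    B <- random_point_set(sample(1:400, 1))
    expect_equal(devomap:::cpp_nn_dist(A, B), brute_nn(A, B), tolerance = 1e-9)
    # symmetry and mean <= max
    expect_equal(modified_hausdorff(A, B), modified_hausdorff(B, A))
    expect_lte(modified_hausdorff(A, B), hausdorff_distance(A, B))
    # homogeneity under scaling
    s <- runif(1, 0.1, 10)
    expect_equal(modified_hausdorff(A * s, B * s), s * modified_hausdorff(A, B),
                 tolerance = 1e-9)
  }
})

make_map <- function(u, dims = c(5, 5, 5), ns = 1, kind = "developmental") {
  grid <- registration_grid(dims, ns, VS)
  growth_map(grid, u, 1L, kind)
}

test_that("average displacement difference uses absolute per-axis means", {
  nn <- prod(registration_grid(c(5, 5, 5), 1, VS)$n_node)
  a <- make_map(matrix(0, nn, 3))
  expect_equal(unname(average_displacement_difference(a, a)), c(0, 0, 0))
  # +3 at half the nodes, -3 at the rest: ADD_x = 3 (not 0)
  ux <- rep(c(3, -3), length.out = nn)
  b <- make_map(cbind(ux, 0, 0), kind = "single")
  expect_equal(unname(average_displacement_difference(a, b)), c(3, 0, 0))
  # random maps vs a brute-force node loop
  set.seed(52)
  m1 <- make_map(matrix(rnorm(nn * 3), nn, 3))
  m2 <- make_map(matrix(rnorm(nn * 3), nn, 3), kind = "single")
  got <- average_displacement_difference(m1, m2)
  keep <- as.vector(devomap:::nodes_of_valid_cells(m1$grid))
  exp_add <- sapply(1:3, function(ax) {
    tot <- 0; n <- 0
    for (i in which(keep)) { tot <- tot + abs(m1$mean_u[i, ax] - m2$mean_u[i, ax]); n <- n + 1 }
    tot / n
  })
  expect_equal(unname(got), exp_add, tolerance = 1e-12)
  wrong <- make_map(matrix(0, prod(registration_grid(c(4, 4, 4), 1, VS)$n_node), 3),
                    dims = c(4, 4, 4))
  expect_error(average_displacement_difference(a, wrong), "different grids")
})

test_that("repeatability summaries follow the mean/SD/range/max-diff layout", {
  rep1 <- structure(list(mhd_um = 20, hd_um = 30, add_um = c(1, 2, 3)),
                    class = "map_comparison")
  expect_error(repeatability_summary(list(rep1)), "at least 2")
  reps <- lapply(c(20, 20, 20), function(v)
    structure(list(mhd_um = v, hd_um = v + 10, add_um = c(1, 2, 3)),
              class = "map_comparison"))
  s <- repeatability_summary(reps)
  mhd <- s[s$metric == "MHD", ]
  expect_equal(mhd$mean, 20); expect_equal(mhd$sd, 0)
  expect_equal(mhd$max_difference, 0)
  reps2 <- lapply(c(19.8, 20.0, 20.2), function(v)
    structure(list(mhd_um = v, hd_um = v, add_um = c(0, 0, 0)),
              class = "map_comparison"))
  s2 <- repeatability_summary(reps2)
  mhd2 <- s2[s2$metric == "MHD", ]
  expect_equal(mhd2$mean, 20)
  expect_equal(mhd2$max_difference, 0.4, tolerance = 1e-12)
  expect_equal(mhd2$min, 19.8); expect_equal(mhd2$max, 20.2)
  # population SD, not sample SD
  expect_equal(mhd2$sd, sqrt(mean((c(19.8, 20, 20.2) - 20)^2)))
})

test_that("growth maps and displacement fields round-trip through JSON", {
  set.seed(53)
  grid <- registration_grid(c(6, 6, 6), 2, VS)
  nn <- prod(grid$n_node)
  grid$cell_valid[1, 1, 1] <- FALSE
  f <- displacement_field(grid, matrix(rnorm(nn * 3), nn, 3),
                          intensity_offset = rnorm(nn), quality = 1.5,
                          converged = TRUE)
  p <- file.path(tempdir(), "field.json")
  write_field(f, p)
  f2 <- read_field(p)
  expect_equal(f2$u, f$u)
  expect_equal(f2$intensity_offset, f$intensity_offset)
  expect_identical(f2$grid$cell_valid, grid$cell_valid)
  m <- growth_map(grid, f$u, 20L, "developmental", "tibia_proximal")
  write_field(m, p)
  m2 <- read_field(p)
  expect_equal(m2$mean_u, m$mean_u)
  expect_identical(m2$n_contributing, 20L)
  expect_identical(m2$kind, "developmental")
})
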