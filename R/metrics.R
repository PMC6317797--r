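#' Directed Hausdorff-type distance between two point sets
#'
#' For each point of `A`, the Euclidean distance to its nearest neighbour in
#' `B`; returns the maximum (classic directed Hausdorff `h(A,B)`) or the
#' arithmetic mean (the directed term of the Modified Hausdorff Distance).
#'
#' @param A,B [surface_point_set()] objects or n x 3 matrices (um).
#' @param mode `"max"` or `"mean"`.
#' @return Scalar distance (um).
#' @export
directed_distance <- function(A, B, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  A <- if (inherits(A, "surface_point_set")) A$points_um else matrix(A, ncol = 3)
  B <- if (inherits(B, "surface_point_set")) B$points_um else matrix(B, ncol = 3)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("point sets must be non-empty")
  d <- cpp_nn_dist(A, B)
  if (mode == "max") max(d) else mean(d)
}

#' Hausdorff Distance
#'
#' `HD(A,B) = max(h(A,B), h(B,A))` with `h` the directed max-min distance.
#'
#' @inheritParams directed_distance
#' @return Scalar (um).
#' @export
hausdorff_distance <- function(A, B) {
  max(directed_distance(A, B, "max"), directed_distance(B, A, "max"))
}

#' Modified Hausdorff Distance
#'
#' The symmetrised mean-of-minimum-distances variant: the directed terms use
#' the average rather than the maximum of the nearest-neighbour distances,
#' removing the influence of outliers; the larger directed value is returned.
#'
#' @inheritParams directed_distance
#' @return Scalar (um).
#' @export
modified_hausdorff <- function(A, B) {
  max(directed_distance(A, B, "mean"), directed_distance(B, A, "mean"))
}

common_valid_nodes <- function(mapA, mapB) {
  ga <- mapA$grid; gb <- mapB$grid
  if (!identical(ga$n_node, gb$n_node) || ga$ns != gb$ns ||
      !identical(ga$dims, gb$dims))
    stop("growth maps live on different grids")
  va <- nodes_of_valid_cells(ga)
  vb <- nodes_of_valid_cells(gb)
  as.vector(va & vb)
}

#' Average Displacement Difference between two growth maps
#'
#' Per axis, the mean absolute difference of the displacement components over
#' the nodes valid in both maps. The absolute value prevents signed
#' differences from cancelling.
#'
#' @param mapA,mapB [growth_map()] objects on the same grid.
#' @return Named numeric 3-vector `c(ADD_X, ADD_Y, ADD_Z)` (um).
#' @export
average_displacement_difference <- function(mapA, mapB) {
  keep <- common_valid_nodes(mapA, mapB)
  if (!any(keep)) stop("no common valid nodes")
  d <- abs(mapA$mean_u[keep, , drop = FALSE] - mapB$mean_u[keep, , drop = FALSE])
  c(ADD_X = mean(d[, 1]), ADD_Y = mean(d[, 2]), ADD_Z = mean(d[, 3]))
}

#' Compare two growth maps on the control mesh
#'
#' Deforms the control specimen's hexahedral mesh with each map, extracts the
#' surface nodes of the two deformed shapes, and reports the Modified
#' Hausdorff Distance, the Hausdorff Distance and the per-axis Average
#' Displacement Difference.
#'
#' @param mapA,mapB [growth_map()] objects on one grid.
#' @param mesh Optional control `hex_mesh`; default: mesh of the cells valid
#'   in both maps.
#' @param labels Character 2-vector naming the maps.
#' @return Object of class `map_comparison` with fields `mhd_um`, `hd_um`,
#'   `add_um`, `n_points_A`, `n_points_B`, `labels`.
#' @export
compare_maps <- function(mapA, mapB, mesh = NULL,
                         labels = c(mapA$kind, mapB$kind)) {
  if (is.null(mesh)) {
    g <- mapA$grid
    g$cell_valid <- mapA$grid$cell_valid & mapB$grid$cell_valid
    mesh <- grid_to_hexmesh(g)
  }
  sa <- extract_surface_nodes(deform_mesh(mesh, mapA))
  sb <- extract_surface_nodes(deform_mesh(mesh, mapB))
  structure(list(
    mhd_um = modified_hausdorff(sa, sb),
    hd_um = hausdorff_distance(sa, sb),
    add_um = average_displacement_difference(mapA, mapB),
    n_points_A = nrow(sa$points_um), n_points_B = nrow(sb$points_um),
    labels = labels
  ), class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("<map_comparison> %s vs %s: MHD %.2f um, HD %.2f um, ADD (%.2f, %.2f, %.2f) um\n",
              x$labels[1], x$labels[2], x$mhd_um, x$hd_um,
              x$add_um[1], x$add_um[2], x$add_um[3]))
  invisible(x)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Repeatability summary of map comparisons
#'
#' For each metric (MHD, HD, ADD-X/Y/Z) over a set of repeated comparisons:
#' mean, population standard deviation, min-max range and the maximum
#' pairwise difference — the layout of a repeatability table.
#'
#' @param reports List of at least two [compare_maps()] results.
#' @return Data frame with one row per metric and columns `metric`, `mean`,
#'   `sd`, `min`, `max`, `max_difference` (all um; population SD).
#' @export
repeatability_summary <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports")
  vals <- list(
    MHD = vapply(reports, `[[`, 0, "mhd_um"),
    HD = vapply(reports, `[[`, 0, "hd_um"),
    `ADD-X` = vapply(reports, function(r) r$add_um[[1]], 0),
    `ADD-Y` = vapply(reports, function(r) r$add_um[[2]], 0),
    `ADD-Z` = vapply(reports, function(r) r$add_um[[3]], 0))
  out <- do.call(rbind, lapply(names(vals), function(m) {
    v <- vals[[m]]
    data.frame(metric = m, mean = mean(v), sd = pop_sd(v),
               min = min(v), max = max(v),
               max_difference = max(v) - min(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Serialize a displacement field or growth map to JSON
#'
#' Stores node extent, nodal spacing, voxel size, origin, the displacement
#' components (um), the intensity offset (fields) and the cell validity.
#'
#' @param x A [displacement_field()] or [growth_map()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_field <- function(x, path) {
  g <- x$grid
  rec <- list(
    class = class(x), n_node = g$n_node, ns = g$ns, dims = g$dims,
    voxel_size_um = g$voxel_size_um, origin_um = g$origin_um,
    cell_valid = as.integer(g$cell_valid),
    u = if (inherits(x, "growth_map")) as.numeric(x$mean_u) else as.numeric(x$u))
  if (inherits(x, "growth_map")) {
    rec$n_contributing <- x$n_contributing; rec$kind <- x$kind; rec$site <- x$site
  } else {
    rec$intensity_offset <- x$intensity_offset
    rec$quality <- x$quality; rec$converged <- x$converged
  }
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a displacement field or growth map written by [write_field()]
#'
#' @param path `.json` path.
#' @return A [displacement_field()] or [growth_map()].
#' @export
read_field <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- registration_grid(rec$dims, rec$ns, rec$voxel_size_um, rec$origin_um)
  grid$cell_valid <- array(rec$cell_valid != 0, dim(grid$cell_valid))
  u <- matrix(rec$u, ncol = 3)
  if ("growth_map" %in% rec$class)
    growth_map(grid, u, rec$n_contributing, rec$kind, rec$site)
  else
    displacement_field(grid, u, rec$intensity_offset, rec$quality, rec$converged)
}
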