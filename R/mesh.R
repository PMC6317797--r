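# Local corner order of a hexahedral cell (VTK_HEXAHEDRON): offsets
# (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1).
hex_corner_offsets <- matrix(c(
  0,0,0, 1,0,0, 1,1,0, 0,1,0,
  0,0,1, 1,0,1, 1,1,1, 0,1,1), ncol = 3, byrow = TRUE)

# Outward-oriented quad faces of a hex, as indices into the 8 local corners.
hex_faces <- matrix(c(
  1,4,3,2,   # -z
  5,6,7,8,   # +z
  1,2,6,5,   # -y
  3,4,8,7,   # +y
  1,5,8,4,   # -x
  2,3,7,6),  # +x
  ncol = 4, byrow = TRUE)

#' Convert the valid cells of a registration grid to a hexahedral mesh
#'
#' One 8-node hexahedron per valid cell; nodes shared between cells are
#' merged (conforming mesh).
#'
#' @param grid A [registration_grid()] with at least one valid cell.
#' @return Object of class `hex_mesh` with `nodes_um` (n x 3), `elements`
#'   (m x 8, 1-based mesh node ids in VTK corner order), `node_map` (grid
#'   linear node index for each mesh node) and the source `grid`.
#' @export
grid_to_hexmesh <- function(grid) {
  cells <- which(grid$cell_valid, arr.ind = TRUE)
  if (nrow(cells) == 0L) stop("grid has no valid cells")
  nn <- grid$n_node
  # grid linear node index (1-based) of every corner of every cell
  corner_lin <- matrix(0L, nrow(cells), 8)
  for (cr in 1:8) {
    ix <- cells[, 1] + hex_corner_offsets[cr, 1]
    iy <- cells[, 2] + hex_corner_offsets[cr, 2]
    iz <- cells[, 3] + hex_corner_offsets[cr, 3]
    corner_lin[, cr] <- ix + nn[1] * (iy - 1L + nn[2] * (iz - 1L))
  }
  used <- sort(unique(as.vector(corner_lin)))
  remap <- integer(prod(nn))
  remap[used] <- seq_along(used)
  elements <- matrix(remap[corner_lin], nrow(cells), 8)
  pos <- node_positions_um(grid)[used, , drop = FALSE]
  structure(list(nodes_um = pos, elements = elements, node_map = used,
                 grid = grid),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d hexahedra\n",
              nrow(x$nodes_um), nrow(x$elements)))
  invisible(x)
}

#' Apply a growth map to a hexahedral mesh as nodal displacements
#'
#' Pure kinematic application (no mechanics): every node is moved by the
#' map's mean displacement at the corresponding grid node. Connectivity is
#' unchanged.
#'
#' @param mesh A [grid_to_hexmesh()] result.
#' @param map A [growth_map()] (or [displacement_field()]) on the mesh's
#'   source grid.
#' @return The deformed `hex_mesh`.
#' @export
deform_mesh <- function(mesh, map) {
  g <- map$grid
  if (!identical(g$n_node, mesh$grid$n_node) || g$ns != mesh$grid$ns)
    stop("map grid does not match the mesh's source grid")
  u <- if (inherits(map, "growth_map")) map$mean_u else map$u
  if (max(mesh$node_map) > nrow(u)) stop("mesh references unmapped nodes")
  mesh$nodes_um <- mesh$nodes_um + u[mesh$node_map, , drop = FALSE]
  mesh
}

# Boundary quads: faces referenced by exactly one element, with their
# outward-ordered node ids.
boundary_quads <- function(mesh) {
  el <- mesh$elements
  nfaces <- nrow(el) * 6L
  quads <- matrix(0L, nfaces, 4)
  for (f in 1:6)
    quads[seq.int(f, nfaces, by = 6L), ] <- el[, hex_faces[f, ], drop = FALSE]
  key <- apply(quads, 1, function(q) paste(sort(q), collapse = "-"))
  tab <- table(key)
  quads[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Construct a surface point set
#'
#' @param points_um n x 3 matrix of points (um); duplicates within 1e-9 um
#'   are collapsed.
#' @param source `"undeformed"`, `"developmental"` or `"single"`.
#' @return Object of class `surface_point_set`.
#' @export
surface_point_set <- function(points_um,
                              source = c("undeformed", "developmental", "single")) {
  source <- match.arg(source)
  points_um <- matrix(points_um, ncol = 3)
  if (nrow(points_um) == 0L) stop("surface point set may not be empty")
  key <- apply(round(points_um / 1e-9), 1, paste, collapse = ",")
  points_um <- points_um[!duplicated(key), , drop = FALSE]
  structure(list(points_um = points_um, source = source),
            class = "surface_point_set")
}

#' @export
print.surface_point_set <- function(x, ...) {
  cat(sprintf("<surface_point_set> %d points (%s)\n", nrow(x$points_um), x$source))
  invisible(x)
}

#' Extract the surface nodes of a hexahedral mesh
#'
#' Nodes lying on boundary faces, i.e. faces referenced by exactly one
#' element.
#'
#' @param mesh A `hex_mesh`.
#' @param source Label stored on the resulting point set.
#' @return A [surface_point_set()].
#' @export
extract_surface_nodes <- function(mesh, source = "undeformed") {
  bq <- boundary_quads(mesh)
  ids <- sort(unique(as.vector(bq)))
  surface_point_set(mesh$nodes_um[ids, , drop = FALSE], source)
}

#' Write the boundary of a hexahedral mesh as a binary STL surface
#'
#' Each boundary quad is split into two triangles with consistent outward
#' orientation.
#'
#' @param mesh A `hex_mesh` with a non-empty boundary.
#' @param path Output `.stl` path.
#' @return `path`, invisibly.
#' @export
surface_to_stl <- function(mesh, path) {
  bq <- boundary_quads(mesh)
  if (nrow(bq) == 0L) stop("mesh has an empty boundary")
  tris <- rbind(bq[, c(1, 2, 3), drop = FALSE], bq[, c(1, 3, 4), drop = FALSE])
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "devomap hex boundary"))
  writeBin(hdr[1:80], con)
  writeBin(as.integer(nrow(tris)), con, size = 4, endian = "little")
  P <- mesh$nodes_um
  for (t in seq_len(nrow(tris))) {
    v1 <- P[tris[t, 1], ]; v2 <- P[tris[t, 2], ]; v3 <- P[tris[t, 3], ]
    nrm <- c((v2[2]-v1[2])*(v3[3]-v1[3]) - (v2[3]-v1[3])*(v3[2]-v1[2]),
             (v2[3]-v1[3])*(v3[1]-v1[1]) - (v2[1]-v1[1])*(v3[3]-v1[3]),
             (v2[1]-v1[1])*(v3[2]-v1[2]) - (v2[2]-v1[2])*(v3[1]-v1[1]))
    nl <- sqrt(sum(nrm^2))
    if (nl > 0) nrm <- nrm / nl
    writeBin(as.numeric(c(nrm, v1, v2, v3)), con, size = 4, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL surface
#'
#' @param path `.stl` path.
#' @return List with `n_triangles` and `vertices` (3 per triangle, n x 3).
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", size = 4, endian = "little")
  verts <- matrix(0, 3 * n, 3)
  for (t in seq_len(n)) {
    rec <- readBin(con, "double", n = 12, size = 4, endian = "little")
    verts[3 * t - 2, ] <- rec[4:6]
    verts[3 * t - 1, ] <- rec[7:9]
    verts[3 * t, ] <- rec[10:12]
    readBin(con, "integer", n = 1, size = 2, endian = "little")
  }
  list(n_triangles = n, vertices = verts)
}

#' Signed volume enclosed by a triangulated surface
#'
#' Positive for consistently outward-oriented closed surfaces.
#'
#' @param stl A [read_stl()] result.
#' @return Scalar volume (um^3).
#' @export
stl_signed_volume <- function(stl) {
  v <- stl$vertices
  n <- stl$n_triangles
  tot <- 0
  for (t in seq_len(n)) {
    a <- v[3 * t - 2, ]; b <- v[3 * t - 1, ]; ce <- v[3 * t, ]
    tot <- tot + (a[1] * (b[2] * ce[3] - b[3] * ce[2]) -
                  a[2] * (b[1] * ce[3] - b[3] * ce[1]) +
                  a[3] * (b[1] * ce[2] - b[2] * ce[1])) / 6
  }
  tot
}

#' Export a hexahedral mesh (plus optional vector field) as legacy VTK
#'
#' ASCII legacy unstructured-grid file; node displacements can be attached as
#' a point-data vector field for external visualisation.
#'
#' @param mesh A `hex_mesh`.
#' @param path Output `.vtk` path.
#' @param point_vectors Optional n x 3 matrix (e.g. node displacements, um).
#' @param vectors_name Name of the vector field in the file.
#' @return `path`, invisibly.
#' @export
write_vtk_hexmesh <- function(mesh, path, point_vectors = NULL,
                              vectors_name = "displacement_um") {
  np <- nrow(mesh$nodes_um); ne <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "devomap hexahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", np)), con)
  writeLines(apply(mesh$nodes_um, 1, function(p)
    sprintf("%.6g %.6g %.6g", p[1], p[2], p[3])), con)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9L), con)
  writeLines(apply(mesh$elements - 1L, 1, function(e)
    paste(c(8L, e), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  if (!is.null(point_vectors)) {
    writeLines(sprintf("POINT_DATA %d", np), con)
    writeLines(sprintf("VECTORS %s float", vectors_name), con)
    writeLines(apply(matrix(point_vectors, ncol = 3), 1, function(p)
      sprintf("%.6g %.6g %.6g", p[1], p[2], p[3])), con)
  }
  invisible(path)
}
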