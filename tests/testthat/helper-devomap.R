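# Shared fixtures and brute-force oracles, all built in code.

VS <- 14.63  # reference voxel size, um

ramp_volume <- function(dims = c(4, 4, 4), vs = 1) {
  volume_image(array(seq_len(prod(dims)), dims), vs)
}

# A small, fast phantom: 32^3 lattice with growth amplitudes scaled to the
# lattice (same voxel proportions as the 48^3 default).
small_spec <- function(...) {
  phantom_spec(dims = c(32, 32, 32), g_c = 80, g_n = 32, ...)
}

# brute-force 6/26-connected erosion (voxel loop; outside = background)
brute_erode <- function(m, conn = 6) {
  d <- dim(m)
  out <- array(FALSE, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (conn == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    keep <- TRUE
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3] ||
          !m[ii, jj, kk]) { keep <- FALSE; break }
    }
    out[i, j, k] <- keep
  }
  out
}

# all-pairs nearest-neighbour distances (the metric oracle)
brute_nn <- function(A, B) {
  D2 <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2 +
    outer(A[, 3], B[, 3], `-`)^2
  sqrt(apply(D2, 1, min))
}

# brute-force boundary-face extraction: for every face of every element,
# count how many elements share it by exhaustive pairwise comparison
brute_boundary_nodes <- function(mesh) {
  faces_of <- function(el) {
    lapply(1:6, function(f) sort(el[devomap:::hex_faces[f, ]]))
  }
  all_faces <- do.call(c, lapply(seq_len(nrow(mesh$elements)), function(e)
    faces_of(mesh$elements[e, ])))
  keys <- vapply(all_faces, paste, "", collapse = "-")
  counts <- table(keys)
  boundary <- all_faces[keys %in% names(counts)[counts == 1]]
  sort(unique(unlist(boundary)))
}

# brute-force valid-cell count for filter_cells: node g sits at voxel
# coordinate g * ns - pad (centred overhang); "inside" = nearest voxel is
# foreground, nodes off the image count as outside
brute_valid_cells <- function(dims, ns, mask_arr) {
  grid <- registration_grid(dims, ns)
  nn <- grid$n_node
  nc <- pmax(nn - 1, 1)
  count <- 0L
  for (ci in seq_len(nc[1])) for (cj in seq_len(nc[2])) for (ck in seq_len(nc[3])) {
    any_in <- FALSE
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      vi <- round((ci - 1L + dx) * ns - grid$pad[1]) + 1L
      vj <- round((cj - 1L + dy) * ns - grid$pad[2]) + 1L
      vk <- round((ck - 1L + dz) * ns - grid$pad[3]) + 1L
      if (vi >= 1L && vj >= 1L && vk >= 1L &&
          vi <= dims[1] && vj <= dims[2] && vk <= dims[3] &&
          mask_arr[vi, vj, vk]) any_in <- TRUE
    }
    if (any_in) count <- count + 1L
  }
  count
}

random_point_set <- function(n, scale = 100) {
  matrix(runif(3 * n, 0, scale), n, 3)
}
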