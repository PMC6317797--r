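#' Isotropic registration grid over an image lattice
#'
#' Nodes sit at voxel-centre positions `origin_um + (index * ns) *
#' voxel_size_um` (0-based node indices); adjacent nodes bound 8-node
#' hexahedral cells. The grid always covers the image: the node extent per
#' axis is `ceil((dim - 1) / ns) + 1`, so every voxel lies inside a cell.
#'
#' @param dims Image dimensions (voxels).
#' @param ns Nodal spacing NS in voxels (positive integer).
#' @param voxel_size_um Voxel size (um).
#' @param origin_um Image origin (um).
#' @return Object of class `registration_grid` with fields `ns`, `dims`,
#'   `n_node` (3-vector), `voxel_size_um`, `origin_um` and the logical
#'   `cell_valid` array of dimension `n_node - 1`.
#' @export
registration_grid <- function(dims, ns, voxel_size_um = 1, origin_um = c(0, 0, 0)) {
  ns <- as.integer(ns)
  if (ns < 1L) stop("nodal spacing must be >= 1 voxel")
  dims <- as.integer(dims)
  n_node <- as.integer(ceiling((dims - 1L) / ns) + 1L)
  # centre the grid on the image: any overhang of the node extent beyond the
  # image is split equally between the two faces of each axis, so boundary
  # effects are symmetric (pad = 0 whenever ns divides dims - 1, e.g. NS = 1)
  pad <- ((n_node - 1L) * ns - (dims - 1L)) / 2
  structure(list(
    ns = ns, dims = dims, n_node = n_node, pad = pad,
    voxel_size_um = voxel_size_um, origin_um = as.numeric(origin_um),
    cell_valid = array(TRUE, pmax(n_node - 1L, 1L))
  ), class = "registration_grid")
}

#' @export
print.registration_grid <- function(x, ...) {
  cat(sprintf("<registration_grid> NS = %d voxel(s), %dx%dx%d nodes, %d/%d valid cells\n",
              x$ns, x$n_node[1], x$n_node[2], x$n_node[3],
              sum(x$cell_valid), length(x$cell_valid)))
  invisible(x)
}

#' Node positions of a registration grid
#'
#' @param grid A [registration_grid()].
#' @return `prod(n_node)` x 3 matrix of positions (um), in array (x-fastest)
#'   node order.
#' @export
node_positions_um <- function(grid) {
  g <- as.matrix(expand.grid(x = 0:(grid$n_node[1] - 1L),
                             y = 0:(grid$n_node[2] - 1L),
                             z = 0:(grid$n_node[3] - 1L)))
  vox <- sweep(g * grid$ns, 2, grid$pad)
  out <- sweep(vox * grid$voxel_size_um, 2, grid$origin_um, `+`)
  dimnames(out) <- NULL
  out
}

#' Displacement field on a registration grid
#'
#' @param grid A [registration_grid()].
#' @param u `prod(n_node)` x 3 matrix of node displacements (um), defined at
#'   early-stage node positions and pointing toward the late-stage
#'   configuration.
#' @param intensity_offset Per-node scalar gray-value offset.
#' @param quality Final NMI of the warped pair.
#' @param converged Logical.
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(grid, u, intensity_offset = NULL,
                               quality = NA_real_, converged = NA) {
  u <- matrix(u, ncol = 3)
  if (nrow(u) != prod(grid$n_node)) stop("u must have one row per grid node")
  if (any(!is.finite(u))) stop("displacements must be finite")
  if (is.null(intensity_offset)) intensity_offset <- numeric(nrow(u))
  structure(list(grid = grid, u = u,
                 intensity_offset = as.numeric(intensity_offset),
                 quality = quality, converged = converged),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(rowSums(x$u^2))
  cat(sprintf("<displacement_field> NS = %d, %d nodes, |u| max %.3f um, NMI %.4f\n",
              x$grid$ns, nrow(x$u), max(mag), x$quality))
  invisible(x)
}

# Graph Laplacian (6-neighbour) on the node lattice, positive semi-definite,
# row sums zero (constant fields are unpenalised).
node_laplacian <- function(n_node) {
  nn <- prod(n_node)
  id <- array(seq_len(nn), n_node)
  ii <- integer(0); jj <- integer(0)
  for (ax in 1:3) {
    if (n_node[ax] < 2L) next
    idxa <- lapply(seq_along(n_node), function(a) seq_len(n_node[a]))
    idxb <- idxa
    idxa[[ax]] <- seq_len(n_node[ax] - 1L)
    idxb[[ax]] <- 2:n_node[ax]
    a <- as.vector(id[idxa[[1]], idxa[[2]], idxa[[3]]])
    b <- as.vector(id[idxb[[1]], idxb[[2]], idxb[[3]]])
    ii <- c(ii, a, b); jj <- c(jj, b, a)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nn, nn))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

# Coarse-to-fine nodal-spacing schedule: start at the largest power of two
# <= min(dims)/4 ("a few times smaller than the image size"), halve per level
# down to the requested fine spacing.
ns_schedule <- function(dims, ns) {
  start <- 2^floor(log2(max(min(dims) / 4, 1)))
  start <- max(start, ns)
  sched <- integer(0)
  s <- start
  while (s > ns) { sched <- c(sched, s); s <- s %/% 2 }
  c(sched, ns)
}

# Trilinear transfer of node values (matrix, one column per component) from a
# coarse grid to a finer one on the same image lattice.
upsample_nodes <- function(vals, grid_coarse, grid_fine) {
  nn_c <- grid_coarse$n_node
  out <- matrix(0, prod(grid_fine$n_node), ncol(vals))
  g <- as.matrix(expand.grid(x = 0:(grid_fine$n_node[1] - 1L),
                             y = 0:(grid_fine$n_node[2] - 1L),
                             z = 0:(grid_fine$n_node[3] - 1L)))
  vox <- sweep(g * grid_fine$ns, 2, grid_fine$pad)  # fine nodes, voxel units
  pts <- sweep(vox, 2, grid_coarse$pad, `+`) / grid_coarse$ns
  pts[, 1] <- pmin(pmax(pts[, 1], 0), nn_c[1] - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), nn_c[2] - 1)
  pts[, 3] <- pmin(pmax(pts[, 3], 0), nn_c[3] - 1)
  for (cmp in seq_len(ncol(vals)))
    out[, cmp] <- cpp_sample_trilinear(array(vals[, cmp], nn_c), nn_c, pts)
  out
}

check_same_lattice <- function(a, b) {
  la <- lattice_of(a); lb <- lattice_of(b)
  if (!identical(la$dims, lb$dims) ||
      abs(la$voxel_size_um - lb$voxel_size_um) > 1e-9 ||
      max(abs(la$origin_um - lb$origin_um)) > 1e-6)
    stop("images must share the same lattice (shape, voxel size, origin)")
  invisible(TRUE)
}

#' Grid-based deformable registration with intensity offset
#'
#' Computes node displacements mapping an early-stage image onto a late-stage
#' image on the same lattice. At each level of a coarse-to-fine nodal-spacing
#' schedule the solver iterates: warp the early image by the current field
#' (trilinear displacement interpolation between nodes, Lanczos-3 image
#' sampling), linearise the intensity-matching residual
#' `late(x) - early(x + u(x)) - c(x)` in per-node updates
#' `(du_x, du_y, du_z, dc)` with trilinear basis functions, add a Laplacian
#' smoothness penalty on each displacement component and on the intensity
#' offset `c`, and solve the sparse normal equations. Between levels the field
#' is transferred by trilinear interpolation. Intensities are normalised to
#' unit dynamic range internally, so `lambda_s` is comparable across images.
#'
#' Iterations stop when the largest node update falls below `tol_voxel` or
#' `max_iter` is reached; per level the field with the best NMI seen
#' (including the level's starting field) is kept, so the reported quality
#' never decreases across a level.
#'
#' @param early,late [volume_image()] objects on one lattice.
#' @param ns Fine nodal spacing NS in voxels (default 1, the protocol value).
#' @param lambda_s Smoothness weight (default 50), in units where the data
#'   term is scaled to its mean diagonal; see the methods vignette.
#' @param schedule Optional integer vector of nodal spacings (coarse to
#'   fine); default as described above.
#' @param max_iter Iteration cap per level (default 50).
#' @param tol_voxel Convergence tolerance on the max node update (default
#'   0.01 voxel).
#' @param offset_penalty_factor Multiplier on the smoothness weight of the
#'   intensity-offset component (default 50000): the offset field may only
#'   vary on a much coarser scale than the displacements, otherwise it could
#'   absorb residuals that are really motion.
#' @param domain_mask Optional [binary_mask()]: the intensity-matching data
#'   term is restricted to these voxels (the protocol feeds the late-stage
#'   binary image into the solver; see [registration_domain()]). Voxels
#'   outside contribute neither residual nor gradient, so empty background
#'   cannot drive the field.
#' @param verbose Print per-iteration diagnostics.
#' @return A [displacement_field()] at spacing `ns` (displacements in um),
#'   with `quality` = final NMI and `converged` flag.
#' @export
register_deformable <- function(early, late, ns = 1L, lambda_s = 50,
                                schedule = NULL, max_iter = 50L,
                                tol_voxel = 0.01, offset_penalty_factor = 50000,
                                domain_mask = NULL, verbose = FALSE) {
  check_same_lattice(early, late)
  dims <- dim(early$intensities)
  dom <- if (is.null(domain_mask)) NULL else {
    if (!identical(dim(domain_mask$voxels), dims))
      stop("domain mask lattice does not match the images")
    as.numeric(domain_mask$voxels)
  }
  rng <- range(c(early$intensities, late$intensities))
  if (rng[2] - rng[1] <= 0)
    stop("no intensity gradient information (constant images)")
  e <- (early$intensities - rng[1]) / (rng[2] - rng[1])
  l <- (late$intensities - rng[1]) / (rng[2] - rng[1])
  if (max(abs(e - mean(e))) < 1e-12 || max(abs(l - mean(l))) < 1e-12)
    stop("no intensity gradient information (constant images)")
  lvec <- as.numeric(l)
  if (is.null(schedule)) schedule <- ns_schedule(dims, ns)
  schedule <- as.integer(schedule)
  if (any(diff(schedule) >= 0) && length(schedule) > 1)
    stop("schedule must be strictly decreasing")
  if (schedule[length(schedule)] != ns)
    stop("schedule must end at the requested nodal spacing")

  grid <- NULL; u <- NULL; cc <- NULL
  converged_all <- TRUE
  quality <- NA_real_
  # each nodal spacing runs a pass on images pre-smoothed proportionally to
  # the spacing (sigma = NS/2, enlarging the capture range), then the finest
  # spacing a final pass at sigma = 1. The final pass is not run unsmoothed:
  # warping interpolates (and thereby smooths) the moving image, so on noisy
  # data any off-lattice displacement lowers the raw SSD - a pure
  # interpolation artifact that drags the field; a light common blur makes
  # the two images' smoothing comparable and removes the reward.
  passes <- data.frame(ns = rep(schedule, each = 2),
                       sigma = as.numeric(rbind(schedule, schedule / 2)))
  passes <- rbind(passes, data.frame(ns = schedule[length(schedule)], sigma = 1))
  passes <- passes[!duplicated(passes), , drop = FALSE]
  for (lev in seq_len(nrow(passes))) {
    ns_l <- passes$ns[lev]
    sigma_l <- passes$sigma[lev]
    e_l <- if (sigma_l > 0) cpp_gaussian_blur(e, dims, sigma_l) else e
    l_l <- if (sigma_l > 0) cpp_gaussian_blur(l, dims, sigma_l) else l
    lvec_l <- as.numeric(l_l)
    g_late <- cpp_gradient(l_l, dims)
    grid_l <- registration_grid(dims, ns_l, early$voxel_size_um, early$origin_um)
    nn <- prod(grid_l$n_node)
    if (is.null(grid)) {
      u <- matrix(0, nn, 3); cc <- numeric(nn)
    } else {
      u <- upsample_nodes(u, grid, grid_l)
      cc <- as.numeric(upsample_nodes(matrix(cc, ncol = 1), grid, grid_l))
    }
    grid <- grid_l
    L <- node_laplacian(grid$n_node)

    warp_state <- function(u_, cc_) {
      w <- cpp_warp_by_node_field(e_l, dims, u_, grid$n_node, ns_l, grid$pad,
                                  TRUE)
      c_vox <- cpp_dense_field_from_nodes(matrix(cc_, ncol = 1), grid$n_node,
                                          ns_l, grid$pad, dims)
      r <- lvec_l - as.numeric(w) - as.numeric(c_vox)
      if (!is.null(dom)) r <- r * dom
      nmi <- if (is.null(dom))
        cpp_nmi(as.numeric(w), lvec_l, 32L, 0, 1, 0, 1)
      else
        cpp_nmi(as.numeric(w)[dom > 0], lvec_l[dom > 0], 32L, 0, 1, 0, 1)
      list(w = w, r = r, ssd = sum(r * r), nmi = nmi)
    }
    penalty_value <- function(u_, cc_, alpha, alpha_c) {
      rough <- sum(vapply(1:3, function(m)
        sum(u_[, m] * as.numeric(L %*% u_[, m])), 0))
      alpha * rough + alpha_c * sum(cc_ * as.numeric(L %*% cc_))
    }
    st <- warp_state(u, cc)
    best <- list(u = u, cc = cc, nmi = st$nmi)
    converged <- FALSE
    plateau <- 0L
    for (it in seq_len(max_iter)) {
      # symmetric (ESM-style) gradient: average of the warped-early and
      # late-image gradients; improves the linearisation near the optimum
      gw <- cpp_gradient(st$w, dims)
      gx <- (gw$gx + g_late$gx) / 2
      gy <- (gw$gy + g_late$gy) / 2
      gz <- (gw$gz + g_late$gz) / 2
      if (!is.null(dom)) { gx <- gx * dom; gy <- gy * dom; gz <- gz * dom }
      sys <- cpp_assemble_system(dims, grid$n_node, ns_l, grid$pad,
                                 gx, gy, gz, st$r)
      N <- Matrix::sparseMatrix(i = sys$i, j = sys$j, x = sys$x,
                                dims = c(4 * nn, 4 * nn))
      dscale <- mean(Matrix::diag(N)[1:(3 * nn)])
      if (!is.finite(dscale) || dscale <= 0) dscale <- 1
      alpha <- lambda_s * dscale / 500
      # the offset penalty is tied to the data scale, not to lambda_s, so
      # weak displacement smoothing cannot free the offset field
      alpha_c <- offset_penalty_factor * dscale / 500
      P <- Matrix::bdiag(alpha * L, alpha * L, alpha * L, alpha_c * L)
      state <- c(u[, 1], u[, 2], u[, 3], cc)
      rhs <- sys$rhs - as.numeric(P %*% state)
      N <- N + P + Matrix::Diagonal(4 * nn, x = 1e-8 * max(Matrix::diag(N)))
      delta <- tryCatch({
        ch <- Matrix::Cholesky(Matrix::forceSymmetric(N), LDL = FALSE,
                               super = TRUE)
        as.numeric(Matrix::solve(ch, rhs))
      }, error = function(err)
        stop("no intensity gradient information (singular system): ",
             conditionMessage(err)))
      du <- cbind(delta[1:nn], delta[nn + 1:nn], delta[2 * nn + 1:nn])
      dc <- delta[3 * nn + 1:nn]
      # trust region: keep the proposed node motion within one nodal spacing
      # so the local linearisation stays meaningful
      mx <- max(abs(du))
      if (mx > ns_l) { du <- du * (ns_l / mx); dc <- dc * (ns_l / mx) }
      # backtracking line search on the penalised SSD objective; plain
      # Gauss-Newton overshoots when the residual is large
      f_curr <- st$ssd + penalty_value(u, cc, alpha, alpha_c)
      accepted <- FALSE
      for (s in 2^-(0:6)) {
        u_try <- u + s * du
        cc_try <- cc + s * dc
        st_try <- warp_state(u_try, cc_try)
        if (st_try$ssd + penalty_value(u_try, cc_try, alpha, alpha_c) < f_curr) {
          u <- u_try; cc <- cc_try; st <- st_try
          step <- s * max(abs(du))
          accepted <- TRUE
          break
        }
      }
      if (!accepted) { converged <- TRUE; break }   # stalled: local optimum
      if (st$nmi > best$nmi) best <- list(u = u, cc = cc, nmi = st$nmi)
      f_new <- st$ssd + penalty_value(u, cc, alpha, alpha_c)
      rel <- (f_curr - f_new) / max(f_curr, 1e-300)
      if (verbose)
        message(sprintf("NS=%d it=%d step=%.3g max|du|=%.4f vox NMI=%.5f rel=%.2e",
                        ns_l, it, s, step, st$nmi, rel))
      if (step < tol_voxel) { converged <- TRUE; break }
      # objective plateau: remaining iterations polish the field by far less
      # than the stated tolerance; stop after two negligible improvements
      plateau <- if (rel < 1e-4) plateau + 1L else 0L
      if (plateau >= 2L) { converged <- TRUE; break }
    }
    u <- best$u; cc <- best$cc
    quality <- best$nmi
    converged_all <- converged_all && converged
  }
  # final quality on the original (unsmoothed) pair
  w_fin <- cpp_warp_by_node_field(e, dims, u, grid$n_node,
                                  schedule[length(schedule)], grid$pad, TRUE)
  quality <- if (is.null(dom))
    cpp_nmi(as.numeric(w_fin), as.numeric(l), 32L, 0, 1, 0, 1)
  else
    cpp_nmi(as.numeric(w_fin)[dom > 0], as.numeric(l)[dom > 0], 32L, 0, 1, 0, 1)
  u_fwd <- pullback_to_forward(u, grid)
  displacement_field(grid, u_fwd * early$voxel_size_um,
                     intensity_offset = cc * (rng[2] - rng[1]),
                     quality = quality, converged = converged_all)
}

# The solver works with the pull-back field u_pb: late(x) = early(x + u_pb(x)).
# The stored field is the forward early->late displacement at the early node
# positions y: u_fwd(y) = x - y where x solves x + u_pb(x) = y (fixed-point
# iteration; converges for |grad u_pb| < 1, i.e. non-folding mappings).
pullback_to_forward <- function(u_pb, grid, n_iter = 20L) {
  nn <- grid$n_node
  Y <- sweep(as.matrix(expand.grid(x = 0:(nn[1] - 1L), y = 0:(nn[2] - 1L),
                                   z = 0:(nn[3] - 1L))) * grid$ns,
             2, grid$pad)                                     # voxel units
  X <- Y
  interp_u <- function(P) {
    G <- sweep(P, 2, grid$pad, `+`) / grid$ns
    G[, 1] <- pmin(pmax(G[, 1], 0), nn[1] - 1)
    G[, 2] <- pmin(pmax(G[, 2], 0), nn[2] - 1)
    G[, 3] <- pmin(pmax(G[, 3], 0), nn[3] - 1)
    vapply(1:3, function(m)
      cpp_sample_trilinear(array(u_pb[, m], nn), nn, G), numeric(nrow(P)))
  }
  for (it in seq_len(n_iter)) X <- Y - interp_u(X)
  X - Y
}

#' Interpolate a displacement field at arbitrary points
#'
#' Trilinear interpolation of the node displacements within the containing
#' cell.
#'
#' @param field A [displacement_field()].
#' @param points_um n x 3 matrix of positions (um) inside the grid extent.
#' @return n x 3 matrix of displacements (um).
#' @export
interpolate_displacement <- function(field, points_um) {
  grid <- field$grid
  points_um <- matrix(points_um, ncol = 3)
  gcoord <- sweep(sweep(points_um, 2, grid$origin_um) / grid$voxel_size_um,
                  2, grid$pad, `+`) / grid$ns
  lo_ok <- gcoord >= -1e-9
  hi_ok <- sweep(gcoord, 2, grid$n_node - 1) <= 1e-9
  bad <- which(!(apply(lo_ok & hi_ok, 1, all)))
  if (length(bad))
    stop(sprintf("point(s) outside grid extent: %s",
                 paste(apply(points_um[bad, , drop = FALSE], 1,
                             function(p) sprintf("(%.6g, %.6g, %.6g)",
                                                 p[1], p[2], p[3])),
                       collapse = "; ")))
  gcoord <- pmin(pmax(gcoord, 0), matrix(grid$n_node - 1, nrow(gcoord), 3,
                                         byrow = TRUE))
  out <- matrix(0, nrow(points_um), 3)
  for (cmp in 1:3)
    out[, cmp] <- cpp_sample_trilinear(array(field$u[, cmp], grid$n_node),
                                       grid$n_node, gcoord)
  out
}

# Nodes incident to at least one valid cell (logical, array node order).
nodes_of_valid_cells <- function(grid) {
  nn <- grid$n_node
  keep <- array(FALSE, nn)
  cv <- grid$cell_valid
  nc <- dim(cv)
  w <- which(cv, arr.ind = TRUE)
  if (nrow(w) == 0L) return(keep)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    idx <- cbind(w[, 1] + dx, w[, 2] + dy, w[, 3] + dz)
    keep[idx] <- TRUE
  }
  keep
}

#' Per-axis precision of a displacement field from repeated scans
#'
#' The population standard deviation of the node displacement components over
#' all nodes of valid cells — the zero-displacement analysis applied to a
#' registration of two repeated scans of one specimen.
#'
#' @param field_repeat A [displacement_field()] computed from a repeated-scan
#'   pair.
#' @return Named numeric 3-vector `c(SD_x, SD_y, SD_z)` in um.
#' @export
displacement_precision <- function(field_repeat) {
  keep <- as.vector(nodes_of_valid_cells(field_repeat$grid))
  u <- field_repeat$u[keep, , drop = FALSE]
  n <- nrow(u)
  if (n == 0L) return(c(SD_x = 0, SD_y = 0, SD_z = 0))
  sds <- sqrt(colMeans(sweep(u, 2, colMeans(u))^2))   # population SD
  c(SD_x = sds[1], SD_y = sds[2], SD_z = sds[3])
}

#' Roughness of a displacement field
#'
#' Sum of the squared discrete node-lattice Laplacian over the three
#' displacement components; used to verify that stronger smoothing yields
#' smoother fields.
#'
#' @param field A [displacement_field()].
#' @return Non-negative scalar (um^2).
#' @export
field_roughness <- function(field) {
  L <- node_laplacian(field$grid$n_node)
  sum(vapply(1:3, function(cmp) sum(as.numeric(L %*% field$u[, cmp])^2), 0))
}
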