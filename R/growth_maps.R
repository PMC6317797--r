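#' Group of specimens of one anatomical site and stage
#'
#' Members must all live on one common lattice (the shared bounding box after
#' rigid registration and resampling).
#'
#' @param site `"tibia_proximal"` or `"femur_distal"`.
#' @param stage `"TS23"` or `"TS24"`.
#' @param members Named list; each element a list with fields `image`
#'   ([volume_image()]) and `mask` ([binary_mask()] or `NULL`).
#' @return Object of class `specimen_group`.
#' @export
specimen_group <- function(site = c("tibia_proximal", "femur_distal"),
                           stage = c("TS23", "TS24"), members) {
  site <- match.arg(site); stage <- match.arg(stage)
  if (length(members) == 0L) stop("specimen group may not be empty")
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stop("members must be a named list of specimens")
  ref <- lattice_of(members[[1]]$image)
  for (m in members) {
    l <- lattice_of(m$image)
    if (!identical(l$dims, ref$dims) ||
        abs(l$voxel_size_um - ref$voxel_size_um) > 1e-9 ||
        max(abs(l$origin_um - ref$origin_um)) > 1e-6)
      stop("all members of a specimen group must share one lattice")
  }
  structure(list(site = site, stage = stage, members = members),
            class = "specimen_group")
}

#' @export
print.specimen_group <- function(x, ...) {
  cat(sprintf("<specimen_group> %s %s, %d specimens: %s\n", x$site, x$stage,
              length(x$members), paste(names(x$members), collapse = ", ")))
  invisible(x)
}

#' Remove grid cells entirely outside the early-stage mask
#'
#' A node is "inside" when its voxel-centre position falls on a foreground
#' voxel of the mask; a cell is kept unless all 8 of its nodes are outside.
#' Nodes beyond the image extent (grids overhang by less than one spacing)
#' count as outside.
#'
#' @param grid A [registration_grid()].
#' @param early_mask A [binary_mask()] on the grid's image lattice.
#' @return The grid with `cell_valid` updated (combined with any existing
#'   invalid flags).
#' @export
filter_cells <- function(grid, early_mask) {
  if (!identical(dim(early_mask$voxels), grid$dims))
    stop("mask lattice does not match the grid's image lattice")
  nn <- grid$n_node
  node_inside <- array(FALSE, nn)
  gx <- round((0:(nn[1] - 1L)) * grid$ns - grid$pad[1])
  gy <- round((0:(nn[2] - 1L)) * grid$ns - grid$pad[2])
  gz <- round((0:(nn[3] - 1L)) * grid$ns - grid$pad[3])
  okx <- gx >= 0 & gx <= grid$dims[1] - 1L
  oky <- gy >= 0 & gy <= grid$dims[2] - 1L
  okz <- gz >= 0 & gz <= grid$dims[3] - 1L
  sub <- early_mask$voxels[gx[okx] + 1L, gy[oky] + 1L, gz[okz] + 1L, drop = FALSE]
  node_inside[which(okx), which(oky), which(okz)] <- sub
  nc <- pmax(nn - 1L, 1L)
  any_inside <- array(FALSE, nc)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    any_inside <- any_inside |
      node_inside[(1:nc[1]) + dx, (1:nc[2]) + dy, (1:nc[3]) + dz, drop = FALSE]
  grid$cell_valid <- grid$cell_valid & any_inside
  grid
}

#' Enumerate early/late registration pairs
#'
#' Full cross product of the early members (minus the excluded control, when
#' building a developmental map) with all late members, in lexicographic
#' order of specimen ids.
#'
#' @param early,late [specimen_group()] objects.
#' @param exclude_control Specimen id to drop from the early group, or `NULL`.
#' @return Data frame with columns `early_id`, `late_id`.
#' @export
enumerate_pairs <- function(early, late, exclude_control = NULL) {
  eids <- sort(names(early$members))
  lids <- sort(names(late$members))
  if (!is.null(exclude_control)) {
    if (!exclude_control %in% eids)
      stop("control specimen '", exclude_control, "' not in the early group")
    eids <- setdiff(eids, exclude_control)
  }
  if (length(eids) == 0L || length(lids) == 0L)
    stop("specimen groups must be non-empty")
  out <- expand.grid(late_id = lids, early_id = eids,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("early_id", "late_id")]
  out[order(out$early_id, out$late_id), , drop = FALSE]
}

#' Averaged growth map (developmental or single)
#'
#' @param grid A [registration_grid()] (the control specimen's, filtered).
#' @param mean_u Per-node mean displacement (um), `prod(n_node)` x 3.
#' @param n_contributing Number of averaged pairwise fields K.
#' @param kind `"developmental"` or `"single"`.
#' @param site Anatomical site label.
#' @return Object of class `growth_map`.
#' @export
growth_map <- function(grid, mean_u, n_contributing,
                       kind = c("developmental", "single"),
                       site = "tibia_proximal") {
  kind <- match.arg(kind)
  mean_u <- matrix(mean_u, ncol = 3)
  if (nrow(mean_u) != prod(grid$n_node))
    stop("mean_u must have one row per grid node")
  structure(list(grid = grid, mean_u = mean_u,
                 n_contributing = as.integer(n_contributing),
                 kind = kind, site = site),
            class = "growth_map")
}

#' @export
print.growth_map <- function(x, ...) {
  keep <- as.vector(nodes_of_valid_cells(x$grid))
  mag <- sqrt(rowSums(x$mean_u[keep, , drop = FALSE]^2))
  cat(sprintf("<growth_map> %s %s, K = %d, %d valid nodes, |u| mean %.1f / max %.1f um\n",
              x$kind, x$site, x$n_contributing, sum(keep),
              if (length(mag)) mean(mag) else NA, if (length(mag)) max(mag) else NA))
  invisible(x)
}

#' Average displacement fields into a growth map
#'
#' Node-wise arithmetic mean of the displacement components over K fields on
#' one lattice and nodal spacing. Validity follows the intersection rule: a
#' cell of the result is valid only where it is valid in all contributing
#' fields, so every averaged node is supported by all K registrations. Set
#' `validity = "union"` for the union alternative.
#'
#' @param fields List of [displacement_field()] objects.
#' @param kind `"developmental"` or `"single"`.
#' @param site Site label.
#' @param validity `"intersection"` (default) or `"union"`.
#' @return A [growth_map()] with `n_contributing = length(fields)`.
#' @export
average_fields <- function(fields, kind = c("developmental", "single"),
                           site = "tibia_proximal",
                           validity = c("intersection", "union")) {
  kind <- match.arg(kind); validity <- match.arg(validity)
  if (length(fields) == 0L) stop("no fields to average")
  g0 <- fields[[1]]$grid
  for (f in fields) {
    g <- f$grid
    if (!identical(g$dims, g0$dims) || g$ns != g0$ns ||
        abs(g$voxel_size_um - g0$voxel_size_um) > 1e-9 ||
        max(abs(g$origin_um - g0$origin_um)) > 1e-6)
      stop("all fields must share one lattice and nodal spacing")
  }
  mean_u <- Reduce(`+`, lapply(fields, `[[`, "u")) / length(fields)
  cv <- lapply(fields, function(f) f$grid$cell_valid)
  valid <- if (validity == "intersection") Reduce(`&`, cv) else Reduce(`|`, cv)
  if (!any(valid)) stop("empty intersection of valid cells")
  grid <- g0
  grid$cell_valid <- valid
  growth_map(grid, mean_u, length(fields), kind, site)
}

#' Build the developmental and single maps of one anatomical site
#'
#' Runs all pairwise deformable registrations (every early specimen against
#' every late specimen), filters each field's grid against its own
#' early-stage mask, and averages: the developmental map over the
#' `(early - control) x late` fields and the single map over the
#' `control x late` fields. Both maps are expressed on the control specimen's
#' filtered grid (all specimens share one lattice, so the grids coincide
#' node-for-node; validity is intersected with the control's).
#'
#' @param early,late [specimen_group()] objects on one common lattice; early
#'   members must carry masks.
#' @param control_id Id of the held-out early control specimen.
#' @param ns,lambda_s,schedule,max_iter,tol_voxel Passed to
#'   [register_deformable()].
#' @param validity Cell-validity combination rule, see [average_fields()].
#' @param verbose Print progress.
#' @return List with `developmental` and `single` [growth_map()]s, the list
#'   of pairwise `fields` (named `"early->late"`), and the pair table.
#' @export
build_site_maps <- function(early, late, control_id, ns = 1L, lambda_s = 50,
                            schedule = NULL, max_iter = 50L, tol_voxel = 0.01,
                            validity = "intersection", verbose = FALSE) {
  if (!control_id %in% names(early$members))
    stop("control specimen '", control_id, "' not found in the early group")
  pairs <- enumerate_pairs(early, late)
  fields <- vector("list", nrow(pairs))
  names(fields) <- paste0(pairs$early_id, "->", pairs$late_id)
  for (r in seq_len(nrow(pairs))) {
    em <- early$members[[pairs$early_id[r]]]
    lm <- late$members[[pairs$late_id[r]]]
    if (verbose) message("registering ", names(fields)[r])
    dom <- if (!is.null(em$mask))
      registration_domain(em$mask, lm$mask) else NULL
    f <- register_deformable(em$image, lm$image, ns = ns, lambda_s = lambda_s,
                             schedule = schedule, max_iter = max_iter,
                             tol_voxel = tol_voxel, domain_mask = dom)
    if (!is.null(em$mask)) f$grid <- filter_cells(f$grid, em$mask)
    fields[[r]] <- f
  }
  site <- early$site
  dev_idx <- pairs$early_id != control_id
  sgl_idx <- pairs$early_id == control_id
  developmental <- average_fields(fields[dev_idx], "developmental", site, validity)
  single <- average_fields(fields[sgl_idx], "single", site, validity)
  ctrl_mask <- early$members[[control_id]]$mask
  if (!is.null(ctrl_mask)) {
    ctrl_grid <- filter_cells(registration_grid(developmental$grid$dims, ns,
                                                developmental$grid$voxel_size_um,
                                                developmental$grid$origin_um),
                              ctrl_mask)
    developmental$grid$cell_valid <- developmental$grid$cell_valid & ctrl_grid$cell_valid
    single$grid$cell_valid <- single$grid$cell_valid & ctrl_grid$cell_valid
  }
  list(developmental = developmental, single = single, fields = fields,
       pairs = pairs)
}
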