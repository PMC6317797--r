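#' Specification of the synthetic rudiment phantom
#'
#' The phantom emulates an epiphysis imaged at two developmental stages: a
#' smooth two-lobed soft body (a base ellipsoid united with two condylar
#' lobes, minus an intercondylar notch), Gaussian-blurred with additive
#' Gaussian noise, and an analytic smooth growth field whose amplitude peaks
#' at the condyle apices (`g_c`) and decays to the intercondylar notch
#' (`g_n`), with `g_c > g_n`. The default amplitudes (150 and 60 um) match
#' the magnitudes reported for the proximal tibia; use
#' `g_c = 160, g_n = 80` for the distal-femur preset.
#'
#' @param dims Lattice shape, default `c(48, 48, 48)` voxels.
#' @param voxel_size_um Isotropic voxel size, default 14.63 um.
#' @param base_semiaxes Base ellipsoid semi-axes (voxels).
#' @param condyle_offset Lobe centre offset from the body centre (voxels),
#'   applied at `+x` and `-x` (the medial and lateral condyles).
#' @param condyle_radius Lobe radius (voxels).
#' @param center_offset Offset of the body centre from the lattice centre
#'   (voxels); the default drops the centre so the grown condyles still fit
#'   the lattice margin.
#' @param notch_depth Depth of the intercondylar notch (implicit-value
#'   units, >= 0).
#' @param g_c Growth amplitude at the condyle apices (um).
#' @param g_n Growth amplitude in the intercondylar region (um); `g_c > g_n
#'   >= 0` is required.
#' @param angular_sigma Angular width of the condylar growth peaks
#'   (chord-length units on the unit sphere).
#' @param perturb_sd SD of the per-specimen log-normal shape perturbation.
#' @param noise_sd Additive Gaussian image noise SD (gray values; the
#'   noise-free profile spans 0-200, so 10 is 5% of the dynamic range).
#' @param texture_amp Amplitude of the smooth internal intensity texture
#'   (fraction of the local profile, default 0.15). Stained cartilage is not
#'   homogeneous; the texture is part of the specimen's anatomy, so repeated
#'   scans share it and growth carries it along. Without it the rudiment
#'   interior would be featureless and interior/tangential displacements
#'   unobservable to any intensity-based registration.
#' @param texture_sigma Correlation length of the texture (voxels).
#' @param blur_sd Gaussian blur SD (voxels).
#' @param intensity_max Peak intensity of the noise-free profile.
#' @param seed Base seed; specimen seeds are derived as `seed + index`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(48, 48, 48), voxel_size_um = 14.63,
                         base_semiaxes = dims * c(0.24, 0.18, 0.20),
                         condyle_offset = c(0.11, 0, 0) * dims,
                         condyle_radius = 0.11 * min(dims),
                         center_offset = c(0, 0, 0),
                         notch_depth = 0.6,
                         g_c = 150, g_n = 60, angular_sigma = 0.7,
                         perturb_sd = 0.03, noise_sd = 10, blur_sd = 1,
                         texture_amp = 0.15, texture_sigma = 4,
                         intensity_max = 200, seed = 1L) {
  if (!(g_c >= g_n && g_n >= 0))
    stop("growth amplitudes must satisfy g_c >= g_n >= 0")
  spec <- structure(list(dims = as.integer(dims), voxel_size_um = voxel_size_um,
                 texture_amp = texture_amp, texture_sigma = texture_sigma,
                 base_semiaxes = base_semiaxes,
                 condyle_offset = condyle_offset,
                 condyle_radius = condyle_radius,
                 center_offset = center_offset, notch_depth = notch_depth,
                 g_c = g_c, g_n = g_n, angular_sigma = angular_sigma,
                 perturb_sd = perturb_sd, noise_sd = noise_sd,
                 blur_sd = blur_sd, intensity_max = intensity_max,
                 seed = as.integer(seed),
                 growth_offset_um = c(0, 0, 0), growth_scale = 1),
            class = "phantom_spec")
  # normalise the growth field over the unperturbed rudiment: the protocol
  # defines displacement maps after centre-of-mass pre-alignment, so the
  # ground-truth field is constructed to leave the mask centre of mass
  # unchanged (no net rigid translation to alias into the maps), and is
  # rescaled so its peak magnitude over the rudiment equals g_c exactly
  if (g_c > 0) {
    co <- voxel_coordinate_arrays(spec$dims)
    f <- phantom_implicit(spec, co$X, co$Y, co$Z)
    mask <- f > 0
    fg <- which(as.vector(mask))
    allpts <- cbind(as.numeric(co$X), as.numeric(co$Y), as.numeric(co$Z))
    pts <- allpts[fg, , drop = FALSE] * voxel_size_um
    com_early <- colMeans(allpts[fg, , drop = FALSE])
    raw <- phantom_growth_field(spec, pts)
    spec$growth_offset_um <- colMeans(raw)
    for (it in 1:3) {
      u_dense <- phantom_growth_field(spec, allpts * voxel_size_um) / voxel_size_um
      warped <- cpp_warp_inverse_fixedpoint(array(as.numeric(mask), spec$dims),
                                            spec$dims, u_dense, 15L)
      wl <- which(as.vector(array(warped, spec$dims) > 0.5))
      com_late <- colMeans(allpts[wl, , drop = FALSE])
      spec$growth_offset_um <- spec$growth_offset_um +
        (com_late - com_early) * voxel_size_um / spec$growth_scale
      u_mask <- phantom_growth_field(spec, pts)
      mx <- max(sqrt(rowSums(u_mask^2)))
      if (mx > 0) spec$growth_scale <- spec$growth_scale * g_c / mx
    }
  }
  spec
}

# Per-specimen perturbed copy of the geometry (seeded, low-order: log-normal
# scaling of the semi-axes and lobe radius, jitter of the lobe offsets).
perturb_geometry <- function(spec, specimen_seed) {
  g <- spec
  if (spec$perturb_sd > 0) {
    set.seed(spec$seed + specimen_seed)
    g$base_semiaxes <- spec$base_semiaxes * exp(rnorm(3, 0, spec$perturb_sd))
    g$condyle_radius <- spec$condyle_radius * exp(rnorm(1, 0, spec$perturb_sd))
    g$condyle_offset <- spec$condyle_offset +
      rnorm(3, 0, spec$perturb_sd * min(spec$dims) / 4)
  }
  g
}

phantom_center <- function(spec) {
  off <- if (is.null(spec$center_offset)) c(0, 0, 0) else spec$center_offset
  (spec$dims - 1) / 2 + off
}

# Implicit shape value on voxel-coordinate arrays; > 0 inside the body.
phantom_implicit <- function(geom, X, Y, Z) {
  ctr <- phantom_center(geom)
  ax <- geom$base_semiaxes
  Fe <- 1 - ((X - ctr[1]) / ax[1])^2 - ((Y - ctr[2]) / ax[2])^2 -
    ((Z - ctr[3]) / ax[3])^2
  r2 <- geom$condyle_radius^2
  val <- Fe
  for (s in c(1, -1)) {
    cl <- ctr + geom$condyle_offset * c(s, 1, 1)
    Fl <- 1 - ((X - cl[1])^2 + (Y - cl[2])^2 + (Z - cl[3])^2) / r2
    val <- pmax(val, Fl)
  }
  # intercondylar notch between the lobes, above the centre
  cn <- ctr + c(0, 0, geom$condyle_offset[3] + geom$condyle_radius / 2)
  sn <- geom$condyle_radius
  val - geom$notch_depth * exp(-((X - cn[1])^2 + (Y - cn[2])^2 +
                                   (Z - cn[3])^2) / (2 * sn^2))
}

# Closed-form inverse of the growth map: for each target voxel y (voxel
# units) the source coordinate x with x + u(x)/vs = y. With o the constant
# offset and the field radial about the centre, z = y + o - c lies on the
# same ray as x - c, and the radius solves r + ramp(r) * k = |z| with
# ramp piecewise linear: r = |z| / (1 + k/apex_r) below the apex radius,
# r = |z| - k above it.
phantom_inverse_coords <- function(spec, pts_vox) {
  vs <- spec$voxel_size_um
  ctr <- phantom_center(spec)
  off <- if (is.null(spec$growth_offset_um)) c(0, 0, 0) else spec$growth_offset_um
  scl <- if (is.null(spec$growth_scale)) 1 else spec$growth_scale
  z <- sweep(sweep(matrix(pts_vox, ncol = 3), 2, scl * off / vs, `+`), 2, ctr)
  s <- sqrt(rowSums(z^2))
  dir <- z / ifelse(s > 1e-12, s, 1)
  w <- phantom_condyle_weight(spec, sweep(dir * 1, 2, ctr, `+`) * vs)
  k <- scl * (spec$g_n + (spec$g_c - spec$g_n) * w) / vs
  apex_r <- sqrt(sum(spec$condyle_offset^2)) + spec$condyle_radius
  r_lin <- s / (1 + k / apex_r)
  r <- ifelse(r_lin <= apex_r, r_lin, s - k)
  r[s <= 1e-12] <- 0
  sweep(dir * r, 2, ctr, `+`)
}

voxel_coordinate_arrays <- function(dims) {
  list(X = array(rep(0:(dims[1] - 1), times = dims[2] * dims[3]), dims),
       Y = array(rep(rep(0:(dims[2] - 1), each = dims[1]), times = dims[3]), dims),
       Z = array(rep(0:(dims[3] - 1), each = dims[1] * dims[2]), dims))
}

#' Generate one early-stage phantom specimen
#'
#' @param spec A [phantom_spec()].
#' @param specimen_seed Integer; together with `spec$seed` makes the specimen
#'   reproducible.
#' @param scan_seed Integer scan index: the same specimen (geometry and
#'   internal texture) re-imaged with independent noise — the repeated-scan
#'   pairs of the precision study.
#' @return List with `image` ([volume_image()]) and `mask` ([binary_mask()]
#'   from the noise-free profile).
#' @export
make_early_specimen <- function(spec, specimen_seed = 0L, scan_seed = 0L) {
  geom <- perturb_geometry(spec, specimen_seed)
  dims <- spec$dims
  co <- voxel_coordinate_arrays(dims)
  f <- phantom_implicit(geom, co$X, co$Y, co$Z)
  m <- 4L
  shell <- f
  shell[(m + 1):(dims[1] - m), (m + 1):(dims[2] - m), (m + 1):(dims[3] - m)] <- -Inf
  if (any(shell > 0))
    stop("phantom shape exceeds the lattice (need a 4-voxel margin)")
  profile <- spec$intensity_max / (1 + exp(-f / 0.08))
  if (spec$texture_amp > 0) {
    # smooth seeded internal texture: part of the anatomy (same for repeated
    # scans of one specimen), modulating the profile multiplicatively
    set.seed(spec$seed + specimen_seed + 30000L)
    tex <- cpp_gaussian_blur(array(rnorm(prod(dims)), dims), dims,
                             spec$texture_sigma)
    tex <- tex / max(stats::sd(tex), 1e-12)
    profile <- profile * (1 + spec$texture_amp * pmax(pmin(tex, 2.5), -2.5))
  }
  img <- cpp_gaussian_blur(profile, dims, spec$blur_sd)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + specimen_seed + 10000L + 1000L * scan_seed)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dims)
  }
  img <- pmax(array(img, dims), 0)
  list(image = volume_image(img, spec$voxel_size_um, stage_label = "TS23",
                            specimen_id = sprintf("early_%03d", specimen_seed)),
       mask = binary_mask(f > 0, spec$voxel_size_um),
       geometry = geom)
}

#' Analytic ground-truth growth field of the phantom
#'
#' Radial growth away from the body centre whose magnitude ramps from 0 at
#' the centre to `g_n` at the surface, rising to `g_c` in two angular lobes
#' centred on the condyle apices — the qualitative pattern of higher growth
#' on the condyles than in the intercondylar region.
#'
#' @param spec A [phantom_spec()] (unperturbed geometry: the population-level
#'   field shared by all specimens).
#' @param points_um n x 3 matrix of positions (um, lattice world
#'   coordinates).
#' @return n x 3 matrix of displacements (um).
#' @export
phantom_growth_field <- function(spec, points_um) {
  vs <- spec$voxel_size_um
  p <- matrix(points_um, ncol = 3) / vs       # voxel units
  ctr <- phantom_center(spec)
  d <- sweep(p, 2, ctr)
  r <- sqrt(rowSums(d^2))
  dir <- d / ifelse(r > 1e-12, r, 1)
  apex_r <- sqrt(sum((spec$condyle_offset)^2)) + spec$condyle_radius
  ramp <- pmin(r / apex_r, 1)
  w <- phantom_condyle_weight(spec, points_um)
  mag <- ramp * (spec$g_n + (spec$g_c - spec$g_n) * w)
  mag[r <= 1e-12] <- 0
  off <- if (is.null(spec$growth_offset_um)) c(0, 0, 0) else spec$growth_offset_um
  scl <- if (is.null(spec$growth_scale)) 1 else spec$growth_scale
  scl * sweep(dir * mag, 2, off)
}

#' Condylar weight of the phantom growth field
#'
#' Value in (0, 1]: 1 on the rays through the condyle apices, decaying with
#' angular (chord) distance; low values mark the intercondylar region. Used
#' to define condylar vs intercondylar node sets in validation analyses.
#'
#' @inheritParams phantom_growth_field
#' @return Numeric vector, one weight per point.
#' @export
phantom_condyle_weight <- function(spec, points_um) {
  p <- matrix(points_um, ncol = 3) / spec$voxel_size_um
  ctr <- phantom_center(spec)
  d <- sweep(p, 2, ctr)
  r <- sqrt(rowSums(d^2))
  dir <- d / ifelse(r > 1e-12, r, 1)
  w <- rep(0, nrow(p))
  for (s in c(1, -1)) {
    a <- spec$condyle_offset * c(s, 1, 1)
    ah <- a / sqrt(sum(a^2))
    chord2 <- rowSums(sweep(dir, 2, ah)^2)
    w <- pmax(w, exp(-chord2 / (2 * spec$angular_sigma^2)))
  }
  w
}

#' Grow an early-stage phantom into its late-stage image
#'
#' The late image is the early image warped by the analytic population
#' growth field (inverse-mapped Lanczos resampling via fixed-point inversion
#' of the forward field) plus independent seeded noise; the mask is warped
#' the same way. The exact field is returned on the NS = 1 grid.
#'
#' @param early A [volume_image()] from [make_early_specimen()].
#' @param mask The matching [binary_mask()].
#' @param spec A [phantom_spec()].
#' @param specimen_seed Seed offset for the independent late-stage noise.
#' @return List with `image`, `mask` and `ground_truth`
#'   (a [displacement_field()] at NS = 1, um).
#' @export
grow_specimen <- function(early, mask, spec, specimen_seed = 0L) {
  dims <- dim(early$intensities)
  vs <- spec$voxel_size_um
  co <- voxel_coordinate_arrays(dims)
  pts_um <- cbind(as.numeric(co$X), as.numeric(co$Y), as.numeric(co$Z)) * vs
  u_um <- phantom_growth_field(spec, pts_um)
  u_vox <- u_um / vs
  fg <- which(as.vector(mask$voxels))
  if (length(fg)) {
    pos <- pts_um[fg, , drop = FALSE] / vs + u_vox[fg, , drop = FALSE]
    if (any(pos < 2) || any(sweep(pos, 2, dims - 3) > 0))
      stop("growth field pushes the shape outside the lattice")
  }
  # exact pull-back coordinates: the growth map is radial about the body
  # centre with a piecewise-linear ramp plus a constant offset, so its
  # inverse is available in closed form (no fixed-point iteration)
  src <- phantom_inverse_coords(spec, pts_um / vs)
  late <- array(cpp_sample_lanczos(early$intensities, dims, src), dims)
  late <- pmax(late, 0)
  mask_f <- array(cpp_sample_trilinear(array(as.numeric(mask$voxels), dims),
                                       dims, src), dims)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + specimen_seed + 20000L)
    late <- late + array(rnorm(length(late), 0, spec$noise_sd), dims)
    late <- pmax(late, 0)
  }
  grid <- registration_grid(dims, 1L, vs, early$origin_um)
  gt <- displacement_field(grid, u_um, quality = NA_real_, converged = TRUE)
  list(image = volume_image(late, vs, stage_label = "TS24",
                            specimen_id = sprintf("late_%03d", specimen_seed)),
       mask = binary_mask(mask_f > 0.5, vs),
       ground_truth = gt)
}

#' Generate a synthetic two-stage population
#'
#' `n_early` early-stage specimens and `n_late` late-stage specimens (each an
#' independent early-like shape grown by the shared population growth
#' field), everything the map-building pipeline needs end-to-end.
#'
#' @param spec A [phantom_spec()].
#' @param n_early,n_late Cohort sizes (>= 1); the reference cohorts are 5/5
#'   (proximal tibia) and 4/5 (distal femur).
#' @param site Site label for the groups.
#' @return List with `early` and `late` [specimen_group()]s and
#'   `ground_truth` (the shared [displacement_field()] at NS = 1).
#' @export
make_population <- function(spec, n_early, n_late, site = "tibia_proximal") {
  if (n_early < 1L || n_late < 1L) stop("cohort sizes must be >= 1")
  early_members <- list()
  for (i in seq_len(n_early)) {
    sp <- make_early_specimen(spec, i)
    sp$image$specimen_id <- sprintf("e%02d", i)
    early_members[[sprintf("e%02d", i)]] <- list(image = sp$image, mask = sp$mask)
  }
  late_members <- list()
  gt <- NULL
  for (i in seq_len(n_late)) {
    sp <- make_early_specimen(spec, 100L + i)
    gr <- grow_specimen(sp$image, sp$mask, spec, 100L + i)
    gr$image$specimen_id <- sprintf("l%02d", i)
    late_members[[sprintf("l%02d", i)]] <- list(image = gr$image, mask = gr$mask)
    gt <- gr$ground_truth
  }
  list(early = specimen_group(site, "TS23", early_members),
       late = specimen_group(site, "TS24", late_members),
       ground_truth = gt)
}
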