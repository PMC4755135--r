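#' Configuration for the synthetic brainstem phantom
#'
#' The phantom emulates a midbrain-like volume: a cerebrospinal-fluid void
#' (the "aqueduct") runs longitudinally through the center of the grid, and a
#' periaqueductal seed annulus flanks it on the left and right. Each side of
#' the seed is divided into `n_columns` angular sectors (for four columns:
#' dorsomedial, dorsolateral, lateral, ventrolateral), and the voxelwise
#' fiber-orientation field routes a smooth, non-crossing bundle from each
#' sector toward a virtual focus beyond `target_radius_mm` on the sector
#' bisector; the designated target of each column is its bundle's
#' cross-section at the `target_radius_mm` shell. A "shared" shell target is
#' crossed by the bundles of the first two sectors, and a "distractor" target
#' sits outside every corridor so that it picks up (at most) stray
#' connectivity and is removed by the connection-probability floor.
#'
#' Defaults mirror the imaging conditions the pipeline is designed for:
#' 1.5 mm isotropic voxels, a seed about 14 mm long and 4.5 mm wide per side,
#' four columns per side.
#'
#' @param grid_shape integer vector of voxels per axis (x, y, z).
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param seed_length_mm longitudinal extent of the seed annulus in mm.
#' @param seed_width_mm radial (lateral) extent of the seed per side in mm.
#' @param n_columns number of ground-truth columns per side (>= 2).
#' @param dispersion_kappa von-Mises-Fisher concentration of the per-voxel
#'   orientation distribution (unitless, >= 0; `Inf` = no dispersion). The
#'   default (100, angular SD about 6 degrees) represents a well-estimated
#'   orientation posterior.
#' @param geometry_jitter_mm SD of the per-subject translation of the whole
#'   geometry; draws are quantized to whole voxels so each subject's affine
#'   maps exactly onto the template lattice.
#' @param orientation_noise_deg SD (degrees) of a per-subject, per-voxel
#'   perturbation of the mean fiber orientations (frozen anatomy noise, on top
#'   of the sampling dispersion).
#' @param target_radius_mm in-plane distance from the aqueduct axis to the
#'   designated target shell of each column.
#' @param span_deg total angular span of the seed on each side, measured from
#'   the dorsal axis; the ventromedial remainder is excluded (it is not part
#'   of the periaqueductal gray).
#' @param rng_seed integer seed controlling the subject draw.
#' @return an object of class `pag_config` (a validated list).
#' @export
phantom_config <- function(grid_shape = c(40L, 40L, 24L),
                           voxel_size_mm = 1.5,
                           seed_length_mm = 14,
                           seed_width_mm = 4.5,
                           n_columns = 4L,
                           dispersion_kappa = 100,
                           geometry_jitter_mm = 1.5,
                           orientation_noise_deg = 3,
                           target_radius_mm = 19.5,
                           span_deg = 160,
                           rng_seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm,
              seed_length_mm = seed_length_mm,
              seed_width_mm = seed_width_mm,
              n_columns = as.integer(n_columns),
              dispersion_kappa = dispersion_kappa,
              geometry_jitter_mm = geometry_jitter_mm,
              orientation_noise_deg = orientation_noise_deg,
              target_radius_mm = target_radius_mm,
              span_deg = span_deg,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "pag_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3, all(cfg$grid_shape >= 8),
            cfg$voxel_size_mm > 0,
            cfg$seed_length_mm > 0, cfg$seed_width_mm > 0,
            cfg$n_columns >= 2,
            cfg$dispersion_kappa >= 0,
            cfg$geometry_jitter_mm >= 0,
            cfg$orientation_noise_deg >= 0,
            cfg$span_deg > 0, cfg$span_deg <= 180)
  invisible(cfg)
}

#' Names of the phantom columns
#'
#' For four columns the canonical anatomical labels are used (dm, dl, l, vl,
#' ordered dorsomedial to ventrolateral); otherwise generic sector names.
#'
#' @param n_columns number of columns per side.
#' @return character vector of column names.
#' @export
column_names <- function(n_columns) {
  if (n_columns == 4) c("dm", "dl", "l", "vl") else paste0("col", seq_len(n_columns))
}

#' Construct a voxelwise fiber-orientation field
#'
#' A lightweight container for per-voxel orientation distributions: up to two
#' fiber populations per voxel, each with an axial mean direction (v and -v
#' are equivalent), per-voxel population weights, and a per-voxel
#' von-Mises-Fisher concentration shared by the populations.
#'
#' @param dirs numeric array `(nx, ny, nz, 3, n_pop)` of mean directions
#'   (unit vectors where the population weight is positive).
#' @param weights numeric array `(nx, ny, nz, n_pop)` of population fractions
#'   in `[0, 1]`, summing to at most 1 per voxel.
#' @param kappa numeric array `(nx, ny, nz)` of concentrations (>= 0, `Inf`
#'   allowed for deterministic orientations).
#' @return object of class `pag_field`.
#' @export
orientation_field <- function(dirs, weights, kappa) {
  dd <- dim(dirs)
  if (length(dd) == 4) {
    dim(dirs) <- c(dd, 1L)
    dd <- dim(dirs)
  }
  stopifnot(length(dd) == 5, dd[4] == 3)
  if (length(dim(weights)) == 3) dim(weights) <- c(dim(weights), 1L)
  stopifnot(identical(dim(weights), dd[c(1, 2, 3, 5)]),
            identical(dim(kappa), dd[1:3]),
            all(weights >= 0), all(weights <= 1),
            all(kappa >= 0))
  structure(list(dirs = dirs, weights = weights, kappa = kappa,
                 dim = dd[1:3], n_pop = dd[5]),
            class = "pag_field")
}

# Clamped integer-voxel jitter draw (see vignette: lattice-exact affines).
draw_shift <- function(jitter_mm, voxel_mm) {
  sd_vox <- jitter_mm / voxel_mm
  clamp <- ceiling(3 * sd_vox)
  pmin(pmax(round(rnorm(3, 0, sd_vox)), -clamp), clamp)
}

#' Generate one synthetic phantom subject
#'
#' Builds the full subject: masks (brain, aqueduct, left/right seed,
#' targets), ground-truth column labels, the orientation field routing each
#' column's bundle to its designated target, and the subject-to-template
#' affine encoding the subject's (integer-voxel) geometric jitter. The draw is
#' deterministic given `config$rng_seed`.
#'
#' @param config a [phantom_config()].
#' @return object of class `pag_phantom` with elements `config`, `field`
#'   ([orientation_field()]), `brain_mask`, `aqueduct_mask`, `seed_mask_left`,
#'   `seed_mask_right`, `target_masks` (named list), `target_labels` (integer
#'   volume), `truth_labels` (integer volume, 0 outside the seed), `shift`,
#'   `subject_affine` (4x4, 1-based voxel to template-voxel coordinates),
#'   `center`, `seed_z`, `columns`.
#' @export
generate_phantom <- function(config) {
  validate_config(config)
  with_seed(config$rng_seed, {
    shift <- if (config$geometry_jitter_mm > 0)
      draw_shift(config$geometry_jitter_mm, config$voxel_size_mm) else c(0, 0, 0)
    ph <- build_phantom(config, shift)
    if (config$orientation_noise_deg > 0)
      ph$field <- perturb_field(ph$field, config$orientation_noise_deg)
    ph
  })
}

#' Generate a cohort of phantom subjects
#'
#' Each subject receives an independent geometry-jitter and orientation-noise
#' draw from a per-subject seed derived from `config$rng_seed` via
#' [derive_seed()], so the cohort is reproducible and any single subject can
#' be regenerated in isolation.
#'
#' @param config a [phantom_config()].
#' @param n_subjects number of subjects (>= 1).
#' @return list of `pag_phantom` objects.
#' @export
generate_cohort <- function(config, n_subjects) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    cfg_i <- config
    cfg_i$rng_seed <- derive_seed(config$rng_seed, "phantom", i)
    generate_phantom(cfg_i)
  })
}

#' Template-space phantom (zero jitter, zero anatomy noise)
#'
#' The common template grid every subject's affine maps onto: the same
#' geometry as [generate_phantom()] with no subject draw.
#'
#' @param config a [phantom_config()].
#' @return `pag_phantom` with identity subject affine.
#' @export
template_phantom <- function(config) {
  build_phantom(config, c(0, 0, 0))
}

# Deterministic geometry construction around a shifted center.
build_phantom <- function(config, shift) {
  gs <- config$grid_shape
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  vox <- config$voxel_size_mm
  k <- config$n_columns
  span <- config$span_deg * pi / 180
  width <- span / k

  cx <- (nx + 1) / 2 + shift[1]
  cy <- (ny + 1) / 2 + shift[2]

  nz_seed <- max(2L, as.integer(round(config$seed_length_mm / vox)))
  z0 <- floor((nz - nz_seed) / 2) + 1L + as.integer(shift[3])
  seed_z <- z0:(z0 + nz_seed - 1L)
  corridor_z <- (z0 - 1L):(z0 + nz_seed)
  if (z0 - 1L < 1L || z0 + nz_seed > nz)
    stop("phantom geometry does not fit the grid: seed span exceeds z extent")

  r_aq <- 1.6                                   # aqueduct radius, voxels
  r_seed_in <- r_aq
  r_seed_out <- r_aq + config$seed_width_mm / vox
  r_target <- config$target_radius_mm / vox
  r_field_out <- r_target + 2.5
  r_brain <- r_target + 4.5
  r_shared0 <- (r_seed_out + r_target) / 2 - 0.75
  r_shared1 <- min(r_shared0 + 1.5, r_target - 1.6)
  if (r_shared1 <= r_shared0 || r_shared0 <= r_seed_out)
    stop("phantom geometry does not fit the grid: no room for the shared shell")

  xs <- seq_len(nx); ys <- seq_len(ny); zs_all <- seq_len(nz)
  dx <- array(rep(xs - cx, times = ny * nz), dim = gs)
  dy <- array(rep(rep(ys - cy, each = nx), times = nz), dim = gs)
  zc <- array(rep(zs_all, each = nx * ny), dim = gs)
  r <- sqrt(dx^2 + dy^2)
  side <- sign(dx)                               # -1 left, +1 right (never 0 off-axis)
  phi <- atan2(abs(dx), dy)                      # angle from dorsal (+y) axis

  brain_mask <- r <= r_brain
  aqueduct_mask <- r <= r_aq
  in_z_seed <- array(zc >= z0 & zc <= z0 + nz_seed - 1L, dim = gs)
  in_z_corr <- array(zc >= z0 - 1L & zc <= z0 + nz_seed, dim = gs)

  in_annulus <- r > r_seed_in & r <= r_seed_out & phi < span & abs(dx) >= 0.5
  seed_mask <- in_annulus & in_z_seed
  seed_mask_left <- seed_mask & dx < 0
  seed_mask_right <- seed_mask & dx > 0

  sector <- pmin(floor(phi / width) + 1, k)
  truth_labels <- array(0L, dim = gs)
  truth_labels[seed_mask] <- as.integer(sector[seed_mask])

  cols <- column_names(k)
  bis <- (seq_len(k) - 0.5) * width              # sector bisector angles
  tz <- round(mean(seed_z))                      # bundles converge to mid-seed z
  z_half <- (nz_seed - 1) / 2

  if (round(cy + r_target + 1.5) > ny || round(cy - r_target - 1.5) < 1 ||
      round(cx + r_target + 1.5) > nx || round(cx - r_target - 1.5) < 1)
    stop("phantom geometry does not fit the grid: target shell out of bounds")

  # --- Bundle geometry -----------------------------------------------------
  # Each column's fibers leave the seed radially (in-plane, so backward
  # half-paths run into the aqueduct and terminate), then blend into a fan of
  # straight chords aimed at a virtual 3D focus placed beyond the target
  # radius on the sector bisector: interior and boundary fibers alike funnel
  # into one bundle per column that converges angularly and axially while
  # remaining a few voxels wide where it crosses the target shell.
  half_w <- width / 2
  r_blend0 <- r_seed_out                  # radial -> chord blend ramp
  r_blend1 <- r_seed_out + 3
  r_focus <- r_target + 4.5

  in_base <- r > r_aq & r <= r_field_out & phi < span & in_z_corr &
    abs(dx) >= 1e-9
  idx <- which(in_base)
  in_field <- in_base

  sec_i <- as.integer(sector[idx])
  b_i <- bis[sec_i]
  fx <- cx + side[idx] * r_focus * sin(b_i)       # 3D focus per voxel's sector
  fy <- cy + r_focus * cos(b_i)
  fz <- tz
  px <- dx[idx] + cx; py <- dy[idx] + cy; pz <- zc[idx]

  # Fan coordinates of each voxel: back-project the ray focus -> voxel onto
  # the blend-exit cylinder; u = angular offset of the chord's seed-side
  # origin from the bisector, zeta = its axial offset from the mid-seed
  # plane. Used to crop the targets to the bundle's true cross-section.
  ddx <- px - fx; ddy <- py - fy; ddz <- pz - fz
  a_q <- ddx^2 + ddy^2
  b_q <- 2 * ((fx - cx) * ddx + (fy - cy) * ddy)
  c_q <- (fx - cx)^2 + (fy - cy)^2 - r_blend1^2
  disc <- b_q^2 - 4 * a_q * c_q
  ok_fan <- disc > 0
  t1 <- (-b_q - sqrt(pmax(disc, 0))) / (2 * a_q)  # near intersection
  qx <- fx + t1 * ddx; qy <- fy + t1 * ddy; qz <- fz + t1 * ddz
  u_fan <- atan2(side[idx] * (qx - cx), qy - cy) - b_i
  zeta0 <- qz - tz

  # --- Targets -------------------------------------------------------------
  # The designated target of each column is its bundle's cross-section: the
  # radial shell [r_target - 1.5, r_target + 1.5] cropped to chords that
  # originate from the column's own seed sector (|u| within the sector
  # half-width, axial origin within the seeded slices). Every seed voxel's
  # chord crosses its target, and every target voxel lies on chords fed by
  # the column's own seeds.
  target_masks <- vector("list", k + 2L)
  names(target_masks) <- c(paste0("t_", cols), "t_shared", "t_distractor")
  in_shell <- abs(r[idx] - r_target) <= 1.5
  fan_ok <- ok_fan & abs(u_fan) <= half_w & abs(zeta0) <= z_half + 0.5
  for (c_i in seq_len(k)) {
    m <- array(FALSE, dim = gs)
    m[idx[in_shell & fan_ok & sec_i == c_i]] <- TRUE
    target_masks[[c_i]] <- m
  }
  target_masks[["t_shared"]] <-
    r >= r_shared0 & r <= r_shared1 & phi < 2 * width & in_z_seed
  # weakly-connected distractor outside every corridor (ventromedial block)
  distractor <- array(FALSE, dim = gs)
  for (s in c(-1, 1)) {
    ang_d <- 170 * pi / 180
    tx_d <- round(cx + s * r_target * sin(ang_d))
    ty_d <- round(cy + r_target * cos(ang_d))
    bx <- (tx_d - 1):(tx_d + 1); by <- (ty_d - 1):(ty_d + 1)
    bz <- (tz - 1):(tz + 1)
    if (min(bx) < 1 || max(bx) > nx || min(by) < 1 || max(by) > ny ||
        min(bz) < 1 || max(bz) > nz)
      stop("phantom geometry does not fit the grid: distractor out of bounds")
    distractor[bx, by, bz] <- TRUE
  }
  target_masks[["t_distractor"]] <- distractor

  target_labels <- array(0L, dim = gs)
  for (t_i in seq_along(target_masks)) {
    if (any(target_labels[target_masks[[t_i]]] != 0L))
      stop("internal error: overlapping target masks")
    target_labels[target_masks[[t_i]]] <- t_i
  }

  # --- Orientation field ---------------------------------------------------
  # Radial in-plane near the seed, blending into the chord direction toward
  # the sector's focus beyond the blend exit.
  dirs <- array(0, dim = c(gs, 3, 1))
  weights <- array(0, dim = c(gs, 1))
  kappa <- array(0, dim = gs)

  rr <- r[idx]
  ux <- fx - px; uy <- fy - py; uz <- fz - pz     # toward focus = outward
  un <- sqrt(ux^2 + uy^2 + uz^2)
  deg <- un < 1e-9
  ux <- ifelse(deg, dx[idx] / rr, ux / pmax(un, 1e-9))
  uy <- ifelse(deg, dy[idx] / rr, uy / pmax(un, 1e-9))
  uz <- ifelse(deg, 0, uz / pmax(un, 1e-9))
  w <- pmin(pmax((rr - r_blend0) / (r_blend1 - r_blend0), 0), 1)
  vx <- (1 - w) * dx[idx] / rr + w * ux
  vy <- (1 - w) * dy[idx] / rr + w * uy
  vz <- w * uz
  vn <- sqrt(vx^2 + vy^2 + vz^2)
  vx <- vx / vn; vy <- vy / vn; vz <- vz / vn

  d1 <- array(0, dim = gs); d2 <- array(0, dim = gs); d3 <- array(0, dim = gs)
  d1[idx] <- vx; d2[idx] <- vy; d3[idx] <- vz
  dirs[, , , 1, 1] <- d1
  dirs[, , , 2, 1] <- d2
  dirs[, , , 3, 1] <- d3
  weights[cbind(index_voxel(idx, gs), 1L)] <- 1
  kappa[idx] <- config$dispersion_kappa

  affine <- diag(4)
  affine[1:3, 4] <- -shift

  ph <- structure(list(
    config = config,
    field = orientation_field(dirs, weights, kappa),
    brain_mask = brain_mask,
    aqueduct_mask = aqueduct_mask,
    seed_mask_left = seed_mask_left,
    seed_mask_right = seed_mask_right,
    target_masks = target_masks,
    target_labels = target_labels,
    truth_labels = truth_labels,
    shift = as.numeric(shift),
    subject_affine = affine,
    center = c(cx, cy),
    seed_z = seed_z,
    columns = cols,
    geometry = list(r_aqueduct = r_aq, r_seed_in = r_seed_in,
                    r_seed_out = r_seed_out, r_target = r_target,
                    r_field_out = r_field_out, bisectors = bis,
                    sector_width = width, span = span)
  ), class = "pag_phantom")
  validate_phantom(ph)
  ph
}

# Frozen per-subject anatomy noise: perturb mean directions by a tangential
# Gaussian kick of SD tan(noise_deg) and renormalize.
perturb_field <- function(field, noise_deg) {
  sigma <- tan(noise_deg * pi / 180)
  dd <- dim(field$dirs)
  n <- prod(dd[1:3])
  for (p in seq_len(field$n_pop)) {
    v <- matrix(field$dirs[, , , , p], nrow = n, ncol = 3)
    act <- field$weights[, , , p] > 0
    if (!any(act)) next
    eps <- matrix(rnorm(3 * sum(act), 0, sigma), ncol = 3)
    vi <- v[act, , drop = FALSE]
    # remove component along v to keep the kick tangential
    proj <- rowSums(eps * vi)
    eps <- eps - proj * vi
    vi <- vi + eps
    vi <- vi / sqrt(rowSums(vi^2))
    v[act, ] <- vi
    field$dirs[, , , , p] <- array(v, dim = c(dd[1:3], 3))
  }
  field
}

#' Validate phantom mask invariants
#'
#' Asserts that the seed, aqueduct, and target masks are pairwise disjoint,
#' every mask is contained in the brain mask, every seed voxel has a truth
#' label in `1..n_columns`, and the subject affine is invertible.
#'
#' @param ph a `pag_phantom`.
#' @return `ph`, invisibly; errors if an invariant is violated.
#' @export
validate_phantom <- function(ph) {
  masks <- c(list(seed = ph$seed_mask_left | ph$seed_mask_right,
                  aqueduct = ph$aqueduct_mask), ph$target_masks)
  for (i in seq_along(masks)) {
    for (j in seq_along(masks)) {
      if (i < j && any(masks[[i]] & masks[[j]]))
        stop("phantom masks overlap: ", names(masks)[i], " vs ", names(masks)[j])
    }
    if (any(masks[[i]] & !ph$brain_mask))
      stop("phantom mask outside brain: ", names(masks)[i])
  }
  seed <- ph$seed_mask_left | ph$seed_mask_right
  lab <- ph$truth_labels[seed]
  if (any(lab < 1 | lab > ph$config$n_columns))
    stop("seed voxels without a valid truth label")
  if (abs(det(ph$subject_affine)) < 1e-12) stop("subject affine is singular")
  invisible(ph)
}

#' Seed voxel coordinates for one side
#'
#' @param ph a `pag_phantom`.
#' @param side `"left"` or `"right"`.
#' @return integer matrix `n x 3` of 1-based voxel coordinates, in ascending
#'   linear-index order (the row order used by the tracker).
#' @export
seed_coords <- function(ph, side = c("left", "right")) {
  side <- match.arg(side)
  m <- if (side == "left") ph$seed_mask_left else ph$seed_mask_right
  index_voxel(which(m), dim(m))
}
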