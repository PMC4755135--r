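#' Probabilistic tractography parameters
#'
#' @param n_samples streamline samples launched per seed voxel (default
#'   10,000; each sample is propagated in both directions along its initial
#'   axis and counts at most once per voxel).
#' @param step_size_mm propagation step (default 0.75 mm, half a voxel at the
#'   default 1.5 mm grid).
#' @param max_steps cap on steps per half-path.
#' @param curvature_limit_deg maximal turning angle per step; a sampled
#'   direction exceeding it terminates the path.
#' @param prob_threshold connection-probability floor: entries with
#'   probability below it are removed wherever profiles are thresholded
#'   (default 0.0003).
#' @param rng_seed integer seed for the Monte-Carlo draws.
#' @return object of class `pag_tracking_params`.
#' @export
tracking_params <- function(n_samples = 10000L, step_size_mm = 0.75,
                            max_steps = 2000L, curvature_limit_deg = 80,
                            prob_threshold = 3e-4, rng_seed = 1L) {
  stopifnot(n_samples >= 1, step_size_mm > 0,
            curvature_limit_deg > 0 || curvature_limit_deg == 0,
            curvature_limit_deg <= 180,
            prob_threshold >= 0, prob_threshold < 1, max_steps >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 step_size_mm = step_size_mm,
                 max_steps = as.integer(max_steps),
                 curvature_limit_deg = curvature_limit_deg,
                 prob_threshold = prob_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "pag_tracking_params")
}

field_args <- function(field) {
  list(dirs = field$dirs, weights = field$weights, kappa = field$kappa)
}

#' Draw orientation samples at a position
#'
#' Samples unit vectors from the local orientation distribution: the fiber
#' population is chosen proportional to the voxel's population weights, the
#' axial mean direction is interpolated trilinearly with signs aligned to
#' `prev_dir` (or to the nearest voxel's mean when `prev_dir` is `NULL`), and
#' the draw is a von-Mises-Fisher deviate at the local concentration. With
#' `prev_dir` given, every returned vector satisfies
#' `sum(dir * prev_dir) >= 0`.
#'
#' @param field a [orientation_field()].
#' @param position continuous 1-based voxel coordinates (length 3).
#' @param prev_dir previous step direction (unit 3-vector) or `NULL`.
#' @param n number of draws.
#' @return `n x 3` matrix of unit vectors.
#' @export
sample_orientation <- function(field, position, prev_dir = NULL, n = 1L) {
  stopifnot(inherits(field, "pag_field"), length(position) == 3)
  fa <- field_args(field)
  cpp_sample_orientations(fa$dirs, fa$weights, fa$kappa,
                          as.numeric(position),
                          if (is.null(prev_dir)) NULL else as.numeric(prev_dir),
                          as.integer(n))
}

#' Propagate a single streamline
#'
#' Stepwise propagation from `start`: at each position an orientation is
#' drawn ([sample_orientation()]), sign-aligned with the previous direction,
#' checked against the curvature limit, and followed for one step. The path
#' ends on leaving the brain mask, entering the termination (aqueduct) mask,
#' losing orientation support, exceeding the curvature limit, or reaching
#' `max_steps`. All terminations are normal outcomes.
#'
#' @param phantom a `pag_phantom` (supplies field and masks).
#' @param start continuous 1-based voxel coordinates.
#' @param params a [tracking_params()].
#' @param init_dir optional fixed initial direction (unit 3-vector); if
#'   `NULL`, drawn from the field at `start` with random axial sign.
#' @return matrix of positions (rows), starting at `start`; consecutive rows
#'   are `step_size_mm` apart.
#' @export
propagate_streamline <- function(phantom, start, params, init_dir = NULL) {
  fa <- field_args(phantom$field)
  step_vox <- params$step_size_mm / phantom$config$voxel_size_mm
  with_seed(params$rng_seed,
    cpp_propagate(fa$dirs, fa$weights, fa$kappa,
                  as.integer(phantom$brain_mask),
                  as.integer(phantom$aqueduct_mask),
                  as.numeric(start),
                  if (is.null(init_dir)) NULL else as.numeric(init_dir),
                  step_vox, params$max_steps,
                  cos(params$curvature_limit_deg * pi / 180)))
}

#' Track every seed voxel of one side
#'
#' Launches `n_samples` bidirectional streamlines from the center of every
#' seed voxel and accumulates, per seed voxel, (i) the number of samples
#' visiting each brain voxel at least once and (ii) the number of samples
#' reaching each named target mask (a sample counts once per target however
#' many target voxels it crosses). Deterministic given `params$rng_seed`.
#'
#' @param phantom a `pag_phantom`.
#' @param params a [tracking_params()].
#' @param side `"left"` or `"right"`.
#' @return object of class `pag_connectivity`: `seed_coords` (n x 3),
#'   `counts` (sparse `n_seed x n_grid_voxels` visit counts,
#'   `Matrix::dgCMatrix`), `target_counts` (dense `n_seed x n_targets`),
#'   `target_names`, `n_samples`, `grid_dim`, `side`, `prob_threshold`.
#' @export
track_seed_mask <- function(phantom, params, side = c("left", "right")) {
  side <- match.arg(side)
  seeds <- seed_coords(phantom, side)
  if (nrow(seeds) == 0) stop("empty seed mask for side ", side)
  stopifnot(params$n_samples >= 1)
  fa <- field_args(phantom$field)
  gd <- dim(phantom$brain_mask)
  step_vox <- params$step_size_mm / phantom$config$voxel_size_mm
  res <- with_seed(params$rng_seed + (side == "right"),
    cpp_track(fa$dirs, fa$weights, fa$kappa,
              as.integer(phantom$brain_mask),
              as.integer(phantom$aqueduct_mask),
              phantom$target_labels, length(phantom$target_masks),
              seeds, params$n_samples, step_vox, params$max_steps,
              cos(params$curvature_limit_deg * pi / 180)))
  counts <- Matrix::sparseMatrix(i = res$i, j = res$j, x = res$x,
                                 dims = c(nrow(seeds), prod(gd)))
  tc <- res$target_counts
  colnames(tc) <- names(phantom$target_masks)
  structure(list(seed_coords = seeds, counts = counts, target_counts = tc,
                 target_names = names(phantom$target_masks),
                 n_samples = params$n_samples, grid_dim = gd, side = side,
                 prob_threshold = params$prob_threshold),
            class = "pag_connectivity")
}

#' Connection probabilities from visit counts
#'
#' Probability of connection is the fraction of launched samples whose path
#' visits the voxel (or target): `count / n_samples`.
#'
#' @param counts numeric vector (or sparse row) of visit counts.
#' @param n_samples samples launched per seed voxel.
#' @return numeric vector of probabilities.
#' @export
connection_probability <- function(counts, n_samples) {
  stopifnot(n_samples > 0)
  as.numeric(counts) / n_samples
}

#' Apply the connection-probability floor
#'
#' Keeps exactly the entries with probability at or above the threshold
#' (entries with `P < threshold` are removed, i.e. zeroed).
#'
#' @param probs numeric vector of probabilities.
#' @param threshold probability floor (default 0.0003).
#' @return probabilities with sub-threshold entries set to 0.
#' @export
threshold_probabilities <- function(probs, threshold = 3e-4) {
  probs[probs < threshold] <- 0
  probs
}

#' @export
print.pag_connectivity <- function(x, ...) {
  cat("Seed connectivity:", nrow(x$seed_coords), "seed voxels (", x$side,
      "side ),", x$n_samples, "samples/voxel,",
      length(x$counts@x), "nonzero brain-voxel entries\n")
  invisible(x)
}
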