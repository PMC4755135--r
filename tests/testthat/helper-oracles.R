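# Independent oracles used across tests. These deliberately re-derive results
# with naive code paths (loops, closed forms, rejection sampling) so that they
# share nothing with the package implementation they check.

# Textbook silhouette: s(i) = (b - a) / max(a, b) on distance 1 - cor(rows),
# all in plain loops.
naive_silhouette <- function(x, labels) {
  n <- nrow(x)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- 1 - suppressWarnings(cor(x[i, ], x[j, ]))
  D[!is.finite(D)] <- 1
  diag(D) <- 0
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, labels == g]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# Voxels crossed by a straight ray in a deterministic field, replicating the
# tracker's termination semantics (nearest-voxel masks, step entry points,
# start voxel included) without touching its code.
ray_voxels <- function(start, dir, step, dims, brain, stop_mask,
                       max_steps = 10000) {
  dir <- dir / sqrt(sum(dir^2))
  seen <- integer(0)
  record <- function(v) {
    idx <- as.integer(v[1] + dims[1] * (v[2] - 1) +
                        dims[1] * dims[2] * (v[3] - 1))
    seen <<- union(seen, idx)
  }
  inside <- function(v) all(v >= 1) && all(v <= dims)
  v0 <- round(start)
  if (inside(v0) && brain[v0[1], v0[2], v0[3]]) record(v0)
  for (sgn in c(1, -1)) {
    p <- start
    for (k in seq_len(max_steps)) {
      p <- p + sgn * step * dir
      v <- round(p)
      if (!inside(v)) break
      if (!brain[v[1], v[2], v[3]]) break
      if (stop_mask[v[1], v[2], v[3]]) break
      record(v)
    }
  }
  sort(seen)
}

# Rejection sampler for the von-Mises-Fisher distribution on S2: uniform
# sphere proposals accepted with probability exp(kappa * (mu.x - 1)).
rejection_vmf <- function(mu, kappa, n) {
  mu <- mu / sqrt(sum(mu^2))
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 1000L)
    z <- matrix(rnorm(3 * m), m, 3)
    z <- z / sqrt(rowSums(z^2))
    keep <- runif(m) < exp(kappa * (z %*% mu - 1))
    out <- rbind(out, z[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Nearest-voxel field-following path oracle for zero-dispersion phantoms:
# follows the stored mean directions with axial sign alignment and reports
# whether the forward path enters the given target mask.
follows_to_target <- function(ph, start, target_mask, step = 0.5,
                              max_steps = 2000) {
  dims <- dim(ph$brain_mask)
  p <- as.numeric(start)
  d <- NULL
  for (k in seq_len(max_steps)) {
    v <- round(p)
    if (any(v < 1) || any(v > dims)) return(FALSE)
    if (ph$field$weights[v[1], v[2], v[3], 1] <= 0) return(FALSE)
    f <- ph$field$dirs[v[1], v[2], v[3], , 1]
    if (!is.null(d) && sum(f * d) < 0) f <- -f
    if (is.null(d)) d <- f
    d <- f
    p <- p + step * d
    v <- round(p)
    if (any(v < 1) || any(v > dims)) return(FALSE)
    if (ph$aqueduct_mask[v[1], v[2], v[3]]) return(FALSE)
    if (target_mask[v[1], v[2], v[3]]) return(TRUE)
  }
  FALSE
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("pagseg-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# Small phantom configuration used by the unit tests (fast to track).
small_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(28L, 28L, 16L), seed_length_mm = 9,
         target_radius_mm = 13.5),
    list(...))
  do.call(phantom_config, args)
}

# Hand-built minimal phantom with a uniform deterministic field: a box brain,
# a constant orientation everywhere, one seed voxel per "side", a single
# target slab, no aqueduct unless given.
uniform_phantom <- function(dims = c(15L, 9L, 9L), dir = c(1, 0, 0),
                            kappa = Inf, seed_vox = c(3L, 5L, 5L),
                            target_x = 12:13, aqueduct = NULL) {
  dir <- dir / sqrt(sum(dir^2))
  dirs <- array(0, dim = c(dims, 3, 1))
  dirs[, , , 1, 1] <- dir[1]; dirs[, , , 2, 1] <- dir[2]
  dirs[, , , 3, 1] <- dir[3]
  weights <- array(1, dim = c(dims, 1))
  kap <- array(kappa, dim = dims)
  field <- orientation_field(dirs, weights, kap)
  brain <- array(TRUE, dim = dims)
  aq <- array(FALSE, dim = dims)
  if (!is.null(aqueduct)) aq[aqueduct] <- TRUE
  seed_l <- array(FALSE, dim = dims)
  seed_l[seed_vox[1], seed_vox[2], seed_vox[3]] <- TRUE
  tmask <- array(FALSE, dim = dims)
  tmask[target_x, , ] <- TRUE
  tlab <- array(0L, dim = dims)
  tlab[tmask] <- 1L
  structure(list(
    config = list(voxel_size_mm = 1.5, n_columns = 2L),
    field = field, brain_mask = brain, aqueduct_mask = aq,
    seed_mask_left = seed_l, seed_mask_right = seed_l,
    target_masks = list(t_slab = tmask), target_labels = tlab,
    truth_labels = array(0L, dim = dims), shift = c(0, 0, 0),
    subject_affine = diag(4), center = (dims[1:2] + 1) / 2,
    seed_z = seq_len(dims[3]), columns = c("a", "b"),
    geometry = list(bisectors = c(0.7, 2.1))
  ), class = "pag_phantom")
}

# Fake connectivity object with prescribed counts (dense matrix) and target
# counts, for toy tests of downstream modules.
fake_connectivity <- function(counts, target_counts, n_samples,
                              grid_dim = c(4L, 4L, 4L), side = "left",
                              seed_coords = NULL, prob_threshold = 3e-4) {
  n <- nrow(counts)
  if (is.null(seed_coords))
    seed_coords <- cbind(seq_len(n), 1L, 1L)
  structure(list(
    seed_coords = seed_coords,
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    target_counts = target_counts,
    target_names = colnames(target_counts),
    n_samples = n_samples, grid_dim = grid_dim, side = side,
    prob_threshold = prob_threshold
  ), class = "pag_connectivity")
}
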