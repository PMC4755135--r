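#' Resample a subject volume onto the template grid
#'
#' Applies the subject-to-template affine (1-based voxel coordinates):
#' template voxel `t` takes the value at subject position `solve(A) %*% t`.
#' Labels use nearest-neighbour lookup; probability volumes may use trilinear
#' interpolation. Out-of-grid template voxels get 0.
#'
#' @param vol numeric or integer 3D array in subject space.
#' @param affine 4x4 voxel-to-template-voxel affine (invertible).
#' @param template_dim template grid dimensions (default: same as `vol`).
#' @param method `"nearest"` (labels) or `"linear"` (continuous values).
#' @return array of `template_dim`.
#' @export
to_template <- function(vol, affine, template_dim = dim(vol),
                        method = c("nearest", "linear")) {
  method <- match.arg(method)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  inv <- solve(affine)
  nd <- prod(template_dim)
  tc <- cbind(index_voxel(seq_len(nd), template_dim), 1)
  sc <- tc %*% t(inv)
  sd_ <- dim(vol)
  out <- array(0, dim = template_dim)
  if (method == "nearest") {
    v <- round(sc[, 1:3])
    ok <- v[, 1] >= 1 & v[, 1] <= sd_[1] & v[, 2] >= 1 & v[, 2] <= sd_[2] &
      v[, 3] >= 1 & v[, 3] <= sd_[3]
    out[ok] <- vol[voxel_index(v[ok, , drop = FALSE], sd_)]
    if (is.integer(vol)) storage.mode(out) <- "integer"
  } else {
    out[] <- trilinear_lookup(vol, sc[, 1:3, drop = FALSE])
  }
  out
}

trilinear_lookup <- function(vol, pts) {
  sd_ <- dim(vol)
  b <- floor(pts)
  f <- pts - b
  acc <- numeric(nrow(pts))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    v <- cbind(b[, 1] + cx, b[, 2] + cy, b[, 3] + cz)
    w <- (cx * f[, 1] + (1 - cx) * (1 - f[, 1])) *
         (cy * f[, 2] + (1 - cy) * (1 - f[, 2])) *
         (cz * f[, 3] + (1 - cz) * (1 - f[, 3]))
    ok <- v[, 1] >= 1 & v[, 1] <= sd_[1] & v[, 2] >= 1 & v[, 2] <= sd_[2] &
      v[, 3] >= 1 & v[, 3] <= sd_[3] & w > 0
    if (any(ok))
      acc[ok] <- acc[ok] + w[ok] * vol[voxel_index(v[ok, , drop = FALSE], sd_)]
  }
  acc
}

#' Group probability map from per-subject binary maps
#'
#' The voxelwise fraction of the cohort positive at each template voxel,
#' with a population-fraction cutoff: the thresholded support keeps voxels
#' strictly above the cutoff (default 0.30, i.e. "> 30% of the population").
#'
#' @param maps list of binary (logical/0-1) template-space arrays, one per
#'   subject (or per side).
#' @param threshold population fraction cutoff in `[0, 1)`.
#' @return object of class `pag_groupmap`: `values` (fractions in `[0, 1]`),
#'   `support` (logical, `values > threshold`), `n_subjects`, `threshold`.
#' @export
group_probability_map <- function(maps, threshold = 0.30) {
  stopifnot(length(maps) >= 1)
  d0 <- dim(maps[[1]])
  for (m in maps)
    if (!identical(dim(m), d0)) stop("group map inputs have mismatched shapes")
  acc <- array(0, dim = d0)
  for (m in maps) acc <- acc + (m != 0)
  values <- acc / length(maps)
  structure(list(values = values, support = values > threshold,
                 n_subjects = length(maps), threshold = threshold),
            class = "pag_groupmap")
}
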