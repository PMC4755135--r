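#' Thresholded, optionally down-binned connectivity profile matrix
#'
#' Builds the per-seed-voxel feature matrix the correlation is computed on:
#' visit counts with the connection-probability floor applied, then (by
#' default) spatially down-binned by aggregating counts over `bin`-voxel
#' cubes, which keeps the correlation tractable without changing which seed
#' voxels resemble each other. `bin = 1` is the exact (no binning) mode.
#'
#' @param cm a `pag_connectivity` from [track_seed_mask()].
#' @param prob_threshold connection-probability floor applied before binning.
#' @param bin integer down-binning factor per axis (default 3).
#' @return dense numeric matrix, seed voxels x (binned) brain voxels.
#' @export
profile_matrix <- function(cm, prob_threshold = cm$prob_threshold, bin = 3L) {
  x <- cm$counts
  floor_count <- prob_threshold * cm$n_samples
  if (floor_count > 0) x@x[x@x < floor_count] <- 0
  x <- Matrix::drop0(x)
  if (bin > 1L) {
    gd <- cm$grid_dim
    bd <- ceiling(gd / bin)
    vox <- index_voxel(seq_len(prod(gd)), gd)
    bcoord <- (vox - 1L) %/% as.integer(bin) + 1L
    bidx <- voxel_index(bcoord, bd)
    agg <- Matrix::sparseMatrix(i = seq_len(prod(gd)), j = bidx, x = 1,
                                dims = c(prod(gd), prod(bd)))
    x <- x %*% agg
  }
  as.matrix(x)
}

#' Cross-correlation matrix of seed-voxel connectivity profiles
#'
#' Entry (i, j) is the Pearson correlation between the thresholded
#' connectivity profiles of seed voxels i and j. Seed voxels with
#' zero-variance (all-zero after thresholding) profiles cannot be correlated;
#' they are excluded from the matrix and flagged in `valid` (downstream they
#' are reported as unclassified, never imputed).
#'
#' @param cm a `pag_connectivity`, or a plain numeric profile matrix (rows =
#'   seed voxels).
#' @param prob_threshold connection-probability floor.
#' @param bin spatial down-binning factor (see [profile_matrix()]).
#' @return list of class `pag_ccmat`: `R` (symmetric correlation matrix over
#'   valid voxels, unit diagonal), `valid` (logical over all seed voxels),
#'   `n_seed`.
#' @export
cross_correlation_matrix <- function(cm, prob_threshold = 3e-4, bin = 3L) {
  x <- if (inherits(cm, "pag_connectivity"))
    profile_matrix(cm, prob_threshold, bin) else as.matrix(cm)
  if (nrow(x) < 2) stop("need at least 2 seed voxels to correlate")
  v <- apply(x, 1, sd) > 0
  if (sum(v) < 2) stop("degenerate input: fewer than 2 seed voxels with nonzero profiles")
  R <- cor(t(x[v, , drop = FALSE]))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R <- (R + t(R)) / 2
  structure(list(R = R, valid = v, n_seed = nrow(x)), class = "pag_ccmat")
}

# k-means++ center seeding on rows of x (standard D^2 weighting).
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = p)
    d2j <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, d2j)
  }
  x[centers, , drop = FALSE]
}

#' k-means clustering of cross-correlation rows
#'
#' Each row of the cross-correlation matrix is the feature vector of its seed
#' voxel. Runs `n_restarts` k-means fits (k-means++ seeding from a fixed
#' RNG) and keeps the fit with the lowest within-cluster sum of squares; ties
#' go to the earliest restart. Deterministic given `rng_seed`.
#'
#' @param ccmat a `pag_ccmat` or a numeric feature matrix.
#' @param k number of clusters (>= 2, <= rows).
#' @param n_restarts number of random restarts (default 50).
#' @param rng_seed integer seed.
#' @return integer vector of cluster labels `1..k` per (valid) row.
#' @export
kmeans_columns <- function(ccmat, k = 4L, n_restarts = 50L, rng_seed = 1L) {
  x <- if (inherits(ccmat, "pag_ccmat")) ccmat$R else as.matrix(ccmat)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(x)) stop("k exceeds the number of rows")
  with_seed(rng_seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- suppressWarnings(
        kmeans(x, centers = kmeanspp_centers(x, k), iter.max = 100L))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12)
        best <- fit
    }
    as.integer(best$cluster)
  })
}

#' Silhouette values on the correlation geometry
#'
#' Per-voxel silhouette `(b - a) / max(a, b)` with `a` the mean distance to
#' the voxel's own cluster and `b` the mean distance to the nearest other
#' cluster, using distance `1 - correlation` between the feature rows the
#' clustering ran on. Singleton clusters get silhouette 0 by convention.
#'
#' @param ccmat a `pag_ccmat` or feature matrix (rows clustered).
#' @param labels integer cluster labels per row.
#' @return numeric vector of silhouettes in `[-1, 1]`.
#' @export
silhouette_values <- function(ccmat, labels) {
  x <- if (inherits(ccmat, "pag_ccmat")) ccmat$R else as.matrix(ccmat)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x))
  if (length(unique(labels)) < 2)
    stop("silhouette is undefined for a single cluster")
  D <- 1 - cor(t(x))
  D[!is.finite(D)] <- 1
  diag(D) <- 0
  n <- nrow(x)
  ks <- sort(unique(labels))
  # mean distance from every point to every cluster, done by group sums
  G <- vapply(ks, function(g) rowSums(D[, labels == g, drop = FALSE]),
              numeric(n))
  sizes <- vapply(ks, function(g) sum(labels == g), numeric(1))
  s <- numeric(n)
  for (i in seq_len(n)) {
    gi <- match(labels[i], ks)
    if (sizes[gi] <= 1) { s[i] <- 0; next }
    a <- G[i, gi] / (sizes[gi] - 1)
    b <- min(G[i, -gi] / sizes[-gi])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  pmin(pmax(s, -1), 1)
}

#' Silhouette filtering of poorly differentiated voxels
#'
#' Voxels with silhouette below the cutoff are flagged as poorly
#' differentiated (overlapping columns at the imaging resolution) and
#' excluded from profile and back-projection computations.
#'
#' @param ccmat a `pag_ccmat` or feature matrix.
#' @param labels integer cluster labels per row.
#' @param cutoff silhouette cutoff (default 0.25); retained means
#'   `silhouette >= cutoff`.
#' @return list: `silhouette`, `retained` (logical), `cutoff`.
#' @export
silhouette_filter <- function(ccmat, labels, cutoff = 0.25) {
  s <- silhouette_values(ccmat, labels)
  list(silhouette = s, retained = s >= cutoff, cutoff = cutoff)
}

#' Cluster the seed voxels of one side
#'
#' Convenience wrapper running the full per-side segmentation:
#' cross-correlation, k-means, silhouette filtering. Zero-connectivity seed
#' voxels are reported with label 0 (unclassified), silhouette `NA`.
#'
#' @param cm a `pag_connectivity` for one side.
#' @param k number of clusters (default 4).
#' @param cutoff silhouette cutoff (default 0.25).
#' @param prob_threshold connection-probability floor.
#' @param bin spatial down-binning factor for the profiles.
#' @param n_restarts,rng_seed passed to [kmeans_columns()].
#' @return object of class `pag_clusters`: `labels`, `silhouette`,
#'   `retained` (all length `n_seed`, label 0 / `NA` / `FALSE` for
#'   unclassified voxels), `seed_coords`, `side`, `k`, `cutoff`,
#'   `column_identity` (filled by [assign_column_identities()]).
#' @export
cluster_side <- function(cm, k = 4L, cutoff = 0.25,
                         prob_threshold = cm$prob_threshold, bin = 3L,
                         n_restarts = 50L, rng_seed = 1L) {
  cc <- cross_correlation_matrix(cm, prob_threshold, bin)
  lab_v <- kmeans_columns(cc, k, n_restarts, rng_seed)
  sf <- silhouette_filter(cc, lab_v, cutoff)
  n <- cc$n_seed
  labels <- integer(n); sil <- rep(NA_real_, n); ret <- logical(n)
  labels[cc$valid] <- lab_v
  sil[cc$valid] <- sf$silhouette
  ret[cc$valid] <- sf$retained
  structure(list(labels = labels, silhouette = sil, retained = ret,
                 seed_coords = cm$seed_coords, side = cm$side, k = k,
                 cutoff = cutoff, column_identity = NULL, columnar = NULL),
            class = "pag_clusters")
}

circ_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Assign anatomical column identities to clusters
#'
#' Formalizes the visual judgment that a successful cluster runs parallel to
#' the aqueduct in one of the canonical aspects (dorsomedial, dorsolateral,
#' lateral, ventrolateral): each
#' cluster's retained voxels get a mean angular position around the aqueduct
#' axis, clusters are matched one-to-one to the canonical sector bisectors by
#' minimal total angular discrepancy, and each cluster is scored for
#' columnarity: its occupied axial slices must form a contiguous run covering
#' at least `min_length_frac` of the seed length, with angular spread at most
#' `max_spread_deg`. Non-columnar clusters are marked unassigned.
#'
#' @param clusters a `pag_clusters` from [cluster_side()].
#' @param phantom the `pag_phantom` the connectivity was tracked on (supplies
#'   the aqueduct center, seed span, and canonical sector geometry).
#' @param min_length_frac minimum contiguous longitudinal coverage as a
#'   fraction of the seed length (default 0.6).
#' @param max_spread_deg maximum angular spread of a columnar cluster
#'   (default 120 degrees).
#' @return `clusters` with `column_identity` (named character vector: cluster
#'   id -> identity or `"unassigned"`), `columnar` (logical per cluster), and
#'   `cluster_angles` filled in.
#' @export
assign_column_identities <- function(clusters, phantom,
                                     min_length_frac = 0.6,
                                     max_spread_deg = 120) {
  k <- clusters$k
  cen <- phantom$center
  vox <- phantom$config$voxel_size_mm
  seed_len_mm <- length(phantom$seed_z) * vox
  bis <- phantom$geometry$bisectors
  if (length(bis) != k)
    stop("phantom has ", length(bis), " canonical sectors but k = ", k)

  co <- clusters$seed_coords
  ang <- atan2(abs(co[, 1] - cen[1]), co[, 2] - cen[2])

  mean_ang <- spread <- zrun <- rep(NA_real_, k)
  for (g in seq_len(k)) {
    sel <- clusters$labels == g & clusters$retained
    if (!any(sel)) sel <- clusters$labels == g       # fall back to all voxels
    if (!any(sel)) next
    a <- ang[sel]
    mean_ang[g] <- atan2(mean(sin(a)), mean(cos(a)))
    spread[g] <- diff(range(a))
    zs <- sort(unique(co[sel, 3]))
    runs <- split(zs, cumsum(c(1, diff(zs) != 1)))
    zrun[g] <- max(vapply(runs, length, numeric(1))) * vox
  }

  columnar <- !is.na(mean_ang) &
    zrun >= min_length_frac * seed_len_mm &
    spread <= max_spread_deg * pi / 180

  # one-to-one matching of clusters to sector identities
  perms <- permutations_of(seq_len(k))
  best <- NULL; best_cost <- Inf
  for (p in perms) {
    cost <- sum(circ_dist(mean_ang, bis[p]), na.rm = TRUE)
    if (cost < best_cost - 1e-12) { best_cost <- cost; best <- p }
  }
  ident <- phantom$columns[best]
  ident[!columnar] <- "unassigned"
  names(ident) <- as.character(seq_len(k))

  clusters$column_identity <- ident
  clusters$columnar <- columnar
  clusters$cluster_angles <- mean_ang
  clusters
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}

#' Per-column clustering success over a cohort
#'
#' A column counts as successfully segmented on a side when some cluster was
#' assigned that column's identity (assignment implies it passed the
#' columnarity rule). Fractions are reported per column across all sides.
#'
#' @param cluster_results list of `pag_clusters` (after
#'   [assign_column_identities()]), one per side per subject.
#' @param columns character vector of column identities to score.
#' @return named numeric vector of success fractions in `[0, 1]`.
#' @export
evaluate_success <- function(cluster_results, columns = column_names(4L)) {
  if (length(cluster_results) == 0) return(setNames(rep(0, length(columns)), columns))
  hits <- vapply(columns, function(cl) {
    mean(vapply(cluster_results,
                function(cr) cl %in% cr$column_identity, logical(1)))
  }, numeric(1))
  setNames(hits, columns)
}

#' Integer label volume from a cluster result
#'
#' @param clusters a `pag_clusters`.
#' @param grid_dim grid dimensions.
#' @param retained_only zero out filtered voxels (default `TRUE`).
#' @param by_identity relabel clusters by canonical identity order (1 = first
#'   column identity, ...); unassigned clusters map to 0. Requires
#'   [assign_column_identities()] to have run.
#' @return integer array (0 = unclassified/filtered).
#' @export
cluster_label_volume <- function(clusters, grid_dim, retained_only = TRUE,
                                 by_identity = FALSE) {
  lab <- clusters$labels
  if (retained_only) lab[!clusters$retained] <- 0L
  if (by_identity) {
    if (is.null(clusters$column_identity))
      stop("no column identities assigned")
    canon <- column_names(clusters$k)
    map <- match(clusters$column_identity[as.character(seq_len(clusters$k))], canon)
    lab <- ifelse(lab > 0 & !is.na(map[pmax(lab, 1L)]), map[pmax(lab, 1L)], 0L)
  }
  out <- array(0L, dim = grid_dim)
  out[voxel_index(clusters$seed_coords, grid_dim)] <- as.integer(lab)
  out
}
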