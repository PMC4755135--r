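#' Winner-take-all back-projection of columns onto the brain
#'
#' For every brain voxel, the connectivity to each column is aggregated over
#' that column's retained seed voxels (mean connection probability by
#' default; `"max"` and `"sum"` are exposed since the aggregation is a
#' modelling choice). The voxel is labeled with the column of strongest
#' connectivity provided that strength reaches the probability floor;
#' sub-threshold voxels are labeled 0, and exact ties are labeled 0 with a
#' tie flag (no evidence, no claim).
#'
#' @param clusters a `pag_clusters` (identities assigned; only clusters with
#'   an assigned identity are projected).
#' @param cm the matching `pag_connectivity`.
#' @param prob_threshold probability floor (default 0.0003).
#' @param agg `"mean"`, `"max"`, or `"sum"` over the column's seed voxels.
#' @return list of class `pag_backprojection`: `labels` (integer volume of
#'   cluster ids, 0 = unassigned), `ties` (logical volume), `strength`
#'   (matrix clusters x voxels of aggregated probabilities), `cluster_ids`.
#' @export
backproject <- function(clusters, cm, prob_threshold = 3e-4,
                        agg = c("mean", "max", "sum")) {
  agg <- match.arg(agg)
  stopifnot(inherits(clusters, "pag_clusters"))
  ident <- clusters$column_identity
  if (is.null(ident)) stop("assign column identities before back-projection")
  ids <- as.integer(names(ident)[ident != "unassigned"])
  if (length(ids) == 0) stop("no assigned columns to back-project")
  gd <- cm$grid_dim
  P <- cm$counts / cm$n_samples
  strength <- matrix(0, length(ids), prod(gd))
  for (i in seq_along(ids)) {
    sel <- clusters$labels == ids[i] & clusters$retained
    if (!any(sel)) next
    sub <- P[sel, , drop = FALSE]
    strength[i, ] <- switch(agg,
      mean = Matrix::colMeans(sub),
      sum = Matrix::colSums(sub),
      max = apply_sparse_colmax(sub))
  }
  top <- apply_top2(strength)
  lab <- ifelse(top$max >= prob_threshold & !top$tie, ids[top$which], 0L)
  ties <- top$tie & top$max >= prob_threshold
  labels <- array(as.integer(lab), dim = gd)
  structure(list(labels = labels, ties = array(ties, dim = gd),
                 strength = strength, cluster_ids = ids,
                 prob_threshold = prob_threshold),
            class = "pag_backprojection")
}

# column-wise max of a sparse matrix, as a dense vector
apply_sparse_colmax <- function(m) {
  m <- as(m, "CsparseMatrix")
  out <- numeric(ncol(m))
  dp <- diff(m@p)
  has <- which(dp > 0)
  for (j in has) {
    xs <- m@x[(m@p[j] + 1):(m@p[j + 1])]
    out[j] <- max(xs, 0)
  }
  out
}

# per-column argmax with exact-tie detection over a small dense matrix
apply_top2 <- function(strength) {
  if (nrow(strength) == 1) {
    return(list(max = strength[1, ], which = rep(1L, ncol(strength)),
                tie = rep(FALSE, ncol(strength))))
  }
  mx <- apply(strength, 2, max)
  wh <- apply(strength, 2, which.max)
  n_at_max <- colSums(strength == rep(mx, each = nrow(strength)))
  list(max = mx, which = wh, tie = n_at_max > 1)
}
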