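#' Total seed connectivity to each target region
#'
#' Per target: the mean, over all seed voxels, of the fraction of samples
#' reaching any voxel of the target. Targets whose mean connection
#' probability falls below the floor are flagged `removed` (false-positive
#' suppression) and excluded from the per-column profile analysis.
#'
#' @param cm a `pag_connectivity` (carries per-target sample hit counts).
#' @param prob_threshold removal floor (default 0.0003).
#' @return data.frame: `target`, `mean_prob`, `removed`.
#' @export
total_seed_connectivity <- function(cm, prob_threshold = 3e-4) {
  stopifnot(length(cm$target_names) > 0)
  probs <- colMeans(cm$target_counts) / cm$n_samples
  data.frame(target = cm$target_names,
             mean_prob = as.numeric(probs),
             removed = as.numeric(probs) < prob_threshold,
             row.names = NULL)
}

#' Per-column connectivity profiles
#'
#' For each column (clusters carrying an assigned identity, over their
#' retained voxels): the mean connection probability to every retained
#' target, and the column's relative share of the summed across-column
#' connectivity per target (shares sum to 1 across columns whenever any
#' column connects).
#'
#' @param clusters a `pag_clusters` after [assign_column_identities()].
#' @param cm the matching `pag_connectivity`.
#' @param retained_targets character vector of target names to profile
#'   (typically the non-removed rows of [total_seed_connectivity()]).
#' @return data.frame: `column`, `target`, `mean_prob`, `relative`. Columns
#'   with no retained voxels are excluded with a warning.
#' @export
column_profiles <- function(clusters, cm, retained_targets) {
  stopifnot(inherits(clusters, "pag_clusters"))
  if (is.null(clusters$column_identity))
    stop("assign column identities before profiling")
  tsel <- match(retained_targets, cm$target_names)
  if (anyNA(tsel)) stop("unknown target name(s)")
  ident <- clusters$column_identity
  cols <- ident[ident != "unassigned"]
  out <- list()
  for (g in names(cols)) {
    gi <- as.integer(g)
    sel <- clusters$labels == gi & clusters$retained
    if (!any(sel)) {
      warning("column ", cols[[g]], " has no retained voxels; excluded")
      next
    }
    p <- colMeans(cm$target_counts[sel, tsel, drop = FALSE]) / cm$n_samples
    out[[g]] <- data.frame(column = cols[[g]], target = retained_targets,
                           mean_prob = as.numeric(p), row.names = NULL)
  }
  if (length(out) == 0) stop("no column has retained voxels")
  prof <- do.call(rbind, out)
  tot <- tapply(prof$mean_prob, prof$target, sum)
  denom <- as.numeric(tot[prof$target])
  prof$relative <- ifelse(denom > 0, prof$mean_prob / denom, 0)
  rownames(prof) <- NULL
  prof
}

#' Assemble per-subject column profiles for a cohort
#'
#' Runs [column_profiles()] per subject and side and averages the two sides
#' within subject (the subject is the statistical unit for the paired
#' comparisons). Columns missing on a side contribute only the other side.
#'
#' @param profile_list list over subjects; each element a list of per-side
#'   profile data.frames (from [column_profiles()]).
#' @return long data.frame: `subject`, `column`, `target`, `mean_prob`,
#'   `relative`.
#' @export
cohort_profiles <- function(profile_list) {
  rows <- list()
  for (s in seq_along(profile_list)) {
    p <- do.call(rbind, profile_list[[s]])
    agg <- aggregate(cbind(mean_prob, relative) ~ column + target, data = p,
                     FUN = mean)
    agg$subject <- s
    rows[[s]] <- agg
  }
  out <- do.call(rbind, rows)
  out[, c("subject", "column", "target", "mean_prob", "relative")]
}

pair_label <- function(a, b) paste(a, "vs", b)

#' Pairwise column comparisons of connectivity profiles
#'
#' For every pair of columns: (i) per target, a paired comparison of
#' connection probabilities across subjects (paired t-test by default,
#' Wilcoxon signed-rank as a nonparametric switch), Bonferroni-corrected over
#' the 6 column pairs; (ii) a multivariate within-subject permutation test
#' over the full target vector, standing in for a repeated-measures MANOVA:
#' the statistic is the sum over targets of squared paired t statistics, and
#' the null distribution is generated by exchanging the two column labels
#' within subject (sign flips of the paired difference vectors).
#'
#' @param profiles long data.frame from [cohort_profiles()] (`subject`,
#'   `column`, `target`, `mean_prob`).
#' @param value which column of `profiles` to compare (default `mean_prob`).
#' @param n_perm number of label-exchange permutations (default 10,000).
#' @param rng_seed integer seed for the permutation draws.
#' @param method `"t"` (paired t-test) or `"wilcoxon"`.
#' @return list: `pairwise` (data.frame `pair`, `target`, `p_raw`,
#'   `p_bonferroni`), `multivariate` (data.frame `pair`, `statistic`,
#'   `p_perm`), `n_subjects`.
#' @export
pairwise_column_tests <- function(profiles, value = "mean_prob",
                                  n_perm = 10000L, rng_seed = 1L,
                                  method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  cols <- unique(profiles$column)
  targets <- unique(profiles$target)
  subjects <- unique(profiles$subject)
  if (length(subjects) < 3) stop("insufficient data: need >= 3 subjects")
  pairs <- utils::combn(cols, 2, simplify = FALSE)
  n_pairs <- length(pairs)

  # subject x target matrix per column
  get_mat <- function(cl) {
    sub <- profiles[profiles$column == cl, ]
    m <- matrix(NA_real_, length(subjects), length(targets),
                dimnames = list(subjects, targets))
    m[cbind(match(sub$subject, subjects), match(sub$target, targets))] <-
      sub[[value]]
    m
  }
  mats <- lapply(setNames(cols, cols), get_mat)

  pw <- list(); mv <- list()
  for (pr in pairs) {
    D <- mats[[pr[1]]] - mats[[pr[2]]]
    ok <- stats::complete.cases(D)
    D <- D[ok, , drop = FALSE]
    n <- nrow(D)
    if (n < 3) stop("insufficient complete pairs for ", pair_label(pr[1], pr[2]))
    p_raw <- vapply(seq_len(ncol(D)), function(j) {
      d <- D[, j]
      if (all(abs(d - d[1]) < 1e-15) && abs(d[1]) < 1e-15) return(1)
      if (method == "t") {
        if (sd(d) < 1e-15) return(0)  # constant nonzero difference
        t.test(d)$p.value
      } else {
        suppressWarnings(wilcox.test(d)$p.value)
      }
    }, numeric(1))
    pw[[pair_label(pr[1], pr[2])]] <-
      data.frame(pair = pair_label(pr[1], pr[2]), target = targets,
                 p_raw = p_raw,
                 p_bonferroni = pmin(1, p_raw * n_pairs), row.names = NULL)

    perm <- multivariate_permutation_test(D, n_perm, rng_seed)
    mv[[pair_label(pr[1], pr[2])]] <-
      data.frame(pair = pair_label(pr[1], pr[2]),
                 statistic = perm$statistic, p_perm = perm$p, row.names = NULL)
  }
  list(pairwise = do.call(rbind, c(pw, list(make.row.names = FALSE))),
       multivariate = do.call(rbind, c(mv, list(make.row.names = FALSE))),
       n_subjects = length(subjects))
}

#' Within-subject multivariate permutation test
#'
#' Tests whether a matrix of paired differences (subjects x variables) is
#' centered at zero, by sign-flipping whole subject rows. The statistic is
#' the sum over variables of squared one-sample t statistics; because row
#' sign flips leave each variable's sum of squares unchanged, the whole null
#' distribution is computed from the flipped means alone.
#'
#' @param D numeric matrix of paired differences, subjects x variables.
#' @param n_perm number of random sign assignments.
#' @param rng_seed integer seed.
#' @return list: `statistic` (observed), `p` (permutation p-value with the
#'   add-one correction).
#' @export
multivariate_permutation_test <- function(D, n_perm = 10000L, rng_seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D); m <- ncol(D)
  stopifnot(n >= 2)
  ss <- colSums(D^2)
  t2_from_means <- function(mu) {
    # var = (ss - n*mu^2)/(n-1); t^2 = mu^2 / (var/n)
    v <- (rep(ss, each = nrow(mu)) - n * mu^2) / (n - 1)
    t2 <- n * mu^2 / pmax(v, 1e-300)
    t2[abs(mu) < 1e-300] <- 0
    rowSums(t2)
  }
  mu_obs <- matrix(colMeans(D), 1)
  stat_obs <- t2_from_means(mu_obs)
  with_seed(rng_seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    mu_perm <- (S %*% D) / n
    stat_perm <- t2_from_means(mu_perm)
    p <- (1 + sum(stat_perm >= stat_obs - 1e-12)) / (1 + n_perm)
    list(statistic = as.numeric(stat_obs), p = p)
  })
}
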