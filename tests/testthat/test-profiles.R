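mk_clusters <- function(labels, retained = rep(TRUE, length(labels)),
                        identity = NULL, k = max(labels)) {
  ident <- identity %||% setNames(column_names(4L)[seq_len(k)],
                                  as.character(seq_len(k)))
  structure(list(labels = labels, silhouette = rep(1, length(labels)),
                 retained = retained,
                 seed_coords = cbind(seq_along(labels), 1L, 1L),
                 side = "left", k = k, cutoff = 0.25,
                 column_identity = ident),
            class = "pag_clusters")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("total seed connectivity averages per-sample target hits", {
  tc <- cbind(t_a = c(10, 0, 5), t_b = c(0, 0, 0), t_c = c(100, 50, 30))
  cm <- fake_connectivity(matrix(1, 3, 4), tc, n_samples = 10000)
  tot <- total_seed_connectivity(cm, prob_threshold = 3e-4)
  expect_equal(tot$mean_prob[tot$target == "t_a"], 0.0005)   # (10+0+5)/3/10000
  expect_false(tot$removed[tot$target == "t_a"])             # 5e-4 >= 3e-4
  expect_true(tot$removed[tot$target == "t_b"])              # zero connectivity
  expect_false(tot$removed[tot$target == "t_c"])
})

test_that("a target fully covering a deterministic ray has probability 1", {
  ph <- uniform_phantom(dir = c(1, 0, 0))
  cm <- track_seed_mask(ph, tracking_params(n_samples = 50, rng_seed = 3),
                        "left")
  tot <- total_seed_connectivity(cm)
  expect_equal(tot$mean_prob[tot$target == "t_slab"], 1)
})

test_that("column profiles give per-column means and conserved relative shares", {
  tc <- cbind(t_a = c(100, 100, 0, 0), t_b = c(0, 0, 50, 50),
              t_c = c(20, 20, 20, 20))
  cm <- fake_connectivity(matrix(1, 4, 4), tc, n_samples = 1000)
  cl <- mk_clusters(c(1L, 1L, 2L, 2L), k = 2)
  prof <- column_profiles(cl, cm, c("t_a", "t_b", "t_c"))
  p_a1 <- prof$mean_prob[prof$column == "dm" & prof$target == "t_a"]
  expect_equal(p_a1, 0.1)
  expect_equal(prof$relative[prof$column == "dm" & prof$target == "t_b"], 0)
  shares <- tapply(prof$relative, prof$target, sum)
  expect_equal(as.numeric(shares), rep(1, 3), tolerance = 1e-9)
})

test_that("retained-voxel filtering and empty columns are handled", {
  tc <- cbind(t_a = c(100, 0, 50), t_b = c(0, 100, 50))
  cm <- fake_connectivity(matrix(1, 3, 4), tc, n_samples = 1000)
  cl <- mk_clusters(c(1L, 1L, 2L), retained = c(TRUE, FALSE, TRUE), k = 2)
  prof <- column_profiles(cl, cm, c("t_a", "t_b"))
  # column 1 mean uses only the retained voxel
  expect_equal(prof$mean_prob[prof$column == "dm" & prof$target == "t_a"], 0.1)
  cl2 <- mk_clusters(c(1L, 1L, 2L), retained = c(TRUE, TRUE, FALSE), k = 2)
  expect_warning(prof2 <- column_profiles(cl2, cm, c("t_a", "t_b")),
                 "no retained voxels")
  expect_false("dl" %in% prof2$column)
})

test_that("restricting the target set does not change other targets' values", {
  tc <- cbind(t_a = c(100, 30, 50, 10), t_b = c(5, 100, 50, 80),
              t_c = c(7, 3, 9, 2))
  cm <- fake_connectivity(matrix(1, 4, 4), tc, n_samples = 1000)
  cl <- mk_clusters(c(1L, 1L, 2L, 2L), k = 2)
  full <- column_profiles(cl, cm, c("t_a", "t_b", "t_c"))
  part <- column_profiles(cl, cm, c("t_a", "t_b"))
  m <- merge(full, part, by = c("column", "target"))
  expect_equal(m$mean_prob.x, m$mean_prob.y)
  expect_equal(m$relative.x, m$relative.y)
})

simulate_profiles <- function(n_subjects, targets = 5,
                              shift = rep(0, targets), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (cn in c("A", "B")) {
      mu <- exp(rnorm(targets, -6, 0.5))
      if (cn == "B") mu <- mu * exp(shift)
      rows[[paste(s, cn)]] <- data.frame(
        subject = s, column = cn, target = paste0("t", seq_len(targets)),
        mean_prob = mu * exp(rnorm(targets, 0, 0.3)), relative = NA)
    }
  }
  do.call(rbind, rows)
}

test_that("pairwise tests: Bonferroni arithmetic and t-test agreement", {
  prof <- simulate_profiles(10, shift = c(1, 0, 0, 0, 0), seed = 4)
  res <- pairwise_column_tests(prof, n_perm = 500, rng_seed = 9)
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, res$pairwise$p_raw * 1))   # one pair -> factor = 1
  # three columns -> 3 pairs, factor 3
  prof3 <- rbind(prof,
                 transform(prof[prof$column == "A", ], column = "C",
                           mean_prob = mean_prob * exp(0.2)))
  res3 <- pairwise_column_tests(prof3, n_perm = 200, rng_seed = 9)
  expect_equal(res3$pairwise$p_bonferroni,
               pmin(1, res3$pairwise$p_raw * 3))
  # raw p matches a direct paired t-test
  d <- prof[prof$column == "A" & prof$target == "t1", "mean_prob"] -
       prof[prof$column == "B" & prof$target == "t1", "mean_prob"]
  p_ref <- t.test(d)$p.value
  expect_equal(res$pairwise$p_raw[res$pairwise$target == "t1"], p_ref)
})

test_that("a genuine profile difference is detected, an identical pair is not", {
  prof_alt <- simulate_profiles(12, shift = c(1.5, -1.5, 0, 0, 0), seed = 7)
  res_alt <- pairwise_column_tests(prof_alt, n_perm = 2000, rng_seed = 3)
  expect_lt(res_alt$multivariate$p_perm, 0.05)
  prof_null <- simulate_profiles(12, seed = 8)
  res_null <- pairwise_column_tests(prof_null, n_perm = 2000, rng_seed = 3)
  expect_gt(res_null$multivariate$p_perm, 0.05)
})

test_that("fewer than three subjects is an error", {
  prof <- simulate_profiles(2)
  expect_error(pairwise_column_tests(prof), "insufficient")
})

test_that("permutation p-values are deterministic given the seed", {
  prof <- simulate_profiles(8, seed = 2)
  r1 <- pairwise_column_tests(prof, n_perm = 300, rng_seed = 5)
  r2 <- pairwise_column_tests(prof, n_perm = 300, rng_seed = 5)
  expect_identical(r1$multivariate$p_perm, r2$multivariate$p_perm)
})

test_that("wilcoxon switch produces valid paired p-values", {
  prof <- simulate_profiles(10, shift = c(2, 0, 0, 0, 0), seed = 11)
  res <- pairwise_column_tests(prof, n_perm = 200, rng_seed = 1,
                               method = "wilcoxon")
  expect_true(all(res$pairwise$p_raw >= 0 & res$pairwise$p_raw <= 1))
  expect_lt(res$pairwise$p_raw[res$pairwise$target == "t1"], 0.05)
})
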