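test_that("cross-correlation matrix has the Pearson structure", {
  x <- rbind(c(1, 2, 3, 4, 0, 0),
             c(2, 4, 6, 8, 0, 0),      # identical profile shape to row 1
             c(0, 0, 0, 0, 5, 5),      # disjoint support
             c(1, 0, 2, 0, 3, 1))
  cc <- cross_correlation_matrix(x, prob_threshold = 0, bin = 1L)
  R <- cc$R
  expect_equal(R[1, 2], 1)
  expect_equal(R[1, 3], cor(x[1, ], x[3, ]))   # hand Pearson, negative
  expect_lt(R[1, 3], 0)
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 4))
})

test_that("zero-variance profiles are excluded, all-zero input errors", {
  x <- rbind(c(1, 2, 3), c(3, 2, 1), c(0, 0, 0))
  cc <- cross_correlation_matrix(x, prob_threshold = 0, bin = 1L)
  expect_equal(cc$valid, c(TRUE, TRUE, FALSE))
  expect_equal(dim(cc$R), c(2L, 2L))
  expect_error(cross_correlation_matrix(matrix(0, 4, 3), prob_threshold = 0,
                                        bin = 1L),
               "degenerate")
})

test_that("profile thresholding zeroes exactly the sub-floor counts", {
  counts <- rbind(c(0, 2, 3, 10), c(1, 4, 0, 2))
  cm <- fake_connectivity(counts, matrix(0, 2, 1,
                                         dimnames = list(NULL, "t")),
                          n_samples = 10000)
  pm <- profile_matrix(cm, prob_threshold = 3e-4, bin = 1L)
  expect_equal(pm[1, seq_len(4)], c(0, 0, 3, 10))   # 2/10000 < 3e-4 removed
  expect_equal(pm[2, seq_len(4)], c(0, 4, 0, 0))
})

test_that("k-means recovers well-separated blobs exactly", {
  set.seed(31)
  x <- rbind(matrix(rnorm(40 * 5, 0), ncol = 5),
             matrix(rnorm(40 * 5, 8), ncol = 5))
  truth <- rep(1:2, each = 40)
  lab <- kmeans_columns(x, k = 2, n_restarts = 10, rng_seed = 2)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  lab2 <- kmeans_columns(x, k = 2, n_restarts = 10, rng_seed = 2)
  expect_identical(lab, lab2)
  expect_error(kmeans_columns(x, k = 81), "exceeds")
  expect_error(kmeans_columns(x, k = 1), ">= 2")
})

test_that("silhouettes match the naive textbook implementation", {
  set.seed(17)
  for (rep in 1:3) {
    n <- c(6, 9, 12)[rep]
    x <- matrix(rnorm(n * 7), n, 7)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- labels[1] %% 3 + 1
    s_pkg <- silhouette_values(x, labels)
    s_ref <- naive_silhouette(x, labels)
    expect_equal(s_pkg, s_ref, tolerance = 1e-12)
    expect_true(all(s_pkg >= -1 & s_pkg <= 1))
  }
})

test_that("perfectly separated clusters are not filtered; ambiguous voxels are", {
  x <- rbind(matrix(rep(c(5, 0, 0), each = 4), 4),
             matrix(rep(c(0, 5, 0), each = 4), 4))
  x <- x + matrix(rnorm(24, sd = 0.01), 8)
  labels <- rep(1:2, each = 4)
  sf <- silhouette_filter(x, labels, cutoff = 0.25)
  expect_true(all(sf$silhouette > 0.9))
  expect_true(all(sf$retained))
  expect_error(silhouette_values(x, rep(1, 8)), "single cluster")
})

test_that("silhouette filtering is monotone in the cutoff", {
  set.seed(5)
  x <- matrix(rnorm(30 * 6), 30, 6)
  labels <- kmeans_columns(x, 3, n_restarts = 5, rng_seed = 1)
  prev <- rep(TRUE, 30)
  for (cut in c(-1, 0, 0.1, 0.25, 0.5, 0.9)) {
    ret <- silhouette_filter(x, labels, cutoff = cut)$retained
    expect_true(all(ret <= prev))   # retained set only shrinks
    prev <- ret
  }
})

test_that("truth-label clusters are assigned their generating sector identities", {
  cfg <- small_config(geometry_jitter_mm = 0, rng_seed = 2L)
  ph <- template_phantom(cfg)
  sc <- seed_coords(ph, "left")
  tl <- ph$truth_labels[cbind(sc[, 1], sc[, 2], sc[, 3])]
  cl <- structure(list(labels = tl, silhouette = rep(1, length(tl)),
                       retained = rep(TRUE, length(tl)), seed_coords = sc,
                       side = "left", k = 4L, cutoff = 0.25),
                  class = "pag_clusters")
  cl <- assign_column_identities(cl, ph)
  expect_equal(unname(cl$column_identity), c("dm", "dl", "l", "vl"))
  expect_true(all(cl$columnar))
})

test_that("a rostro-caudally split cluster is flagged non-columnar", {
  cfg <- small_config(geometry_jitter_mm = 0, rng_seed = 2L)
  ph <- template_phantom(cfg)
  sc <- seed_coords(ph, "left")
  tl <- ph$truth_labels[cbind(sc[, 1], sc[, 2], sc[, 3])]
  zs <- sc[, 3]
  z_lo <- sort(unique(zs))[1:2]
  z_hi <- sort(unique(zs))[5:6]
  # cluster 1: two separated axial segments of sector 1 (rostral + caudal)
  lab <- tl
  lab[tl == 1 & !(zs %in% c(z_lo, z_hi))] <- 2L
  cl <- structure(list(labels = lab, silhouette = rep(1, length(lab)),
                       retained = rep(TRUE, length(lab)), seed_coords = sc,
                       side = "left", k = 4L, cutoff = 0.25),
                  class = "pag_clusters")
  cl <- assign_column_identities(cl, ph)
  expect_false(cl$columnar[1])
  expect_equal(unname(cl$column_identity[1]), "unassigned")
})

test_that("single-voxel clusters are scored by their own angle and flagged by the rule", {
  cfg <- small_config(geometry_jitter_mm = 0, rng_seed = 2L)
  ph <- template_phantom(cfg)
  sc <- seed_coords(ph, "left")
  tl <- ph$truth_labels[cbind(sc[, 1], sc[, 2], sc[, 3])]
  lab <- tl
  one <- which(tl == 3)[1]
  lab[tl == 3] <- 4L
  lab[one] <- 3L                       # cluster 3 = a single voxel
  cl <- structure(list(labels = lab, silhouette = rep(1, length(lab)),
                       retained = rep(TRUE, length(lab)), seed_coords = sc,
                       side = "left", k = 4L, cutoff = 0.25),
                  class = "pag_clusters")
  cl <- assign_column_identities(cl, ph)
  v <- sc[one, ]
  own_angle <- atan2(abs(v[1] - ph$center[1]), v[2] - ph$center[2])
  expect_equal(cl$cluster_angles[3], own_angle)
  expect_false(cl$columnar[3])         # one slice < 60% of the seed length
})

test_that("identities and success metrics are invariant to cluster relabeling", {
  cfg <- small_config(geometry_jitter_mm = 0, rng_seed = 2L)
  ph <- template_phantom(cfg)
  sc <- seed_coords(ph, "left")
  tl <- ph$truth_labels[cbind(sc[, 1], sc[, 2], sc[, 3])]
  perm <- c(3L, 1L, 4L, 2L)
  mk <- function(lab) structure(
    list(labels = lab, silhouette = rep(1, length(lab)),
         retained = rep(TRUE, length(lab)), seed_coords = sc, side = "left",
         k = 4L, cutoff = 0.25), class = "pag_clusters")
  cl1 <- assign_column_identities(mk(tl), ph)
  cl2 <- assign_column_identities(mk(perm[tl]), ph)
  for (g in 1:4)
    expect_equal(unname(cl1$column_identity[as.character(g)]),
                 unname(cl2$column_identity[as.character(perm[g])]))
  expect_equal(evaluate_success(list(cl1)), evaluate_success(list(cl2)))
})

test_that("success evaluation counts assigned columnar identities per side", {
  cfg <- small_config(geometry_jitter_mm = 0, rng_seed = 2L)
  ph <- template_phantom(cfg)
  sc <- seed_coords(ph, "left")
  tl <- ph$truth_labels[cbind(sc[, 1], sc[, 2], sc[, 3])]
  mk <- function(lab) structure(
    list(labels = lab, silhouette = rep(1, length(lab)),
         retained = rep(TRUE, length(lab)), seed_coords = sc, side = "left",
         k = 4L, cutoff = 0.25), class = "pag_clusters")
  good <- assign_column_identities(mk(tl), ph)
  # break dm into two axial halves -> dm unassigned on that side
  zs <- sc[, 3]; zmid <- stats::median(unique(zs))
  lab_bad <- tl
  lab_bad[tl == 1 & zs > zmid] <- 2L
  lab_bad[tl == 2 & zs <= zmid] <- 1L
  bad <- assign_column_identities(mk(lab_bad), ph)
  succ <- evaluate_success(list(good, good, bad))
  expect_equal(unname(succ["l"]), 1)
  expect_equal(unname(succ["vl"]), 1)
  expect_lt(succ["dm"], 1)
  expect_equal(unname(evaluate_success(list())), rep(0, 4))
})
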