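test_that("deterministic straight field yields the closed-form path", {
  ph <- uniform_phantom(dir = c(1, 0, 0))
  tp <- tracking_params(n_samples = 1, step_size_mm = 0.75, rng_seed = 1)
  path <- propagate_streamline(ph, c(3, 5, 5), tp, init_dir = c(1, 0, 0))
  k <- seq_len(nrow(path)) - 1
  expect_equal(path[, 1], 3 + k * 0.5)   # 0.75 mm = 0.5 voxel at 1.5 mm
  expect_equal(path[, 2], rep(5, nrow(path)))
  expect_equal(path[, 3], rep(5, nrow(path)))
  # terminates by leaving the grid near x = 15
  expect_gt(max(path[, 1]), 14)
})

test_that("zero-dispersion visit counts equal n_samples on the oracle ray and 0 elsewhere", {
  ph <- uniform_phantom(dir = c(2, 1, 0))     # oblique ray
  tp <- tracking_params(n_samples = 100, rng_seed = 42)
  cm <- track_seed_mask(ph, tp, "left")
  dims <- dim(ph$brain_mask)
  oracle <- ray_voxels(c(3, 5, 5), c(2, 1, 0), 0.5, dims,
                       ph$brain_mask, ph$aqueduct_mask)
  counts <- as.numeric(cm$counts[1, ])
  expect_equal(sort(which(counts > 0)), oracle)
  expect_true(all(counts[oracle] == 100))
  expect_true(all(counts[-oracle] == 0))
})

test_that("aqueduct mask hard-terminates the path", {
  ph <- uniform_phantom(dir = c(1, 0, 0),
                        aqueduct = cbind(10, 1:9, rep(1:9, each = 9)))
  tp <- tracking_params(n_samples = 10, rng_seed = 9)
  cm <- track_seed_mask(ph, tp, "left")
  hit <- index_coords <- which(as.numeric(cm$counts[1, ]) > 0)
  xs <- ((hit - 1) %% dim(ph$brain_mask)[1]) + 1
  expect_true(all(xs < 10))   # nothing at or beyond the stop plane forward
})

test_that("finite-kappa sampling matches an independent rejection sampler", {
  ph <- uniform_phantom(dir = c(0, 0, 1), kappa = 20)
  mu <- c(0, 0, 1)
  n <- 20000
  set.seed(123)
  draws <- sample_orientation(ph$field, c(8, 5, 5), prev_dir = mu, n = n)
  ang <- acos(pmin(1, draws %*% mu))
  set.seed(456)
  ref <- rejection_vmf(mu, 20, n)
  ang_ref <- acos(pmin(1, abs(ref %*% mu)))  # axial: fold to the hemisphere
  se <- sqrt(var(ang) / n + var(ang_ref) / n)
  expect_lt(abs(mean(ang) - mean(ang_ref)), 4 * se)
})

test_that("orientation sign resolves against the previous direction", {
  ph <- uniform_phantom(dir = c(1, 0, 0), kappa = Inf)
  d_fwd <- sample_orientation(ph$field, c(5, 5, 5), prev_dir = c(1, 0, 0))
  d_bwd <- sample_orientation(ph$field, c(5, 5, 5), prev_dir = c(-1, 0, 0))
  expect_equal(as.numeric(d_fwd), c(1, 0, 0))
  expect_equal(as.numeric(d_bwd), c(-1, 0, 0))
  # the contract holds for dispersed draws too
  ph2 <- uniform_phantom(dir = c(1, 0, 0), kappa = 15)
  dr <- sample_orientation(ph2$field, c(5, 5, 5), prev_dir = c(1, 0, 0), n = 500)
  expect_true(all(dr %*% c(1, 0, 0) >= 0))
})

test_that("a zero curvature limit terminates at the first required turn", {
  # field bends 90 degrees at x > 8
  dims <- c(15L, 15L, 7L)
  dirs <- array(0, dim = c(dims, 3, 1))
  dirs[1:8, , , 1, 1] <- 1
  dirs[9:15, , , 2, 1] <- 1
  field <- orientation_field(dirs, array(1, dim = c(dims, 1)),
                             array(Inf, dim = dims))
  ph <- uniform_phantom(dims = dims, dir = c(1, 0, 0), seed_vox = c(3L, 8L, 4L))
  ph$field <- field
  tp0 <- tracking_params(n_samples = 1, curvature_limit_deg = 0, rng_seed = 1)
  path0 <- propagate_streamline(ph, c(3, 8, 4), tp0, init_dir = c(1, 0, 0))
  expect_lt(max(path0[, 1]), 9.6)        # stopped at the bend
  expect_equal(max(path0[, 2]), 8)       # never turned
  tp80 <- tracking_params(n_samples = 1, curvature_limit_deg = 100, rng_seed = 1)
  path80 <- propagate_streamline(ph, c(3, 8, 4), tp80, init_dir = c(1, 0, 0))
  expect_gt(max(path80[, 2]), 13)        # generous limit follows the bend
})

test_that("sampled paths on a dispersed phantom respect the curvature contract", {
  cfg <- small_config(rng_seed = 4L)
  ph <- generate_phantom(cfg)
  sc <- seed_coords(ph, "left")
  tp <- tracking_params(n_samples = 1, curvature_limit_deg = 80, rng_seed = 21)
  for (i in seq(1, nrow(sc), length.out = 15)) {
    tp$rng_seed <- 100 + i
    path <- propagate_streamline(ph, sc[round(i), ], tp)
    if (nrow(path) < 3) next
    steps <- diff(path)
    steps <- steps / sqrt(rowSums(steps^2))
    turns <- acos(pmin(1, rowSums(steps[-1, , drop = FALSE] *
                                    steps[-nrow(steps), , drop = FALSE])))
    expect_lte(max(turns), 80 * pi / 180 + 1e-6)
  }
})

test_that("connection probability arithmetic and the removal floor", {
  expect_equal(connection_probability(3, 10000), 3e-4)
  expect_equal(connection_probability(0, 10000), 0)
  p <- connection_probability(c(0, 2, 3, 10), 10000)
  kept <- threshold_probabilities(p, 3e-4)
  expect_equal(kept, c(0, 0, 3e-4, 1e-3))   # 2/10000 removed, 3/10000 survives
  expect_error(connection_probability(3, 0))
})

test_that("raising the probability floor never grows the surviving set", {
  set.seed(8)
  for (rep in 1:20) {
    p <- runif(50, 0, 2e-3)
    prev <- threshold_probabilities(p, 0)
    for (thr in c(1e-4, 3e-4, 6e-4, 1e-3)) {
      cur <- threshold_probabilities(p, thr)
      expect_true(all(which(cur > 0) %in% which(prev > 0)))
      prev <- cur
    }
  }
})

test_that("tracking is reproducible and respects the per-sample count cap", {
  cfg <- small_config(rng_seed = 6L)
  ph <- generate_phantom(cfg)
  tp <- tracking_params(n_samples = 60, rng_seed = 77)
  cm1 <- track_seed_mask(ph, tp, "left")
  cm2 <- track_seed_mask(ph, tp, "left")
  expect_identical(cm1$counts, cm2$counts)
  expect_identical(cm1$target_counts, cm2$target_counts)
  expect_true(all(cm1$counts@x <= 60))       # one count per sample per voxel
  expect_true(all(cm1$target_counts <= 60))
  cm3 <- track_seed_mask(ph, tracking_params(n_samples = 60, rng_seed = 78), "left")
  expect_false(identical(cm1$counts, cm3$counts))
})

test_that("degenerate tracking inputs are rejected", {
  ph <- uniform_phantom()
  expect_error(tracking_params(n_samples = 0))
  ph$seed_mask_left[] <- FALSE
  expect_error(track_seed_mask(ph, tracking_params(n_samples = 5), "left"),
               "empty seed mask")
})
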