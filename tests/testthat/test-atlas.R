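test_that("PCA atlas reconstructs every training row through its own scores", {
  x <- generate_atlas_training(fixture_spec(n_train = 40, n_features = 50), seed = 3)
  atlas <- fit_atlas(x)
  scores <- atlas_encode(atlas, x)
  back <- atlas_decode(atlas, scores)
  expect_lt(max(abs(back - x)), 1e-8)
})

test_that("a full-rank 94-subject training matrix yields 93 components", {
  expect_identical(shared_atlas$K, 93L)
  expect_identical(shared_atlas$n_train, 94L)
})

test_that("atlas modes are orthonormal and score samples are centred", {
  g <- crossprod(shared_atlas$modes)
  expect_lt(max(abs(g - diag(shared_atlas$K))), 1e-8)
  means <- vapply(shared_atlas$score_samples, mean, numeric(1))
  expect_lt(max(abs(means)), 1e-8)
})

test_that("collinear rows give one component matching the hand eigendecomposition", {
  d <- c(3, 4, 0)
  t_i <- c(-1, 0.5, 2)
  x <- sweep(outer(t_i, d), 2, c(10, 20, 30), `+`)
  expect_warning(atlas <- fit_atlas(x), "rank-deficient")
  expect_identical(atlas$K, 1L)
  # independent oracle: leading eigenvector of the covariance matrix
  ev <- eigen(stats::cov(x))$vectors[, 1]
  align <- abs(sum(atlas$modes[, 1] * ev))
  expect_equal(align, 1, tolerance = 1e-10)
  expect_equal(abs(sum(atlas$modes[, 1] * d / sqrt(sum(d^2)))), 1,
               tolerance = 1e-10)
})

test_that("degenerate training inputs are rejected", {
  expect_error(fit_atlas(matrix(1, 2, 5)), "at least 3")
  expect_error(fit_atlas(matrix(1, 5, 3)), "at least as many features")
  x <- matrix(rnorm(25), 5, 5)
  x[2, 3] <- NA
  expect_error(fit_atlas(x), "non-finite")
})

test_that("zero scores return the mean features and quantile 0.5 the score medians", {
  f <- sample_patient_features(shared_atlas, n = 1,
                               scores = rep(0, shared_atlas$K))
  expect_equal(as.vector(f), unname(shared_atlas$mean_features), tolerance = 1e-10)

  f_med <- sample_patient_features(shared_atlas, n = 1,
                                   quantiles = matrix(0.5, 1, shared_atlas$K))
  med_scores <- vapply(shared_atlas$score_samples, stats::median, numeric(1))
  expect_equal(as.vector(atlas_encode(shared_atlas, f_med)), med_scores,
               tolerance = 1e-8)
})

test_that("sampled scores follow the training score distributions (KS at 1%)", {
  set.seed(42)
  n <- 10000
  f <- sample_patient_features(shared_atlas, n = n)
  scores <- atlas_encode(shared_atlas, f)
  for (j in c(1, 2, 5, 20, 93)) {
    train <- shared_atlas$score_samples[[j]]
    d <- suppressWarnings(stats::ks.test(scores[, j], train)$statistic)
    crit <- 1.628 * sqrt((length(train) + n) / (length(train) * n))
    expect_lt(unname(d), crit)
  }
})

test_that("areal BMD of a uniform slab equals density times thickness", {
  rho <- 0.8
  slab <- array(rho, dim = c(4, 5, 3))
  # thickness along y: 5 voxels x 2 mm = 1 cm
  expect_equal(compute_abmd(slab, voxel_mm = c(1, 2, 1)), rho * 1)
  expect_equal(compute_abmd(slab, voxel_mm = c(1, 4, 1)), rho * 2)
})

test_that("areal BMD is homogeneous of degree 1 in density", {
  set.seed(9)
  vol <- array(runif(60, 0.1, 1.5), dim = c(3, 4, 5))
  base <- compute_abmd(vol, voxel_mm = c(1.5, 1, 2))
  for (s in c(0.5, 2, 10)) {
    expect_equal(compute_abmd(s * vol, voxel_mm = c(1.5, 1, 2)), s * base,
                 tolerance = 1e-12)
  }
  expect_equal(compute_abmd(0 * vol, voxel_mm = c(1, 1, 1)), 0)
})

test_that("ROI selection works and empty ROIs are rejected", {
  vol <- array(1, dim = c(4, 4, 4))
  vol[, 1:2, ] <- 2 # denser anterior half
  roi <- list(x = 1:4, y = 1:2, z = 1:4)
  # thickness 2 voxels x 1 mm = 0.2 cm at density 2
  expect_equal(compute_abmd(vol, voxel_mm = c(1, 1, 1), roi = roi), 2 * 0.2)
  expect_error(compute_abmd(vol, voxel_mm = c(1, 1, 1),
                            roi = list(x = integer(0), y = 1:4, z = 1:4)),
               "empty ROI")
})
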