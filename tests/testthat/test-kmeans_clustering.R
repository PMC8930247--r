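test_that("pixel features are patch mean and std, matching hand arithmetic", {
  img <- const_image(0.4, 6)
  f <- pixel_features(img, 1L)
  expect_lt(max(abs(f[, "mean"] - 0.4)), 1e-14)
  expect_lt(max(f[, "sd"]), 1e-14)

  set.seed(30)
  m <- matrix(round(runif(25), 2), 5, 5)
  f <- pixel_features(gray_image(m), 1L)
  patch <- m[2:4, 2:4]                       # interior pixel (3,3)
  i <- 3L + (3L - 1L) * 5L                   # column-major index
  expect_equal(unname(f[i, "mean"]), mean(patch))
  expect_equal(unname(f[i, "sd"]), sqrt(mean((patch - mean(patch))^2)))
})

test_that("features away from edges of a two-level image have zero std", {
  img <- step_image(12, 0.3, 0.9)
  f <- pixel_features(img, 1L)
  fm <- matrix(f[, "mean"], 12, 12)
  fs <- matrix(f[, "sd"], 12, 12)
  expect_lt(max(abs(fm[, 1:4] - 0.3)), 1e-14)
  expect_lt(max(fs[, 1:4]), 1e-14)
  expect_lt(max(abs(fm[, 9:12] - 0.9)), 1e-14)
})

test_that("init_centers picks K distinct pixels deterministically", {
  f <- pixel_features(random_image(8, seed = 1), 1L)
  c1 <- init_centers(f, 5, seed = 3)
  c2 <- init_centers(f, 5, seed = 3)
  expect_identical(c1, c2)
  expect_identical(dim(c1), c(5L, 2L))
  expect_identical(nrow(init_centers(f, nrow(f), seed = 1)), nrow(f))
  expect_error(init_centers(f, nrow(f) + 1L, seed = 1), "exceeds")
})

test_that("assignment picks the nearest center with lowest-index ties", {
  feats <- matrix(c(0.3, 0), 1, 2)
  centers <- rbind(c(0.2, 0), c(0.8, 0))
  expect_identical(assign_step(feats, centers), 1L)
  # exactly equidistant from centers 0 and 1 -> lowest index
  feats <- matrix(c(0.5, 0), 1, 2)
  centers <- rbind(c(0, 0), c(1, 0))
  expect_identical(assign_step(feats, centers), 1L)
  # all pixels coincide with one center
  feats <- matrix(rep(c(0.8, 0), 4), 4, 2, byrow = TRUE)
  expect_true(all(assign_step(feats, centers) == 2L))
})

test_that("update step takes member means and reseeds empty clusters", {
  feats <- rbind(c(0.2, 0), c(0.4, 0), c(0.9, 0.1))
  centers <- update_step(feats, labels = c(1L, 1L, 2L), K = 2L)
  expect_equal(centers[1, ], c(0.3, 0))
  expect_equal(centers[2, ], c(0.9, 0.1))
  # cluster 3 empty -> reseeded to the point farthest from its nearest
  # center; points 1 and 2 tie at squared distance 0.01, first one wins
  centers <- update_step(feats, labels = c(1L, 1L, 2L), K = 3L)
  expect_equal(centers[3, ], c(0.2, 0))
})

test_that("K = 1 converges to the global feature mean", {
  f <- pixel_features(random_image(8, seed = 5), 1L)
  cl <- kmeans_run(f, 1L, seed = 0)
  expect_true(cl$converged)
  expect_lte(cl$iterations, 2L)
  expect_equal(as.numeric(cl$centers), unname(colMeans(unclass(f))))
  expect_true(all(cl$labels == 1L))
})

test_that("two delta-separated populations are perfectly recovered from any seed", {
  feats <- rbind(matrix(rep(c(0.1, 0.02), 50), 50, 2, byrow = TRUE),
                 matrix(rep(c(0.9, 0.02), 50), 50, 2, byrow = TRUE))
  truth <- rep(1:2, each = 50)
  for (seed in 1:10) {
    cl <- kmeans_run(feats, 2L, seed = seed)
    expect_true(cl$converged)
    # compare partitions, not raw labels (label permutation invariance)
    expect_identical(length(unique(paste(cl$labels, truth))), 2L)
    expect_equal(sort(cl$centers[, 1]), c(0.1, 0.9))
  }
})

test_that("objective trace is non-increasing and the run is seed-reproducible", {
  for (seed in 1:10) {
    set.seed(seed + 500)
    feats <- matrix(runif(64 * 64 * 2), ncol = 2)
    cl <- kmeans_run(feats, 4L, seed = seed)
    expect_true(all(diff(cl$objective_trace) <= 1e-9))
  }
  f <- pixel_features(small_phantom(3), 2L)
  a <- kmeans_run(f, 4L, seed = 7)
  b <- kmeans_run(f, 4L, seed = 7)
  expect_identical(a[c("labels", "centers", "iterations")],
                   b[c("labels", "centers", "iterations")])
})

test_that("a converged state terminates after one verification pass", {
  feats <- rbind(matrix(rep(c(0.1, 0), 10), 10, 2, byrow = TRUE),
                 matrix(rep(c(0.9, 0), 10), 10, 2, byrow = TRUE))
  cl1 <- kmeans_run(feats, 2L, seed = 1)
  # restart from the converged centers via a run whose init hits them
  labels <- assign_step(feats, cl1$centers)
  centers2 <- update_step(feats, labels, 2L)
  expect_equal(centers2, cl1$centers, tolerance = 1e-15)
})

test_that("max_iter exhaustion flags converged = FALSE without error", {
  set.seed(77)
  feats <- matrix(runif(400), ncol = 2)
  cl <- kmeans_run(feats, 5L, seed = 1, max_iter = 1L)
  expect_false(cl$converged)
  expect_identical(cl$iterations, 1L)
})

test_that("partition agrees with stats::kmeans on well-separated data", {
  # independent cross-check of the clustering route
  set.seed(99)
  feats <- rbind(cbind(rnorm(40, 0.2, 0.01), rnorm(40, 0.1, 0.01)),
                 cbind(rnorm(40, 0.8, 0.01), rnorm(40, 0.3, 0.01)))
  ours <- kmeans_run(feats, 2L, seed = 2)
  ref <- stats::kmeans(feats, centers = 2L, nstart = 5)
  agree <- table(ours$labels, ref$cluster)
  # every one of our clusters maps to exactly one reference cluster
  expect_true(all(rowSums(agree > 0) == 1))
  expect_equal(sort(ours$centers[, 1]), sort(unname(ref$centers[, 1])),
               tolerance = 1e-8)
})
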