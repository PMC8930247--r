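test_that("patch_distance is zero at i == j and symmetric in i, j", {
  img <- random_image(9, seed = 2)
  cfg <- patch_config(patch_radius = 2L, search_radius = 4L)
  expect_identical(patch_distance(img, c(4, 5), c(4, 5), cfg), 0)
  pairs <- list(list(c(1, 1), c(9, 9)), list(c(3, 7), c(6, 2)),
                list(c(1, 5), c(5, 1)))
  for (p in pairs) {
    expect_equal(patch_distance(img, p[[1]], p[[2]], cfg),
                 patch_distance(img, p[[2]], p[[1]], cfg))
  }
})

test_that("patch_distance with a uniform kernel matches hand summation", {
  set.seed(10)
  m <- matrix(round(runif(25), 2), 5, 5)
  img <- gray_image(m)
  cfg <- patch_config(patch_radius = 1L, search_radius = 2L,
                      gaussian_sigma = Inf)
  # interior pixels (3,2) and (3,4): plain mean squared patch difference
  expected <- sum((m[2:4, 1:3] - m[2:4, 3:5])^2) / 9
  expect_equal(patch_distance(img, c(3, 2), c(3, 4), cfg), expected)
})

test_that("gradient magnitude is exact on constants and linear ramps", {
  expect_true(all(gradient_magnitude(const_image(0.3, 6)) == 0))
  g <- 0.05
  ramp <- gray_image(matrix(rep(g * (0:9), each = 10), 10, 10))
  gm <- gradient_magnitude(ramp)
  expect_equal(max(abs(gm[, 2:9] - g)), 0)   # interior columns exact
})

test_that("gradient magnitude matches the hand-evaluated stencil on a spike", {
  v <- 0.8
  m <- matrix(0, 3, 3); m[2, 2] <- v
  gm <- gradient_magnitude(gray_image(m))
  expect_equal(gm[2, 2], 0)               # symmetric neighbors cancel
  # the 4-neighbors of the center see v/2 (mirror-padded central diff)
  expect_equal(gm[1, 2], v / 2)
  expect_equal(gm[2, 1], v / 2)
  expect_equal(gm[3, 2], v / 2)
  expect_equal(gm[2, 3], v / 2)
})

test_that("constant images are exact fixed points of all filter variants", {
  img <- const_image(0.42, 10)
  cfg <- fast_config(h = 0.1)
  expect_equal(unclass(nlmeans_denoise(img, cfg)), unclass(img),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(unclass(nlmeans_gradient_denoise(img, cfg)), unclass(img),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(unclass(knl_denoise(img, knl_config(cfg, K = 2))),
               unclass(img), tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("windowed filter agrees with the brute-force oracle at whole-image search", {
  img <- random_image(12, seed = 4)
  for (use_grad in c(FALSE, TRUE)) {
    cfg <- patch_config(patch_radius = 2L, search_radius = Inf,
                        h = 0.15, use_gradient = use_grad)
    fast <- if (use_grad) nlmeans_gradient_denoise(img, cfg) else
      nlmeans_denoise(img, cfg)
    slow <- naive_oracle_denoise(img, cfg)
    expect_lt(max(abs(unclass(fast) - unclass(slow))), 1e-10)
  }
})

test_that("oracle handles the degenerate 1x1 image and refuses large input", {
  one <- gray_image(matrix(0.7, 1, 1))
  expect_equal(unclass(naive_oracle_denoise(one, patch_config(h = 0.1)))[1, 1],
               0.7)
  expect_error(naive_oracle_denoise(gray_image(matrix(0.5, 40, 40)),
                                    patch_config(h = 0.1)),
               "32x32")
})

test_that("weights are nonnegative, sum to one, and give a convex combination", {
  img <- random_image(16, seed = 6)
  cfg <- fast_config(h = 0.1)
  den <- unclass(nlmeans_denoise(img, cfg))
  for (px in list(c(1, 1), c(8, 8), c(16, 3))) {
    wf <- nlmeans_weights(img, px, cfg)
    expect_true(all(wf$weights >= 0))
    expect_lt(abs(sum(wf$weights) - 1), 1e-10)
    cand_vals <- unclass(img)[wf$candidates]
    expect_gte(den[px[1], px[2]], min(cand_vals))
    expect_lte(den[px[1], px[2]], max(cand_vals))
  }
})

test_that("output range is contained in input range", {
  img <- random_image(20, seed = 8)
  for (fun in list(nlmeans_denoise, nlmeans_gradient_denoise)) {
    den <- fun(img, fast_config(h = 0.2))
    expect_gte(min(den), min(img))
    expect_lte(max(den), max(img))
  }
})

test_that("very large h drives every pixel to its candidate-window mean", {
  img <- random_image(10, seed = 9)
  cfg <- patch_config(patch_radius = 1L, search_radius = Inf, h = 1e6)
  den <- nlmeans_denoise(img, cfg)
  expect_equal(unclass(den),
               matrix(mean(img), 10, 10), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("denoising commutes with horizontal mirroring", {
  img <- random_image(14, seed = 12)
  cfg <- fast_config(h = 0.12)
  mirror <- function(m) m[, ncol(m):1]
  for (fun in list(nlmeans_denoise, nlmeans_gradient_denoise)) {
    a <- mirror(unclass(fun(img, cfg)))
    b <- unclass(fun(gray_image(mirror(unclass(img))), cfg))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("gradient augmentation sharpens the detail/flat weight discrimination", {
  # On the normalized scale gradient differences are < 1, so the
  # pointwise product shrinks every distance: at equal h the gradient
  # variant smooths more overall.  What the augmentation buys is
  # relative: for a flat target pixel, candidates whose patches carry
  # structural detail (high gradient magnitude, here the step edge)
  # see their patch distance grow relative to flat same-class
  # candidates, so per unit of flat-region smoothing, detail-region
  # candidates are suppressed much harder.
  set.seed(20)
  base <- unclass(step_image(16))     # low cols 1:8, high cols 9:16
  noisy <- gray_image(pmin(pmax(base + rnorm(256, sd = 0.03), 0), 1))
  quot <- sapply(c(FALSE, TRUE), function(g) {
    cfg <- patch_config(patch_radius = 1L, search_radius = 6L, h = 0.1,
                        use_gradient = g)
    vals <- sapply(2:15, function(r) {
      i <- c(r, 6)                 # flat pixel, patch fully on low side
      d_detail <- patch_distance(noisy, i, c(r, 9), cfg)  # edge patch
      d_flat <- patch_distance(noisy, i, c(r, 3), cfg)    # flat patch
      d_detail / d_flat
    })
    median(vals)
  })
  expect_gt(quot[2], quot[1])
})

test_that("denoising raises PSNR on the speckled phantom across seeds", {
  ph <- small_phantom(seed = 2, n = 48)
  gains <- vapply(0:19, function(s) {
    noisy <- add_speckle(ph, speckle_params(0.2, seed = s))
    cfg <- patch_config(patch_radius = 1L, search_radius = 5L)
    psnr(ph, nlmeans_denoise(noisy, cfg)) - psnr(ph, noisy)
  }, 0)
  expect_gt(mean(gains), 0)
})

test_that("patch_config validates its hyperparameters", {
  expect_error(patch_config(patch_radius = 0), ">= 1")
  expect_error(patch_config(search_radius = 1, patch_radius = 2),
               "search_radius")
  expect_error(patch_config(h = -1), "`h`")
  expect_error(patch_config(a = 0), "`a`")
  expect_error(patch_config(gaussian_sigma = 0), "gaussian_sigma")
  cfg <- patch_config(search_radius = Inf)
  expect_true(is.infinite(cfg$search_radius))
})
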