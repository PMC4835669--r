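test_that("normalized raw stress matches its definition", {
  x0 <- planted_config(2, seed = 5, labels = letters[1:4])
  d0 <- as.matrix(dist(x0))

  # exact distances -> 0; all points coincident -> 1
  expect_equal(mds_stress(d0, x0), 0)
  expect_equal(mds_stress(d0, matrix(0, 4, 2, dimnames = list(letters[1:4], NULL))), 1)

  # brute-force double-loop oracle on an arbitrary configuration
  set.seed(8)
  cfg <- matrix(rnorm(8), 4, 2, dimnames = list(letters[1:4], NULL))
  expect_equal(mds_stress(d0, cfg), oracle_stress(d0, cfg), tolerance = 1e-12)

  srcs <- simulate_sources(x0, n_sources = 3, noise_sd = 0.1, seed = 2)
  expect_equal(mds_stress(srcs, cfg), oracle_stress(srcs, cfg), tolerance = 1e-12)

  # label alignment and degenerate input
  bad <- d0; rownames(bad) <- colnames(bad) <- LETTERS[1:4]
  expect_error(mds_stress(bad, cfg), "labels")
  expect_error(mds_stress(matrix(0, 4, 4, dimnames = dimnames(d0)), cfg),
               "degenerate")
})

test_that("stress is invariant under isometries of the configuration", {
  x0 <- planted_config(3, seed = 6)
  srcs <- simulate_sources(x0, noise_sd = 0.05, seed = 3)
  s0 <- mds_stress(srcs, x0)
  set.seed(10)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))  # random orthogonal transform
  moved <- x0 %*% q + matrix(c(3, -1, 7), nrow(x0), 3, byrow = TRUE)
  rownames(moved) <- rownames(x0)
  expect_equal(mds_stress(srcs, moved), s0, tolerance = 1e-12)
})

test_that("initial configurations behave as specified", {
  # classical start recovers a planted configuration from exact distances
  x0 <- planted_config(3, seed = 4)
  init <- mds_init(16, 3, "classical", sources = as.matrix(dist(x0)))
  expect_lt(procrustes_disparity(x0, init), 1e-8)

  # simplex start: equilateral triangle for 3 objects in 2D
  tri <- mds_init(3, 2, "simplex")
  d <- dist(tri)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)
  expect_equal(unname(colMeans(tri)), c(0, 0), tolerance = 1e-12)

  # random start is seeded and centered
  r1 <- mds_init(10, 2, "random", seed = 42)
  r2 <- mds_init(10, 2, "random", seed = 42)
  expect_identical(r1, r2)
  expect_equal(unname(colMeans(r1)), c(0, 0), tolerance = 1e-12)

  expect_error(mds_init(3, 3, "classical", sources = as.matrix(dist(x0[1:3, ]))),
               "ndim < n_objects")
})

test_that("the engine recovers a planted 16 x 3 configuration from exact distances", {
  x0 <- planted_config(3, seed = 1)
  srcs <- simulate_sources(x0, n_sources = 1, noise_sd = 0, seed = 1)
  fit <- mds_fit(srcs, ndim = 3)
  expect_lt(fit$stress, 1e-6)
  expect_lt(procrustes_disparity(x0, fit$configuration), 1e-3)
  expect_equal(unname(colMeans(fit$configuration)), rep(0, 3), tolerance = 1e-9)
  expect_equal(fit$fit + fit$stress, 1)
})

test_that("final stress matches a brute-force optimizer oracle on small instances", {
  for (seed in c(21, 22)) {
    x0 <- planted_config(2, seed = seed, labels = letters[1:5])
    src <- simulate_sources(x0, n_sources = 1, noise_sd = 0.3, seed = seed)
    fit <- mds_fit(src, ndim = 2, restarts = 10, seed = seed, tol = 1e-9)
    oracle <- oracle_min_stress(src[[1]], ndim = 2, n_starts = 50, seed = seed)
    expect_lte(fit$stress, oracle + 1e-4)
  }
})

test_that("majorization never increases stress", {
  x0 <- planted_config(3, seed = 2)
  srcs <- simulate_sources(x0, n_sources = 4, noise_sd = 0.2, seed = 17)
  fit <- mds_fit(srcs, ndim = 3, tol = 1e-8)
  imp <- fit$trajectory$improvement[-1]
  expect_true(all(imp >= -1e-12))
  # iteration 0 of the trajectory is the stress of the initial configuration
  expect_equal(fit$trajectory$stress[1],
               mds_stress(srcs, mds_init(16, 3, "classical", sources = srcs)),
               tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("weighted stress downweights entries and zero-weights missing ones", {
  x0 <- planted_config(2, seed = 9, labels = letters[1:5])
  d0 <- as.matrix(dist(x0))
  d_noisy <- d0; d_noisy[1, 2] <- d_noisy[2, 1] <- d0[1, 2] * 5
  w <- matrix(1, 5, 5); w[1, 2] <- w[2, 1] <- 0
  expect_equal(mds_stress(d_noisy, x0, weights = w), 0)  # bad entry masked
  fit <- mds_fit(d_noisy, ndim = 2, weights = w, tol = 1e-10)
  expect_lt(fit$stress, 1e-8)
  d_na <- d_noisy; d_na[1, 2] <- d_na[2, 1] <- NA
  expect_equal(mds_stress(d_na, x0), 0)  # NA entries get weight 0
})

test_that("total fit and the Kruskal rule of thumb are as stated", {
  expect_equal(total_fit(0.04), 0.96)
  expect_equal(total_fit(0), 1)
  expect_equal(total_fit(1), 0)
  expect_error(total_fit(1.2), "\\[0, 1\\]")
  expect_equal(kruskal_label(0), "perfect")
  expect_equal(kruskal_label(0.05), "good")
  expect_equal(kruskal_label(c(0.02, 0.07, 0.15, 0.3)),
               c("excellent", "fair", "poor", "unacceptable"))
  expect_error(kruskal_label(-0.1), "nonnegative")
})

test_that("scree saturates at the planted dimensionality on noiseless data", {
  x0 <- planted_config(3, seed = 12)
  srcs <- simulate_sources(x0, n_sources = 4, noise_sd = 0, seed = 5)
  sc <- mds_scree(srcs, dims = 1:5, tol = 1e-9)
  expect_equal(nrow(sc), 5L)
  expect_gt(sc$fit[sc$ndim == 3], 1 - 1e-6)
  expect_lt(sc$gain[sc$ndim == 4], 1e-6)
  expect_equal(select_ndim(sc), 3L, ignore_attr = TRUE)
})

test_that("warm-started scree has non-decreasing fit and single-row ranges work", {
  x0 <- planted_config(2, seed = 13, labels = letters[1:8])
  srcs <- simulate_sources(x0, n_sources = 2, noise_sd = 0.3, seed = 13)
  sc <- mds_scree(srcs, dims = 1:5, warm_start = TRUE)
  expect_true(all(diff(sc$fit) >= -1e-12))
  sc1 <- mds_scree(srcs, dims = 1)
  expect_equal(nrow(sc1), 1L)
  expect_equal(sc1$gain, sc1$fit)  # the 1D row's gain is over the trivial model
})

test_that("select_ndim picks the first dimensionality with a sub-threshold successor", {
  gains <- c(0.5, 0.2, 0.1, 0.005, 0.004)
  sc <- structure(data.frame(ndim = 1:5, stress = 1 - cumsum(gains),
                             fit = cumsum(gains), gain = gains),
                  class = c("mds_scree", "data.frame"))
  expect_equal(select_ndim(sc), 3L, ignore_attr = TRUE)
  expect_warning(p <- select_ndim(sc, gain_threshold = 1e-4), "max")
  expect_equal(as.integer(p), 5L)
  expect_true(attr(p, "all_gains_above_threshold"))
  expect_error(select_ndim(sc[0, ]), "empty")
})

test_that("fit object methods are coherent", {
  x0 <- planted_config(3, seed = 30)
  srcs <- simulate_sources(x0, n_sources = 4, noise_sd = 0.05, seed = 30)
  fit <- mds_fit(srcs, ndim = 3)
  expect_s3_class(fit, "mds_fit")
  expect_identical(coef(fit), fit$configuration)
  fd <- fitted(fit)
  expect_s3_class(fd, "proximity_matrix")
  expect_equal(unclass(fd), as.matrix(dist(fit$configuration)), ignore_attr = TRUE)
  res <- residuals(fit)
  expect_length(res, 4L)
  expect_equal(res[[1]], srcs[[1]] - unclass(fd), ignore_attr = TRUE)
  expect_output(print(fit), "normalized raw stress")
  expect_output(print(summary(fit)), "Frontier")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
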