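# Spatial analysis: kernel weights, Gaussian amplification, local bivariate
# Moran's I, permutation significance, four-way segmentation.

test_that("kernel weights follow the Gaussian density with a radius cutoff", {
  coords <- rbind(c(0, 0), c(1, 0), c(10, 0))
  kw <- kernel_weights(coords, sigma = 1, radius = 2)
  W <- kw$weights
  expect_equal(W[1, 2], dnorm(1, 0, 1), tolerance = 1e-12)
  expect_equal(W[2, 1], W[1, 2])   # symmetry
  expect_equal(W[1, 3], 0)         # beyond the radius
  expect_true(all(diag(W) == 0))   # no self weight by default
  kw_self <- kernel_weights(coords, sigma = 1, radius = 2, self_weight = TRUE)
  expect_equal(unname(diag(kw_self$weights)), rep(dnorm(0, 0, 1), 3))
  expect_error(kernel_weights(coords, sigma = -1, radius = 2), "> 0")
  # duplicate coordinates are allowed (distance zero)
  expect_silent(kernel_weights(rbind(c(0, 0), c(0, 0), c(1, 1)),
                               sigma = 1, radius = 3))
})

test_that("gaussian amplification is a convex neighbourhood average", {
  set.seed(10)
  coords <- as.matrix(expand.grid(1:6, 1:6))
  f <- spatial_field(coords, rnorm(36))
  # constant field is a fixed point
  const <- spatial_field(coords, rep(3.5, 36))
  expect_equal(gaussian_amplify(const, sigma = 1, radius = 3)$values,
               rep(3.5, 36), tolerance = 1e-12)
  # radius below the spot spacing reduces to the identity
  expect_equal(gaussian_amplify(f, sigma = 1, radius = 0.5)$values,
               f$values, tolerance = 1e-12)
  # brute-force oracle on 3 collinear spots at distances (0, 1, 2)
  tri <- spatial_field(rbind(c(0, 0), c(1, 0), c(2, 0)), c(2, -1, 5))
  amp <- gaussian_amplify(tri, sigma = 1, radius = 2.5)
  expect_equal(amp$values,
               oracle_amplify(tri$coordinates, tri$values, 1, 2.5),
               tolerance = 1e-12)
  # general oracle agreement and convexity bounds
  amp2 <- gaussian_amplify(f, sigma = 1.2, radius = 3)
  expect_equal(amp2$values,
               oracle_amplify(coords, f$values, 1.2, 3), tolerance = 1e-12)
  expect_true(all(amp2$values >= min(f$values) - 1e-12))
  expect_true(all(amp2$values <= max(f$values) + 1e-12))
  # the paper-literal unnormalized form multiplies the centre value
  lit <- gaussian_amplify(tri, sigma = 1, radius = 2.5, literal = TRUE)
  wsum <- sapply(1:3, function(i)
    sum(dnorm(abs(tri$coordinates[, 1] - tri$coordinates[i, 1]), 0, 1)))
  expect_equal(lit$values, tri$values * wsum, tolerance = 1e-12)
})

test_that("local bivariate Moran's I matches the double-sum oracle", {
  set.seed(2)
  coords <- as.matrix(expand.grid(1:5, 1:5))
  x <- spatial_field(coords, rnorm(25))
  y <- spatial_field(coords, rnorm(25))
  kw <- kernel_weights(coords, sigma = 1, radius = 3)
  I <- local_bivariate_moran(x, y, kw)
  expect_equal(I, oracle_moran(x$values, y$values, kw$weights),
               tolerance = 1e-12)
  # y identically zero (raw scale) gives I = 0 everywhere
  y0 <- spatial_field(coords, rep(0, 25))
  expect_equal(local_bivariate_moran(x, y0, kw, scale = FALSE), rep(0, 25))
  # a spot with a zero weight row contributes I = 0 (raw scale)
  xs <- spatial_field(coords, c(1, rep(0, 24)))
  W0 <- kw; W0$weights[1, ] <- 0
  expect_equal(local_bivariate_moran(xs, y, W0, scale = FALSE)[1], 0)
  # hand-set 3-spot configuration
  w3 <- structure(list(weights = rbind(c(0, 2, 1), c(2, 0, 0.5),
                                       c(1, 0.5, 0)),
                       sigma = 1, radius = 10, self_weight = FALSE),
                  class = "kernel_weights")
  x3 <- spatial_field(rbind(c(0, 0), c(1, 0), c(2, 0)), c(1, -1, 2))
  y3 <- spatial_field(x3$coordinates, c(0.5, 2, -1))
  expect_equal(local_bivariate_moran(x3, y3, w3, scale = FALSE),
               oracle_moran(x3$values, y3$values, w3$weights, scale = FALSE),
               tolerance = 1e-12)
  # scale invariance of the z-scored default
  xc <- spatial_field(coords, 7 * x$values)
  expect_equal(local_bivariate_moran(xc, y, kw), I, tolerance = 1e-12)
  expect_error(local_bivariate_moran(spatial_field(coords, rep(1, 25)), y, kw),
               "zero variance")
})

test_that("permutation pseudo-p-values are bounded, seeded, and reproducible", {
  pair <- simulate_spatial_pair(6, "strong", seed = 4)
  kw <- kernel_weights(pair$x$coordinates)
  res <- permutation_pvalues(pair$x, pair$y, kw, n_permutations = 199,
                             seed = 31)
  expect_true(all(res$pseudo_p >= 1 / 200))
  expect_true(all(res$pseudo_p <= 1))
  res2 <- permutation_pvalues(pair$x, pair$y, kw, n_permutations = 199,
                              seed = 31)
  expect_identical(res$pseudo_p, res2$pseudo_p)
  # strong colocalization drives many concordant spots to the lower bound
  expect_gt(mean(res$pseudo_p < 0.05), 0.2)
  # bare-proportion variant can reach zero but never exceeds the add-one p
  res3 <- permutation_pvalues(pair$x, pair$y, kw, n_permutations = 199,
                              seed = 31, add_one = FALSE)
  expect_true(all(res3$pseudo_p <= res$pseudo_p))
})

test_that("segmentation assigns the four dependency labels by sign pattern", {
  set.seed(9)
  coords <- as.matrix(expand.grid(1:8, 1:8))
  x <- spatial_field(coords, rnorm(64))
  y <- spatial_field(coords, rnorm(64))
  kw <- kernel_weights(coords)
  # all p = 1 (degenerate result) -> everything not significant
  res_all1 <- structure(list(local_I = rep(0, 64), pseudo_p = rep(1, 64),
                             n_permutations = 9L, seed = 1L,
                             alternative = "greater"),
                        class = "moran_result")
  labs <- segment_regions(x, y, kw, res_all1)
  expect_true(all(labs == "not_significant"))
  # force significance everywhere and check the sign-pattern rule directly
  res_all0 <- res_all1
  res_all0$pseudo_p <- rep(0.001, 64)
  labs2 <- segment_regions(x, y, kw, res_all0)
  zx <- scale(x$values)[, 1]
  ny <- drop(kw$weights %*% scale(y$values)[, 1])
  expect_identical(as.character(labs2[zx > 0 & ny > 0][1]),
                   "high_antigen_high_T")
  expect_identical(as.character(labs2[zx > 0 & ny <= 0][1]),
                   "high_antigen_low_T")
  expect_identical(as.character(labs2[zx <= 0 & ny > 0][1]),
                   "low_antigen_high_T")
  expect_identical(as.character(labs2[zx <= 0 & ny <= 0][1]),
                   "low_antigen_low_T")
  # labels partition the spot set
  expect_false(any(is.na(labs2)))
  # a z-score of exactly zero resolves to the low side, deterministically
  xz <- x$values; xz[5] <- mean(xz[-5])  # makes xz[5] equal the overall mean
  x0 <- spatial_field(coords, xz)
  zx0 <- scale(x0$values)[, 1]
  expect_lt(abs(zx0[5]), 1e-10)
  l0 <- segment_regions(x0, y, kw, res_all0)
  expect_true(as.character(l0[5]) %in%
                c("low_antigen_high_T", "low_antigen_low_T"))
  expect_error(segment_regions(spatial_field(coords, rep(1, 64)), y, kw,
                               res_all0), "zero variance")
})
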