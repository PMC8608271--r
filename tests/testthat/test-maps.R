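# Spatial analysis: axes, smoothing, interpolation, imputation,
# correlations, hemisphere tests, joint PCA and the CCA best direction.

test_that("along-axis distance equals arc position for collinear sites", {
  t <- seq(0, 10, length.out = 8)
  coords <- cbind(t / sqrt(2), t / sqrt(2))      # the line y = x
  along <- along_hg_distance(coords)
  expect_equal(as.numeric(along), t, tolerance = 1e-9)
})

test_that("isotropic clouds trigger the unstable-axis warning", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  expect_warning(along_hg_distance(cbind(cos(th), sin(th))), "isotropic")
})

test_that("an elongated array at 40 degrees is recovered within 5 degrees", {
  set.seed(4)
  t <- runif(40, 0, 20); a <- 40 * pi / 180
  coords <- cbind(t * cos(a) + rnorm(40, 0, 0.5),
                  t * sin(a) + rnorm(40, 0, 0.5))
  along <- along_hg_distance(coords)
  ax <- attr(along, "axis")
  ang <- atan2(ax[2], ax[1]) * 180 / pi
  expect_lt(abs((ang - 40 + 90) %% 180 - 90), 5)
})

test_that("knn smoothing has the stated fixed points and contractions", {
  set.seed(5)
  coords <- matrix(runif(24, 0, 10), 12)
  const <- rep(3.3, 12)
  expect_equal(knn_smooth(const, coords), const)
  # one outlier among uniform neighbors smooths to the neighbor mean
  v <- rep(1, 12); v[4] <- 50
  sm <- knn_smooth(v, coords, k = 4)
  expect_equal(sm[4], 1)
  # k = N-1 equals the leave-one-out mean
  sm_all <- knn_smooth(v, coords, k = 11)
  loo <- vapply(1:12, function(i) mean(v[-i]), 0)
  expect_equal(sm_all, loo)
  # variance contraction on random fields
  x <- rnorm(12)
  expect_lte(var(knn_smooth(x, coords, k = 4)), var(x))
})

test_that("piecewise-linear interpolation reproduces planar fields", {
  set.seed(6)
  coords <- rbind(matrix(runif(30, 0, 10), 15),
                  c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  v <- 2 * coords[, 1] - 3 * coords[, 2] + 1
  gx <- seq(1, 9, by = 2); gy <- seq(1, 9, by = 2)
  surf <- interpolate_surface(v, coords, gx, gy)
  want <- outer(gx, gy, function(x, y) 2 * x - 3 * y + 1)
  expect_equal(surf, want, tolerance = 1e-6)
  # queries outside the hull are masked
  out <- interpolate_surface(v, coords, c(-5), c(-5))
  expect_true(is.na(out[1, 1]))
  expect_error(interpolate_surface(1:3, cbind(1:3, 1:3), 1, 1), "collinear")
})

test_that("nearest-neighbor imputation copies the closest observed value", {
  coords <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  v <- c(NA, 3.2, 9)
  expect_equal(impute_missing(v, coords), c(3.2, 3.2, 9))
  expect_error(impute_missing(c(NA, NA, NA), coords), "missing")
})

test_that("feature-axis correlation is exact on identical inputs", {
  along <- seq(0, 20, length.out = 15)
  r <- feature_axis_correlation(along, along)
  expect_equal(r$r, 1)
  expect_error(feature_axis_correlation(rep(1, 15), along), "variance")
  # permuted values fall in the null band
  set.seed(7)
  rs <- replicate(200, feature_axis_correlation(sample(along), along)$r)
  expect_lt(quantile(abs(rs), 0.5), 2 / sqrt(15))
})

test_that("hemisphere comparison detects shifts and preserves sizes", {
  set.seed(8)
  v <- c(rnorm(64), rnorm(68))
  h <- rep(c("L", "R"), c(64, 68))
  same <- compare_hemispheres(v, h)
  expect_equal(same$n_left, 64)
  expect_equal(same$n_right, 68)
  v2 <- v; v2[h == "L"] <- v2[h == "L"] + 5
  expect_lt(compare_hemispheres(v2, h)$p, 1e-6)
})

test_that("joint PCA concentrates on correlated features with fixed signs", {
  set.seed(9)
  n <- 80
  base <- rnorm(n)
  X <- cbind(f1 = base + rnorm(n, 0, 0.1), f2 = base + rnorm(n, 0, 0.1),
             f3 = rnorm(n), f4 = rnorm(n))
  pc <- joint_pca(X)
  w1 <- abs(pc$weights[, 1])
  expect_true(all(w1[c("f1", "f2")] > 2 * w1[c("f3", "f4")]))
  expect_gt(pc$weights[which.max(abs(pc$weights[, 1])), 1], 0)
  # permuting feature columns permutes the weights, nothing else
  perm <- c(3, 1, 4, 2)
  pc2 <- joint_pca(X[, perm])
  expect_equal(pc2$var_frac, pc$var_frac, tolerance = 1e-9)
  expect_equal(abs(pc2$weights[, 1]), abs(pc$weights[perm, 1]),
               tolerance = 1e-9)
  Xc <- cbind(X, f5 = rep(2, n))
  expect_error(joint_pca(Xc), "f5")
})

test_that("CCA recovers planted directions and r", {
  set.seed(10)
  coords <- cbind(runif(60, 0, 20), runif(60, 0, 20))
  out <- cca_best_direction(coords[, 1], coords)
  expect_equal(out$a, c(1, 0), tolerance = 1e-6)
  expect_equal(out$r, 1, tolerance = 1e-9)
  y45 <- (coords[, 1] + coords[, 2]) / sqrt(2) + rnorm(60, 0, 1)
  out45 <- cca_best_direction(y45, coords)
  expect_lt(abs((out45$angle_deg - 45 + 90) %% 180 - 90), 10)
  expect_error(cca_best_direction(1:10, cbind(rep(1, 10), rep(2, 10))),
               "degenerate")
})

test_that("random projections give directions uniform on the circle", {
  set.seed(11)
  coords <- cbind(runif(50, 0, 20), runif(50, 0, 20))
  angs <- vapply(1:200, function(i)
    cca_best_direction(rnorm(50), coords)$angle_deg, 0)
  expect_gt(rayleigh_test(angs)$p, 0.01)
  # sanity: concentrated angles are rejected
  expect_lt(rayleigh_test(rnorm(200, 45, 3))$p, 1e-6)
})
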