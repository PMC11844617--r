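# Agreement metrics against brute-force oracles.

test_that("relative L2 error matches its definition", {
  x <- matrix(rnorm(40), 20, 2)
  expect_equal(unname(l2_relative_error(x, x)), c(0, 0))
  expect_equal(unname(l2_relative_error(1.01 * x, x)), c(1, 1),
               tolerance = 1e-12)
  set.seed(2)
  y <- x + matrix(rnorm(40, 0, 0.1), 20, 2)
  brute <- 100 * sqrt(sum((y[, 1] - x[, 1])^2) / sum(x[, 1]^2))
  expect_equal(unname(l2_relative_error(y, x))[1], brute,
               tolerance = 1e-12)
})

test_that("MSD equals the brute-force double loop and is symmetric", {
  expect_equal(mean_symmetric_distance(matrix(1:6, 2, 3),
                                       matrix(1:6, 2, 3)), 0)
  expect_equal(mean_symmetric_distance(matrix(c(0, 0, 0), 1),
                                       matrix(c(3, 4, 0), 1)), 5)
  set.seed(5)
  P <- matrix(rnorm(150), 50, 3)
  R <- matrix(rnorm(150), 50, 3)
  brute <- function(P, R) {
    dPR <- apply(P, 1, function(p)
      min(sqrt(colSums((t(R) - p)^2))))
    dRP <- apply(R, 1, function(r)
      min(sqrt(colSums((t(P) - r)^2))))
    0.5 * (mean(dPR) + mean(dRP))
  }
  expect_equal(mean_symmetric_distance(P, R), brute(P, R),
               tolerance = 1e-12)
  expect_equal(mean_symmetric_distance(P, R),
               mean_symmetric_distance(R, P), tolerance = 1e-14)
  expect_equal(data_loss_msd(P, R), mean_symmetric_distance(P, R))
})

test_that("HD95 matches brute force, symmetry, and translation", {
  set.seed(6)
  # translated copy of a unit grid: the shift is smaller than half the
  # grid spacing, so every nearest neighbor is the point's own copy
  P <- as.matrix(expand.grid(1:5, 1:5, 1:4))
  d <- c(0.1, -0.15, 0.2)
  R <- sweep(P, 2, d, "+")
  expect_equal(hausdorff95(P, R), sqrt(sum(d^2)), tolerance = 1e-12)
  P <- matrix(rnorm(300), 100, 3)
  R2 <- matrix(rnorm(300), 100, 3)
  brute <- function(P, R) {
    dPR <- apply(P, 1, function(p) min(sqrt(colSums((t(R) - p)^2))))
    dRP <- apply(R, 1, function(r) min(sqrt(colSums((t(P) - r)^2))))
    quantile(c(dPR, dRP), 0.95, names = FALSE)
  }
  expect_equal(hausdorff95(P, R2), brute(P, R2), tolerance = 1e-12)
  expect_equal(hausdorff95(P, R2), hausdorff95(R2, P), tolerance = 1e-14)
  expect_gte(hausdorff95(P, R2, direction = "max"), hausdorff95(P, R2))
  expect_equal(hausdorff95(P, P), 0, tolerance = 1e-7)
})

test_that("tangent modulus comes from the quadratic fit at the percentile", {
  # exactly linear cloud returns the slope at any percentile
  strain <- seq(0, 0.3, length.out = 40)
  expect_equal(tangent_modulus(strain, 7 * strain), 7, tolerance = 1e-10)
  # noiseless quadratic sigma = 2 e^2 + e: slope 2*2*e75 + 1
  stress <- 2 * strain^2 + strain
  e75 <- quantile(strain, 0.75, names = FALSE)
  expect_equal(tangent_modulus(strain, stress), 4 * e75 + 1,
               tolerance = 1e-10)
  # cloud whose 75th strain percentile is exactly 0.15 (order statistic)
  s2 <- c(0, 0.05, 0.1, 0.15, 0.2)
  expect_equal(quantile(s2, 0.75, names = FALSE), 0.15)
  expect_equal(tangent_modulus(s2, 2 * s2^2 + s2), 1.6, tolerance = 1e-8)
  # order-invariance and agreement with explicit normal equations
  set.seed(9)
  e <- runif(60, 0, 0.25)
  s <- 3 * e^2 + 0.5 * e + 0.01 + rnorm(60, 0, 1e-3)
  perm <- sample(60)
  expect_equal(tangent_modulus(e, s), tangent_modulus(e[perm], s[perm]),
               tolerance = 1e-10)
  A <- cbind(1, e, e^2)
  cf <- solve(t(A) %*% A, t(A) %*% s)
  expect_equal(tangent_modulus(e, s),
               2 * cf[3] * quantile(e, 0.75, names = FALSE) + cf[2],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("MSE data loss matches the brute-force mean", {
  set.seed(3)
  a <- matrix(rnorm(30), 10, 3)
  b <- matrix(rnorm(30), 10, 3)
  expect_equal(data_loss_mse(a, a), 0)
  expect_equal(data_loss_mse(a + 0.3, a), 0.09, tolerance = 1e-12)
  expect_equal(data_loss_mse(a, b), mean((a - b)^2))
})

test_that("MSD subgradient decreases the loss along its negative", {
  set.seed(8)
  P <- matrix(rnorm(60), 20, 3)
  R <- matrix(rnorm(60), 20, 3)
  g <- pinnelast:::msd_with_grad(P, R)
  expect_equal(g$value, mean_symmetric_distance(P, R), tolerance = 1e-12)
  step <- 1e-3
  v2 <- mean_symmetric_distance(P - step * g$grad / max(abs(g$grad)), R)
  expect_lt(v2, g$value)
  # directional derivative check along a random direction
  V <- matrix(rnorm(60), 20, 3)
  h <- 1e-7
  fd <- (mean_symmetric_distance(P + h * V, R) -
           mean_symmetric_distance(P - h * V, R)) / (2 * h)
  expect_equal(sum(g$grad * V), fd, tolerance = 1e-5)
})
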