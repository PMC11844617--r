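# Closed-form benchmark solutions as self-consistent oracles.

test_that("cylinder displacement matches direct evaluation of the form", {
  case <- cylinder_case()
  u <- cylinder_displacement(c(1, 0), case)
  # ri^2 Pi r / (E (ro^2 - ri^2)) [1 - nu + (ro/r)^2 (1 + nu)] at r = ri
  expect_equal(u[1, 1], 1e-5 * (0.7 + 25 * 1.3) / (0.135 * 24),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(u[1, 2], 0, ignore_attr = TRUE)
  # symmetry axis x = 0: ux = 0
  u2 <- cylinder_displacement(cbind(0, seq(1, 5, length.out = 9)), case)
  expect_equal(u2[, 1], rep(0, 9), ignore_attr = TRUE)
  # radial displacement decreases monotonically outward
  r <- seq(1, 5, length.out = 200)
  ur <- cylinder_displacement(cbind(r, 0), case)[, 1]
  expect_true(all(diff(ur) < 0))
  expect_error(cylinder_displacement(c(0, 0), case), "outside")
})

test_that("cylinder stresses satisfy the boundary conditions exactly", {
  case <- cylinder_case()
  th <- seq(0.01, pi / 2 - 0.01, length.out = 7)
  Xi <- cbind(cos(th), sin(th))
  Xo <- 5 * Xi
  si <- cylinder_stress(Xi, case)
  so <- cylinder_stress(Xo, case)
  # radial stress: sigma_rr = n' sigma n with n the radial direction
  srr_i <- si[, 1] * Xi[, 1]^2 + si[, 2] * Xi[, 2]^2 +
    2 * si[, 3] * Xi[, 1] * Xi[, 2]
  nro <- Xo / 5
  srr_o <- so[, 1] * nro[, 1]^2 + so[, 2] * nro[, 2]^2 +
    2 * so[, 3] * nro[, 1] * nro[, 2]
  expect_equal(srr_i, rep(-1e-5, 7), tolerance = 1e-15)
  expect_equal(srr_o, rep(0, 7), tolerance = 1e-20)
})

test_that("cylinder stresses are in equilibrium (finite differences)", {
  case <- cylinder_case()
  cs <- sample_quarter_annulus(quarter_annulus(1.2, 4.8), 200, 0, seed = 5)
  X <- cs$points
  sfun <- function(Z) cylinder_stress(Z, case)
  gx <- fd_partial(sfun, X, 1)
  gy <- fd_partial(sfun, X, 2)
  res <- cbind(gx[, 1] + gy[, 3], gx[, 3] + gy[, 2])
  expect_lt(max(abs(res)), 1e-8 * case$P_internal / case$r_inner)
})

test_that("plate deflection matches the printed closed form", {
  # E = 1e6, q = 1e6 (N/m^2 units): D = 91.575, uz(0) = q a^4/(64 D)
  case <- plate_case(radius = 1, thickness = 0.1, q = 1e6,
                     params = elastic_params(1e6, 0.3))
  D <- flexural_rigidity(case$params, 0.1)
  expect_equal(D, 1e6 * 1e-3 / (12 * 0.91), tolerance = 1e-12)
  expect_equal(plate_deflection(c(0, 0), case), 1e6 / (64 * D),
               tolerance = 1e-12)
  # clamped edge: uz = 0 and the gradient vanishes
  th <- seq(0, 2 * pi, length.out = 11)
  edge <- cbind(cos(th), sin(th))
  expect_equal(plate_deflection(edge, case), rep(0, 11))
  g <- fd_partial(function(Z) plate_deflection(Z, case), edge, 1, 1e-7)
  expect_lt(max(abs(g)), 1e-6 * plate_deflection(c(0, 0), case))
})

test_that("plate deflection satisfies the biharmonic equation", {
  case <- plate_case()
  set.seed(6)
  X <- sample_disk(clamped_disk(0.7, 0.1), 50, 0, seed = 6)$points
  h <- 1e-2
  lap <- function(f, X) {
    (f(cbind(X[, 1] + h, X[, 2])) + f(cbind(X[, 1] - h, X[, 2])) +
       f(cbind(X[, 1], X[, 2] + h)) + f(cbind(X[, 1], X[, 2] - h)) -
       4 * f(X)) / h^2
  }
  uz <- function(Z) plate_deflection(Z, case)
  bih <- lap(function(Z) lap(uz, Z), X)
  target <- case$q / case$D
  expect_lt(max(abs(bih - target)) / target, 1e-6)
})

test_that("top-surface stresses follow the kinematic + plane-stress chain", {
  case <- plate_case()
  expect_equal(unname(plate_top_stress(c(0.3, -0.2), case, z = 0)),
               c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(unname(plate_top_stress(c(0, 0), case)[1, 3]), 0)
  # cross-module consistency: -E z/(1-nu^2)... equals C . plate_strain
  set.seed(12)
  X <- matrix(runif(10, -0.6, 0.6), 5, 2)
  s1 <- plate_top_stress(X, case)
  hfun <- function(Z) plate_deflection(Z, case)
  h <- 1e-4
  uxx <- (hfun(cbind(X[, 1] + h, X[, 2])) - 2 * hfun(X) +
            hfun(cbind(X[, 1] - h, X[, 2]))) / h^2
  uyy <- (hfun(cbind(X[, 1], X[, 2] + h)) - 2 * hfun(X) +
            hfun(cbind(X[, 1], X[, 2] - h))) / h^2
  uxy <- (hfun(X + h) - hfun(cbind(X[, 1] + h, X[, 2] - h)) -
            hfun(cbind(X[, 1] - h, X[, 2] + h)) + hfun(X - h)) / (4 * h^2)
  eps <- plate_strain(0.05, cbind(uxx, uyy, uxy))
  s2 <- eps %*% plane_stress_matrix(case$params)
  expect_equal(unname(s1), unname(s2), tolerance = 1e-6)
})

test_that("reference datasets are exact, noisy on request, reproducible", {
  case <- cylinder_case()
  f0 <- build_reference_dataset("cylinder", case, 200, seed = 3)
  expect_equal(f0$u, cylinder_displacement(f0$points, case),
               ignore_attr = TRUE)
  fn <- build_reference_dataset("cylinder", case, 10000, noise_sd = 1e-6,
                                seed = 3)
  resid <- fn$u - cylinder_displacement(fn$points, case)
  expect_lt(abs(sd(as.numeric(resid)) - 1e-6) / 1e-6, 0.05)
  f1 <- build_reference_dataset("cylinder", case, 200, seed = 3)
  expect_identical(f0$u, f1$u)
})

test_that("displacement fields normalize safely and round-trip to disk", {
  pts <- matrix(runif(30), 10, 3)
  u <- cbind(rnorm(10), rnorm(10), rep(0, 10))  # flat z component
  f <- displacement_field(pts, u)
  expect_equal(f$stats$sd[3], 1)
  expect_true(f$stats$flat[3])
  path <- tempfile(fileext = ".txt")
  write_displacement_field(f, path)
  g <- read_displacement_field(path)
  expect_equal(g$points, f$points, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(g$u, f$u, tolerance = 1e-9, ignore_attr = TRUE)
  unlink(path)
})
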