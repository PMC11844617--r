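# Constitutive models and kinematics.

test_that("plane-stress stiffness matches the closed form and 2*mu shear", {
  C <- plane_stress_matrix(elastic_params(0.135, 0.3))
  expect_equal(C[1, 1], 0.135 / 0.91, tolerance = 1e-12)
  expect_equal(C[1, 2], 0.135 * 0.3 / 0.91, tolerance = 1e-12)
  # nu = 0 decouples into the identity scaled by E
  expect_equal(plane_stress_matrix(elastic_params(1, 0)), diag(3))
  # shear row with tensor strain equals 2 mu exy
  p <- elastic_params(0.7, 0.22)
  mu <- lame_from_Ev(p)$mu
  set.seed(4)
  for (exy in rnorm(5)) {
    sxy <- (plane_stress_matrix(p) %*% c(0, 0, exy))[3]
    expect_equal(sxy, 2 * mu * exy, tolerance = 1e-12)
  }
  expect_error(plane_stress_matrix(list(E = 1, nu = 1)), "singular")
})

test_that("small strain is the symmetric gradient part", {
  expect_equal(unname(small_strain(matrix(0, 2, 2))), c(0, 0, 0))
  expect_equal(unname(small_strain(diag(c(0.1, -0.2)))),
               c(0.1, -0.2, 0))
  set.seed(7)
  G <- matrix(rnorm(4), 2, 2)
  sym <- 0.5 * (G + t(G))
  expect_equal(unname(small_strain(G)),
               c(sym[1, 1], sym[2, 2], sym[1, 2]), tolerance = 1e-14)
})

test_that("plate strains follow Kirchhoff-Love kinematics", {
  expect_equal(unname(plate_strain(0, matrix(rnorm(4), 2, 2))),
               c(0, 0, 0))
  # uz = x^2 + y^2 -> hessian diag(2, 2); z = 0.05
  H <- diag(c(2, 2))
  expect_equal(unname(plate_strain(0.05, H)), c(-0.1, -0.1, 0))
  # positive curvature above the mid-surface compresses
  expect_lt(plate_strain(0.01, diag(c(1, 1)))[1], 0)
})

test_that("Lame parameters match printed conversions", {
  lm <- lame_from_Ev(elastic_params(526.84, 0.317))
  expect_equal(lm$mu, 200.0152, tolerance = 1e-4)
  expect_equal(lm$lambda, 346.4788, tolerance = 1e-4)
  lm0 <- lame_from_Ev(elastic_params(1, 0))
  expect_equal(lm0$mu, 0.5)
  expect_equal(lm0$lambda, 0)
  expect_warning(lame_from_Ev(elastic_params(1, 0.499)),
                 "near-incompressible")
})

test_that("Neo-Hookean stress is energy-consistent and linearizes", {
  pars <- lame_from_Ev(elastic_params(2, 0.3))
  expect_equal(neo_hookean_pk1(diag(3), pars), diag(3) * 0,
               ignore_attr = TRUE)
  # P = dPsi/dF by central differences, 100 random admissible F
  for (F in random_F(100, seed = 11)) {
    P <- neo_hookean_pk1(F, pars)
    Pfd <- matrix(0, 3, 3)
    for (i in 1:9) {
      Fp <- F; Fp[i] <- Fp[i] + 1e-6
      Fm <- F; Fm[i] <- Fm[i] - 1e-6
      Pfd[i] <- (neo_hookean_energy(Fp, pars) -
                   neo_hookean_energy(Fm, pars)) / 2e-6
    }
    expect_lt(max(abs(P - Pfd)) / max(abs(P)), 1e-6)
  }
  # small-strain linearization equals lambda tr(eps) I + 2 mu eps
  set.seed(5)
  eps <- 0.5 * (function(A) A + t(A))(matrix(rnorm(9), 3, 3))
  h <- 1e-6
  Pl <- neo_hookean_pk1(diag(3) + h * eps, pars) / h
  sig_lin <- pars$lambda * sum(diag(eps)) * diag(3) + 2 * pars$mu * eps
  expect_equal(unclass(Pl), sig_lin, tolerance = 1e-4, ignore_attr = TRUE)
  expect_error(neo_hookean_pk1(diag(c(-1, 1, 1)), pars), "inadmissible")
})

test_that("Lee-Sacks stress follows the printed law and its energy", {
  pars <- lee_sacks_params(0.16, 0.02, 2.1)
  # at rest the printed law gives c0 * I (no volumetric term)
  expect_equal(unclass(lee_sacks_pk1(diag(3), pars)), 0.16 * diag(3),
               ignore_attr = TRUE)
  # c1 = 0 removes the exponential stiffening entirely
  p0 <- lee_sacks_params(0.3, 0, 5)
  for (F in random_F(5, seed = 2))
    expect_equal(unclass(lee_sacks_pk1(F, p0)), 0.3 * F,
                 ignore_attr = TRUE)
  # printed P equals dPsi/dF (I1 = trace(F^T F) so dI1/dF = 2F)
  for (F in random_F(50, seed = 3)) {
    P <- lee_sacks_pk1(F, pars)
    Pfd <- matrix(0, 3, 3)
    for (i in 1:9) {
      Fp <- F; Fp[i] <- Fp[i] + 1e-6
      Fm <- F; Fm[i] <- Fm[i] - 1e-6
      Pfd[i] <- (lee_sacks_energy(Fp, pars) -
                   lee_sacks_energy(Fm, pars)) / 2e-6
    }
    expect_lt(max(abs(P - Pfd)) / max(abs(P)), 1e-6)
  }
})

test_that("both energies are objective under rotations", {
  nh <- lame_from_Ev(elastic_params(1.3, 0.25))
  ls <- lee_sacks_params(0.1, 0.05, 1.5)
  set.seed(8)
  for (F in random_F(20, seed = 9)) {
    Q <- rand_rotation()
    if (det(Q) < 0) Q <- -Q
    expect_equal(neo_hookean_energy(Q %*% F, nh),
                 neo_hookean_energy(F, nh), tolerance = 1e-10)
    expect_equal(lee_sacks_energy(Q %*% F, ls),
                 lee_sacks_energy(F, ls), tolerance = 1e-10)
  }
})

test_that("Cauchy stress conversion is consistent", {
  pars <- lame_from_Ev(elastic_params(1, 0.3))
  P <- matrix(rnorm(9), 3, 3)
  expect_equal(unclass(cauchy_from_pk1(P, diag(3))),
               0.5 * (P + t(P)), ignore_attr = TRUE)
  # pure rotation is stress-free for Neo-Hookean
  Q <- rand_rotation(); if (det(Q) < 0) Q <- -Q
  sg <- cauchy_from_pk1(neo_hookean_pk1(Q, pars), Q)
  expect_lt(max(abs(sg)), 1e-12)
  # J-scaling: F = alpha I gives sigma = alpha^-3 P (alpha F^T) directly
  alpha <- 1.3
  F <- alpha * diag(3)
  P <- matrix(rnorm(9), 3, 3)
  expect_equal(unclass(cauchy_from_pk1(P, F)),
               0.5 * (function(S) S + t(S))(P %*% t(F)) / alpha^3,
               ignore_attr = TRUE)
  expect_error(cauchy_from_pk1(P, diag(c(1, -1, 1))), "inadmissible")
})

test_that("3D isotropic stiffness matches Lame form on tensor strains", {
  p <- elastic_params(5, 0.3)
  lm <- lame_from_Ev(p)
  C6 <- isotropic_stiffness_3d(p)
  set.seed(10)
  eps <- 0.5 * (function(A) A + t(A))(matrix(rnorm(9), 3, 3))
  v <- c(eps[1, 1], eps[2, 2], eps[3, 3], eps[1, 2], eps[2, 3], eps[1, 3])
  sig <- lm$lambda * sum(diag(eps)) * diag(3) + 2 * lm$mu * eps
  sv <- c(sig[1, 1], sig[2, 2], sig[3, 3], sig[1, 2], sig[2, 3], sig[1, 3])
  expect_equal(as.numeric(C6 %*% v), sv, tolerance = 1e-12)
})
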