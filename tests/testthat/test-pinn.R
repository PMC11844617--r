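# Residual operators under oracle pinning: with both heads replaced by
# analytic fields, every residual must vanish to tight tolerance,
# isolating the residual implementations from training behavior.

test_that("static momentum residual vanishes on the Lame stress field", {
  case <- cylinder_case()
  X <- sample_quarter_annulus(quarter_annulus(1.3, 4.7), 100, 0,
                              seed = 1)$points
  r <- residual_static_momentum(cylinder_sigma_eval(case), X)
  # nondimensionalized by the natural stress gradient Pi / ri
  expect_lt(max(abs(r)) / (case$P_internal / case$r_inner), 1e-6)
})

test_that("static momentum residual detects a linear non-equilibrium", {
  # sigma_xx = x, everything else 0 -> div sigma = (1, 0)
  ev <- function(X) {
    g1 <- matrix(0, nrow(X), 3); g1[, 1] <- 1
    list(grads = list(g1, matrix(0, nrow(X), 3)))
  }
  r <- residual_static_momentum(ev, matrix(rnorm(10), 5, 2))
  expect_equal(unname(r), cbind(rep(1, 5), rep(0, 5)))
  # constant stress field is divergence-free
  ev0 <- function(X) list(grads = list(matrix(0, 5, 3), matrix(0, 5, 3)))
  expect_equal(max(abs(residual_static_momentum(ev0, matrix(0, 5, 2)))), 0)
})

test_that("constitutive residual vanishes with matched analytic fields", {
  case <- cylinder_case()
  X <- sample_quarter_annulus(quarter_annulus(1.3, 4.7), 80, 0,
                              seed = 2)$points
  r <- residual_constitutive(cylinder_sigma_eval(case),
                             cylinder_u_eval(case), X, case$params)
  expect_lt(max(abs(r)) / case$P_internal, 1e-6)
  # linear scaling in E: doubling E doubles the model stress exactly
  wrong <- elastic_params(2 * case$params$E, case$params$nu)
  r2 <- residual_constitutive(cylinder_sigma_eval(case),
                              cylinder_u_eval(case), X, wrong)
  sig <- cylinder_stress(X, case)
  expect_equal(unname(r2), unname(-sig), tolerance = 1e-5)
  # zero fields give zero residual for the linear model
  z2 <- function(X) list(sigma = matrix(0, nrow(X), 3),
                         grad_u = matrix(0, nrow(X), 4))
  expect_equal(max(abs(residual_constitutive(z2, z2, X, case$params))), 0)
})

test_that("hyperelastic constitutive residual matches the scalar chain", {
  pars <- lame_from_Ev(elastic_params(0.5, 0.3))
  mat <- list(kind = "neo-hookean", params = pars)
  set.seed(4)
  n <- 6
  gu <- matrix(rnorm(n * 9, 0, 0.05), n, 9)
  sig6 <- matrix(rnorm(n * 6), n, 6)
  r <- residual_constitutive(function(X) list(sigma = sig6),
                             function(X) list(grad_u = gu),
                             matrix(0, n, 3), mat)
  for (i in seq_len(n)) {
    Fm <- diag(3) + matrix(gu[i, ], 3, 3)
    sg <- cauchy_from_pk1(neo_hookean_pk1(Fm, pars), Fm)
    model <- c(sg[1, 1], sg[2, 2], sg[3, 3], sg[1, 2], sg[2, 3], sg[1, 3])
    expect_equal(unname(r[i, ]), unname(sig6[i, ] - model),
                 tolerance = 1e-12)
  }
})

test_that("traction residual vanishes on the pressurized inner wall", {
  case <- cylinder_case()
  th <- seq(0.1, pi / 2 - 0.1, length.out = 25)
  X <- cbind(cos(th), sin(th))
  normals <- -X                       # body outward normal at the bore
  r <- residual_traction(cylinder_sigma_eval(case), X, normals,
                         case$P_internal)
  expect_lt(max(abs(r)) / case$P_internal, 1e-10)
  # zero pressure, zero stress
  ev0 <- function(X) list(sigma = matrix(0, nrow(X), 3))
  expect_equal(max(abs(residual_traction(ev0, X, normals, 0))), 0)
  # flipping the normal flips the sign
  r2 <- residual_traction(cylinder_sigma_eval(case), X, -normals,
                          case$P_internal)
  expect_equal(unname(r2), unname(-r), tolerance = 1e-14)
})

test_that("biharmonic residual vanishes on the plate closed form", {
  case <- plate_case()
  X <- sample_disk(clamped_disk(0.7, 0.1), 40, 0, seed = 5)$points
  h <- 1e-2
  lap <- function(f, Z) {
    (f(cbind(Z[, 1] + h, Z[, 2])) + f(cbind(Z[, 1] - h, Z[, 2])) +
       f(cbind(Z[, 1], Z[, 2] + h)) + f(cbind(Z[, 1], Z[, 2] - h)) -
       4 * f(Z)) / h^2
  }
  uz_eval <- function(Z) {
    f <- function(W) plate_deflection(W, case)
    list(uz = f(Z), biharmonic = lap(function(W) lap(f, W), Z))
  }
  r <- residual_biharmonic(uz_eval, X, case$q, case$params, case$H)
  expect_lt(max(abs(r)) / (case$q / case$D), 1e-6)
  # uz = 0 gives -q/D everywhere
  z_eval <- function(Z) list(biharmonic = numeric(nrow(Z)))
  r0 <- residual_biharmonic(z_eval, X, case$q, case$params, case$H)
  expect_equal(r0, rep(-case$q / case$D, nrow(X)))
  # doubling E halves q/D: residual shifts by +q/(2D)
  r2 <- residual_biharmonic(z_eval, X, case$q,
                            elastic_params(2 * case$params$E,
                                           case$params$nu), case$H)
  expect_equal(r2 - r0, rep(case$q / (2 * case$D), nrow(X)),
               tolerance = 1e-12)
})

test_that("dynamic momentum residual reduces to static and cancels a
           manufactured inertia", {
  sig_ev <- function(X) list(grads = list(cbind(1, 0, 0, 0, 0, 0) %x%
                                            rep(1, nrow(X)) * 1,
                                          matrix(0, nrow(X), 6),
                                          matrix(0, nrow(X), 6)))
  sig_ev <- function(X) {
    g1 <- matrix(0, nrow(X), 6); g1[, 1] <- 1   # d sigma_xx / dx = 1
    list(grads = list(g1, matrix(0, nrow(X), 6), matrix(0, nrow(X), 6)))
  }
  X <- matrix(rnorm(15), 5, 3)
  u_static <- function(X) list(u_tt = matrix(0, nrow(X), 3))
  r0 <- residual_dynamic_momentum(sig_ev, u_static, X, rho = 2)
  expect_equal(unname(r0), cbind(rep(1, 5), 0, 0))
  # rho = 0 equals the static residual exactly
  u_any <- function(X) list(u_tt = matrix(rnorm(nrow(X) * 3), nrow(X), 3))
  expect_equal(residual_dynamic_momentum(sig_ev, u_any, X, rho = 0),
               residual_static_momentum(sig_ev, X))
  # manufactured balance: u_tt = div sigma / rho -> residual 0
  u_bal <- function(X) {
    u <- matrix(0, nrow(X), 3); u[, 1] <- 1 / 2
    list(u_tt = u)
  }
  expect_lt(max(abs(residual_dynamic_momentum(sig_ev, u_bal, X, rho = 2))),
            1e-14)
})

test_that("hard Dirichlet transforms satisfy the constraint exactly", {
  a <- 1
  boundary <- list(d = function(X) (a^2 - rowSums(X^2))^2 / a^4)
  th <- seq(0, 2 * pi, length.out = 13)
  edge <- cbind(a * cos(th), a * sin(th))
  out <- hard_dirichlet(matrix(rnorm(13), 13, 1), edge, boundary)
  expect_equal(max(abs(out)), 0)
  # the squared-distance form also kills the gradient at the edge
  N <- function(X) sin(3 * X[, 1]) + cos(2 * X[, 2])
  uz <- function(X) boundary$d(X) * N(X)
  g <- fd_partial(function(Z) cbind(uz(Z)), edge, 1, h = 1e-6)
  expect_lt(max(abs(g)), 1e-9)
  # prescribed nonzero boundary values pass through g(x)
  b2 <- list(d = function(X) X[, 1], g = function(X) 2 * X[, 2])
  X0 <- cbind(0, rnorm(7))
  expect_equal(hard_dirichlet(matrix(5, 7, 1), X0, b2),
               cbind(2 * X0[, 2]))
})

test_that("the jet-based plate biharmonic matches finite differences", {
  # core of the plate PDE loss: fourth directional Taylor coefficients of
  # the composite d(x)^2 N(x) assembled into lap^2 via four directions
  spec <- network_spec(2, 1, c(8, 8))
  net <- mlp_init(spec, 3)
  s2 <- 1 / sqrt(2)
  dirs <- list(c(1, 0), c(0, 1), c(s2, s2), c(s2, -s2))
  set.seed(6)
  X <- matrix(runif(16, -0.5, 0.5), 8, 2)
  fu <- mlp_jet(net, X, dirs, 4L)
  T4 <- numeric(8)
  for (d in 1:4) {
    v <- dirs[[d]]
    p0 <- 1 - X[, 1]^2 - X[, 2]^2
    p1 <- -2 * (X[, 1] * v[1] + X[, 2] * v[2])
    q0 <- p0^2; q1 <- 2 * p0 * p1; q2 <- p1^2 - 2 * p0
    q3 <- -2 * p1; q4 <- rep(1, 8)
    T4 <- T4 + q4 * fu$y[, 1] + q3 * fu$T[[d]][[1]][, 1] +
      q2 * fu$T[[d]][[2]][, 1] + q1 * fu$T[[d]][[3]][, 1] +
      q0 * fu$T[[d]][[4]][, 1]
  }
  bih_jet <- 16 * T4
  f <- function(Z) {
    o <- mlp_jet(net, Z)
    cbind((1 - Z[, 1]^2 - Z[, 2]^2)^2 * o$y[, 1])
  }
  h <- 5e-3
  lap <- function(g, Z) {
    (g(cbind(Z[, 1] + h, Z[, 2])) + g(cbind(Z[, 1] - h, Z[, 2])) +
       g(cbind(Z[, 1], Z[, 2] + h)) + g(cbind(Z[, 1], Z[, 2] - h)) -
       4 * g(Z)) / h^2
  }
  bih_fd <- lap(function(Z) lap(f, Z), X)[, 1]
  expect_lt(max(abs(bih_jet - bih_fd) / (abs(bih_fd) + 1)), 2e-4)
})
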