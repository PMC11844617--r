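# Finite-element forward solver.

unit_cube <- function() {
  nodes <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(nodes) <- NULL
  list(nodes = nodes, hex = matrix(c(1, 2, 4, 3, 5, 6, 8, 7), 1))
}

test_that("single-hex patch test reproduces uniform uniaxial stress", {
  cube <- unit_cube()
  X <- cube$nodes
  bc <- rbind(cbind(which(X[, 3] == 0), 3, 0),
              cbind(which(X[, 1] == 0), 1, 0),
              cbind(which(X[, 2] == 0), 2, 0))
  pr <- fe_problem(cube, elastic_params(10, 0.25), dirichlet = bc,
                   pressure = list(faces = matrix(c(5, 6, 8, 7), 1),
                                   p = -2))
  sol <- fe_solve(pr)
  U <- sol$field$u
  # sigma_zz = 2: ezz = 0.2, lateral contraction -nu * 0.2
  expect_equal(U[X[, 3] == 1, 3], rep(0.2, 4), tolerance = 1e-10)
  expect_equal(U[X[, 1] == 1, 1], rep(-0.05, 4), tolerance = 1e-10)
  expect_equal(sol$stress[1, ], c(0, 0, 2, 0, 0, 0), tolerance = 1e-10)
})

test_that("hyperelastic patch: Neo-Hookean Newton matches uniaxial solve", {
  cube <- unit_cube()
  X <- cube$nodes
  bc <- rbind(cbind(which(X[, 3] == 0), 3, 0),
              cbind(which(X[, 1] == 0), 1, 0),
              cbind(which(X[, 2] == 0), 2, 0))
  pars <- lame_from_Ev(elastic_params(5, 0.3))
  pr <- fe_problem(cube, list(kind = "neo-hookean", params = pars),
                   dirichlet = bc,
                   pressure = list(faces = matrix(c(5, 6, 8, 7), 1),
                                   p = -0.5))
  sol <- fe_solve(pr)
  lz <- 1 + sol$field$u[X[, 3] == 1, 3][1]
  lx <- 1 + sol$field$u[X[, 1] == 1, 1][1]
  # independent 1D oracle: uniaxial Neo-Hookean with dead load
  # P_zz(lz, lx) = 0.5 * (reference area), P_xx = 0
  f <- function(l) {
    Fm <- diag(c(l[1], l[1], l[2]))
    P <- neo_hookean_pk1(Fm, pars)
    c(P[1, 1], P[3, 3] - 0.5)
  }
  root <- c(0.97, 1.1)
  for (i in 1:60) {
    J <- matrix(0, 2, 2)
    h <- 1e-7
    f0 <- f(root)
    J[, 1] <- (f(root + c(h, 0)) - f0) / h
    J[, 2] <- (f(root + c(0, h)) - f0) / h
    root <- root - solve(J, f0)
  }
  expect_equal(lx, root[1], tolerance = 1e-7)
  expect_equal(lz, root[2], tolerance = 1e-7)
})

test_that("FE ring converges to the Lame solution at O(h^2)", {
  # a cylindrical ring (equal end diameters) with free ends is exactly in
  # plane stress; internal pressure via reversed-orientation outer faces
  case <- cylinder_case(1, 5, 0.01, elastic_params(2, 0.3))
  errs <- c()
  hs <- c()
  for (ref in c(2, 4, 8)) {
    dom <- truncated_cone_shell(0.4, 10, 10, 4)   # ri = 1, ro = 5 ring
    mesh <- cone_hex_mesh(dom, 2 * ref, 8 * ref, 1)
    inner <- mesh$inner_faces
    X <- mesh$nodes
    r <- sqrt(X[, 1]^2 + X[, 2]^2)
    bc <- rbind(cbind(which(X[, 3] == 0), 3, 0),
                cbind(which(abs(X[, 2]) < 1e-9), 2, 0),
                cbind(which(abs(X[, 1]) < 1e-9), 1, 0))
    pr <- fe_problem(mesh, case$params, dirichlet = bc,
                     pressure = list(faces = inner, p = 0.01))
    sol <- fe_solve(pr)
    ur <- rowSums(sol$field$u[, 1:2] * X[, 1:2]) / r
    ur_exact <- sqrt(rowSums(
      cylinder_displacement(cbind(r, 0), case,
                            params = case$params)^2))
    errs <- c(errs, sqrt(mean((ur - ur_exact)^2)) / sqrt(mean(ur_exact^2)))
    hs <- c(hs, 1 / ref)
  }
  expect_lt(errs[3], 0.01)           # within 1% at moderate refinement
  order <- log(errs[1] / errs[3]) / log(hs[1] / hs[3])
  expect_gt(order, 1.5)              # ~O(h^2) convergence
})

test_that("ill-posed and degenerate problems are rejected", {
  cube <- unit_cube()
  # insufficient constraints -> singular stiffness
  pr <- fe_problem(cube, elastic_params(1, 0.3),
                   dirichlet = matrix(numeric(0), 0, 3),
                   pressure = list(faces = matrix(c(5, 6, 8, 7), 1), p = 1))
  expect_error(fe_solve(pr), regexp = "ingular|xact|olve")
  # inverted element
  bad <- cube
  bad$hex <- matrix(c(2, 1, 3, 4, 6, 5, 7, 8), 1)
  pr2 <- fe_problem(bad, elastic_params(1, 0.3),
                    dirichlet = cbind(1:4, 3, 0))
  expect_error(fe_solve(pr2), "Jacobian")
})

test_that("transient solve approaches the quasi-static state with damping
           through time averaging", {
  # step load on a single hex: Newmark response oscillates about the
  # static solution; its time average over whole periods approaches it
  cube <- unit_cube()
  X <- cube$nodes
  bc <- rbind(cbind(which(X[, 3] == 0), 3, 0),
              cbind(which(X[, 1] == 0), 1, 0),
              cbind(which(X[, 2] == 0), 2, 0))
  mat <- elastic_params(10, 0)
  stat <- fe_solve(fe_problem(cube, mat, dirichlet = bc,
                              pressure = list(faces = matrix(c(5, 6, 8, 7), 1),
                                              p = -2)))
  uz_stat <- stat$field$u[5, 3]
  tr <- fe_problem(cube, mat, dirichlet = bc,
                   pressure = list(faces = matrix(c(5, 6, 8, 7), 1), p = -2),
                   kind = "transient", rho = 1, dt = 0.02, nsteps = 400)
  sol <- fe_solve(tr)
  uz_t <- vapply(sol$frames, function(f) f[5, 3], numeric(1))
  expect_equal(mean(uz_t), uz_stat, tolerance = 0.05)
  expect_gt(max(uz_t), uz_stat)      # overshoot of the undamped step
})
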