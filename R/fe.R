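# Displacement-based finite elements on trilinear hexahedra.
#
# Forward verification solver: linear isotropic elasticity or compressible
# Neo-Hookean hyperelasticity, quasi-static (direct solve / Newton) or
# transient (Newmark average acceleration, lumped mass).  Pressure loads
# are consistent nodal forces on reference-configuration faces (dead load,
# not follower pressure); full 2x2x2 Gauss quadrature throughout.

hex_gauss <- function() {
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  list(points = gp, weights = rep(1, 8))
}

# reference hex node coordinates matching cone_hex_mesh connectivity
hex_ref_nodes <- function() {
  rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
        c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
}

# shape functions and reference-coordinate gradients at one Gauss point
hex_shape <- function(xi) {
  rn <- hex_ref_nodes()
  N <- (1 + xi[1] * rn[, 1]) * (1 + xi[2] * rn[, 2]) *
    (1 + xi[3] * rn[, 3]) / 8
  dN <- cbind(rn[, 1] * (1 + xi[2] * rn[, 2]) * (1 + xi[3] * rn[, 3]),
              rn[, 2] * (1 + xi[1] * rn[, 1]) * (1 + xi[3] * rn[, 3]),
              rn[, 3] * (1 + xi[1] * rn[, 1]) * (1 + xi[2] * rn[, 2])) / 8
  list(N = N, dN = dN)
}

#' Define a finite-element problem
#'
#' @param mesh List with `nodes` (n x 3) and `hex` (ne x 8 connectivity),
#'   e.g. from [cone_hex_mesh()].
#' @param material An [elastic_params()] (linear) or
#'   `list(kind = "neo-hookean", params = lame_from_Ev(...))`.
#' @param dirichlet Integer vector of node ids pinned in all three
#'   components (u = 0), or a 3-column matrix `(node, comp, value)`.
#' @param pressure Optional list `list(faces, p)`: outward-oriented quad
#'   faces (nf x 4 node ids) loaded with pressure `p` along the inward
#'   normal.
#' @param kind `"quasi-static"` or `"transient"`.
#' @param rho Density (transient only).
#' @param dt,nsteps Time step and step count (transient only).
#' @return An `fe_problem` object.
#' @export
fe_problem <- function(mesh, material, dirichlet, pressure = NULL,
                       kind = c("quasi-static", "transient"),
                       rho = NULL, dt = NULL, nsteps = NULL) {
  kind <- match.arg(kind)
  nn <- nrow(mesh$nodes)
  stopifnot(max(mesh$hex) <= nn, min(mesh$hex) >= 1)
  if (is.matrix(dirichlet)) {
    bc <- dirichlet
  } else {
    bc <- cbind(node = rep(as.integer(dirichlet), each = 3),
                comp = rep(1:3, length(dirichlet)), value = 0)
  }
  if (!is.null(pressure)) stopifnot(max(pressure$faces) <= nn)
  if (kind == "transient") stopifnot(!is.null(rho), !is.null(dt),
                                     !is.null(nsteps))
  structure(list(mesh = mesh, material = material, bc = bc,
                 pressure = pressure, kind = kind, rho = rho, dt = dt,
                 nsteps = nsteps),
            class = "fe_problem")
}

# engineering-shear-convention elasticity matrix for assembly
d_matrix_eng <- function(params) {
  lm <- lame_from_Ev(params)
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lm$lambda
  diag(D)[1:3] <- lm$lambda + 2 * lm$mu
  diag(D)[4:6] <- lm$mu
  D
}

# consistent nodal forces from pressure p acting along the inward normal of
# outward-oriented reference quad faces
pressure_forces <- function(nodes, faces, p) {
  f <- numeric(3 * nrow(nodes))
  g <- 1 / sqrt(3)
  qp <- as.matrix(expand.grid(c(-g, g), c(-g, g)))
  for (e in seq_len(nrow(faces))) {
    ids <- faces[e, ]
    X <- nodes[ids, , drop = FALSE]
    for (k in 1:4) {
      xi <- qp[k, 1]; eta <- qp[k, 2]
      N <- c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
             (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
      dNxi <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
      dNeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
      t1 <- drop(dNxi %*% X); t2 <- drop(dNeta %*% X)
      nvec <- crossprod3(t1, t2)       # area-weighted outward normal
      tr <- -p * nvec                  # traction x area element
      for (a in 1:4) {
        ia <- 3 * (ids[a] - 1)
        f[ia + 1:3] <- f[ia + 1:3] + N[a] * tr
      }
    }
  }
  f
}

# assemble linear stiffness (triplets) and optionally internal forces for a
# displacement state; material linear elastic
assemble_linear <- function(mesh, params) {
  gauss <- hex_gauss()
  D <- d_matrix_eng(params)
  ne <- nrow(mesh$hex)
  ii <- vector("list", ne); jj <- vector("list", ne); vv <- vector("list", ne)
  shp <- lapply(seq_len(8), function(k) hex_shape(gauss$points[k, ]))
  for (e in seq_len(ne)) {
    ids <- mesh$hex[e, ]
    X <- mesh$nodes[ids, , drop = FALSE]
    Ke <- matrix(0, 24, 24)
    for (k in seq_len(8)) {
      dN <- shp[[k]]$dN
      J <- t(dN) %*% X                 # 3x3
      detJ <- det(J)
      if (detJ <= 0) stop("non-positive element Jacobian (element ", e, ")")
      G <- dN %*% t(solve(J))          # 8x3 gradients wrt x (J[i,j] = dx_j/dxi_i)
      B <- matrix(0, 6, 24)
      ix <- 3 * (1:8) - 2
      B[1, ix] <- G[, 1]; B[2, ix + 1] <- G[, 2]; B[3, ix + 2] <- G[, 3]
      B[4, ix] <- G[, 2]; B[4, ix + 1] <- G[, 1]
      B[5, ix + 1] <- G[, 3]; B[5, ix + 2] <- G[, 2]
      B[6, ix] <- G[, 3]; B[6, ix + 2] <- G[, 1]
      Ke <- Ke + crossprod(B, D %*% B) * detJ
    }
    dofs <- as.integer(t(outer(ids, 1:3, function(n, c) 3 * (n - 1) + c)))
    ii[[e]] <- rep(dofs, times = 24)
    jj[[e]] <- rep(dofs, each = 24)
    vv[[e]] <- as.numeric(Ke)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = rep(3 * nrow(mesh$nodes), 2))
}

# Neo-Hookean internal forces and (optionally) tangent triplets
assemble_nh <- function(mesh, pars, U, tangent = TRUE) {
  gauss <- hex_gauss()
  ne <- nrow(mesh$hex)
  nn <- nrow(mesh$nodes)
  fint <- numeric(3 * nn)
  shp <- lapply(seq_len(8), function(k) hex_shape(gauss$points[k, ]))
  ii <- if (tangent) vector("list", ne)
  jj <- if (tangent) vector("list", ne)
  vv <- if (tangent) vector("list", ne)
  Umat <- matrix(U, ncol = 3, byrow = TRUE)
  for (e in seq_len(ne)) {
    ids <- mesh$hex[e, ]
    X <- mesh$nodes[ids, , drop = FALSE]
    Ue <- Umat[ids, , drop = FALSE]
    fe <- matrix(0, 8, 3)
    Ke <- if (tangent) matrix(0, 24, 24)
    for (k in seq_len(8)) {
      dN <- shp[[k]]$dN
      J <- t(dN) %*% X
      detJ <- det(J)
      if (detJ <= 0) stop("non-positive element Jacobian (element ", e, ")")
      G <- dN %*% t(solve(J))          # 8x3
      Fm <- diag(3) + t(Ue) %*% G      # deformation gradient
      Jf <- det(Fm)
      if (Jf <= 0) stop("element inverted during Newton solve")
      Fit <- t(solve(Fm))
      cc <- pars$lambda * log(Jf) - pars$mu
      P <- pars$mu * Fm + cc * Fit
      fe <- fe + (G %*% t(P)) * detJ
      if (tangent) {
        FG <- G %*% t(Fit)             # rows: Fit %*% G_a
        GG <- G %*% t(G)               # 8x8 of Ga . Gb
        for (a in 1:8) {
          ra <- 3 * (a - 1) + 1:3
          for (b in 1:8) {
            rb <- 3 * (b - 1) + 1:3
            blk <- pars$mu * GG[a, b] * diag(3) +
              pars$lambda * tcrossprod(FG[a, ], FG[b, ]) -
              cc * tcrossprod(FG[b, ], FG[a, ])
            Ke[ra, rb] <- Ke[ra, rb] + blk * detJ
          }
        }
      }
    }
    dofs <- as.integer(t(outer(ids, 1:3, function(n, c) 3 * (n - 1) + c)))
    fint[dofs] <- fint[dofs] + as.numeric(t(fe))
    if (tangent) {
      ii[[e]] <- rep(dofs, times = 24)
      jj[[e]] <- rep(dofs, each = 24)
      vv[[e]] <- as.numeric(Ke)
    }
  }
  K <- if (tangent)
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                         dims = c(3 * nn, 3 * nn))
  list(fint = fint, K = K)
}

apply_bc <- function(K, r, bc) {
  dofs <- 3 * (bc[, 1] - 1) + bc[, 2]
  if (length(dofs) > 0) {
    r[dofs] <- 0
    K[dofs, ] <- 0
    K[, dofs] <- 0
    K[cbind(dofs, dofs)] <- 1
  }
  list(K = K, r = r, dofs = dofs)
}

#' Solve a finite-element problem
#'
#' Quasi-static linear problems are solved directly; Neo-Hookean problems
#' by Newton iteration with an analytic tangent and load stepping;
#' transient problems by Newmark average acceleration with a lumped mass
#' matrix.  Convergence criterion: residual norm below `tol` times the
#' external force norm.
#'
#' @param problem An [fe_problem()].
#' @param tol Relative residual tolerance (default 1e-8).
#' @param max_newton Maximum Newton iterations per (load/time) step.
#' @param n_load_steps Load increments for hyperelastic quasi-static
#'   solves.
#' @param save_every For transient runs, save every k-th frame.
#' @return A list: `field` (a [displacement_field()] of final nodal
#'   displacements), `stress` (element centroid Cauchy stresses, n_e x 6),
#'   `strain` (element centroid tensor strains), and for transient runs
#'   `frames` (list of displacement matrices) and `times`.
#' @export
fe_solve <- function(problem, tol = 1e-8, max_newton = 30L,
                     n_load_steps = 4L, save_every = 1L) {
  mesh <- problem$mesh
  nn <- nrow(mesh$nodes)
  ndof <- 3 * nn
  fext <- if (!is.null(problem$pressure))
    pressure_forces(mesh$nodes, problem$pressure$faces, problem$pressure$p)
  else numeric(ndof)
  linear <- inherits(problem$material, "elastic_params")
  bc <- problem$bc
  fnorm <- sqrt(sum(fext^2))
  if (fnorm == 0) fnorm <- 1

  if (problem$kind == "quasi-static") {
    if (linear) {
      K <- assemble_linear(mesh, problem$material)
      sys <- apply_bc(K, fext, bc)
      rhs <- sys$r
      rhs[sys$dofs] <- bc[, 3]
      U <- as.numeric(Matrix::solve(sys$K, rhs))
    } else {
      pars <- problem$material$params
      U <- numeric(ndof)
      for (ls in seq_len(n_load_steps)) {
        fstep <- fext * ls / n_load_steps
        conv <- FALSE
        for (nit in seq_len(max_newton)) {
          asm <- assemble_nh(mesh, pars, U)
          r <- asm$fint - fstep
          sys <- apply_bc(asm$K, r, bc)
          if (sqrt(sum(sys$r^2)) < tol * fnorm) { conv <- TRUE; break }
          dU <- as.numeric(Matrix::solve(sys$K, sys$r))
          U <- U - dU
        }
        if (!conv) stop("Newton did not converge at load step ", ls)
      }
    }
    Umat <- matrix(U, ncol = 3, byrow = TRUE)
    st <- fe_element_state(mesh, problem$material, U)
    return(list(field = displacement_field(mesh$nodes, Umat),
                stress = st$stress, strain = st$strain))
  }

  # transient: Newmark average acceleration (beta 1/4, gamma 1/2)
  rho <- problem$rho; dt <- problem$dt
  Mlump <- lumped_mass(mesh, rho)
  beta <- 0.25; gamma <- 0.5
  U <- numeric(ndof); V <- numeric(ndof); A <- numeric(ndof)
  pars <- if (!linear) problem$material$params
  Klin <- if (linear) assemble_linear(mesh, problem$material)
  frames <- list(); times <- numeric(0)
  for (step in seq_len(problem$nsteps)) {
    Upred <- U + dt * V + dt^2 * (0.5 - beta) * A
    Vpred <- V + dt * (1 - gamma) * A
    Un <- U
    conv <- FALSE
    for (nit in seq_len(max_newton)) {
      Acur <- (Un - Upred) / (beta * dt^2)
      if (linear) {
        fint <- as.numeric(Klin %*% Un)
        Kt <- Klin
      } else {
        asm <- assemble_nh(mesh, pars, Un)
        fint <- asm$fint
        Kt <- asm$K
      }
      r <- Mlump * Acur + fint - fext
      Keff <- Kt + Matrix::Diagonal(x = Mlump / (beta * dt^2))
      sys <- apply_bc(Keff, r, bc)
      if (sqrt(sum(sys$r^2)) < tol * fnorm) { conv <- TRUE; break }
      dU <- as.numeric(Matrix::solve(sys$K, sys$r))
      Un <- Un - dU
    }
    if (!conv) stop("Newton did not converge at time step ", step)
    Anew <- (Un - Upred) / (beta * dt^2)
    V <- Vpred + gamma * dt * Anew
    A <- Anew
    U <- Un
    if (step %% save_every == 0 || step == problem$nsteps) {
      frames[[length(frames) + 1L]] <- matrix(U, ncol = 3, byrow = TRUE)
      times <- c(times, step * dt)
    }
  }
  Umat <- matrix(U, ncol = 3, byrow = TRUE)
  st <- fe_element_state(mesh, problem$material, U)
  list(field = displacement_field(mesh$nodes, Umat),
       stress = st$stress, strain = st$strain,
       frames = frames, times = times)
}

lumped_mass <- function(mesh, rho) {
  gauss <- hex_gauss()
  m <- numeric(nrow(mesh$nodes))
  shp <- lapply(seq_len(8), function(k) hex_shape(gauss$points[k, ]))
  for (e in seq_len(nrow(mesh$hex))) {
    ids <- mesh$hex[e, ]
    X <- mesh$nodes[ids, , drop = FALSE]
    vol <- 0
    for (k in seq_len(8)) vol <- vol + det(t(shp[[k]]$dN) %*% X)
    m[ids] <- m[ids] + rho * vol / 8
  }
  rep(m, each = 3)
}

# element centroid stresses/strains (Cauchy stress; tensor strain measures:
# small strain for linear material, Green-Lagrange for Neo-Hookean)
fe_element_state <- function(mesh, material, U) {
  linear <- inherits(material, "elastic_params")
  Umat <- matrix(U, ncol = 3, byrow = TRUE)
  ne <- nrow(mesh$hex)
  stress <- matrix(0, ne, 6)
  strain <- matrix(0, ne, 6)
  shp0 <- hex_shape(c(0, 0, 0))
  C6 <- if (linear) isotropic_stiffness_3d(material)
  for (e in seq_len(ne)) {
    ids <- mesh$hex[e, ]
    X <- mesh$nodes[ids, , drop = FALSE]
    G <- shp0$dN %*% t(solve(t(shp0$dN) %*% X))
    H <- t(Umat[ids, , drop = FALSE]) %*% G   # displacement gradient
    if (linear) {
      eps <- 0.5 * (H + t(H))
      ev <- c(eps[1, 1], eps[2, 2], eps[3, 3], eps[1, 2], eps[2, 3],
              eps[1, 3])
      strain[e, ] <- ev
      stress[e, ] <- as.numeric(C6 %*% ev)
    } else {
      Fm <- diag(3) + H
      Eg <- 0.5 * (t(Fm) %*% Fm - diag(3))
      strain[e, ] <- c(Eg[1, 1], Eg[2, 2], Eg[3, 3], Eg[1, 2], Eg[2, 3],
                       Eg[1, 3])
      P <- neo_hookean_pk1(Fm, material$params)
      sg <- cauchy_from_pk1(P, Fm)
      stress[e, ] <- c(sg[1, 1], sg[2, 2], sg[3, 3], sg[1, 2], sg[2, 3],
                       sg[1, 3])
    }
  }
  list(stress = stress, strain = strain)
}
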