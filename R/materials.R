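# Constitutive models and kinematic relations.
#
# Linear isotropic elasticity in plane stress (2D benchmarks) and full 3D,
# and two compressible hyperelastic models used for soft-tissue membranes:
# Neo-Hookean and Lee-Sacks.  Stresses follow the units of the input moduli;
# no internal unit system is imposed.

#' Isotropic linear elastic parameters
#'
#' @param E Young's modulus (> 0), in problem stress units.
#' @param nu Poisson's ratio, `0 <= nu < 0.5`.
#' @return An `elastic_params` object.
#' @export
elastic_params <- function(E, nu) {
  stopifnot(E > 0, nu >= 0, nu < 0.5)
  structure(list(E = E, nu = nu), class = "elastic_params")
}

#' Lee-Sacks stiffness parameters
#'
#' @param c0,c1 Stiffness parameters (stress units), `>= 0`.
#' @param c2 Dimensionless exponential stiffening parameter, `>= 0`.
#' @return A `lee_sacks_params` object.
#' @export
lee_sacks_params <- function(c0, c1, c2) {
  stopifnot(c0 >= 0, c1 >= 0, c2 >= 0)
  structure(list(c0 = c0, c1 = c1, c2 = c2), class = "lee_sacks_params")
}

#' Plane-stress stiffness matrix
#'
#' Returns `E/(1 - nu^2) * [[1, nu, 0], [nu, 1, 0], [0, 0, 1 - nu]]`, acting
#' on the tensor strain vector `(exx, eyy, exy)` with
#' `exy = (du_x/dy + du_y/dx) / 2`.  With tensor shear strain the `(1 - nu)`
#' shear entry is equivalent to `sigma_xy = 2 * mu * exy`, since
#' `E (1 - nu) / (1 - nu^2) = E / (1 + nu) = 2 mu`.
#'
#' @param params An [elastic_params()] object.
#' @return 3x3 stiffness matrix.
#' @export
plane_stress_matrix <- function(params) {
  E <- params$E; nu <- params$nu
  if (abs(1 - nu^2) < .Machine$double.eps)
    stop("plane-stress matrix is singular at nu = 1")
  E / (1 - nu^2) *
    matrix(c(1, nu, 0,
             nu, 1, 0,
             0, 0, 1 - nu), 3, 3, byrow = TRUE)
}

#' Small-strain tensor from a displacement gradient
#'
#' @param grad_u Either a 2x2 matrix `[[dux/dx, dux/dy], [duy/dx, duy/dy]]`
#'   or an n x 4 matrix with those columns (batched).
#' @return Strain components `(exx, eyy, exy)` (vector, or n x 3 matrix).
#' @export
small_strain <- function(grad_u) {
  if (is.matrix(grad_u) && all(dim(grad_u) == c(2, 2))) {
    c(exx = grad_u[1, 1], eyy = grad_u[2, 2],
      exy = 0.5 * (grad_u[1, 2] + grad_u[2, 1]))
  } else {
    g <- as.matrix(grad_u)
    stopifnot(ncol(g) == 4)
    cbind(exx = g[, 1], eyy = g[, 4], exy = 0.5 * (g[, 2] + g[, 3]))
  }
}

#' Kirchhoff-Love plate strains from the deflection Hessian
#'
#' In thin-plate kinematics `ux = -z duz/dx`, `uy = -z duz/dy`, so the
#' in-plane strains at height z above the mid-surface are
#' `exx = -z d2uz/dx2`, `eyy = -z d2uz/dy2`, `exy = -z d2uz/dxdy`.
#'
#' @param z Height above the mid-surface (same length units as the plate).
#' @param hessian_uz 2x2 Hessian of the deflection, or an n x 3 matrix of
#'   `(d2uz/dx2, d2uz/dy2, d2uz/dxdy)`.
#' @return Strain components `(exx, eyy, exy)`.
#' @export
plate_strain <- function(z, hessian_uz) {
  if (is.matrix(hessian_uz) && all(dim(hessian_uz) == c(2, 2))) {
    c(exx = -z * hessian_uz[1, 1], eyy = -z * hessian_uz[2, 2],
      exy = -z * hessian_uz[1, 2])
  } else {
    h <- as.matrix(hessian_uz)
    stopifnot(ncol(h) == 3)
    cbind(exx = -z * h[, 1], eyy = -z * h[, 2], exy = -z * h[, 3])
  }
}

#' Lame parameters from (E, nu)
#'
#' `lambda = E nu / ((1 + nu)(1 - 2 nu))`, `mu = E / (2 (1 + nu))`.
#' Warns when `nu > 0.49` (near-incompressible; lambda diverges at 0.5).
#'
#' @param params An [elastic_params()] object.
#' @return List with `lambda` and `mu`.
#' @export
lame_from_Ev <- function(params) {
  if (params$nu > 0.49)
    warning("nu close to 0.5: near-incompressible, lambda is very large")
  lame_(params$E, params$nu)
}

# warning-free internal version (training loops evaluate this every
# iteration while nu explores its bounds)
lame_ <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

#' Full 3D isotropic stiffness (Voigt)
#'
#' 6x6 matrix acting on tensor strains `(exx, eyy, ezz, exy, eyz, exz)`;
#' shear rows return `2 mu e_ij` (tensor shear convention).
#'
#' @param params An [elastic_params()] object.
#' @return 6x6 stiffness matrix.
#' @export
isotropic_stiffness_3d <- function(params) {
  lm <- lame_(params$E, params$nu)
  la <- lm$lambda; mu <- lm$mu
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- la
  diag(C)[1:3] <- la + 2 * mu
  diag(C)[4:6] <- 2 * mu
  C
}

#' Neo-Hookean first Piola-Kirchhoff stress
#'
#' `P = mu F + (lambda log J - mu) F^{-T}` with `J = det F`; the associated
#' strain energy is `Psi = lambda/2 (log J)^2 - mu log J + mu/2 (I1 - 3)`,
#' `I1 = trace(F^T F)`.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param params List with `lambda` and `mu` (see [lame_from_Ev()]).
#' @return 3x3 PK1 stress with the energy attached as attribute `"energy"`.
#' @export
neo_hookean_pk1 <- function(F, params) {
  J <- det(F)
  if (J <= 0) stop("inadmissible deformation: det(F) <= 0")
  Finvt <- t(solve(F))
  P <- params$mu * F + (params$lambda * log(J) - params$mu) * Finvt
  attr(P, "energy") <- neo_hookean_energy(F, params)
  P
}

#' Neo-Hookean strain energy density
#'
#' @inheritParams neo_hookean_pk1
#' @return Scalar energy.
#' @export
neo_hookean_energy <- function(F, params) {
  J <- det(F)
  if (J <= 0) stop("inadmissible deformation: det(F) <= 0")
  I1 <- sum(F * F)
  0.5 * params$lambda * log(J)^2 - params$mu * log(J) +
    0.5 * params$mu * (I1 - 3)
}

#' Lee-Sacks first Piola-Kirchhoff stress
#'
#' Implements the isotropic Lee-Sacks law exactly as commonly printed for
#' valve tissue:
#' `P = (c0 + 2 c1 c2 (I1 - 3) exp[c2 (I1 - 3)^2]) F` with
#' `I1 = trace(F^T F)`.  Note the printed stress is nonzero at `F = I`
#' (`P = c0 I`): the law carries no volumetric/pressure term, and the
#' printed `P` is the gradient of
#' `Psi = c0/2 (I1 - 3) + c1/2 (exp[c2 (I1 - 3)^2] - 1)` only up to the
#' factor-2 convention in `dI1/dF = 2F`; this package treats the printed
#' `P` as canonical and exposes the energy separately as a diagnostic.
#'
#' @param F 3x3 deformation gradient.
#' @param params A [lee_sacks_params()] object.
#' @return 3x3 PK1 stress with attribute `"energy"`.
#' @export
lee_sacks_pk1 <- function(F, params) {
  I1 <- sum(F * F)
  x <- I1 - 3
  coef <- params$c0 + 2 * params$c1 * params$c2 * x * exp(params$c2 * x^2)
  P <- coef * F
  attr(P, "energy") <- lee_sacks_energy(F, params)
  P
}

#' Lee-Sacks strain energy density
#'
#' @inheritParams lee_sacks_pk1
#' @return Scalar energy.
#' @export
lee_sacks_energy <- function(F, params) {
  x <- sum(F * F) - 3
  0.5 * params$c0 * x + 0.5 * params$c1 * (exp(params$c2 * x^2) - 1)
}

#' Cauchy stress from first Piola-Kirchhoff stress
#'
#' `sigma = J^{-1} P F^T`, symmetrized; the norm of the skew part before
#' symmetrization is attached as attribute `"asymmetry"` (a diagnostic --
#' it vanishes for stresses derived from an objective energy).
#'
#' @param P 3x3 PK1 stress.
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @return 3x3 symmetric Cauchy stress.
#' @export
cauchy_from_pk1 <- function(P, F) {
  J <- det(F)
  if (J <= 0) stop("inadmissible deformation: det(F) <= 0")
  s <- (P %*% t(F)) / J
  sym <- 0.5 * (s + t(s))
  skew <- 0.5 * (s - t(s))
  attr(sym, "asymmetry") <- sqrt(sum(skew^2))
  sym
}

# ---- batched 3x3 helpers (rows = points, 9 columns in column-major
#      order F11,F21,F31,F12,...)  used by the training loop ----

b3_det <- function(F) {
  F[, 1] * (F[, 5] * F[, 9] - F[, 8] * F[, 6]) -
  F[, 4] * (F[, 2] * F[, 9] - F[, 8] * F[, 3]) +
  F[, 7] * (F[, 2] * F[, 6] - F[, 5] * F[, 3])
}

b3_inv <- function(F, detF = b3_det(F)) {
  A <- cbind(F[, 5] * F[, 9] - F[, 8] * F[, 6],
             F[, 8] * F[, 3] - F[, 2] * F[, 9],
             F[, 2] * F[, 6] - F[, 5] * F[, 3],
             F[, 7] * F[, 6] - F[, 4] * F[, 9],
             F[, 1] * F[, 9] - F[, 7] * F[, 3],
             F[, 4] * F[, 3] - F[, 1] * F[, 6],
             F[, 4] * F[, 8] - F[, 7] * F[, 5],
             F[, 7] * F[, 2] - F[, 1] * F[, 8],
             F[, 1] * F[, 5] - F[, 4] * F[, 2])
  A / detF
}

# C = A %*% B per row (3x3 each, column-major 9-vectors)
b3_mult <- function(A, B) {
  idx <- function(i, j) (j - 1L) * 3L + i
  C <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in 1:3) {
    C[, idx(i, j)] <- A[, idx(i, 1)] * B[, idx(1, j)] +
      A[, idx(i, 2)] * B[, idx(2, j)] + A[, idx(i, 3)] * B[, idx(3, j)]
  }
  C
}

b3_t <- function(A) A[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
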