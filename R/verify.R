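# Forward verification of recovered parameters and agreement reporting.
#
# Closed forms (cylinder, plate) or the FE solver (cone, membrane) are
# re-evaluated with the PINN-recovered parameters and compared against the
# ground-truth reference: componentwise relative L2 errors for matched
# fields, MSD and HD95 for deformed surfaces.

#' Verify recovered parameters against a benchmark reference
#'
#' Evaluates the forward solution with the recovered mean parameters and
#' reports agreement with the ground-truth solution.
#'
#' @param example One of `"cylinder"`, `"plate"`, `"cone"`, `"membrane"`.
#' @param estimate A `param_estimate` from [train_inverse()], or a named
#'   vector/list of parameter values (e.g. `c(E = 0.133, nu = 0.3)`).
#' @param case The benchmark case object: a [cylinder_case()] /
#'   [plate_case()], or for `"cone"`/`"membrane"` a list with the FE setup
#'   (see [cone_reference()] / [membrane_reference()], whose output
#'   carries it).
#' @param n_grid Grid resolution for the closed-form comparisons.
#' @return An `agreement_report`: list with `l2_pct` (componentwise
#'   relative L2 errors, %), `max_abs_err`, and for surface problems `msd`
#'   and `hd95`.
#' @export
verify_example <- function(example = c("cylinder", "plate", "cone",
                                       "membrane"),
                           estimate, case, n_grid = 60L) {
  example <- match.arg(example)
  vals <- estimate_values(estimate)
  rep_ <- switch(example,
    cylinder = verify_cylinder(vals, case, n_grid),
    plate = verify_plate(vals, case, n_grid),
    cone = verify_cone(vals, case),
    membrane = verify_membrane(vals, case))
  class(rep_) <- "agreement_report"
  rep_
}

estimate_values <- function(estimate) {
  if (inherits(estimate, "param_estimate")) estimate$mean
  else unlist(estimate)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  if (!is.null(x$l2_pct)) {
    cat("  relative L2 errors (%):\n")
    for (nm in names(x$l2_pct))
      cat(sprintf("    %-4s %.4g\n", nm, x$l2_pct[nm]))
  }
  if (!is.null(x$msd)) cat(sprintf("  MSD  %.4g\n", x$msd))
  if (!is.null(x$hd95)) cat(sprintf("  HD95 %.4g\n", x$hd95))
  invisible(x)
}

# dense area-uniform evaluation grids
grid_quarter_annulus <- function(case, n) {
  r <- seq(case$r_inner, case$r_outer, length.out = n)
  th <- seq(0, pi / 2, length.out = n)
  g <- expand.grid(r = r[-c(1)], th = th)
  cbind(g$r * cos(g$th), g$r * sin(g$th))
}

grid_disk <- function(case, n) {
  s <- seq(-case$a, case$a, length.out = n)
  g <- as.matrix(expand.grid(s, s))
  g[g[, 1]^2 + g[, 2]^2 <= case$a^2, , drop = FALSE]
}

verify_cylinder <- function(vals, case, n_grid) {
  X <- grid_quarter_annulus(case, n_grid)
  u_true <- cylinder_displacement(X, case)
  u_est <- cylinder_displacement(X, case,
                                 params = elastic_params(vals["E"],
                                                         vals["nu"]))
  l2 <- l2_relative_error(u_est, u_true)
  names(l2) <- c("ux", "uy")
  list(l2_pct = l2, max_abs_err = max(abs(u_est - u_true)),
       params = vals)
}

verify_plate <- function(vals, case, n_grid) {
  X <- grid_disk(case, n_grid)
  est <- elastic_params(vals["E"], vals["nu"])
  uz_true <- plate_deflection(X, case)
  uz_est <- plate_deflection(X, case, params = est)
  s_true <- plate_top_stress(X, case)
  s_est <- plate_top_stress(X, case, params = est)
  l2 <- c(uz = unname(l2_relative_error(uz_est, uz_true)),
          sxx = unname(l2_relative_error(s_est[, 1], s_true[, 1])),
          syy = unname(l2_relative_error(s_est[, 2], s_true[, 2])),
          sxy = unname(l2_relative_error(s_est[, 3], s_true[, 3])))
  list(l2_pct = l2, max_abs_err = max(abs(uz_est - uz_true)),
       params = vals)
}

verify_cone <- function(vals, setup) {
  pr <- fe_problem(setup$mesh,
                   elastic_params(vals["E"], vals["nu"]),
                   dirichlet = setup$mesh$top_nodes,
                   pressure = list(faces = setup$mesh$outer_faces,
                                   p = setup$pressure))
  sol <- fe_solve(pr)
  u_true <- setup$reference$u
  u_est <- sol$field$u
  l2 <- l2_relative_error(u_est, u_true)
  names(l2) <- c("ux", "uy", "uz")
  list(l2_pct = l2, max_abs_err = max(abs(u_est - u_true)), params = vals)
}

verify_membrane <- function(vals, setup) {
  mat <- list(kind = "neo-hookean",
              params = lame_from_Ev(elastic_params(vals["E"], vals["nu"])))
  pr <- fe_problem(setup$mesh, mat,
                   dirichlet = setup$mesh$top_nodes,
                   pressure = list(faces = setup$mesh$outer_faces,
                                   p = setup$pressure),
                   kind = "transient", rho = setup$rho, dt = setup$dt,
                   nsteps = setup$nsteps)
  sol <- fe_solve(pr, tol = 1e-7)
  def_est <- setup$mesh$nodes + sol$field$u
  def_ref <- setup$reference$points + setup$reference$u
  l2 <- l2_relative_error(sol$field$u, setup$reference$u)
  names(l2) <- c("ux", "uy", "uz")
  list(l2_pct = l2,
       max_abs_err = max(abs(sol$field$u - setup$reference$u)),
       msd = mean_symmetric_distance(def_est, def_ref),
       hd95 = hausdorff95(def_est, def_ref),
       params = vals, stress = sol$stress, strain = sol$strain)
}

#' Finite-element reference for the cone benchmark
#'
#' Solves the pressurized truncated-cone shell with the ground-truth
#' parameters on a structured hex mesh and returns the reference
#' displacement field together with the FE setup reused by
#' [verify_example()].
#'
#' @param domain A [truncated_cone_shell()].
#' @param params Ground-truth [elastic_params()].
#' @param pressure External pressure.
#' @param n_r,n_theta,n_z Mesh resolution.
#' @return List with `reference` (a [displacement_field()]), `mesh`,
#'   `pressure`, `params`.
#' @export
cone_reference <- function(domain = truncated_cone_shell(1, 2, 1, 0.1),
                           params = elastic_params(5, 0.3),
                           pressure = 0.01,
                           n_r = 2L, n_theta = 24L, n_z = 10L) {
  mesh <- cone_hex_mesh(domain, n_r, n_theta, n_z)
  pr <- fe_problem(mesh, params, dirichlet = mesh$top_nodes,
                   pressure = list(faces = mesh$outer_faces, p = pressure))
  sol <- fe_solve(pr)
  list(reference = sol$field, mesh = mesh, pressure = pressure,
       params = params, domain = domain, stress = sol$stress,
       strain = sol$strain)
}

#' Transient finite-element reference for the membrane fixture
#'
#' Runs a Newmark transient solve of the pressurized Neo-Hookean membrane
#' wall (pressure applied as a step at t = 0, fixed annulus) and returns
#' the closed-frame displacement field plus the FE setup for verification.
#'
#' @param domain A [truncated_cone_shell()] fixture wall (lengths in mm).
#' @param params Ground-truth [elastic_params()] (stress units MPa).
#' @param pressure Transvalvular-like pressure (MPa).
#' @param rho Density (1e-3 = 1 g/cm^3 in mm/MPa/ms units).
#' @param t_end Frame interval (ms).
#' @param nsteps Time steps.
#' @param n_r,n_theta,n_z Mesh resolution.
#' @return List with `reference` (closed-frame [displacement_field()]),
#'   `frames`, `times`, `mesh`, and the solver setup.
#' @export
membrane_reference <- function(domain = truncated_cone_shell(10, 20, 10, 1),
                               params = elastic_params(0.52684, 0.317),
                               pressure = 0.0129,
                               rho = 1e-3, t_end = 2, nsteps = 20L,
                               n_r = 1L, n_theta = 16L, n_z = 6L) {
  mesh <- cone_hex_mesh(domain, n_r, n_theta, n_z)
  mat <- list(kind = "neo-hookean", params = lame_from_Ev(params))
  pr <- fe_problem(mesh, mat, dirichlet = mesh$top_nodes,
                   pressure = list(faces = mesh$outer_faces, p = pressure),
                   kind = "transient", rho = rho, dt = t_end / nsteps,
                   nsteps = nsteps)
  sol <- fe_solve(pr, tol = 1e-7)
  list(reference = sol$field, frames = sol$frames, times = sol$times,
       mesh = mesh, pressure = pressure, params = params, rho = rho,
       dt = t_end / nsteps, nsteps = nsteps, t_end = t_end,
       domain = domain, stress = sol$stress, strain = sol$strain)
}
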