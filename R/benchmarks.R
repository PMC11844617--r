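# Closed-form benchmark solutions.
#
# Thick-walled cylinder under internal pressure (plane stress, quarter
# domain by symmetry) and clamped circular plate under uniform transverse
# pressure (Kirchhoff-Love).  These generate reference displacement data
# for the inverse runs and serve as verification oracles for recovered
# parameters.

#' Thick-walled cylinder load case
#'
#' @param r_inner,r_outer Radii (`0 < r_inner < r_outer`).
#' @param P_internal Internal pressure (> 0), stress units.
#' @param params Ground-truth [elastic_params()].
#' @return A `cylinder_case` object.
#' @export
cylinder_case <- function(r_inner = 1, r_outer = 5, P_internal = 1e-5,
                          params = elastic_params(0.135, 0.3)) {
  stopifnot(P_internal > 0)
  dom <- quarter_annulus(r_inner, r_outer)
  structure(list(domain = dom, r_inner = r_inner, r_outer = r_outer,
                 P_internal = P_internal, params = params),
            class = "cylinder_case")
}

#' Clamped circular plate load case
#'
#' @param radius Plate radius a.
#' @param thickness Plate thickness H.
#' @param q Uniform transverse pressure on the top surface.
#' @param params Ground-truth [elastic_params()].
#' @return A `plate_case` object with the flexural rigidity
#'   `D = H^3 E / (12 (1 - nu^2))` attached.
#' @export
plate_case <- function(radius = 1, thickness = 0.1, q = 1,
                       params = elastic_params(1, 0.3)) {
  dom <- clamped_disk(radius, thickness)
  D <- flexural_rigidity(params, thickness)
  stopifnot(D > 0)
  structure(list(domain = dom, a = radius, H = thickness, q = q,
                 params = params, D = D),
            class = "plate_case")
}

#' Plate flexural rigidity `D = H^3 E / (12 (1 - nu^2))`
#'
#' @param params An [elastic_params()].
#' @param H Plate thickness.
#' @return Bending stiffness D.
#' @export
flexural_rigidity <- function(params, H) {
  H^3 * params$E / (12 * (1 - params$nu^2))
}

#' Analytical cylinder displacement (Lame solution, plane stress)
#'
#' `ux = ri^2 Pi r / (E (ro^2 - ri^2)) [1 - nu + (ro/r)^2 (1 + nu)] cos(theta)`
#' and likewise `uy` with `sin(theta)`, with `r = sqrt(x^2 + y^2)` and the
#' polar angle evaluated by the two-argument arctangent (first quadrant).
#'
#' @param xy Point `(x, y)` or an n x 2 matrix of points.
#' @param case A [cylinder_case()]; optionally override `params`.
#' @param params Parameters to evaluate with (defaults to the case truth).
#' @return n x 2 matrix of `(ux, uy)`.
#' @export
cylinder_displacement <- function(xy, case, params = case$params) {
  X <- rbind2mat(xy)
  r <- sqrt(X[, 1]^2 + X[, 2]^2)
  if (any(r == 0)) stop("r = 0 is outside the annulus")
  ri <- case$r_inner; ro <- case$r_outer
  Pi_ <- case$P_internal; E <- params$E; nu <- params$nu
  ur <- ri^2 * Pi_ * r / (E * (ro^2 - ri^2)) *
    (1 - nu + (ro / r)^2 * (1 + nu))
  cbind(ux = ur * X[, 1] / r, uy = ur * X[, 2] / r)
}

#' Analytical cylinder stresses (Lame solution, plane stress)
#'
#' Radial/hoop stresses `srr = A - B/r^2`, `stt = A + B/r^2` with
#' `A = Pi ri^2/(ro^2 - ri^2)`, `B = A ro^2`, rotated to Cartesian
#' components.  Independent of the elastic constants.
#'
#' @inheritParams cylinder_displacement
#' @return n x 3 matrix `(sxx, syy, sxy)`.
#' @export
cylinder_stress <- function(xy, case) {
  X <- rbind2mat(xy)
  r2 <- X[, 1]^2 + X[, 2]^2
  if (any(r2 == 0)) stop("r = 0 is outside the annulus")
  ri <- case$r_inner; ro <- case$r_outer
  A <- case$P_internal * ri^2 / (ro^2 - ri^2)
  B <- A * ro^2
  srr <- A - B / r2
  stt <- A + B / r2
  c2 <- X[, 1]^2 / r2; s2 <- X[, 2]^2 / r2
  sc <- X[, 1] * X[, 2] / r2
  cbind(sxx = srr * c2 + stt * s2,
        syy = srr * s2 + stt * c2,
        sxy = (srr - stt) * sc)
}

#' Analytical clamped-plate deflection
#'
#' `uz(x, y) = q / (64 D) * [a^2 - (x^2 + y^2)]^2`; the clamped conditions
#' `uz = 0`, `grad uz = 0` on `r = a` are built into the form.
#'
#' @param xy Point(s), n x 2.
#' @param case A [plate_case()].
#' @param params Parameters to evaluate with (defaults to the case truth).
#' @return Vector of deflections.
#' @export
plate_deflection <- function(xy, case, params = case$params) {
  X <- rbind2mat(xy)
  D <- flexural_rigidity(params, case$H)
  case$q / (64 * D) * (case$a^2 - (X[, 1]^2 + X[, 2]^2))^2
}

#' Analytical top-surface plate stresses
#'
#' In-plane stresses at height z (default the top surface `z = H/2`):
#' `sxx = -E z / (1 - nu^2) (uz_xx + nu uz_yy)`, `syy` symmetric,
#' `sxy = -E z / (1 + nu) uz_xy`, with the closed-form deflection Hessian.
#' At the mid-surface (z = 0) all components vanish.
#'
#' @inheritParams plate_deflection
#' @param z Height above the mid-surface; default `H/2`.
#' @return n x 3 matrix `(sxx, syy, sxy)`.
#' @export
plate_top_stress <- function(xy, case, params = case$params, z = case$H / 2) {
  X <- rbind2mat(xy)
  D <- flexural_rigidity(params, case$H)
  k <- case$q / (64 * D)
  phi <- case$a^2 - (X[, 1]^2 + X[, 2]^2)
  uxx <- -4 * k * phi + 8 * k * X[, 1]^2
  uyy <- -4 * k * phi + 8 * k * X[, 2]^2
  uxy <- 8 * k * X[, 1] * X[, 2]
  E <- params$E; nu <- params$nu
  cbind(sxx = -E * z / (1 - nu^2) * (uxx + nu * uyy),
        syy = -E * z / (1 - nu^2) * (uyy + nu * uxx),
        sxy = -E * z / (1 + nu) * uxy)
}

rbind2mat <- function(xy) {
  if (is.matrix(xy)) xy else matrix(xy, 1)
}

# --- displacement fields ---

#' Displacement field container
#'
#' Points with one displacement vector per point, optional per-point time,
#' and componentwise normalization statistics fitted from the data.  A
#' zero-variance component (e.g. `uz = 0` in a 2D problem) gets `sd = 1`
#' and is flagged, so normalization never divides by zero.
#'
#' @param points n x d matrix.
#' @param u n x d_u matrix of displacements.
#' @param time Optional per-point time stamps.
#' @return A `displacement_field` object with `stats` (mean, sd).
#' @export
displacement_field <- function(points, u, time = NULL) {
  points <- as.matrix(points); u <- as.matrix(u)
  stopifnot(nrow(points) == nrow(u))
  if (!is.null(time)) stopifnot(length(time) == nrow(points))
  mu <- colMeans(u)
  sdv <- apply(u, 2, sd)
  if (nrow(u) < 2) sdv <- rep(0, ncol(u))
  flat <- !is.finite(sdv) | sdv == 0
  sdv[flat] <- 1
  structure(list(points = points, u = u, time = time,
                 stats = list(mean = mu, sd = sdv, flat = flat)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("<displacement_field>", nrow(x$points), "points,",
      ncol(x$u), "displacement components\n")
  invisible(x)
}

#' Assemble a reference displacement dataset for a benchmark
#'
#' Samples the domain uniformly by area, evaluates the closed form with the
#' ground-truth parameters, optionally adds iid Gaussian noise, and fits
#' normalization statistics.  (The paper-style references are noise-free;
#' noise injection is an extension, default off.)
#'
#' @param example One of `"cylinder"`, `"plate"`.
#' @param case The matching load case object.
#' @param n_points Number of data points.
#' @param noise_sd Standard deviation of additive displacement noise.
#' @param seed Integer seed.
#' @return A [displacement_field()].
#' @export
build_reference_dataset <- function(example = c("cylinder", "plate"),
                                    case, n_points, noise_sd = 0, seed = 0L) {
  example <- match.arg(example)
  if (example == "cylinder") {
    cs <- sample_quarter_annulus(case$domain, n_points, 0L, seed = seed)
    u <- cylinder_displacement(cs$points, case)
  } else {
    cs <- sample_disk(case$domain, n_points, 0L, seed = seed)
    u <- cbind(uz = plate_deflection(cs$points, case))
  }
  if (noise_sd > 0)
    u <- u + with_seed(seed + 1L,
                       matrix(rnorm(length(u), 0, noise_sd), nrow(u)))
  displacement_field(cs$points, u)
}

#' Write / read a displacement field as a plain table
#'
#' Whitespace-separated columns `x y [z] [t] ux uy [uz]` with a header line.
#'
#' @param field A [displacement_field()].
#' @param path File path.
#' @return `path` invisibly; `read_displacement_field` returns the field.
#' @export
write_displacement_field <- function(field, path) {
  d <- ncol(field$points)
  du <- ncol(field$u)
  df <- data.frame(field$points, check.names = FALSE)
  names(df) <- c("x", "y", "z")[seq_len(d)]
  if (!is.null(field$time)) df$t <- field$time
  un <- data.frame(field$u)
  names(un) <- c("ux", "uy", "uz")[seq_len(du)]
  write.table(cbind(df, un), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  df <- read.table(path, header = TRUE)
  pc <- intersect(c("x", "y", "z"), names(df))
  uc <- intersect(c("ux", "uy", "uz"), names(df))
  if (length(uc) == 0) stop("no displacement columns found")
  tm <- if ("t" %in% names(df)) df$t else NULL
  displacement_field(as.matrix(df[pc]), as.matrix(df[uc]), time = tm)
}
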