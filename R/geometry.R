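# Benchmark domains and reproducible collocation sampling.
#
# Coordinate conventions: right-handed Cartesian axes; the quarter annulus
# occupies the first quadrant (x >= 0, y >= 0); the cone axis is +z with the
# (wider) top edge at z = height and the bottom rim at z = 0.  Interior
# sampling is uniform by area/volume (not uniform in parameters), since PDE
# residual means implicitly weight collocation points equally.

#' Quarter thick-walled annulus domain
#'
#' @param r_inner,r_outer Inner/outer radii (`0 < r_inner < r_outer`).
#' @return A `quarter_annulus` domain object.
#' @export
quarter_annulus <- function(r_inner, r_outer) {
  if (!(r_inner > 0 && r_outer > r_inner))
    stop("invalid radii: need 0 < r_inner < r_outer")
  structure(list(r_inner = r_inner, r_outer = r_outer),
            class = c("quarter_annulus", "pinn_domain"))
}

#' Clamped circular plate domain
#'
#' @param radius Plate radius a (> 0).
#' @param thickness Plate thickness H (> 0); a warning flags `H/a > 0.2`
#'   where the thin-plate assumption degrades.
#' @return A `clamped_disk` domain object.
#' @export
clamped_disk <- function(radius, thickness) {
  stopifnot(radius > 0, thickness > 0)
  if (thickness / radius > 0.2)
    warning("H/a > 0.2: thin-plate (Kirchhoff-Love) assumption questionable")
  structure(list(radius = radius, thickness = thickness),
            class = c("clamped_disk", "pinn_domain"))
}

#' Truncated-cone shell domain
#'
#' A hollow truncated cone, axis +z, top (diameter `top_diameter`) at
#' `z = height`, bottom (diameter `bottom_diameter`) at `z = 0`; the wall of
#' thickness `wall_thickness` lies inside the outer conical surface.
#'
#' @param height Cone height.
#' @param top_diameter,bottom_diameter End diameters.
#' @param wall_thickness Wall thickness, measured normal to the outer
#'   surface (`< bottom_diameter / 2`).
#' @return A `truncated_cone_shell` domain object.
#' @export
truncated_cone_shell <- function(height, top_diameter, bottom_diameter,
                                 wall_thickness) {
  stopifnot(height > 0, top_diameter > 0, bottom_diameter > 0,
            wall_thickness > 0)
  if (wall_thickness >= bottom_diameter / 2)
    stop("wall thickness must be smaller than the bottom radius")
  structure(list(height = height, top_diameter = top_diameter,
                 bottom_diameter = bottom_diameter,
                 wall_thickness = wall_thickness),
            class = c("truncated_cone_shell", "pinn_domain"))
}

# outer-surface radius of the cone at height z
cone_outer_radius <- function(domain, z) {
  rb <- domain$bottom_diameter / 2
  rt <- domain$top_diameter / 2
  rb + (rt - rb) * z / domain$height
}

new_collocation_set <- function(points, role, normals = NULL, time = NULL) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(role))
  structure(list(points = points, role = role, normals = normals,
                 time = time),
            class = "collocation_set")
}

#' @export
print.collocation_set <- function(x, ...) {
  cat("<collocation_set>", nrow(x$points), "points in",
      ncol(x$points), "dims; roles:",
      paste(names(table(x$role)), table(x$role), collapse = ", "), "\n")
  invisible(x)
}

#' Sample collocation points in a quarter annulus
#'
#' Interior points are uniform by area (radius drawn as
#' `sqrt(u (ro^2 - ri^2) + ri^2)`); boundary points are placed uniformly on
#' the inner arc `r = r_inner` and tagged `"traction"` with the body's
#' outward unit normal (pointing toward the axis) attached.  Optionally
#' points on the outer (traction-free) arc can be requested.
#'
#' @param domain A [quarter_annulus()].
#' @param n_interior,n_boundary Numbers of interior / inner-arc points.
#' @param seed Integer seed; output is deterministic given
#'   (domain, counts, seed).
#' @param n_outer Points on the outer arc (also tagged `"traction"`,
#'   outward normal); default 0.
#' @return A `collocation_set` with roles `"pde"` and `"traction"`.
#' @export
sample_quarter_annulus <- function(domain, n_interior, n_boundary, seed = 0L,
                                   n_outer = 0L) {
  stopifnot(n_interior >= 0, n_boundary >= 0, n_outer >= 0)
  ri <- domain$r_inner; ro <- domain$r_outer
  with_seed(seed, {
    r <- sqrt(runif(n_interior) * (ro^2 - ri^2) + ri^2)
    th <- runif(n_interior) * pi / 2
    Xi <- cbind(r * cos(th), r * sin(th))
    thb <- runif(n_boundary) * pi / 2
    Xb <- cbind(ri * cos(thb), ri * sin(thb))
    Nb <- -cbind(cos(thb), sin(thb))      # body outward normal at inner wall
    tho <- runif(n_outer) * pi / 2
    Xo <- cbind(ro * cos(tho), ro * sin(tho))
    No <- cbind(cos(tho), sin(tho))
  })
  pts <- rbind(Xi, Xb, Xo)
  role <- c(rep("pde", n_interior), rep("traction", n_boundary + n_outer))
  normals <- rbind(matrix(NA_real_, n_interior, 2), Nb, No)
  cs <- new_collocation_set(pts, role, normals)
  cs$pressure <- c(rep(NA_real_, n_interior),
                   rep(1, n_boundary), rep(0, n_outer)) # filled with Pi later
  cs
}

#' Sample collocation points in a clamped disk
#'
#' Interior points are uniform by area (`r = a sqrt(u)`); edge points lie on
#' `x^2 + y^2 = a^2` and are tagged `"dirichlet"` (clamped).
#'
#' @param domain A [clamped_disk()].
#' @param n_interior,n_edge Point counts.
#' @param seed Integer seed.
#' @return A `collocation_set`.
#' @export
sample_disk <- function(domain, n_interior, n_edge = 0L, seed = 0L) {
  stopifnot(n_interior >= 0, n_edge >= 0)
  a <- domain$radius
  with_seed(seed, {
    r <- a * sqrt(runif(n_interior))
    th <- runif(n_interior) * 2 * pi
    Xi <- cbind(r * cos(th), r * sin(th))
    the <- runif(n_edge) * 2 * pi
    Xe <- cbind(a * cos(the), a * sin(the))
  })
  new_collocation_set(rbind(Xi, Xe),
                      c(rep("pde", n_interior), rep("dirichlet", n_edge)))
}

#' Sample collocation points in a truncated-cone shell wall
#'
#' Interior points lie within `wall_thickness` of the outer conical surface,
#' measured along the inward surface normal; outer-surface points are tagged
#' `"traction"` with analytic outward unit normals attached; top-edge points
#' (on the outer rim at `z = height`) are tagged `"dirichlet"`.
#'
#' @param domain A [truncated_cone_shell()].
#' @param n_interior,n_outer_surface,n_top_edge Point counts.
#' @param seed Integer seed.
#' @return A `collocation_set`.
#' @export
sample_cone_shell <- function(domain, n_interior, n_outer_surface = 0L,
                              n_top_edge = 0L, seed = 0L) {
  stopifnot(n_interior >= 0, n_outer_surface >= 0, n_top_edge >= 0)
  h <- domain$height; tt <- domain$wall_thickness
  rb <- domain$bottom_diameter / 2; rt <- domain$top_diameter / 2
  slope <- (rt - rb) / h
  cosa <- 1 / sqrt(1 + slope^2)   # cos of surface tilt from vertical axis
  # outward normal at angle theta: (cos th, sin th, -slope) / sqrt(1+slope^2)
  surf_pt <- function(n) {
    # z density proportional to local outer radius (lateral area element)
    u <- runif(n)
    if (abs(rt - rb) < 1e-12 * h) z <- u * h
    else z <- (sqrt(rb^2 + u * (rt^2 - rb^2)) - rb) / slope
    th <- runif(n) * 2 * pi
    R <- cone_outer_radius(domain, z)
    list(x = cbind(R * cos(th), R * sin(th), z), th = th, z = z)
  }
  with_seed(seed, {
    si <- surf_pt(n_interior)
    d <- runif(n_interior) * tt
    ni <- cbind(cos(si$th) * cosa, sin(si$th) * cosa,
                rep(-slope * cosa, n_interior))
    Xi <- si$x - d * ni
    so <- surf_pt(n_outer_surface)
    No <- cbind(cos(so$th) * cosa, sin(so$th) * cosa,
                rep(-slope * cosa, n_outer_surface))
    Xo <- so$x
    the <- runif(n_top_edge) * 2 * pi
    Xe <- cbind(rt * cos(the), rt * sin(the), rep(h, n_top_edge))
  })
  pts <- rbind(Xi, Xo, Xe)
  role <- c(rep("pde", n_interior), rep("traction", n_outer_surface),
            rep("dirichlet", n_top_edge))
  normals <- rbind(matrix(NA_real_, n_interior, 3), No,
                   matrix(NA_real_, n_top_edge, 3))
  new_collocation_set(pts, role, normals)
}

# signed distance (>= 0 inside) of points to the outer conical surface,
# measured along the surface normal
cone_surface_depth <- function(domain, X) {
  h <- domain$height
  rb <- domain$bottom_diameter / 2; rt <- domain$top_diameter / 2
  slope <- (rt - rb) / h
  cosa <- 1 / sqrt(1 + slope^2)
  r <- sqrt(X[, 1]^2 + X[, 2]^2)
  (cone_outer_radius(domain, X[, 3]) - r) * cosa
}
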