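# Surface meshes and plain-text mesh formats.
#
# Hand-rolled readers/writers for the small subset of VTK legacy ASCII,
# ASCII STL, OBJ and ASCII PLY needed to exchange surface meshes and
# per-node displacement vectors; no installed R package covers these
# formats.  All files are plain text.

#' Surface mesh
#'
#' @param vertices n x 3 matrix of node coordinates.
#' @param faces Integer matrix (n_faces x 3 or x 4) or list of integer
#'   vectors (1-based node indices).
#' @param labels Optional character vector of node labels (e.g. `"annulus"`,
#'   `"free_edge"`, `"interior"`).
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) == 0) stop("empty mesh: no vertices")
  stopifnot(ncol(vertices) == 3)
  if (is.matrix(faces)) faces <- lapply(seq_len(nrow(faces)),
                                        function(i) as.integer(faces[i, ]))
  faces <- lapply(faces, as.integer)
  if (length(faces) == 0) stop("empty mesh: no faces")
  rng <- range(unlist(faces))
  if (rng[1] < 1 || rng[2] > nrow(vertices))
    stop("face indices out of range")
  for (f in faces) {
    v <- vertices[f, , drop = FALSE]
    e1 <- v[2, ] - v[1, ]; e2 <- v[3, ] - v[1, ]
    a <- crossprod3(e1, e2)
    if (sqrt(sum(a^2)) <= 0) stop("degenerate (zero-area) face")
  }
  if (!is.null(labels)) stopifnot(length(labels) == nrow(vertices))
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "surface_mesh")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh>", nrow(x$vertices), "vertices,",
      length(x$faces), "faces\n")
  invisible(x)
}

face_normals <- function(mesh) {
  t(vapply(mesh$faces, function(f) {
    v <- mesh$vertices[f, , drop = FALSE]
    n <- crossprod3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    n / sqrt(sum(n^2))
  }, numeric(3)))
}

mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("vtk", "stl", "obj", "ply"))
    stop("unknown mesh format: .", ext)
  ext
}

#' Write a surface mesh
#'
#' Formats by extension: VTK legacy ASCII polydata (`.vtk`), ASCII STL
#' (`.stl`, triangles only, vertices duplicated per facet), Wavefront OBJ
#' (`.obj`) and ASCII PLY (`.ply`).  An optional per-node vector field is
#' written as a VTK point-data array named `"displacement"`.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output file path; the extension selects the format.
#' @param displacement Optional n x 3 matrix written as VTK point data.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, displacement = NULL) {
  fmt <- mesh_format(path)
  v <- mesh$vertices
  num <- function(x) formatC(x, format = "g", digits = 17)
  con <- file(path, "w")
  on.exit(close(con))
  if (fmt == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0", "pinnelast surface mesh",
                 "ASCII", "DATASET POLYDATA",
                 paste("POINTS", nrow(v), "double")), con)
    writeLines(apply(v, 1, function(r) paste(num(r), collapse = " ")), con)
    sizes <- vapply(mesh$faces, length, 1L)
    writeLines(paste("POLYGONS", length(mesh$faces),
                     sum(sizes) + length(sizes)), con)
    writeLines(vapply(mesh$faces, function(f)
      paste(c(length(f), f - 1L), collapse = " "), ""), con)
    if (!is.null(displacement)) {
      writeLines(c(paste("POINT_DATA", nrow(v)),
                   "VECTORS displacement double"), con)
      writeLines(apply(as.matrix(displacement), 1,
                       function(r) paste(num(r), collapse = " ")), con)
    }
  } else if (fmt == "stl") {
    if (any(vapply(mesh$faces, length, 1L) != 3))
      stop("STL supports triangles only")
    nrm <- face_normals(mesh)
    writeLines("solid pinnelast", con)
    for (i in seq_along(mesh$faces)) {
      f <- mesh$faces[[i]]
      writeLines(c(paste("facet normal", paste(num(nrm[i, ]), collapse = " ")),
                   "  outer loop",
                   paste("    vertex", apply(v[f, , drop = FALSE], 1,
                         function(r) paste(num(r), collapse = " "))),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid pinnelast", con)
  } else if (fmt == "obj") {
    writeLines(apply(v, 1, function(r)
      paste("v", paste(num(r), collapse = " "))), con)
    writeLines(vapply(mesh$faces, function(f)
      paste("f", paste(f, collapse = " ")), ""), con)
  } else { # ply
    sizes <- vapply(mesh$faces, length, 1L)
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property double x", "property double y", "property double z",
                 paste("element face", length(mesh$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(v, 1, function(r) paste(num(r), collapse = " ")), con)
    writeLines(vapply(mesh$faces, function(f)
      paste(c(length(f), f - 1L), collapse = " "), ""), con)
  }
  invisible(path)
}

#' Read a surface mesh
#'
#' Supports the formats written by [write_mesh()].  STL facets (which carry
#' no shared topology) have their vertices merged by exact coordinate match.
#'
#' @param path Input file; the extension selects the parser.
#' @return A [surface_mesh()]; for VTK files with a `"displacement"` point
#'   data array, the field is attached as attribute `"displacement"`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- mesh_format(path)
  lines <- readLines(path, warn = FALSE)
  if (fmt == "vtk") {
    toks <- strsplit(trimws(lines), "\\s+")
    ip <- which(vapply(toks, function(t) length(t) > 0 && t[1] == "POINTS",
                       TRUE))
    if (length(ip) != 1) stop("malformed VTK file: no POINTS section")
    np <- as.integer(toks[[ip]][2])
    # points are the first 3*np numeric tokens after POINTS
    flat <- numeric(0); row <- ip
    while (length(flat) < 3 * np) {
      row <- row + 1
      flat <- c(flat, suppressWarnings(as.numeric(toks[[row]])))
    }
    verts <- matrix(flat[1:(3 * np)], ncol = 3, byrow = TRUE)
    ifc <- which(vapply(toks, function(t)
      length(t) > 0 && t[1] == "POLYGONS", TRUE))
    if (length(ifc) != 1) stop("malformed VTK file: no POLYGONS section")
    nf <- as.integer(toks[[ifc]][2])
    faces <- vector("list", nf)
    row <- ifc
    for (i in seq_len(nf)) {
      row <- row + 1
      tt <- as.integer(toks[[row]])
      faces[[i]] <- tt[-1] + 1L
    }
    disp <- NULL
    iv <- which(vapply(toks, function(t)
      length(t) > 1 && t[1] == "VECTORS" && t[2] == "displacement", TRUE))
    if (length(iv) == 1) {
      flat <- numeric(0); row <- iv
      while (length(flat) < 3 * np) {
        row <- row + 1
        flat <- c(flat, suppressWarnings(as.numeric(toks[[row]])))
      }
      disp <- matrix(flat[1:(3 * np)], ncol = 3, byrow = TRUE)
    }
    m <- surface_mesh(verts, faces)
    attr(m, "displacement") <- disp
    return(m)
  }
  if (fmt == "stl") {
    vt <- grep("^\\s*vertex", lines, value = TRUE)
    if (length(vt) == 0 || length(vt) %% 3 != 0)
      stop("malformed STL file")
    coords <- t(vapply(strsplit(trimws(vt), "\\s+"),
                       function(t) as.numeric(t[2:4]), numeric(3)))
    key <- apply(coords, 1, paste, collapse = ",")
    uk <- !duplicated(key)
    verts <- coords[uk, , drop = FALSE]
    id <- match(key, key[uk])
    faces <- split(id, rep(seq_len(length(id) / 3), each = 3))
    return(surface_mesh(verts, unname(faces)))
  }
  if (fmt == "obj") {
    toks <- strsplit(trimws(lines), "\\s+")
    vs <- Filter(function(t) length(t) > 0 && t[1] == "v", toks)
    fs <- Filter(function(t) length(t) > 0 && t[1] == "f", toks)
    if (length(vs) == 0 || length(fs) == 0) stop("malformed OBJ file")
    verts <- t(vapply(vs, function(t) as.numeric(t[2:4]), numeric(3)))
    faces <- lapply(fs, function(t)
      as.integer(vapply(strsplit(t[-1], "/"), `[`, "", 1)))
    return(surface_mesh(verts, faces))
  }
  # ply (ascii)
  hend <- which(trimws(lines) == "end_header")
  if (length(hend) != 1) stop("malformed PLY file")
  hdr <- strsplit(trimws(lines[1:hend]), "\\s+")
  if (!any(vapply(hdr, function(t)
    length(t) > 1 && t[1] == "format" && t[2] == "ascii", TRUE)))
    stop("only ASCII PLY is supported")
  nv <- nf <- NA_integer_
  for (t in hdr) if (length(t) == 3 && t[1] == "element") {
    if (t[2] == "vertex") nv <- as.integer(t[3])
    if (t[2] == "face") nf <- as.integer(t[3])
  }
  body <- strsplit(trimws(lines[(hend + 1):length(lines)]), "\\s+")
  verts <- t(vapply(body[1:nv], function(t) as.numeric(t[1:3]), numeric(3)))
  faces <- lapply(body[nv + seq_len(nf)], function(t) {
    t <- as.integer(t); t[1 + seq_len(t[1])] + 1L
  })
  surface_mesh(verts, faces)
}

#' Synthetic open conical membrane fixture
#'
#' Builds a triangulated membrane on the outer surface of a truncated-cone
#' shell with exactly `n_nodes` nodes, as a stand-in for an image-derived
#' valve surface.  Nodes are arranged in rings between the bottom rim
#' (labeled `"free_edge"`) and the top rim (labeled `"annulus"`); each ring
#' gets a seeded random rotational offset, and adjacent rings are stitched
#' by an angle-merging sweep.  Faces are oriented outward.
#'
#' @param shape A [truncated_cone_shell()]; only its outer surface is used.
#' @param n_nodes Total node count (>= 16).
#' @param seed Integer seed (ring offsets); deterministic for a fixed seed.
#' @return A [surface_mesh()] with node `labels`.
#' @export
make_membrane_fixture <- function(shape, n_nodes, seed = 0L) {
  stopifnot(n_nodes >= 16)
  h <- shape$height
  rb <- shape$bottom_diameter / 2; rt <- shape$top_diameter / 2
  circ <- pi * (rb + rt)
  nz <- max(3L, round(sqrt(n_nodes * h / circ)) + 1L)
  base <- n_nodes %/% nz; extra <- n_nodes %% nz
  counts <- rep(base, nz) + c(rep(1L, extra), rep(0L, nz - extra))
  zs <- h * (seq_len(nz) - 1) / (nz - 1)
  offs <- with_seed(seed, runif(nz))
  verts <- matrix(0, n_nodes, 3)
  angs <- vector("list", nz)
  start <- integer(nz)
  pos <- 0L
  for (j in seq_len(nz)) {
    m <- counts[j]
    a <- sort((2 * pi * (seq_len(m) - 1 + offs[j]) / m) %% (2 * pi))
    R <- cone_outer_radius(shape, zs[j])
    verts[pos + seq_len(m), ] <- cbind(R * cos(a), R * sin(a), zs[j])
    angs[[j]] <- a
    start[j] <- pos
    pos <- pos + m
  }
  faces <- list()
  for (j in seq_len(nz - 1)) {
    faces <- c(faces, zip_rings(angs[[j]], angs[[j + 1]],
                                start[j], start[j + 1]))
  }
  # orient all faces outward (positive dot with the outer cone normal)
  slope <- (rt - rb) / h
  for (i in seq_along(faces)) {
    f <- faces[[i]]
    v <- verts[f, , drop = FALSE]
    n <- crossprod3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    cen <- colMeans(v)
    rad <- sqrt(cen[1]^2 + cen[2]^2)
    out <- c(cen[1] / rad, cen[2] / rad, -slope)
    if (sum(n * out) < 0) faces[[i]] <- f[c(1, 3, 2)]
  }
  labels <- rep("interior", n_nodes)
  labels[start[1] + seq_len(counts[1])] <- "free_edge"
  labels[start[nz] + seq_len(counts[nz])] <- "annulus"
  surface_mesh(verts, faces, labels)
}

# stitch two rings of sorted angles into a triangle strip (indices are
# 0-based offsets of the first node in each ring; returns 1-based faces).
# Both rings are swept counterclockwise from a common reference angle; at
# each step the ring whose next node comes first contributes a triangle.
zip_rings <- function(a, b, offa, offb) {
  ma <- length(a); mb <- length(b)
  ra <- (a - a[1]) %% (2 * pi)           # ascending, starts at 0
  rb_all <- (b - a[1]) %% (2 * pi)
  bord <- order(rb_all)                  # sweep order of ring b
  rb <- rb_all[bord]
  Aidx <- function(i) offa + ((i - 1L) %% ma) + 1L
  Bidx <- function(j) offb + bord[((j - 1L) %% mb) + 1L]
  Aang <- function(i) if (i <= ma) ra[i] else 2 * pi + ra[i - ma]
  Bang <- function(j) if (j <= mb) rb[j] else 2 * pi + rb[j - mb]
  i <- 1L; j <- 1L
  faces <- vector("list", ma + mb)
  for (k in seq_len(ma + mb)) {
    adv_a <- if (i > ma) FALSE else if (j > mb) TRUE else
      Aang(i + 1L) <= Bang(j + 1L)
    if (adv_a) {
      faces[[k]] <- c(Aidx(i), Aidx(i + 1L), Bidx(j))
      i <- i + 1L
    } else {
      faces[[k]] <- c(Aidx(i), Bidx(j), Bidx(j + 1L))
      j <- j + 1L
    }
  }
  faces
}

#' Structured hexahedral mesh of a truncated-cone shell
#'
#' Nodes are generated on offset surfaces inward from the outer cone;
#' element connectivity follows the standard trilinear hex ordering.
#' Face/node sets: `outer` (quads on the pressurized outer surface, with
#' outward orientation) and `top` (all nodes on the z = height plane, the
#' pinned end).
#'
#' @param domain A [truncated_cone_shell()].
#' @param n_r,n_theta,n_z Elements through thickness, around, and along the
#'   axis.
#' @return List with `nodes` (n x 3), `hex` (ne x 8, 1-based),
#'   `outer_faces` (nf x 4 node ids), `top_nodes` (integer vector).
#' @export
cone_hex_mesh <- function(domain, n_r = 2L, n_theta = 24L, n_z = 10L) {
  h <- domain$height; tt <- domain$wall_thickness
  rb <- domain$bottom_diameter / 2; rt <- domain$top_diameter / 2
  slope <- (rt - rb) / h
  cosa <- 1 / sqrt(1 + slope^2)
  n_r <- as.integer(n_r); n_theta <- as.integer(n_theta)
  n_z <- as.integer(n_z)
  nid <- function(iz, ith, ir) { # iz 0..n_z, ith 0..n_theta-1, ir 0..n_r
    1L + (ith %% n_theta) + n_theta * (ir + (n_r + 1L) * iz)
  }
  nodes <- matrix(0, (n_z + 1L) * (n_theta) * (n_r + 1L), 3)
  for (iz in 0:n_z) for (ir in 0:n_r) for (ith in 0:(n_theta - 1L)) {
    z <- h * iz / n_z
    th <- 2 * pi * ith / n_theta
    R <- cone_outer_radius(domain, z)
    d <- tt * ir / n_r
    nrm <- c(cos(th) * cosa, sin(th) * cosa, -slope * cosa)
    nodes[nid(iz, ith, ir), ] <- c(R * cos(th), R * sin(th), z) - d * nrm
  }
  hex <- matrix(0L, n_z * n_theta * n_r, 8)
  e <- 0L
  for (iz in 0:(n_z - 1L)) for (ir in 0:(n_r - 1L))
    for (ith in 0:(n_theta - 1L)) {
      e <- e + 1L
      # bottom face (iz) counterclockwise seen from +z, then top face (iz+1)
      hex[e, ] <- c(nid(iz, ith, ir), nid(iz, ith + 1L, ir),
                    nid(iz, ith + 1L, ir + 1L), nid(iz, ith, ir + 1L),
                    nid(iz + 1L, ith, ir), nid(iz + 1L, ith + 1L, ir),
                    nid(iz + 1L, ith + 1L, ir + 1L), nid(iz + 1L, ith, ir + 1L))
    }
  outer <- matrix(0L, n_z * n_theta, 4)
  inner <- matrix(0L, n_z * n_theta, 4)
  e <- 0L
  for (iz in 0:(n_z - 1L)) for (ith in 0:(n_theta - 1L)) {
    e <- e + 1L
    # outward-oriented quad on ir = 0 surface
    outer[e, ] <- c(nid(iz, ith, 0L), nid(iz, ith + 1L, 0L),
                    nid(iz + 1L, ith + 1L, 0L), nid(iz + 1L, ith, 0L))
    # inner wall (ir = n_r), oriented out of the body (toward the axis)
    inner[e, ] <- c(nid(iz, ith + 1L, n_r), nid(iz, ith, n_r),
                    nid(iz + 1L, ith, n_r), nid(iz + 1L, ith + 1L, n_r))
  }
  top <- unlist(lapply(0:n_r, function(ir)
    vapply(0:(n_theta - 1L), function(ith) nid(n_z, ith, ir), integer(1))))
  list(nodes = nodes, hex = hex, outer_faces = outer, inner_faces = inner,
       top_nodes = sort(unique(top)))
}
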