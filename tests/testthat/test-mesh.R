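# Surface meshes, file formats, and the membrane fixture.

quad_sheet <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               list(c(1L, 2L, 3L, 4L)))
}

tri_sheet <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0.2)),
               list(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

test_that("mesh writers and readers round-trip each format", {
  m <- tri_sheet()
  for (ext in c("vtk", "obj", "ply", "stl")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(nrow(m2$vertices), 4, info = ext)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-9)
    if (ext != "stl")           # STL re-indexes after vertex merging
      expect_identical(lapply(m2$faces, as.integer), m$faces)
    expect_equal(length(m2$faces), length(m$faces), info = ext)
    unlink(path)
  }
  # quad faces survive the polygonal formats
  q <- quad_sheet()
  path <- tempfile(fileext = ".vtk")
  write_mesh(q, path)
  expect_equal(nrow(read_mesh(path)$vertices), 4)
  unlink(path)
})

test_that("STL vertex merging agrees with brute-force deduplication", {
  m <- make_membrane_fixture(truncated_cone_shell(1, 2, 1, 0.1), 60,
                             seed = 1)
  path <- tempfile(fileext = ".stl")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  # brute force: count unique coordinate triplets among facet vertices
  lines <- readLines(path)
  vt <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- t(vapply(strsplit(trimws(vt), "\\s+"),
                     function(t) as.numeric(t[2:4]), numeric(3)))
  expect_equal(nrow(m2$vertices), nrow(unique(coords)))
  expect_equal(length(m2$faces), length(m$faces))
  unlink(path)
})

test_that("VTK files carry displacement point data", {
  m <- tri_sheet()
  u <- matrix(rnorm(12), 4, 3)
  path <- tempfile(fileext = ".vtk")
  write_mesh(m, path, displacement = u)
  m2 <- read_mesh(path)
  expect_equal(attr(m2, "displacement"), u, tolerance = 1e-12)
  unlink(path)
})

test_that("malformed or empty meshes are rejected", {
  expect_error(surface_mesh(matrix(0, 0, 3), list()), "empty")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                            list(c(1L, 2L, 3L))), "degenerate")
  expect_error(surface_mesh(diag(3), list(c(1L, 2L, 5L))), "out of range")
  expect_error(read_mesh(tempfile(fileext = ".xyz")), "not found")
  p <- tempfile(fileext = ".xyz"); writeLines("x", p)
  expect_error(read_mesh(p), "unknown mesh format")
  p2 <- tempfile(fileext = ".vtk"); writeLines("garbage", p2)
  expect_error(read_mesh(p2), "malformed")
  unlink(c(p, p2))
})

test_that("membrane fixture has exact node count, labels and orientation", {
  shape <- truncated_cone_shell(1, 2, 1, 0.1)
  for (n in c(16L, 300L, 1200L)) {
    m <- make_membrane_fixture(shape, n, seed = 0)
    expect_equal(nrow(m$vertices), n)
    expect_gt(sum(m$labels == "annulus"), 0)
    expect_gt(sum(m$labels == "free_edge"), 0)
  }
  m <- make_membrane_fixture(shape, 400, seed = 2)
  # annulus nodes on the top rim, free edge at the bottom
  expect_true(all(m$vertices[m$labels == "annulus", 3] == shape$height))
  expect_true(all(m$vertices[m$labels == "free_edge", 3] == 0))
  # every face normal points outward (positive dot with the cone normal)
  nrm <- pinnelast:::face_normals(m)
  slope <- (1 - 0.5) / 1
  for (i in seq_along(m$faces)) {
    cen <- colMeans(m$vertices[m$faces[[i]], ])
    r <- sqrt(cen[1]^2 + cen[2]^2)
    out <- c(cen[1] / r, cen[2] / r, -slope)
    expect_gt(sum(nrm[i, ] * out), 0)
  }
  # deterministic for a fixed seed
  m2 <- make_membrane_fixture(shape, 400, seed = 2)
  expect_identical(m$vertices, m2$vertices)
  expect_identical(m$faces, m2$faces)
})

test_that("fixture triangulation is a closed band between the rims", {
  m <- make_membrane_fixture(truncated_cone_shell(1, 2, 1, 0.1), 200,
                             seed = 3)
  # every edge is shared by exactly two faces except rim edges
  edges <- do.call(rbind, lapply(m$faces, function(f)
    rbind(sort(f[1:2]), sort(f[2:3]), sort(f[c(3, 1)]))))
  key <- paste(edges[, 1], edges[, 2])
  counts <- table(key)
  expect_true(all(counts <= 2))
  rim <- sum(counts == 1)
  # boundary edge count equals the two rim node counts
  expect_equal(rim, sum(m$labels == "annulus") +
                 sum(m$labels == "free_edge"))
})

test_that("cone hex mesh has positive Jacobians and coherent sets", {
  dom <- truncated_cone_shell(1, 2, 1, 0.1)
  mesh <- cone_hex_mesh(dom, 2, 12, 5)
  gs <- pinnelast:::hex_gauss()
  for (e in seq_len(nrow(mesh$hex))) {
    X <- mesh$nodes[mesh$hex[e, ], ]
    for (k in 1:8)
      expect_gt(det(t(pinnelast:::hex_shape(gs$points[k, ])$dN) %*% X), 0)
  }
  # the pinned end: outer-surface node at z = height, inner nodes offset
  # along the tilted inward normal (slightly above the z = height plane)
  zt <- mesh$nodes[mesh$top_nodes, 3]
  slope <- 0.5; cosa <- 1 / sqrt(1 + slope^2)
  expect_true(all(zt >= 1 - 1e-12 & zt <= 1 + 0.1 * slope * cosa + 1e-12))
  # outer faces lie on the outer cone surface
  ids <- unique(as.integer(mesh$outer_faces))
  depth <- pinnelast:::cone_surface_depth(dom, mesh$nodes[ids, ])
  expect_lt(max(abs(depth)), 1e-12)
})
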