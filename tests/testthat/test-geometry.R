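test_that("surface geometry matches closed forms", {
  # right triangle in the xy plane
  s <- triangle_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(c(1, 2, 3), 1))
  g <- surface_geometry(s)
  expect_equal(g$centroids[1, ], c(1 / 3, 1 / 3, 0))
  expect_equal(g$areas[1], 0.5)
  expect_equal(g$normals[1, ], c(0, 0, 1))

  # equilateral triangle, side 2
  s2 <- triangle_surface(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)),
                         matrix(c(1, 2, 3), 1))
  expect_equal(surface_area(s2), sqrt(3))

  # unit tetrahedron total area 1.5 + sqrt(3)/2
  expect_equal(surface_area(unit_tetrahedron()), 1.5 + sqrt(3) / 2)
  expect_gt(signed_volume(unit_tetrahedron()), 0)

  # icosphere area converges to 4 pi R^2 from below
  areas <- vapply(1:3, function(k)
    surface_area(icosphere(10, subdivisions = k)), numeric(1))
  rel <- abs(areas - 4 * pi * 100) / (4 * pi * 100)
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[3], 0.01)
})

test_that("degenerate faces and bad indices are rejected", {
  expect_error(
    triangle_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                     matrix(c(1, 2, 3), 1)),
    "degenerate")
  expect_error(
    triangle_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     matrix(c(1, 2, 4), 1)),
    "out of range")
})

test_that("STL/PLY/OBJ round-trips preserve counts and area", {
  tet <- unit_tetrahedron()
  for (fmt in c("stl", "ply", "obj")) {
    path <- tempfile(fileext = paste0(".", fmt))
    save_surface(tet, path)
    back <- load_surface(path)
    expect_identical(nrow(back$vertices), 4L)
    expect_identical(nrow(back$faces), 4L)
    expect_equal(surface_area(back), surface_area(tet), tolerance = 1e-9)
  }
  # binary STL dialect
  pb <- tempfile(fileext = ".stl")
  save_surface(tet, pb, binary = TRUE)
  back <- load_surface(pb)
  expect_identical(nrow(back$faces), 4L)
  expect_equal(surface_area(back), surface_area(tet), tolerance = 1e-6)

  # phantom femur round-trips with identical face count and area
  fem <- cached_phantom(1)$femur
  p <- tempfile(fileext = ".stl")
  save_surface(fem, p)
  back <- load_surface(p, label = "femur")
  expect_identical(nrow(back$faces), nrow(fem$faces))
  expect_equal(surface_area(back), surface_area(fem), tolerance = 1e-9)
  # load -> save -> load is stable
  p2 <- tempfile(fileext = ".ply")
  save_surface(back, p2)
  back2 <- load_surface(p2)
  expect_identical(nrow(back2$vertices), nrow(back$vertices))
  expect_equal(surface_area(back2), surface_area(back), tolerance = 1e-9)
})

test_that("duplicate vertices are merged at load, topology preserved", {
  # PLY with two redundant copies of existing vertices
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(0, 0, 0), c(1, 0, 0))
  f <- rbind(c(1, 3, 2), c(5, 6, 4), c(1, 4, 3), c(2, 3, 4))
  path <- tempfile(fileext = ".ply")
  con <- file(path, "w")
  writeLines(c("ply", "format ascii 1.0", "element vertex 6",
               "property double x", "property double y", "property double z",
               "element face 4",
               "property list uchar int vertex_indices", "end_header",
               apply(v, 1, paste, collapse = " "),
               paste("3", f[, 1] - 1, f[, 2] - 1, f[, 3] - 1)), con)
  close(con)
  s <- load_surface(path)
  expect_identical(nrow(s$vertices), 4L)   # reduced by the 2 duplicates
  expect_identical(nrow(s$faces), 4L)
  expect_equal(surface_area(s), 1.5 + sqrt(3) / 2)
  expect_error(load_surface(tempfile()), "no such file")
})

test_that("rigid poses transform as expected", {
  fem <- cached_phantom(1)$femur
  # identity leaves vertices bit-identical
  expect_identical(apply_pose(fem, rigid_pose())$vertices, fem$vertices)
  # pure translation shifts the centroid exactly
  sh <- apply_pose(fem, rigid_pose(tx = 5))
  expect_equal(surface_centroid(sh) - surface_centroid(fem), c(5, 0, 0))
  # rotation forth and back recovers vertices
  r1 <- apply_pose(fem, rigid_pose(rz = 90))
  r2 <- apply_pose(r1, rigid_pose(rz = -90))
  expect_equal(r2$vertices, fem$vertices, tolerance = 1e-9)
  # rigid transforms preserve pairwise distances and areas
  pose <- rigid_pose(3, -2, 7, 25, -40, 110)
  moved <- apply_pose(fem, pose)
  i <- c(1, 10, 50); j <- c(5, 40, 90)
  d0 <- sqrt(rowSums((fem$vertices[i, ] - fem$vertices[j, ])^2))
  d1 <- sqrt(rowSums((moved$vertices[i, ] - moved$vertices[j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_equal(surface_area(moved), surface_area(fem), tolerance = 1e-9)
  expect_error(apply_pose(fem, structure(list(tx = NaN, ty = 0, tz = 0,
                                              rx = 0, ry = 0, rz = 0),
                                         class = "rigid_pose")),
               "non-finite")
})

test_that("pose composition matches matrix products and inversion", {
  set.seed(11)
  for (k in 1:5) {
    p1 <- pose_from_vector(c(runif(3, -10, 10), runif(3, -60, 60)))
    p2 <- pose_from_vector(c(runif(3, -10, 10), runif(3, -60, 60)))
    cen <- runif(3, -5, 5)
    M12 <- pose_to_matrix(pose_compose(p1, p2, cen), cen)
    expect_equal(M12, pose_to_matrix(p1, cen) %*% pose_to_matrix(p2, cen),
                 tolerance = 1e-12)
    # composing with the inverse yields identity within 1e-9
    pid <- pose_compose(p1, pose_inverse(p1, cen), cen)
    expect_equal(pose_to_vector(pid), rep(0, 6), tolerance = 1e-9)
  }
})
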