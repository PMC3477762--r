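test_that("scene construction realises the acquisition protocol", {
  sc <- build_scene()
  # 72 inches from the detector, exactly converted
  foot <- c(sc$source[1], sc$source[2], 0)
  expect_equal(sqrt(sum((sc$source - foot)^2)), 1828.8, tolerance = 1e-6)
  # central ray makes exactly the caudal angle with the detector normal
  ang <- acos(abs(sum(sc$central_axis * sc$normal))) * 180 / pi
  expect_equal(ang, 10, tolerance = 1e-9)
  # zero-angle override: beam perpendicular to the detector
  sc0 <- build_scene(caudal_angle = 0, allow_any_angle = TRUE)
  expect_equal(sc0$central_axis, c(0, 0, -1))
  expect_error(build_scene(caudal_angle = 7), "caudal angle")
  expect_error(build_scene(pixel_spacing = -1, caudal_angle = 5),
               "positive")
})

test_that("projection follows similar triangles", {
  sc <- build_scene(caudal_angle = 0, allow_any_angle = TRUE)
  # hand calculation: x = 10 * 1828.8 / (1828.8 - 100)
  p <- project_to_detector(c(10, 0, 100), sc)
  expect_equal(unname(p[1, 1]), 10 * 1828.8 / 1728.8, tolerance = 1e-9)
  # a point on the detector plane projects to itself
  p2 <- project_to_detector(c(25, -13, 0), sc)
  expect_equal(as.numeric(p2), c(25, -13), tolerance = 1e-9)
  # points on the central ray hit the same detector point at any depth
  sc10 <- build_scene(caudal_angle = 10)
  pts <- rbind(sc10$source + 300 * sc10$central_axis,
               sc10$source + 1100 * sc10$central_axis)
  pr <- project_to_detector(pts, sc10)
  expect_equal(pr[1, ], pr[2, ], tolerance = 1e-9)
  # magnification of an object at distance d is SDD/(SDD - d)
  ruler <- cbind(seq(-20, 20, 10), 0, 150)
  pr3 <- project_to_detector(ruler, sc)
  expect_equal(unname(diff(pr3[, 1]) / diff(ruler[, 1])),
               rep(1828.8 / (1828.8 - 150), 4), tolerance = 1e-9)
})

test_that("silhouette edge extraction obeys the facing-sign rule", {
  # a single isolated triangle: all 3 (boundary) edges
  tri <- triangle_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                          matrix(c(1, 2, 3), 1))
  expect_identical(nrow(extract_silhouette_edges(tri, c(0, 0, 100))), 3L)

  # cube viewed along +z from far away: silhouette = the 8 edges that
  # project onto the square outline; verified against a brute-force
  # per-edge sign test
  cube <- box_mesh(c(-1, -1, -1), c(1, 1, 1))
  src <- c(0, 0, 1000)
  sil <- extract_silhouette_edges(cube, src)
  g <- surface_geometry(cube)
  e <- kneedea:::surface_edges(cube)
  sgn <- rowSums(g$normals * sweep(g$centroids, 2, src)) > 0
  brute <- e[sgn[e[, 3]] != sgn[e[, 4]], 1:2, drop = FALSE]
  expect_identical(unname(sil[order(sil[, 1], sil[, 2]), ]),
                   brute[order(brute[, 1], brute[, 2]), ])
  # under perspective the near (+z) face projects largest, so the outline
  # is exactly that face's 4 edges
  v <- cube$vertices
  expect_identical(nrow(sil), 4L)
  expect_true(all(v[as.vector(sil), 3] == 1))

  # icosphere from a distant source: silhouette edges form one closed loop:
  # every silhouette vertex has degree 2 and the edge graph is connected
  sp <- icosphere(10, subdivisions = 2)
  sil2 <- extract_silhouette_edges(sp, c(0, 0, 1000))
  deg <- table(as.vector(sil2))
  expect_true(all(deg == 2))
  verts <- sort(unique(as.vector(sil2)))
  reach <- verts[1]
  repeat {
    grow <- unique(as.vector(sil2[sil2[, 1] %in% reach |
                                    sil2[, 2] %in% reach, ]))
    if (length(grow) == length(reach)) break
    reach <- grow
  }
  expect_identical(sort(reach), verts)
  expect_error(extract_silhouette_edges(
    triangle_surface(matrix(0, 0, 3), matrix(0L, 0, 3), validate = FALSE),
    c(0, 0, 1)), "empty")
})

test_that("contour rasterisation produces connected binary contours", {
  sc <- test_scene()
  # two points 10 px apart on a row: a horizontal run of 11 pixels
  run <- rasterize_contour(rbind(c(0, 0), c(10 * sc$pixel_spacing, 0)), sc)
  expect_identical(sum(run$pixels), 11L)
  rows <- which(run$pixels == 1L, arr.ind = TRUE)
  expect_identical(length(unique(rows[, 1])), 1L)

  # a projected square outline: one 8-connected component
  sq <- rbind(c(-20, -20), c(20, -20), c(20, 20), c(-20, 20))
  img <- rasterize_contour(sq, sc, close = TRUE)
  expect_identical(count_components(img$pixels), 1L)

  # single repeated point: a single foreground pixel
  one <- rasterize_contour(rbind(c(3, 3), c(3, 3)), sc)
  expect_identical(sum(one$pixels), 1L)

  expect_error(rasterize_contour(rbind(c(1e5, 1e5), c(1e5 + 1, 1e5)), sc),
               "outside")
})

test_that("contour cost is a symmetric mean distance in mm", {
  sc <- test_scene(pixel_spacing = 0.2, image_size = c(128L, 128L))
  a <- matrix(0L, 128, 128)
  a[60, 30:90] <- 1L
  ia <- edge_image(a, 0.2)
  expect_identical(contour_cost(ia, ia), 0)
  # perpendicular shift by exactly one pixel: cost = one pixel = 0.2 mm
  b <- matrix(0L, 128, 128)
  b[61, 30:90] <- 1L
  ib <- edge_image(b, 0.2)
  expect_equal(contour_cost(ia, ib), 0.2, tolerance = 1e-12)
  expect_identical(contour_cost(ia, ib), contour_cost(ib, ia))
  # brute-force nearest-foreground oracle on a small random pair
  set.seed(4)
  m1 <- matrix(0L, 40, 40); m1[cbind(sample(40, 15), sample(40, 15))] <- 1L
  m2 <- matrix(0L, 40, 40); m2[cbind(sample(40, 12), sample(40, 12))] <- 1L
  nnmean <- function(from, to) {
    pf <- which(from == 1L, arr.ind = TRUE)
    pt <- which(to == 1L, arr.ind = TRUE)
    mean(apply(pf, 1, function(p)
      sqrt(min((pt[, 1] - p[1])^2 + (pt[, 2] - p[2])^2))))
  }
  expected <- 0.5 * (nnmean(m1, m2) + nnmean(m2, m1)) * 0.3
  expect_equal(contour_cost(edge_image(m1, 0.3), edge_image(m2, 0.3)),
               expected, tolerance = 1e-12)
  expect_error(contour_cost(ia, edge_image(matrix(0L, 128, 128), 0.2)),
               "empty")
})

test_that("distance transform agrees with the EBImage oracle", {
  skip_if_not_installed("EBImage")
  set.seed(9)
  for (k in 1:3) {
    img <- matrix(0L, 60, 50)
    img[cbind(sample(60, 25, TRUE), sample(50, 25, TRUE))] <- 1L
    ours <- kneedea:::edt_cpp(img)
    # EBImage::distmap: distance of nonzero pixels to the nearest zero,
    # so invert the mask to get distance-to-foreground
    theirs <- EBImage::distmap(1 - img, metric = "euclidean")
    expect_equal(ours, theirs@.Data, tolerance = 1e-6)
  }
})

test_that("silhouette projection respects magnification and convexity", {
  sc <- build_scene(caudal_angle = 0, allow_any_angle = TRUE)
  sp <- icosphere(20, c(0, 0, 100), subdivisions = 3)
  img <- kneedea:::render_silhouette(sp, sc)
  px <- which(img$pixels == 1L, arr.ind = TRUE)
  # projected radius = R * magnification at the sphere depth (the silhouette
  # plane of a sphere is slightly nearer the source; 1% tolerance)
  mag <- 1828.8 / (1828.8 - 100)
  half_width <- (diff(range(px[, 2])) / 2) * sc$pixel_spacing
  expect_equal(half_width, 20 * mag, tolerance = 0.02)
  # convex body at zero caudal angle: every silhouette pixel lies within
  # one pixel of the convex hull boundary of the pixel set
  pts <- px[, c(2, 1)]  # (x, y)
  hull <- grDevices::chull(pts)
  poly <- pts[hull, , drop = FALSE]
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    sqrt(sum((a + t * ab - p)^2))
  }
  dmax <- max(apply(pts, 1, function(p) {
    min(vapply(seq_len(nrow(poly)), function(i)
      seg_dist(p, poly[i, ], poly[i %% nrow(poly) + 1, ]), numeric(1)))
  }))
  expect_lt(dmax, 1 + 1e-9)
})

test_that("contour cost decreases monotonically approaching ground truth", {
  sc <- test_scene()
  ph <- cached_phantom(1)
  fem <- place_in_scene(ph$femur, sc)$surfaces
  target <- synthesize_radiograph_edges(fem, sc)
  shifts <- seq(5, 0, length.out = 10)
  costs <- vapply(shifts, function(s) {
    moved <- kneedea:::render_silhouette(fem, sc, pose = rigid_pose(tx = s))
    contour_cost(moved, target)
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
  expect_equal(costs[10], 0)
})
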