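test_that("nearest-facet pairing matches construction and cutoff", {
  # two parallel unit squares 1 mm apart: facets pair with the facing facet
  bottom <- kneedea:::heightfield_solid(0:1, 0:1,
                                        function(x, y) rep(0, length(x)),
                                        -1, "b")
  top <- box_mesh(c(0, 0, 1), c(1, 1, 2))
  pairs <- find_contact_pairs(bottom, top, search_radius = 2)
  tg <- surface_geometry(bottom)
  fg <- surface_geometry(top)
  up <- which(tg$normals[, 3] > 0.9)       # bottom surface's top facets
  expect_true(all(up %in% pairs$tibial))
  down <- which(fg$normals[pairs$femoral[match(up, pairs$tibial)], 3] < -0.9)
  expect_identical(length(down), length(up))
  # radius smaller than the gap: empty set
  pairs0 <- find_contact_pairs(bottom, top, search_radius = 0.5)
  expect_identical(nrow(pairs0), 0L)
  expect_error(find_contact_pairs(
    triangle_surface(matrix(0, 0, 3), matrix(0L, 0, 3), validate = FALSE),
    top, 1), "empty")
})

test_that("grid pairing is identical to exhaustive search", {
  ph <- cached_phantom(1)
  tg <- surface_geometry(ph$tibia)
  fg <- surface_geometry(ph$femur)
  for (radius in c(3, 8, 20)) {
    nn <- kneedea:::nearest_within_cpp(tg$centroids, fg$centroids, radius)
    brute <- brute_nearest_within(tg$centroids, fg$centroids, radius)
    expect_identical(nn$idx, brute)
  }
})

test_that("spring laws match the closed forms", {
  p <- dea_params()
  # compressive-only deformation
  expect_identical(spring_deformation(6, 6), 0)
  expect_equal(spring_deformation(5.7, 6), 0.3)
  expect_identical(spring_deformation(7, 6), 0)   # tension never modelled
  expect_equal(spring_deformation(-1, 6), 7)      # overlap: d > t allowed
  # confined-compression coefficient 30.6338 MPa at E=12, nu=0.42
  expect_equal(confined_modulus(p), 30.63380282, tolerance = 1e-8)
  expect_identical(spring_stress(0, p), 0)
  expect_equal(spring_stress(0.3, p), 1.53169, tolerance = 1e-5)
  # linearity
  expect_equal(spring_stress(0.6, p), 2 * spring_stress(0.3, p))
  expect_error(dea_params(nu = 0.5), "singular")
  expect_error(spring_stress(-0.1, p), "negative")
})

test_that("contact force sums stress times area along directions", {
  springs <- list(directions = rbind(c(0, 0, 1)), areas = 3)
  expect_equal(contact_force(springs, 2), c(0, 0, 6))
  expect_equal(contact_force(list(directions = matrix(0, 0, 3),
                                  areas = numeric(0)), numeric(0)),
               c(0, 0, 0))
  # mirror-symmetric springs: lateral components cancel
  n1 <- c(sin(0.3), 0, cos(0.3))
  n2 <- c(-sin(0.3), 0, cos(0.3))
  f <- contact_force(list(directions = rbind(n1, n2), areas = c(2, 2)),
                     c(1.5, 1.5))
  expect_lt(abs(f[1]), 1e-12)
  expect_equal(f[3], 2 * 1.5 * 2 * cos(0.3))
})

test_that("congruent flat contact carries load / area uniformly", {
  # 25 x 20 mm parallel plates: equilibrium stress must be P/A = 2 MPa
  plate <- kneedea:::heightfield_solid(seq(0, 25, 1), seq(0, 20, 1),
                                       function(x, y) rep(0, length(x)),
                                       -5, "tibia")
  punch <- kneedea:::heightfield_solid(seq(0, 25, 1), seq(0, 20, 1),
                                       function(x, y) rep(18, length(x)),
                                       8, "punch")
  field <- solve_equilibrium(punch, plate, dea_params())
  expect_true(field$converged)
  active <- field$stress[field$stress > 0]
  expect_equal(mean(active), 2.0, tolerance = 0.005)
  expect_lt(diff(range(active)), 1e-6)     # uniform
  expect_equal(field$force, 1000, tolerance = 0.005 * 1000)
  # vertical force within 0.5% of the applied load
  expect_lte(abs(field$force - 1000), 5)
})

test_that("equilibrium failure modes raise informative errors", {
  plate <- kneedea:::heightfield_solid(seq(0, 10, 1), seq(0, 10, 1),
                                       function(x, y) rep(0, length(x)),
                                       -5, "tibia")
  punch <- box_mesh(c(0, 0, 30), c(10, 10, 40))  # far out of reach
  expect_error(solve_equilibrium(punch, plate, dea_params(),
                                 travel_bound = 3),
               "travel")
})

test_that("peak stress increases strictly with load", {
  ph <- cached_phantom(1, conforming = TRUE)
  peaks <- vapply(c(500, 1000, 1500), function(P) {
    f <- solve_equilibrium(ph$femur, ph$tibia, dea_params(load = P))
    expect_lte(abs(f$force - P), 0.005 * P)
    max(f$stress)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("compartment metrics split by the sagittal midline", {
  ph <- cached_phantom(2, conforming = TRUE)
  field <- solve_equilibrium(ph$femur, ph$tibia, dea_params())
  m <- compartment_metrics(field)
  # symmetric phantom under symmetric load: compartments agree within 1%
  expect_equal(m$peak_medial, m$peak_lateral,
               tolerance = 0.01 * m$peak_medial)
  expect_equal(m$mean_medial, m$mean_lateral,
               tolerance = 0.01 * m$mean_medial)
  expect_gte(m$peak_medial, m$mean_medial)
  expect_gte(m$peak_lateral, m$mean_lateral)
  # uniform field: peak = mean in both compartments
  plate <- kneedea:::heightfield_solid(seq(-10, 10, 1), seq(-8, 8, 1),
                                       function(x, y) rep(0, length(x)),
                                       -5, "tibia")
  punch <- kneedea:::heightfield_solid(seq(-10, 10, 1), seq(-8, 8, 1),
                                       function(x, y) rep(18, length(x)),
                                       8, "punch")
  uf <- solve_equilibrium(punch, plate,
                          dea_params(load = 2 * 20 * 16))  # 2 MPa uniform
  um <- compartment_metrics(uf)
  expect_equal(um$peak_medial, um$mean_medial, tolerance = 1e-6)
  expect_equal(um$peak_lateral, um$mean_lateral, tolerance = 1e-6)
  expect_equal(um$peak_medial, 2, tolerance = 0.01)
  # all contact on one side: the other compartment reports zeros
  off_punch <- kneedea:::heightfield_solid(seq(-10, -2, 1), seq(-8, 8, 1),
                                           function(x, y) rep(18, length(x)),
                                           8, "punch")
  of <- solve_equilibrium(off_punch, plate, dea_params(load = 200))
  expect_warning(om <- compartment_metrics(of), "lateral")
  expect_identical(om$peak_lateral, 0)
  expect_identical(om$mean_lateral, 0)
  expect_gt(om$peak_medial, 0)
})
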