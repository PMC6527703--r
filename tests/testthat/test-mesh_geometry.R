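test_that("surface_area matches closed forms and converges on the sphere", {
  expect_equal(surface_area(unit_cube()), 6.0)
  expect_equal(surface_area(single_triangle()), 0.5)
  # inscribed polyhedron underestimates the analytic sphere area
  s <- make_icosphere(radius = 1, subdivisions = 4)
  expect_lt(surface_area(s), 4 * pi)
  expect_equal(surface_area(s), 4 * pi, tolerance = 0.005)
  s2 <- make_icosphere(radius = 2, subdivisions = 4)
  expect_equal(surface_area(s2), 16 * pi, tolerance = 0.005)
})

test_that("surface validation rejects broken meshes", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(triangulated_surface(v, matrix(c(1, 2, 4), 1)),
               "out of range")
  expect_error(
    triangulated_surface(rbind(v, c(2, 0, 0)),
                         rbind(c(1, 2, 3), c(1, 2, 4))),
    "degenerate")  # (1,2,4) collinear -> zero area
  # duplicated directed edge -> inconsistent winding warning
  expect_warning(
    triangulated_surface(rbind(v, c(1, 1, 1)),
                         rbind(c(1, 2, 3), c(1, 2, 4))),
    "winding")
})

test_that("angle deficits match closed-form corner geometry", {
  cube <- unit_cube()
  d <- vertex_angle_deficits(cube)
  expect_equal(as.double(d), rep(pi / 2, 8))  # 2*pi - 3*(pi/2)

  # apex of an equilateral square pyramid: 2*pi - 4*(pi/3) = 2*pi/3
  pyr <- equilateral_pyramid()
  d <- vertex_angle_deficits(pyr)
  expect_equal(d[5], 2 * pi / 3)
  # base vertices sit on boundary edges: deficit forced to 0 and reported
  expect_equal(as.double(d[1:4]), rep(0, 4))
  expect_equal(attr(d, "n_boundary"), 4L)

  # interior vertex of a planar triangulation is flat
  d <- vertex_angle_deficits(flat_grid())
  expect_equal(d[5], 0)

  # a vertex not referenced by any triangle is an error
  expect_error(
    vertex_angle_deficits(
      triangulated_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                 c(5, 5, 5)),
                           matrix(c(1, 2, 3), 1))),
    "no incident triangle")
})

test_that("Gauss-Bonnet: integrated curvature is 2*pi*chi on closed meshes", {
  expect_equal(integrated_curvature(unit_cube()), 4 * pi, tolerance = 1e-12)
  for (lev in 1:5) {
    s <- make_icosphere(1, lev)
    expect_equal(integrated_curvature(s), 4 * pi, tolerance = 1e-9)
  }
  expect_equal(integrated_curvature(make_torus()), 0, tolerance = 1e-9)
  g <- make_gyrified_sphere(50, 0.15, 8, subdivisions = 3)
  expect_equal(integrated_curvature(g$surface), 4 * pi, tolerance = 1e-9)
})

test_that("curvature is additive over any disjoint vertex partition", {
  s <- make_icosphere(1, 3)
  d <- vertex_angle_deficits(s)
  lab <- as.integer(octant_labels(s))
  subset_sums <- vapply(0:7, function(L)
    integrated_curvature(s, which(lab == L), deficits = d), numeric(1))
  expect_equal(sum(subset_sums), integrated_curvature(s, deficits = d),
               tolerance = 1e-12)
  # one octant of a sphere carries ~ 1/8 of the total curvature
  expect_equal(subset_sums, rep(pi / 2, 8), tolerance = 0.1)
})

test_that("refinement leaves curvature invariant while area converges", {
  areas <- numeric(5)
  for (lev in 1:5) {
    s <- make_icosphere(1, lev)
    expect_equal(integrated_curvature(s), 4 * pi, tolerance = 1e-9)
    areas[lev] <- surface_area(s)
  }
  expect_true(all(diff(areas) > 0))       # monotone from below
  expect_true(all(areas < 4 * pi))
  expect_equal(areas[5], 4 * pi, tolerance = 5e-4)
})

test_that("vertex areas are a barycentric partition of the surface", {
  tri <- single_triangle()
  expect_equal(as.double(vertex_areas(tri)), rep(1 / 6, 3))
  for (s in list(unit_cube(), make_icosphere(1, 3))) {
    va <- vertex_areas(s)
    expect_true(all(va > 0))
    expect_equal(sum(va), surface_area(s), tolerance = 1e-12)
  }
})

test_that("topology_report diagnoses closedness and Euler characteristic", {
  s <- make_icosphere(1, 2)
  tr <- topology_report(s)
  expect_identical(tr$euler_characteristic, 2L)
  expect_true(tr$is_closed)
  expect_identical(tr$boundary_edge_count, 0L)
  expect_equal(tr$total_angle_deficit, 4 * pi, tolerance = 1e-9)

  holed <- triangulated_surface(s$vertices, s$triangles[-1, , drop = FALSE])
  trh <- topology_report(holed)
  expect_identical(trh$euler_characteristic, 1L)
  expect_identical(trh$boundary_edge_count, 3L)
  expect_false(trh$is_closed)

  trt <- topology_report(make_torus())
  expect_identical(trt$euler_characteristic, 0L)
  expect_true(trt$is_closed)
  expect_equal(trt$total_angle_deficit, 0, tolerance = 1e-9)

  # non-manifold edge: three triangles sharing one edge
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(topology_report(suppressWarnings(triangulated_surface(v, f))),
               "non-manifold edge")
})

test_that("convex hull is a closed outward triangulation of extreme points", {
  corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  h <- convex_hull_surface(corners)
  expect_equal(surface_area(h), 6.0, tolerance = 1e-12)
  expect_true(topology_report(h)$is_closed)
  expect_equal(integrated_curvature(h), 4 * pi, tolerance = 1e-9)

  # regular tetrahedron: 4 faces, chi = 2
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  ht <- convex_hull_surface(tet)
  expect_identical(nrow(ht$triangles), 4L)
  expect_identical(topology_report(ht)$euler_characteristic, 2L)

  # hull of a bumpy sphere point cloud is closed genus 0
  g <- make_gyrified_sphere(10, 0.2, 6, subdivisions = 3)
  hg <- convex_hull_surface(g$surface$vertices)
  expect_equal(integrated_curvature(hg), 4 * pi, tolerance = 1e-9)
  expect_lte(surface_area(hg), surface_area(g$surface))

  # interior points do not change the hull
  withr::local_seed(11)
  inner <- matrix(stats::runif(300, 0.2, 0.8), ncol = 3)
  h2 <- convex_hull_surface(rbind(corners, inner))
  expect_equal(surface_area(h2), 6.0, tolerance = 1e-12)

  expect_error(convex_hull_surface(cbind(stats::runif(10),
                                         stats::runif(10), 0)),
               "coplanar")
})
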