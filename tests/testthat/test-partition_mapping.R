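test_that("transfer_labels picks the nearest pial label, ties to lowest id", {
  pial <- triangulated_surface(rbind(c(0, 0, 30), c(10, 0, 0), c(0, 10, 0)),
                               matrix(c(1, 2, 3), 1))
  plab <- label_field(c(1L, 2L, 5L), surface = pial)
  exposed <- triangulated_surface(rbind(c(1, 0, 29), c(0, 0, 30), c(5, 5, 0)),
                                  matrix(c(1, 2, 3), 1))
  out <- transfer_labels(pial, plab, exposed)
  expect_identical(as.integer(out[1]), 1L)   # nearest is (0,0,30)
  expect_identical(as.integer(out[2]), 1L)   # coincident vertex
  expect_identical(as.integer(out[3]), 2L)   # equidistant from 2 and 5

  # identical meshes: labels transfer idempotently
  s <- make_icosphere(1, 2)
  lab <- octant_labels(s)
  once <- transfer_labels(s, lab, s)
  back <- transfer_labels(s, once, s)
  again <- transfer_labels(s, back, s)
  expect_identical(as.integer(once), as.integer(lab))
  expect_identical(as.integer(again), as.integer(once))

  far <- triangulated_surface(pial$vertices + 1000, pial$triangles)
  expect_error(transfer_labels(pial, plab, far), "disjoint")
})

test_that("face labels use majority vote with lowest-id tie-break", {
  s <- single_triangle()
  expect_identical(face_labels(s, label_field(c(1L, 1L, 2L), surface = s)), 1L)
  expect_identical(face_labels(s, label_field(c(1L, 2L, 3L), surface = s)), 1L)
  expect_identical(face_labels(s, label_field(c(3L, 2L, 1L), surface = s)), 1L)
  expect_identical(face_labels(s, label_field(c(7L, 7L, 7L), surface = s)), 7L)
})

test_that("aggregate_partitions conserves areas and curvature", {
  s <- make_icosphere(1, 3)
  thick <- vertex_field(rep(1, nrow(s$vertices)), s, role = "thickness")
  lab <- octant_labels(s)
  parts <- aggregate_partitions(s, thick, lab, s, lab)
  expect_identical(nrow(parts), 8L)
  expect_equal(sum(parts$A_t), surface_area(s), tolerance = 1e-12)
  expect_equal(sum(parts$A_e), surface_area(s), tolerance = 1e-12)
  expect_equal(sum(parts$I_G), 4 * pi, tolerance = 1e-9)
  expect_equal(parts$I_G, rep(pi / 2, 8), tolerance = 0.1)
  expect_equal(parts$T, rep(1, 8))
  expect_equal(parts$A_t / parts$A_e, rep(1, 8))  # pial == exposed here

  # whole surface under one label equals the whole-mesh quantities
  one <- label_field(rep(0L, nrow(s$vertices)), surface = s)
  whole <- aggregate_partitions(s, thick, one, s, one)
  expect_identical(nrow(whole), 1L)
  expect_equal(whole$A_t, surface_area(s))
  expect_equal(whole$I_G, 4 * pi, tolerance = 1e-9)
})

test_that("gyrified pial inside its hull yields g > 1 per partition", {
  g <- make_gyrified_sphere(10, 0.25, 8, subdivisions = 3)
  pial <- g$surface
  hull <- convex_hull_surface(pial$vertices, name = "hull")
  # two hemispherical labels on the pial surface, transferred to the hull
  lab <- label_field(as.integer(pial$vertices[, 3] < 0), surface = pial)
  hlab <- transfer_labels(pial, lab, hull)
  parts <- aggregate_partitions(pial, g$thickness, lab, hull, hlab)
  expect_equal(sum(parts$I_G), 4 * pi, tolerance = 1e-9)
  expect_true(all(parts$A_t > parts$A_e))
  expect_equal(sum(parts$A_e), surface_area(hull), tolerance = 1e-12)
})

test_that("group_to_lobes sums members and conserves totals", {
  s <- make_icosphere(1, 3)
  thick <- vertex_field(rep(2.5, nrow(s$vertices)), s, role = "thickness")
  lab <- octant_labels(s)
  parts <- aggregate_partitions(s, thick, lab, s, lab)

  # pair the 8 octants into 4 pseudo-lobes
  map <- data.frame(region = sort(unique(parts$partition)),
                    lobe = rep(c("frontal", "parietal", "temporal",
                                 "occipital"), each = 2))
  lobes <- group_to_lobes(parts, map)
  expect_identical(nrow(lobes), 4L)
  expect_equal(lobes$I_G, rep(pi, 4), tolerance = 0.2)
  expect_equal(sum(lobes$A_t), sum(parts$A_t), tolerance = 1e-12)
  expect_equal(sum(lobes$I_G), sum(parts$I_G), tolerance = 1e-12)

  # all regions into one lobe reproduces the whole surface
  map_one <- data.frame(region = map$region, lobe = "frontal")
  one <- group_to_lobes(parts, map_one)
  expect_identical(nrow(one), 1L)
  expect_equal(one$A_t, surface_area(s), tolerance = 1e-12)
  expect_equal(one$T, 2.5)

  # an excluded region is dropped but reported, conserving totals
  map_ex <- map
  map_ex$lobe[1] <- "excluded"
  lex <- group_to_lobes(parts, map_ex)
  extot <- attr(lex, "excluded_totals")
  expect_equal(sum(lex$A_t) + extot[["A_t"]], sum(parts$A_t),
               tolerance = 1e-12)
  expect_equal(sum(lex$I_G) + extot[["I_G"]], sum(parts$I_G),
               tolerance = 1e-12)

  # a partition missing from the map is an error
  expect_error(group_to_lobes(parts, map[-1, , drop = FALSE]),
               "not in lobe map")
  # a mapped lobe whose member regions are all absent is an error naming it
  map_ghost <- rbind(map_one,
                     data.frame(region = "ghost_region", lobe = "occipital"))
  expect_error(group_to_lobes(parts, map_ghost), "occipital")
})

test_that("almost-closed surfaces can renormalise partition curvature to 4*pi", {
  s <- make_icosphere(1, 3)
  holed <- triangulated_surface(s$vertices, s$triangles[-1, , drop = FALSE])
  thick <- vertex_field(rep(2, nrow(s$vertices)), s, role = "thickness")
  lab <- octant_labels(s)
  raw <- aggregate_partitions(holed, thick, lab, holed, lab)
  expect_lt(sum(raw$I_G), 4 * pi)  # boundary vertices zeroed
  expect_equal(attr(raw, "total_deficit"), sum(raw$I_G), tolerance = 1e-12)
  ren <- aggregate_partitions(holed, thick, lab, holed, lab,
                              renormalize_curvature = TRUE)
  expect_equal(sum(ren$I_G), 4 * pi, tolerance = 1e-12)
  expect_equal(ren$I_G / raw$I_G, rep(4 * pi / sum(raw$I_G), 8))
})

test_that("permuting label ids permutes outputs without changing values", {
  s <- make_icosphere(1, 2)
  thick <- vertex_field(rep(2, nrow(s$vertices)), s, role = "thickness")
  lab <- label_field(as.integer(s$vertices[, 3] < 0), surface = s)
  parts <- aggregate_partitions(s, thick, lab, s, lab)
  perm <- label_field(1L - as.integer(lab), surface = s)
  parts_perm <- aggregate_partitions(s, thick, perm, s, perm)
  ord <- order(parts_perm$label_id, decreasing = TRUE)
  expect_equal(parts_perm$A_t[ord], parts$A_t)
  expect_equal(parts_perm$A_e[ord], parts$A_e)
  expect_equal(parts_perm$I_G[ord], parts$I_G)
})
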