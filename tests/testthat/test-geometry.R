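test_that("planar areas: rectangles, holes, multiparts", {
  expect_equal(polygon_area(geom_rect(0, 0, 30, 20), km(), "planar"), 600)
  # square with a square hole
  outer <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  hole <- cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))
  g <- nra_geom(list(list(outer, hole)))
  expect_equal(polygon_area(g, km(), "planar"), 100 - 4)
  # two disjoint parts sum
  g2 <- nra_geom(list(list(outer), list(outer + 20)))
  expect_equal(polygon_area(g2, km(), "planar"), 200)
  expect_equal(polygon_area(nra_geom(), km(), "planar"), 0)
})

test_that("intersection: disjoint, nested, partial overlap", {
  a <- geom_rect(0, 0, 10, 10)
  b <- geom_rect(20, 20, 30, 30)
  expect_equal(polygon_area(geom_intersection(a, b), km(), "planar"), 0)
  inner <- geom_rect(2, 2, 5, 5)
  expect_equal(polygon_area(geom_intersection(inner, a), km(), "planar"), 9)
  ia <- intersection_area(inner, a, km())
  expect_equal(ia$proportion_of_first, 1)
  # 30x20 rectangle overlapping a 50x50 square by a 10x20 strip
  sp <- geom_rect(40, 10, 70, 30)
  foc <- geom_rect(0, 0, 50, 50)
  expect_equal(polygon_area(geom_intersection(sp, foc), km(), "planar"), 200)
  # intersection with a holed polygon respects the hole
  holed <- nra_geom(list(list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                              cbind(c(4, 6, 6, 4), c(4, 4, 6, 6)))))
  probe <- geom_rect(3, 3, 7, 7)
  expect_equal(polygon_area(geom_intersection(holed, probe), km(), "planar"),
               16 - 4)
})

test_that("triangulation conserves area, including concave rings", {
  set.seed(7)
  for (i in 1:10) {
    g <- random_convex_polygon(10)
    soup <- nratool:::as_tris(g)
    expect_equal(nratool:::tris_area_planar(soup),
                 nratool:::geom_area_planar(g), tolerance = 1e-12)
  }
  # L-shaped concave polygon: 3x1 bar plus 1x2 upright = 5
  L <- nra_geom(cbind(c(0, 3, 3, 1, 1, 0), c(0, 0, 1, 1, 3, 3)))
  expect_equal(nratool:::geom_area_planar(L), 5)
  expect_equal(nratool:::tris_area_planar(nratool:::as_tris(L)), 5, tolerance = 1e-12)
})

test_that("area additivity under a split, planar and geodesic", {
  set.seed(11)
  left <- geom_rect(-1000, -1000, 25, 1000)
  right <- geom_rect(25, -1000, 1000, 1000)
  for (i in 1:8) {
    g <- random_convex_polygon(12)
    whole <- polygon_area(g, km(), "planar")
    parts <- polygon_area(geom_intersection(g, left), km(), "planar") +
      polygon_area(geom_intersection(g, right), km(), "planar")
    expect_equal(parts, whole, tolerance = 1e-6)
  }
  # geodesic: degree-scale convex polygons, split at a meridian
  leftg <- geom_rect(-90, -80, 2.5, 80)
  rightg <- geom_rect(2.5, -80, 90, 80)
  for (i in 1:5) {
    g <- random_convex_polygon(10, 0, 0, 5, 5)
    whole <- polygon_area(g, crs_geographic(), "geodesic")
    parts <- polygon_area(geom_intersection(g, leftg), crs_geographic(), "geodesic") +
      polygon_area(geom_intersection(g, rightg), crs_geographic(), "geodesic")
    expect_equal(parts, whole, tolerance = 1e-6)
  }
})

test_that("geodesic area agrees with an equal-area weighted raster oracle", {
  # convex polygon spanning < 10 degrees; oracle weights lon/lat grid cells by
  # the spherical area element R^2 cos(phi) dlon dlat
  set.seed(3)
  R <- 6371.0071809
  for (i in 1:3) {
    g <- random_convex_polygon(9, 10, 30, 18, 38)
    cell <- 0.02
    r <- g$parts[[1]][[1]]
    xs <- seq(min(r[, 1]) + cell / 2, max(r[, 1]), by = cell)
    ys <- seq(min(r[, 2]) + cell / 2, max(r[, 2]), by = cell)
    pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    inside <- mgcv::in.out(rbind(r, r[1, ]), pts)
    oracle <- sum(R^2 * cos(pts[inside, 2] * pi / 180) * (cell * pi / 180)^2)
    expect_equal(polygon_area(g, crs_geographic(), "geodesic"), oracle,
                 tolerance = 5e-3)
  }
})

test_that("self-intersecting rings are rejected with the feature named", {
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(
    nra_layer("species", list(list(id = "bad_sp", geometry = nra_geom(bowtie))),
              km()),
    "bad_sp")
})
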