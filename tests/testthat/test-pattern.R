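occ_world <- function() {
  crs <- km()
  list(
    crs = crs,
    ref = nra_layer("reference", list(list(id = "ref", geometry = geom_rect(0, 0, 100, 100))), crs),
    units = nra_layer("units", list(
      list(id = "A", geometry = geom_rect(0, 0, 100, 50)),
      list(id = "B", geometry = geom_rect(0, 50, 100, 80)),
      list(id = "C", geometry = geom_rect(0, 80, 100, 100))), crs)
  )
}

test_that("occupancy: per-unit areas, sliver exclusion, boundary touching", {
  w <- occ_world()
  cfg <- nra_config()
  # entirely inside unit A
  sp <- nra_layer("species", list(list(id = "s", geometry = geom_rect(10, 10, 30, 30))), w$crs)
  occ <- compute_occupancy(sp, w$units, w$ref, cfg)
  expect_equal(occ$n_units, 1L)
  expect_equal(occ$p_max, 1.0)
  expect_equal(unname(occ$per_unit["A"]), 400)
  # 70/30 split between A and B: y 36..56 with 14 in A (0..50), 6 in B
  sp2 <- nra_layer("species", list(list(id = "s", geometry = geom_rect(0, 36, 50, 56))), w$crs)
  occ2 <- compute_occupancy(sp2, w$units, w$ref, cfg)
  expect_equal(occ2$n_units, 2L)
  expect_equal(occ2$p_max, 0.7, tolerance = 1e-12)
  # touching unit C along the y = 80 line only: C excluded
  sp3 <- nra_layer("species", list(list(id = "s", geometry = geom_rect(0, 60, 50, 80))), w$crs)
  occ3 <- compute_occupancy(sp3, w$units, w$ref, cfg)
  expect_equal(occ3$n_units, 1L)
  expect_equal(sum(occ3$per_unit > cfg$sliver_tolerance * 1e4), 1L)
  # empty within-reference distribution cannot be patterned
  sp4 <- nra_layer("species", list(list(id = "s", geometry = geom_rect(300, 300, 310, 310))), w$crs)
  expect_error(compute_occupancy(sp4, w$units, w$ref, cfg), "cannot be patterned")
})

test_that("count-approach thresholds: 1 local, 2-3 regional, >3 wide", {
  cfg <- nra_config()
  expect_equal(classify_pattern_count(list(n_units = 1L), cfg), "local")
  expect_equal(classify_pattern_count(list(n_units = 2L), cfg), "regional")
  expect_equal(classify_pattern_count(list(n_units = 3L), cfg), "regional")
  expect_equal(classify_pattern_count(list(n_units = 4L), cfg), "wide")
  expect_equal(classify_pattern_count(list(n_units = 5L), cfg), "wide")
  expect_error(classify_pattern_count(list(n_units = 0L), cfg), "at least one")
  # thresholds are configurable
  cfg2 <- nra_config(pc_local_max = 2, pc_regional_max = 5)
  expect_equal(classify_pattern_count(list(n_units = 2L), cfg2), "local")
  expect_equal(classify_pattern_count(list(n_units = 5L), cfg2), "regional")
})

test_that("area-approach shares: single unit local, 2/3 rule inclusive", {
  cfg <- nra_config()
  expect_equal(classify_pattern_area(list(n_units = 1L, p_max = 1.0), cfg), "local")
  expect_equal(classify_pattern_area(list(n_units = 2L, p_max = 0.70), cfg), "regional")
  expect_equal(classify_pattern_area(list(n_units = 3L, p_max = 0.50), cfg), "wide")
  # boundary tie at exactly the regional fraction classifies as regional
  expect_equal(classify_pattern_area(list(n_units = 2L, p_max = 2 / 3), cfg), "regional")
  expect_equal(classify_pattern_area(list(n_units = 2L, p_max = 2 / 3 - 1e-9), cfg), "wide")
})

test_that("area-approach is invariant under uniform rescaling", {
  w <- occ_world()
  cfg <- nra_config("area")
  sp <- nra_layer("species", list(list(id = "s", geometry = geom_rect(0, 36, 50, 56))), w$crs)
  occ1 <- compute_occupancy(sp, w$units, w$ref, cfg)
  for (k in c(0.25, 3, 10)) {
    scale_layer <- function(layer) {
      layer$features <- lapply(layer$features, function(f) {
        f$geometry$parts <- lapply(f$geometry$parts, function(p) lapply(p, function(r) r * k))
        f
      })
      layer
    }
    occk <- compute_occupancy(scale_layer(sp), scale_layer(w$units),
                              scale_layer(w$ref), cfg)
    expect_equal(occk$p_max, occ1$p_max, tolerance = 1e-9)
    expect_equal(occk$n_units, occ1$n_units)
    expect_equal(classify_pattern_area(occk, cfg), classify_pattern_area(occ1, cfg))
  }
})

test_that("shrinking into fewer units never moves the count pattern toward wide", {
  cfg <- nra_config()
  rank <- function(p) match(p, PATTERN_LEVELS)
  for (n in 5:2) {
    wider <- classify_pattern_count(list(n_units = n), cfg)
    narrower <- classify_pattern_count(list(n_units = n - 1L), cfg)
    expect_lte(rank(narrower), rank(wider))
  }
})
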