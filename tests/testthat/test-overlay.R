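test_that("expected and observed proportions: rectangle arithmetic", {
  crs <- km()
  ref <- geom_rect(0, 0, 100, 100)
  expect_equal(dp_expected(geom_rect(10, 10, 40, 30), ref, crs = crs), 0.06)
  expect_equal(dp_expected(ref, ref, crs = crs), 1.0)
  expect_equal(dp_expected(geom_rect(200, 200, 210, 210), ref, crs = crs), 0.0)

  foc <- geom_rect(0, 0, 50, 50)
  expect_equal(dp_observed(geom_rect(40, 10, 70, 30), foc, crs = crs), 0.08)
  expect_equal(dp_observed(geom_rect(200, 0, 230, 20), foc, crs = crs), 0.0)
  expect_equal(dp_observed(geom_rect(-10, -10, 60, 60), foc, crs = crs), 1.0)

  expect_error(dp_expected(foc, nra_geom(), nra_config(), crs = crs), "positive area")
  expect_error(dp_observed(foc, nra_geom(), nra_config(), crs = crs), "positive area")
})

test_that("intersection_area matches the raster counting oracle", {
  crs <- km()
  sp <- geom_rect(40, 10, 70, 30)
  foc <- geom_rect(0, 0, 50, 50)
  got <- intersection_area(sp, foc, crs)$area_intersection
  expect_equal(got, 200)
  expect_equal(got, raster_intersection_area(sp, foc, cell = 0.1), tolerance = 5e-3)
  # symmetric
  expect_equal(intersection_area(foc, sp, crs)$area_intersection, got, tolerance = 1e-12)
})

test_that("tiling conservation: per-country observed mass sums to expected mass", {
  w <- make_toy_world(1)
  cfg <- nra_config("count")
  run <- assess(toy_layerset(w), toy_metadata(w), cfg)
  for (sp in names(w$species)) {
    rec <- run$records[run$records$species_id == sp, ]
    lhs <- sum(rec$dp_obs * rec$area_focal)
    rhs <- rec$dp_exp[1] * rec$area_reference[1]
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("subdivision invariance: splitting inputs leaves proportions unchanged", {
  crs <- km()
  ref <- geom_rect(0, 0, 100, 100)
  whole <- geom_rect(10, 10, 40, 30)
  split2 <- nra_geom(list(list(cbind(c(10, 25, 25, 10), c(10, 10, 30, 30))),
                          list(cbind(c(25, 40, 40, 25), c(10, 10, 30, 30)))))
  expect_equal(dp_expected(split2, ref, crs = crs),
               dp_expected(whole, ref, crs = crs), tolerance = 1e-9)
  foc <- geom_rect(0, 0, 50, 50)
  expect_equal(dp_observed(split2, foc, crs = crs),
               dp_observed(whole, foc, crs = crs), tolerance = 1e-9)
  # splitting the reference into tiles leaves dp_exp unchanged too
  ref_tiles <- nra_geom(list(list(cbind(c(0, 100, 100, 0), c(0, 0, 55, 55))),
                             list(cbind(c(0, 100, 100, 0), c(55, 55, 100, 100)))))
  expect_equal(dp_expected(whole, ref_tiles, crs = crs),
               dp_expected(whole, ref, crs = crs), tolerance = 1e-9)
})

test_that("monotonicity: enlarging the species range never decreases proportions", {
  crs <- km()
  ref <- geom_rect(0, 0, 100, 100)
  foc <- geom_rect(0, 0, 50, 50)
  set.seed(5)
  for (i in 1:10) {
    x0 <- runif(1, 0, 80); y0 <- runif(1, 0, 80)
    w1 <- runif(1, 5, 20); h1 <- runif(1, 5, 20)
    grow <- runif(1, 0, 15)
    small <- geom_rect(x0, y0, x0 + w1, y0 + h1)
    big <- geom_rect(x0, y0, x0 + w1 + grow, y0 + h1 + grow)
    expect_gte(dp_expected(big, ref, crs = crs) - dp_expected(small, ref, crs = crs), -1e-12)
    expect_gte(dp_observed(big, foc, crs = crs) - dp_observed(small, foc, crs = crs), -1e-12)
  }
})
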