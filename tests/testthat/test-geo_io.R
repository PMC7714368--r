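test_that("layer roles follow the filename convention", {
  expect_equal(nratool:::role_from_filename("s-vulpes_vulpes.geojson"), "species")
  expect_equal(nratool:::role_from_filename("f-asian_countries.geojson"), "focal")
  expect_equal(nratool:::role_from_filename("g-biomes.geojson"), "units")
  expect_true(is.na(nratool:::role_from_filename("ranges.geojson")))

  w <- make_toy_world(1)
  d <- withr::local_tempdir()
  write_fixture_files(w, d)
  sp <- read_layer(file.path(d, "s-endemic.geojson"))
  expect_equal(sp$role, "species")
  un <- read_layer(file.path(d, "g-units.geojson"))
  expect_equal(un$role, "units")
  rf <- read_layer(file.path(d, "g-reference.geojson"), role_override = "reference")
  expect_equal(rf$role, "reference")
  # unconventional name requires an override
  file.copy(file.path(d, "s-endemic.geojson"), file.path(d, "ranges.geojson"))
  expect_error(read_layer(file.path(d, "ranges.geojson")), "convention")
  forced <- read_layer(file.path(d, "ranges.geojson"), role_override = "species")
  expect_equal(forced$role, "species")
  expect_error(read_layer(file.path(d, "nope.geojson")), "no such file")
})

test_that("GeoJSON write/read round trip preserves ids, counts and areas", {
  w <- make_toy_world(1)
  d <- withr::local_tempdir()
  for (layer in c(w$species, list(w$units, w$countries))) {
    p <- file.path(d, sprintf("s-%s.geojson", layer$features[[1]]$id))
    write_layer_geojson(layer, p)
    back <- read_layer(p, role_override = layer$role)
    expect_equal(length(back$features), length(layer$features))
    expect_identical(vapply(back$features, `[[`, "", "id"),
                     vapply(layer$features, `[[`, "", "id"))
    expect_identical(back$crs, layer$crs)
    for (i in seq_along(layer$features)) {
      expect_equal(polygon_area(back$features[[i]]$geometry, back$crs),
                   polygon_area(layer$features[[i]]$geometry, layer$crs),
                   tolerance = 1e-9)
    }
  }
})

test_that("polygon_area follows CRS in auto mode and validates inputs", {
  expect_equal(polygon_area(geom_rect(0, 0, 30, 20), km(), "auto"), 600)
  expect_error(polygon_area(geom_rect(0, 0, 1, 1), crs = NULL, mode = "auto"),
               "spatial reference")
  # metre-unit projected CRS converts to km^2
  expect_equal(polygon_area(geom_rect(0, 0, 30e3, 20e3), crs_planar("m"), "auto"), 600)
  # 1-degree equatorial cell: ellipsoidal area within 0.5% of the spherical
  # closed form with authalic radius
  cell <- geo_cell(0, 0)
  a <- polygon_area(cell, crs_geographic(), "auto")
  expect_equal(a, spherical_cell_area(0, 1, 0, 1), tolerance = 5e-3)
})

test_that("dissolve groups by attribute and conserves area", {
  crs <- km()
  mk <- function(id, x0, zone) list(id = id, geometry = geom_rect(x0, 0, x0 + 10, 10),
                                    attributes = list(zone = zone))
  units <- nra_layer("units", list(mk("u1", 0, "A"), mk("u2", 10, "A"),
                                   mk("u3", 20, "B"), mk("u4", 30, "B")), crs)
  dis <- dissolve_by_attribute(units, "zone")
  expect_equal(length(dis$features), 2L)
  expect_setequal(vapply(dis$features, `[[`, "", "id"), c("A", "B"))
  expect_equal(sum(vapply(dis$features, function(f) polygon_area(f$geometry, crs), 0)),
               400, tolerance = 1e-9)
  one <- dissolve_by_attribute(
    nra_layer("units", list(mk("u1", 0, "Z"), mk("u2", 10, "Z")), crs), "zone")
  expect_equal(length(one$features), 1L)
  expect_equal(polygon_area(one$features[[1]]$geometry, crs), 200, tolerance = 1e-9)
  expect_error(dissolve_by_attribute(units, "realm"), "missing")
  # overlapping inputs warn
  ovl <- nra_layer("units", list(mk("u1", 0, "Z"),
                                 list(id = "u2", geometry = geom_rect(5, 0, 15, 10),
                                      attributes = list(zone = "Z"))), crs)
  expect_warning(dissolve_by_attribute(ovl, "zone"), "overlap")
})

test_that("layer-set checks: CRS, focal containment, species clipping", {
  crs <- km()
  ref <- nra_layer("reference", list(list(id = "ref", geometry = geom_rect(0, 0, 100, 100))), crs)
  units <- nra_layer("units", list(list(id = "u1", geometry = geom_rect(0, 0, 100, 100))), crs)
  focal <- nra_layer("focal", list(list(id = "F1", geometry = geom_rect(0, 0, 50, 100)),
                                   list(id = "F2", geometry = geom_rect(50, 0, 100, 100))), crs)
  inside <- nra_layer("species", list(list(id = "in_sp", geometry = geom_rect(10, 10, 30, 30))), crs)
  chk <- check_layerset(nra_layerset(inside, units, focal, ref))
  expect_true(all(chk$focal$contained))
  expect_equal(chk$species$containment_ratio, 1.0)
  expect_length(chk$warnings, 0)

  # species half outside: clipped with a warning under warn_and_clip
  half <- nra_layer("species", list(list(id = "half_sp", geometry = geom_rect(-20, 0, 20, 50))), crs)
  chk2 <- check_layerset(nra_layerset(half, units, focal, ref))
  expect_equal(chk2$species$containment_ratio, 0.5, tolerance = 1e-12)
  expect_match(chk2$warnings, "half_sp", all = FALSE)
  expect_equal(polygon_area(chk2$clipped[["half_sp"]], crs), 1000, tolerance = 1e-9)
  # ... and rejected under the error policy
  expect_error(check_layerset(nra_layerset(half, units, focal, ref),
                              nra_config(containment_policy = "error")),
               "half_sp")

  # focal feature straddling the reference border is reported
  bad_focal <- nra_layer("focal", list(list(id = "F1", geometry = geom_rect(-10, 0, 50, 100))), crs)
  chk3 <- check_layerset(nra_layerset(inside, units, bad_focal, ref))
  expect_false(chk3$focal$contained[1])
  expect_match(chk3$warnings, "not completely enclosed", all = FALSE)

  # CRS mismatch across layers is rejected
  geo_sp <- nra_layer("species", list(list(id = "s", geometry = geom_rect(0, 0, 1, 1))),
                      crs_geographic())
  expect_error(check_layerset(nra_layerset(geo_sp, units, focal, ref)),
               "same coordinate reference")
})

test_that("outputs: maps, tables, truncated dBase fields and ASCII summary", {
  crs <- km()
  w <- make_toy_world(1, n_countries = 2, n_units = 2)
  run <- assess(toy_layerset(w), toy_metadata(w)[1, , drop = FALSE], nra_config("count"))
  rec <- run$records[run$records$species_id == "endemic", ]
  expect_equal(nrow(rec), 2L)  # 1 species x 2 focal areas
  d <- withr::local_tempdir()
  manifest <- write_outputs(rec, w$countries, d, cfg = run$config,
                            warnings = run$warnings)
  expect_true(any(grepl("map-endemic\\.geojson$", manifest)))
  expect_true(any(grepl("records\\.csv$", manifest)))
  expect_true(any(grepl("records\\.dbf$", manifest)))
  expect_true(any(grepl("summary\\.txt$", manifest)))
  expect_true(all(file.exists(manifest)))

  tab <- read_records_csv(file.path(d, "records.csv"))
  expect_equal(nrow(tab), 2L)
  dbf <- foreign::read.dbf(file.path(d, "records.dbf"), as.is = TRUE)
  expect_true(all(nchar(names(dbf)) <= 10))
  expect_equal(nrow(dbf), 2L)

  summ <- readLines(file.path(d, "summary.txt"))
  expect_true(any(grepl("by Biome count", summ)))
  expect_true(any(grepl("area_dist_in_reference", summ)))  # truncation map note
  expect_true(any(grepl("decision-tree mapping", summ)))
  expect_error(write_outputs(rec[0, ], w$countries, d), "non-empty")
})

test_that("dBase field truncation is deterministic and collision-free", {
  nms <- c("area_dist_in_reference", "area_dist_in_focal", "dp_exp", "dp_obs")
  short <- nratool:::dbf_field_names(nms)
  expect_true(all(nchar(short) <= 10))
  expect_false(anyDuplicated(short) > 0)
  expect_identical(short, nratool:::dbf_field_names(nms))
})
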