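# Deterministic synthetic worlds with analytically known truths. The toy
# world is built from axis-aligned rectangles in a planar kilometre CRS so
# that every area, proportion, occupancy and class can be computed by
# closed-form interval arithmetic, independently of the polygon-overlay
# engine. Four species archetypes mirror the classic shrew illustration: an
# endemic confined to one country and one unit, a regionally concentrated
# range spanning two countries, a disjunct two-patch range, and a widespread
# range covering most of the reference area.

overlap1d <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))

rect_overlap_area <- function(r, xmin, ymin, xmax, ymax) {
  overlap1d(r[1L], r[3L], xmin, xmax) * overlap1d(r[2L], r[4L], ymin, ymax)
}

# Threshold rules restated as closed-form truth (kept deliberately separate
# from the classifier implementation).
truth_pattern_count <- function(n_units, local_max = 1L, regional_max = 3L) {
  if (n_units <= local_max) "local" else if (n_units <= regional_max) "regional" else "wide"
}
truth_pattern_area <- function(n_units, p_max, frac = 2 / 3) {
  if (n_units == 1L) "local" else if (p_max >= frac) "regional" else "wide"
}
truth_nr <- function(pattern, higher, present) {
  if (!present) return("none")
  key <- paste(pattern, higher)
  c("wide FALSE" = "basic", "wide TRUE" = "medium",
    "regional FALSE" = "medium", "regional TRUE" = "high",
    "local FALSE" = "high", "local TRUE" = "very_high")[[key]]
}

#' Generate a synthetic toy world
#'
#' Builds a planar-kilometre world: a rectangular reference area tiled exactly
#' by `n_countries` vertical country strips (100 km wide, 100 km tall) and by
#' `n_units` horizontal biogeographical-unit bands carrying a higher-level
#' `zone` attribute, plus four archetype species ranges. All expected truths
#' (areas, distribution proportions, occupancy, patterns and responsibility
#' classes under the default configuration) are computed by closed-form
#' rectangle arithmetic and stored in `$expected`.
#'
#' Default IUCN categories exercise the interesting priority rows:
#' endemic = EN, regional_closed = VU, disjunct = NT, widespread = LC.
#'
#' @param seed integer stored with the world (the default world is fully
#'   deterministic; the seed keys fixture regeneration).
#' @param n_countries number of country strips (>= 2).
#' @param n_units number of unit bands (>= 2).
#' @return an object of class `nra_toyworld` with layers `reference`,
#'   `units`, `countries`, a list of `species` layers, `iucn` categories and
#'   the `expected` truth list.
#' @export
make_toy_world <- function(seed = 1L, n_countries = 4L, n_units = 5L) {
  n_countries <- as.integer(n_countries)
  n_units <- as.integer(n_units)
  if (n_countries < 2L || n_units < 2L)
    stop("the toy world needs at least 2 countries and 2 units")
  crs <- crs_planar("km", "toy-world planar km")
  W <- 100 * n_countries
  H <- 100
  h <- H / n_units

  reference <- nra_layer("reference", list(
    list(id = "world", geometry = geom_rect(0, 0, W, H),
         attributes = list(name = "world"))), crs, quiet = TRUE)
  countries <- nra_layer("focal", lapply(seq_len(n_countries), function(i) {
    list(id = sprintf("C%d", i),
         geometry = geom_rect((i - 1) * 100, 0, i * 100, H),
         attributes = list(name = sprintf("C%d", i)))
  }), crs, quiet = TRUE)
  units <- nra_layer("units", lapply(seq_len(n_units), function(i) {
    list(id = sprintf("U%d", i),
         geometry = geom_rect(0, (i - 1) * h, W, i * h),
         attributes = list(name = sprintf("U%d", i),
                           zone = if (i <= ceiling(n_units / 2)) "S" else "N"))
  }), crs, quiet = TRUE)

  # archetype ranges as rectangles c(xmin, ymin, xmax, ymax)
  sp_rects <- list(
    endemic = list(c(20, 0.1 * h, 50, 0.9 * h)),
    regional_closed = list(c(60, 0.6 * h, 160, 2 * h)),
    disjunct = list(
      c((max(1L, n_countries - 1L) - 1L) * 100 + 20, (n_units - 2L) * h + 0.25 * h,
        (max(1L, n_countries - 1L) - 1L) * 100 + 60, (n_units - 2L) * h + 0.75 * h),
      c((n_countries - 1L) * 100 + 20, (n_units - 1L) * h + 0.25 * h,
        (n_countries - 1L) * 100 + 60, (n_units - 1L) * h + 0.75 * h)),
    widespread = list(c(10, 0.25 * h, W - 10, H - 0.25 * h))
  )
  species <- lapply(names(sp_rects), function(nm) {
    geoms <- lapply(sp_rects[[nm]], function(r) geom_rect(r[1L], r[2L], r[3L], r[4L]))
    nra_layer("species", list(list(id = nm, geometry = geom_combine(geoms),
                                   attributes = list(name = nm))),
              crs, quiet = TRUE)
  })
  names(species) <- names(sp_rects)
  iucn <- c(endemic = "EN", regional_closed = "VU", disjunct = "NT",
            widespread = "LC")

  area_ref <- W * H
  expected <- lapply(names(sp_rects), function(nm) {
    rects <- sp_rects[[nm]]
    area_total <- sum(vapply(rects, function(r) (r[3L] - r[1L]) * (r[4L] - r[2L]), 0))
    per_country <- vapply(seq_len(n_countries), function(i) {
      sum(vapply(rects, rect_overlap_area, 0, (i - 1) * 100, 0, i * 100, H))
    }, 0)
    names(per_country) <- sprintf("C%d", seq_len(n_countries))
    per_unit <- vapply(seq_len(n_units), function(i) {
      sum(vapply(rects, rect_overlap_area, 0, 0, (i - 1) * h, W, i * h))
    }, 0)
    names(per_unit) <- sprintf("U%d", seq_len(n_units))
    n_occ <- sum(per_unit > 0)
    p_max <- max(per_unit) / area_total
    dp_exp <- area_total / area_ref
    dp_obs <- per_country / (100 * H)
    pat_c <- truth_pattern_count(n_occ)
    pat_a <- truth_pattern_area(n_occ, p_max)
    present <- per_country > 0
    higher <- present & (dp_obs > dp_exp)
    nr_c <- mapply(function(p, hi) truth_nr(pat_c, hi, p), present, higher)
    nr_a <- mapply(function(p, hi) truth_nr(pat_a, hi, p), present, higher)
    list(area_total = area_total, area_in_reference = area_total,
         per_country = per_country, per_unit = per_unit,
         n_units = n_occ, p_max = p_max, dp_exp = dp_exp, dp_obs = dp_obs,
         pattern_count = pat_c, pattern_area = pat_a,
         nr_count = nr_c, nr_area = nr_a)
  })
  names(expected) <- names(sp_rects)

  structure(list(reference = reference, units = units, countries = countries,
                 species = species, iucn = iucn, seed = as.integer(seed),
                 crs = crs, n_countries = n_countries, n_units = n_units,
                 expected = expected),
            class = "nra_toyworld")
}

#' @export
print.nra_toyworld <- function(x, ...) {
  cat(sprintf("<nra_toyworld: %d countries x %d units, %d species, seed %d>\n",
              x$n_countries, x$n_units, length(x$species), x$seed))
  invisible(x)
}

#' Layer set of a toy world
#'
#' @param world an `nra_toyworld`.
#' @return an [nra_layerset()] ready for [assess()].
#' @export
toy_layerset <- function(world) {
  nra_layerset(world$species, world$units, world$countries, world$reference)
}

#' Rasterized brute-force area oracle
#'
#' Approximates a polygon area by counting grid-cell centres inside the
#' geometry (point-in-polygon via `mgcv::in.out`, independent of the package's
#' clipping engine). Error is bounded by O(perimeter x cell size).
#'
#' @param geometry an [nra_geom()] (planar coordinates).
#' @param cell_km grid cell size in coordinate units.
#' @return approximate area in squared coordinate units.
#' @export
raster_oracle_area <- function(geometry, cell_km = 0.1) {
  stopifnot(cell_km > 0)
  if (geom_is_empty(geometry)) return(0)
  bb <- geom_bbox(geometry)
  xs <- seq(bb[1L] + cell_km / 2, bb[3L], by = cell_km)
  ys <- seq(bb[2L] + cell_km / 2, bb[4L], by = cell_km)
  if (!length(xs) || !length(ys)) return(0)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- numeric(nrow(pts))
  for (p in geometry$parts) {
    for (i in seq_along(p)) {
      hit <- mgcv::in.out(ring_close(p[[i]]), pts)
      inside <- inside + (if (i == 1L) 1 else -1) * hit
    }
  }
  sum(inside > 0) * cell_km^2
}

#' Write toy-world fixture files
#'
#' Emits the conventionally named GeoJSON layers (`s-*` species ranges,
#' `g-units`, `g-reference`, `f-countries`), a species metadata CSV with IUCN
#' categories, and a semicolon-separated species list file.
#'
#' @param world an `nra_toyworld`.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths (the manifest).
#' @export
write_fixture_files <- function(world, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir))
  }
  manifest <- character(0)
  for (nm in names(world$species)) {
    p <- file.path(out_dir, sprintf("s-%s.geojson", nm))
    write_layer_geojson(world$species[[nm]], p)
    manifest <- c(manifest, p)
  }
  p <- file.path(out_dir, "g-units.geojson")
  write_layer_geojson(world$units, p); manifest <- c(manifest, p)
  p <- file.path(out_dir, "g-reference.geojson")
  write_layer_geojson(world$reference, p); manifest <- c(manifest, p)
  p <- file.path(out_dir, "f-countries.geojson")
  write_layer_geojson(world$countries, p); manifest <- c(manifest, p)
  p <- file.path(out_dir, "metadata.csv")
  utils::write.csv(data.frame(species_id = names(world$iucn),
                              iucn_category = unname(world$iucn),
                              stringsAsFactors = FALSE),
                   p, row.names = FALSE)
  manifest <- c(manifest, p)
  p <- file.path(out_dir, "species-list.txt")
  writeLines(paste(names(world$species), collapse = ";"), p)
  manifest <- c(manifest, p)
  manifest
}
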