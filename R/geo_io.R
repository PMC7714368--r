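# Vector layer I/O and layer-set validation. Geometry interchange is GeoJSON
# (Polygon / MultiPolygon features); attribute tables go out as dBase and CSV
# and the run summary as plain ASCII text. File roles follow the naming
# convention: "s-" species range, "g-" biogeographical units / reference area,
# "f-" focal areas.

#' Geographic coordinate reference (longitude/latitude, WGS84)
#' @return a CRS descriptor list.
#' @export
crs_geographic <- function() {
  list(kind = "geographic", units = "degrees", name = "WGS84 lon/lat")
}

#' Planar (projected) coordinate reference
#' @param units linear unit of the coordinates, `"km"` or `"m"`.
#' @param name free-text identifier; layers with projected CRS are only
#'   considered compatible when the names match.
#' @return a CRS descriptor list.
#' @export
crs_planar <- function(units = c("km", "m"), name = "synthetic planar") {
  list(kind = "projected", units = match.arg(units), name = name)
}

crs_compatible <- function(a, b) {
  if (is.null(a) || is.null(b)) return(FALSE)
  if (!identical(a$kind, b$kind) || !identical(a$units, b$units)) return(FALSE)
  if (identical(a$kind, "geographic")) return(TRUE)
  identical(a$name, b$name)
}

crs_label <- function(crs) {
  if (is.null(crs)) "none" else sprintf("%s (%s, %s)", crs$name, crs$kind, crs$units)
}

#' Construct a polygon layer
#'
#' Geometries are validated on construction: rings are closed/deduplicated and
#' re-oriented (counted as repairs), degenerate rings are dropped, and rings
#' with genuine self-intersections are rejected naming the feature.
#'
#' @param role layer role: `"species"`, `"units"`, `"focal"` or `"reference"`.
#' @param features list of features, each a list with elements `id` (unique
#'   name), `geometry` (an [nra_geom()]) and optional `attributes` (named list).
#' @param crs a CRS descriptor from [crs_geographic()] or [crs_planar()].
#' @param source provenance string; `"synthetic"` for generated layers.
#' @param quiet suppress repair messages.
#' @return an object of class `nra_layer`.
#' @export
nra_layer <- function(role, features, crs, source = "synthetic", quiet = FALSE) {
  role <- match.arg(role, c("species", "units", "focal", "reference"))
  ids <- vapply(features, function(f) as.character(f$id), "")
  if (anyDuplicated(ids)) stop("feature ids must be unique within a layer")
  if (role %in% c("units", "focal") && length(features) < 1L)
    stop(sprintf("%s layer must contain at least one feature", role))
  n_repair <- 0L
  features <- lapply(features, function(f) {
    g <- f$geometry
    if (!inherits(g, "nra_geom")) g <- nra_geom(g)
    for (p in g$parts) {
      for (r in p) {
        if (ring_self_intersects(r))
          stop(sprintf("feature '%s': self-intersecting ring cannot be repaired", f$id))
      }
    }
    raw <- f$geometry
    if (inherits(raw, "nra_geom") && !identical(raw, g)) n_repair <<- n_repair + 1L
    list(id = as.character(f$id), geometry = g,
         attributes = if (is.null(f$attributes)) list() else f$attributes)
  })
  if (n_repair > 0L && !quiet)
    message(sprintf("repaired %d geometr%s on ingestion", n_repair,
                    if (n_repair == 1L) "y" else "ies"))
  structure(list(role = role, features = features, crs = crs, source = source),
            class = "nra_layer")
}

#' @export
print.nra_layer <- function(x, ...) {
  cat(sprintf("<nra_layer role=%s features=%d crs=%s source=%s>\n",
              x$role, length(x$features), crs_label(x$crs), x$source))
  invisible(x)
}

layer_ids <- function(layer) vapply(layer$features, `[[`, "", "id")

# Union-as-collection of all feature geometries of a layer (valid for
# non-overlapping features, which units/focal/reference layers are assumed
# to be; species layers are single-feature by convention).
layer_geometry <- function(layer) {
  geom_combine(lapply(layer$features, `[[`, "geometry"))
}

role_from_filename <- function(path) {
  base <- basename(path)
  if (startsWith(base, "s-")) "species"
  else if (startsWith(base, "g-")) "units"
  else if (startsWith(base, "f-")) "focal"
  else NA_character_
}

# ---- GeoJSON ---------------------------------------------------------------

geojson_crs <- function(crs) {
  if (identical(crs$kind, "geographic")) {
    list(type = "name", properties = list(name = "urn:ogc:def:crs:OGC:1.3:CRS84"))
  } else {
    list(type = "name",
         properties = list(name = sprintf("urn:nra:planar:%s:%s", crs$units, crs$name)))
  }
}

crs_from_geojson <- function(obj) {
  nm <- tryCatch(obj$crs$properties$name, error = function(e) NULL)
  if (is.null(nm)) return(crs_geographic())
  if (grepl("^urn:nra:planar:", nm)) {
    parts <- strsplit(sub("^urn:nra:planar:", "", nm), ":", fixed = TRUE)[[1L]]
    crs_planar(units = parts[1L], name = paste(parts[-1L], collapse = ":"))
  } else {
    crs_geographic()
  }
}

geom_to_geojson <- function(g) {
  polys <- lapply(g$parts, function(p) {
    lapply(p, function(r) {
      rc <- ring_close(r)
      lapply(seq_len(nrow(rc)), function(i) c(rc[i, 1L], rc[i, 2L]))
    })
  })
  if (length(polys) == 1L) {
    list(type = "Polygon", coordinates = polys[[1L]])
  } else {
    list(type = "MultiPolygon", coordinates = polys)
  }
}

geojson_to_geom <- function(geomobj) {
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(as.numeric(pt[[1L]]), as.numeric(pt[[2L]]))))
  }
  tp <- geomobj$type
  if (identical(tp, "Polygon")) {
    nra_geom(list(lapply(geomobj$coordinates, ring_mat)))
  } else if (identical(tp, "MultiPolygon")) {
    nra_geom(lapply(geomobj$coordinates, function(p) lapply(p, ring_mat)))
  } else {
    stop(sprintf("unsupported GeoJSON geometry type '%s'", tp))
  }
}

#' Read a polygon layer from GeoJSON
#'
#' The layer role is inferred from the filename prefix ("s-" species,
#' "g-" units, "f-" focal) unless `role_override` is given; files following
#' neither convention are rejected. A "g-" file is read as biogeographical
#' units; pass `role_override = "reference"` to read it as the reference area.
#'
#' @param path path to a `.geojson`/`.json` FeatureCollection.
#' @param role_override optional explicit role.
#' @param id_field attribute used as feature id (default `"id"`, falling back
#'   to `"name"` then a running index).
#' @param quiet suppress repair messages.
#' @return an [nra_layer()].
#' @export
read_layer <- function(path, role_override = NULL, id_field = "id", quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  role <- if (!is.null(role_override)) {
    match.arg(role_override, c("species", "units", "focal", "reference"))
  } else {
    r <- role_from_filename(path)
    if (is.na(r))
      stop(sprintf(paste0("'%s' does not follow the s-/g-/f- naming convention; ",
                          "files not named according to these conventions are not ",
                          "selectable (pass role_override to force a role)"),
                   basename(path)))
    r
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection"))
    stop(sprintf("'%s' is not a GeoJSON FeatureCollection", path))
  crs <- crs_from_geojson(obj)
  feats <- lapply(seq_along(obj$features), function(i) {
    f <- obj$features[[i]]
    props <- if (is.null(f$properties)) list() else f$properties
    id <- props[[id_field]]
    if (is.null(id)) id <- props[["name"]]
    if (is.null(id)) id <- f$id
    if (is.null(id)) id <- as.character(i)
    list(id = as.character(id), geometry = geojson_to_geom(f$geometry),
         attributes = props)
  })
  nra_layer(role, feats, crs, source = path, quiet = quiet)
}

#' Write a polygon layer to GeoJSON
#'
#' @param layer an [nra_layer()].
#' @param path output path.
#' @param extra_attributes optional data.frame keyed by column `feature_id`,
#'   merged into feature properties.
#' @return `path`, invisibly.
#' @export
write_layer_geojson <- function(layer, path, extra_attributes = NULL) {
  feats <- lapply(layer$features, function(f) {
    props <- f$attributes
    props$id <- f$id
    if (!is.null(extra_attributes)) {
      row <- extra_attributes[extra_attributes$feature_id == f$id, , drop = FALSE]
      if (nrow(row) == 1L) {
        for (nm in setdiff(names(row), "feature_id")) props[[nm]] <- row[[nm]][1L]
      }
    }
    list(type = "Feature", properties = props, geometry = geom_to_geojson(f$geometry))
  })
  obj <- list(type = "FeatureCollection", crs = geojson_crs(layer$crs), features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

# ---- areas -----------------------------------------------------------------

planar_to_km2 <- function(area, units) {
  switch(units, km = area, m = area / 1e6,
         stop(sprintf("unsupported planar unit '%s'", units)))
}

#' Polygon area in square kilometres
#'
#' In `"auto"` mode the algorithm follows the CRS: geodesic (ellipsoidal,
#' WGS84) area for geographic coordinates, planar shoelace area for projected
#' coordinates. Multi-part areas are sums of parts; holes subtract.
#'
#' @param geometry an [nra_geom()] or an intersection piece soup from
#'   [geom_intersection()].
#' @param crs CRS descriptor; required in `"auto"` mode.
#' @param mode `"auto"`, `"planar"` or `"geodesic"`.
#' @return area in km^2 (>= 0 for valid input).
#' @export
polygon_area <- function(geometry, crs = NULL, mode = c("auto", "planar", "geodesic")) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    if (is.null(crs)) stop("geodata should have a spatial reference: crs is required in auto mode")
    mode <- if (identical(crs$kind, "geographic")) "geodesic" else "planar"
  }
  if (mode == "geodesic") {
    geom_area_geodesic(geometry)
  } else {
    units <- if (!is.null(crs)) crs$units else "km"
    planar_to_km2(geom_area_planar(geometry), units)
  }
}

#' Dissolve a layer by an attribute
#'
#' Aggregates all features sharing a value of `field` into one multi-part
#' feature per distinct value. Inputs are assumed non-overlapping (as
#' biogeographical-unit partitions are); overlaps above the sliver tolerance
#' trigger a warning, and total area is conserved for non-overlapping inputs.
#'
#' @param units an [nra_layer()].
#' @param field attribute name present on every feature.
#' @param role role of the output layer (default `"reference"`).
#' @param sliver_tolerance overlap-warning threshold as a fraction of total
#'   layer area.
#' @return an [nra_layer()] with one feature per distinct attribute value.
#' @export
dissolve_by_attribute <- function(units, field, role = "reference",
                                  sliver_tolerance = 1e-9) {
  vals <- lapply(units$features, function(f) f$attributes[[field]])
  if (any(vapply(vals, is.null, TRUE)))
    stop(sprintf("attribute '%s' is missing on some features", field))
  vals <- vapply(vals, as.character, "")
  total <- sum(vapply(units$features, function(f) geom_area_planar(f$geometry), 0))
  tol <- sliver_tolerance * max(total, .Machine$double.eps)
  n <- length(units$features)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ov <- geom_area_planar(geom_intersection(units$features[[i]]$geometry,
                                                 units$features[[j]]$geometry))
        if (ov > tol)
          warning(sprintf("features '%s' and '%s' overlap (%.6g sq units); dissolve counts the overlap toward both",
                          units$features[[i]]$id, units$features[[j]]$id, ov))
      }
    }
  }
  groups <- split(seq_len(n), vals)
  feats <- lapply(names(groups), function(v) {
    list(id = v,
         geometry = geom_combine(lapply(units$features[groups[[v]]], `[[`, "geometry")),
         attributes = stats::setNames(list(v), field))
  })
  nra_layer(role, feats, units$crs, source = units$source, quiet = TRUE)
}

# ---- layer sets ------------------------------------------------------------

#' Bundle the four assessment layers
#'
#' @param species list of species [nra_layer()]s (one range per layer).
#' @param units biogeographical-unit layer.
#' @param focal focal-area layer (one polygon per administrative unit).
#' @param reference reference-area layer.
#' @return an object of class `nra_layerset`.
#' @export
nra_layerset <- function(species, units, focal, reference) {
  if (inherits(species, "nra_layer")) species <- list(species)
  stopifnot(inherits(units, "nra_layer"), inherits(focal, "nra_layer"),
            inherits(reference, "nra_layer"))
  structure(list(species = species, units = units, focal = focal,
                 reference = reference), class = "nra_layerset")
}

#' Validate a layer set against a configuration
#'
#' Checks that all layers share a compatible CRS, that every focal feature is
#' contained in the reference area (up to sliver tolerance), and computes each
#' species' containment ratio (share of its total range inside the reference
#' area). Under the `"warn_and_clip"` policy, partially contained species are
#' clipped to the reference with a logged warning; under `"error"` they are
#' rejected.
#'
#' @param ls an [nra_layerset()].
#' @param cfg an [nra_config()].
#' @return a list of class `nra_check` with elements `crs_ok`, `area_mode`,
#'   `area_reference`, `focal` (containment data.frame), `species`
#'   (containment-ratio data.frame), `clipped` (named list of clipped species
#'   geometries) and `warnings`.
#' @export
check_layerset <- function(ls, cfg = nra_config()) {
  cfg <- validate_config(cfg)
  crs0 <- ls$reference$crs
  all_layers <- c(ls$species, list(ls$units, ls$focal, ls$reference))
  for (ly in all_layers) {
    if (!crs_compatible(crs0, ly$crs))
      stop(sprintf(paste0("all input layers should use the same coordinate reference ",
                          "system: reference is %s but a %s layer is %s"),
                   crs_label(crs0), ly$role, crs_label(ly$crs)))
  }
  mode <- cfg$area_mode
  warnings <- character(0)
  ref_geom <- layer_geometry(ls$reference)
  area_ref <- polygon_area(ref_geom, crs0, mode)
  if (area_ref <= 0) stop("reference area must have positive area")
  tol_area <- cfg$sliver_tolerance * area_ref

  focal_df <- do.call(rbind, lapply(ls$focal$features, function(f) {
    a_f <- polygon_area(f$geometry, crs0, mode)
    a_in <- polygon_area(geom_intersection(f$geometry, ref_geom), crs0, mode)
    contained <- (a_f - a_in) <= max(tol_area, 1e-9 * a_f)
    data.frame(focal_id = f$id, area_focal = a_f, area_in_reference = a_in,
               contained = contained, stringsAsFactors = FALSE)
  }))
  for (k in which(!focal_df$contained)) {
    warnings <- c(warnings, sprintf(
      "focal feature '%s' is not completely enclosed by the reference area (%.6g of %.6g km2 inside)",
      focal_df$focal_id[k], focal_df$area_in_reference[k], focal_df$area_focal[k]))
  }

  clipped <- list()
  sp_rows <- list()
  for (sl in ls$species) {
    for (f in sl$features) {
      a_tot <- polygon_area(f$geometry, crs0, mode)
      clip <- geom_intersection(f$geometry, ref_geom)
      a_in <- polygon_area(clip, crs0, mode)
      ratio <- if (a_tot > 0) min(1, max(0, a_in / a_tot)) else 0
      if (a_tot - a_in > max(tol_area, 1e-9 * max(a_tot, 1))) {
        if (cfg$containment_policy == "error")
          stop(sprintf("species '%s' is not fully contained in the reference area (ratio %.4f)",
                       f$id, ratio))
        warnings <- c(warnings, sprintf(
          "species '%s' not fully contained in the reference area (ratio %.4f); clipped to the reference",
          f$id, ratio))
      }
      clipped[[f$id]] <- clip
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        species_id = f$id, area_total = a_tot, area_in_reference = a_in,
        containment_ratio = ratio, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    crs_ok = TRUE, area_mode = mode, area_reference = area_ref,
    focal = focal_df,
    species = if (length(sp_rows)) do.call(rbind, sp_rows) else
      data.frame(species_id = character(0), area_total = numeric(0),
                 area_in_reference = numeric(0), containment_ratio = numeric(0)),
    clipped = clipped, warnings = warnings
  ), class = "nra_check")
}

# ---- outputs ---------------------------------------------------------------

# Deterministic truncation of field names to the 10-character dBase III limit;
# collisions get a numeric suffix in input order.
dbf_field_names <- function(nms) {
  out <- substr(nms, 1L, 10L)
  seen <- character(0)
  for (i in seq_along(out)) {
    cand <- out[i]
    k <- 1L
    while (cand %in% seen) {
      suff <- as.character(k)
      cand <- paste0(substr(out[i], 1L, 10L - nchar(suff)), suff)
      k <- k + 1L
    }
    out[i] <- cand
    seen <- c(seen, cand)
  }
  out
}

#' Write assessment outputs
#'
#' Produces (a) per-species map layers in GeoJSON whose focal-area features
#' carry `dp_exp`, `dp_obs`, `pattern`, `nr`, `cp_class` and `score`
#' attributes, (b) a flat attribute table as dBase (`.dbf`, field names
#' truncated deterministically to 10 characters) and CSV, and (c) an ASCII
#' summary listing the configuration, thresholds, decision-tree mapping,
#' field-name truncation map, warnings, and per-species per-country classes.
#'
#' @param records data.frame of assessment records (from [assess()]).
#' @param focal the focal [nra_layer()].
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("geojson", "dbf", "csv", "summary")`.
#' @param cfg the [nra_config()] used for the run (printed in the summary).
#' @param warnings character vector of run warnings mirrored into the summary.
#' @return character vector of written file paths (the manifest).
#' @export
write_outputs <- function(records, focal, out_dir,
                          formats = c("geojson", "dbf", "csv", "summary"),
                          cfg = nra_config(), warnings = character(0)) {
  if (!nrow(records)) stop("records must be non-empty")
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  manifest <- character(0)
  name_map <- NULL

  if ("geojson" %in% formats) {
    for (sp in unique(records$species_id)) {
      sub <- records[records$species_id == sp, , drop = FALSE]
      extra <- data.frame(feature_id = sub$focal_id, dp_exp = sub$dp_exp,
                          dp_obs = sub$dp_obs, pattern = sub$pattern,
                          nr = sub$nr, cp_class = sub$cp_class,
                          score = sub$score, stringsAsFactors = FALSE)
      p <- file.path(out_dir, sprintf("map-%s.geojson", sp))
      write_layer_geojson(focal, p, extra_attributes = extra)
      manifest <- c(manifest, p)
    }
  }
  if ("csv" %in% formats) {
    p <- file.path(out_dir, "records.csv")
    write_records_csv(records, p)
    manifest <- c(manifest, p)
  }
  if ("dbf" %in% formats) {
    short <- dbf_field_names(names(records))
    name_map <- data.frame(field = names(records), dbf_field = short,
                           stringsAsFactors = FALSE)
    df <- records
    names(df) <- short
    for (nm in names(df)) if (is.logical(df[[nm]])) df[[nm]] <- as.integer(df[[nm]])
    p <- file.path(out_dir, "records.dbf")
    foreign::write.dbf(df, p)
    manifest <- c(manifest, p)
  }
  if ("summary" %in% formats) {
    p <- file.path(out_dir, "summary.txt")
    lines <- c(
      "National responsibility and conservation priority assessment",
      "============================================================",
      "",
      sprintf("approach: %s", approach_label(cfg$approach)),
      sprintf("PC-A thresholds: n_units <= %d local; %d < n_units <= %d regional; else wide",
              cfg$pc_local_max, cfg$pc_local_max, cfg$pc_regional_max),
      sprintf("PA-A regional cutoff: p_max >= %.6f (inclusive)", cfg$pa_regional_fraction),
      sprintf("comparison: %s",
              if (cfg$strict_comparison) "strict (DP_obs > DP_exp)" else "non-strict (DP_obs >= DP_exp)"),
      sprintf("area mode: %s", cfg$area_mode),
      sprintf("sliver tolerance: %g of reference area", cfg$sliver_tolerance),
      "",
      "decision-tree mapping (pattern, higher-than-expected -> responsibility):",
      sprintf("  %-8s %-5s -> %s", cfg$nr_mapping$pattern,
              ifelse(cfg$nr_mapping$higher, "yes", "no"), cfg$nr_mapping$nr),
      ""
    )
    if (!is.null(name_map)) {
      lines <- c(lines, "dBase field-name truncation map:",
                 sprintf("  %-24s -> %s", name_map$field, name_map$dbf_field), "")
    }
    if (length(warnings)) {
      lines <- c(lines, "warnings:", paste0("  - ", warnings), "")
    }
    lines <- c(lines, "per-species per-focal-area classes:",
               sprintf("  %-20s %-16s dp_exp=%-12.6g dp_obs=%-12.6g pattern=%-8s nr=%-9s cp=%s score=%s",
                       records$species_id, records$focal_id, records$dp_exp,
                       records$dp_obs, records$pattern, records$nr,
                       ifelse(is.na(records$cp_class), "-", records$cp_class),
                       ifelse(is.na(records$score), "-", records$score)))
    writeLines(lines, p)
    manifest <- c(manifest, p)
  }
  manifest
}
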