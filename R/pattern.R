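# Distribution-pattern classification. A species' within-reference range is
# overlaid on the biogeographical units; the pattern (local / regional / wide)
# follows either the count of occupied units (PC-A) or the largest per-unit
# area share (PA-A).

#' Per-unit occupancy of a species range
#'
#' Intersects the species' within-reference distribution with every
#' biogeographical unit. Units overlapped by no more than the sliver tolerance
#' (a fraction of the reference area) are excluded from the occupied count.
#'
#' @param species species range: [nra_layer()], [nra_geom()] or a clipped
#'   piece soup.
#' @param units biogeographical-unit [nra_layer()].
#' @param reference reference-area layer or geometry; the species range is
#'   clipped to it before overlay.
#' @param cfg an [nra_config()].
#' @return a list of class `nra_occupancy`: `per_unit` (named vector of
#'   overlap areas, km^2), `total` (within-reference range area), `n_units`
#'   (occupied-unit count) and `p_max` (largest per-unit share).
#' @export
compute_occupancy <- function(species, units, reference, cfg = nra_config()) {
  cfg <- validate_config(cfg)
  crs <- units$crs
  if (inherits(species, "nra_layer") && !crs_compatible(species$crs, crs))
    stop("compute_occupancy: species and units layers have incompatible CRS")
  gr <- as_geom_input(reference)
  a_ref <- polygon_area(gr, crs, cfg$area_mode)
  clipped <- geom_intersection(as_geom_input(species), gr)
  total <- polygon_area(clipped, crs, cfg$area_mode)
  tol <- cfg$sliver_tolerance * a_ref
  if (total <= tol)
    stop("species has an empty within-reference distribution and cannot be patterned")
  per_unit <- vapply(units$features, function(u) {
    polygon_area(geom_intersection(clipped, u$geometry), crs, cfg$area_mode)
  }, 0)
  names(per_unit) <- layer_ids(units)
  occupied <- per_unit > tol
  structure(list(
    per_unit = per_unit,
    total = total,
    n_units = sum(occupied),
    p_max = if (any(occupied)) max(per_unit[occupied]) / total else 0
  ), class = "nra_occupancy")
}

#' Pattern by the Polygon Count-Approach
#'
#' Classifies from the number of occupied biogeographical units: at most
#' `pc_local_max` units is `local`, at most `pc_regional_max` is `regional`,
#' more is `wide`.
#'
#' @param occ an `nra_occupancy` from [compute_occupancy()] (or a list with an
#'   `n_units` element).
#' @param cfg an [nra_config()].
#' @return one of `"local"`, `"regional"`, `"wide"`.
#' @export
classify_pattern_count <- function(occ, cfg = nra_config()) {
  cfg <- validate_config(cfg)
  n <- occ$n_units
  if (is.null(n) || n < 1L) stop("occupancy must cover at least one unit")
  if (n <= cfg$pc_local_max) "local"
  else if (n <= cfg$pc_regional_max) "regional"
  else "wide"
}

#' Pattern by the Polygon Area-Approach
#'
#' Classifies from per-unit area shares of the within-reference range: a
#' single occupied unit is `local`; otherwise the range is `regional` when the
#' largest per-unit share reaches `pa_regional_fraction` (default two-thirds,
#' inclusive at the boundary) and `wide` otherwise.
#'
#' @param occ an `nra_occupancy` from [compute_occupancy()] (or a list with
#'   `n_units` and `p_max` elements).
#' @param cfg an [nra_config()].
#' @return one of `"local"`, `"regional"`, `"wide"`.
#' @export
classify_pattern_area <- function(occ, cfg = nra_config()) {
  cfg <- validate_config(cfg)
  n <- occ$n_units
  if (is.null(n) || n < 1L) stop("occupancy must cover at least one unit")
  if (n == 1L) "local"
  else if (occ$p_max >= cfg$pa_regional_fraction) "regional"
  else "wide"
}

classify_pattern <- function(occ, cfg) {
  if (cfg$approach == "count") classify_pattern_count(occ, cfg)
  else classify_pattern_area(occ, cfg)
}
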