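# Intersection areas and the expected / observed distribution proportions.
# The expected proportion relates a species' within-reference range to the
# reference area; the observed proportion relates its within-focal range to
# the focal area. A focal area holding a larger observed than expected
# proportion is over-represented for that species.

as_geom_input <- function(x) {
  if (inherits(x, "nra_layer")) layer_geometry(x) else x
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Intersection area of two polygon sets
#'
#' @param a,b [nra_geom()] objects, intersection soups or [nra_layer()]s
#'   (a layer contributes all its features).
#' @param crs shared CRS descriptor (required in `"auto"` mode).
#' @param mode area mode passed to [polygon_area()].
#' @return a list with `area_intersection` (km^2), `proportion_of_first` and
#'   `proportion_of_second` (each clamped to \[0, 1\]).
#' @export
intersection_area <- function(a, b, crs = NULL, mode = c("auto", "planar", "geodesic")) {
  mode <- match.arg(mode)
  if (inherits(a, "nra_layer") && inherits(b, "nra_layer") &&
      !crs_compatible(a$crs, b$crs))
    stop("intersection_area: layers have incompatible CRS")
  if (is.null(crs) && inherits(a, "nra_layer")) crs <- a$crs
  ga <- as_geom_input(a); gb <- as_geom_input(b)
  ai <- polygon_area(geom_intersection(ga, gb), crs, mode)
  aa <- polygon_area(ga, crs, mode)
  ab <- polygon_area(gb, crs, mode)
  list(area_intersection = ai,
       proportion_of_first = if (aa > 0) clamp01(ai / aa) else 0,
       proportion_of_second = if (ab > 0) clamp01(ai / ab) else 0)
}

#' Expected distribution proportion
#'
#' The ratio of a species' distribution area inside the reference area to the
#' total reference area. Under proportional expectation, a focal area covering
#' x% of the reference would be expected to hold this share of the species'
#' range if the species were distributed evenly.
#'
#' @param species species range: [nra_layer()], [nra_geom()] or piece soup.
#' @param reference reference area layer or geometry.
#' @param cfg an [nra_config()] (supplies the area mode).
#' @param crs CRS descriptor when geometries (not layers) are passed.
#' @return a proportion in \[0, 1\].
#' @export
dp_expected <- function(species, reference, cfg = nra_config(), crs = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(crs)) {
    crs <- if (inherits(reference, "nra_layer")) reference$crs
           else if (inherits(species, "nra_layer")) species$crs
  }
  gs <- as_geom_input(species); gr <- as_geom_input(reference)
  a_ref <- polygon_area(gr, crs, cfg$area_mode)
  if (a_ref <= 0) stop("reference area must have positive area")
  a_int <- polygon_area(geom_intersection(gs, gr), crs, cfg$area_mode)
  clamp01(a_int / a_ref)
}

#' Observed distribution proportion
#'
#' The ratio of a species' distribution area inside one focal area to the
#' total area of that focal area.
#'
#' @param species species range: [nra_layer()], [nra_geom()] or piece soup.
#' @param focal_feature focal-area geometry (or single-feature layer).
#' @param cfg an [nra_config()].
#' @param crs CRS descriptor when geometries (not layers) are passed.
#' @return a proportion in \[0, 1\].
#' @export
dp_observed <- function(species, focal_feature, cfg = nra_config(), crs = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(crs)) {
    crs <- if (inherits(focal_feature, "nra_layer")) focal_feature$crs
           else if (inherits(species, "nra_layer")) species$crs
  }
  gs <- as_geom_input(species); gf <- as_geom_input(focal_feature)
  a_f <- polygon_area(gf, crs, cfg$area_mode)
  if (a_f <= 0) stop("focal feature must have positive area")
  a_int <- polygon_area(geom_intersection(gs, gf), crs, cfg$area_mode)
  clamp01(a_int / a_f)
}
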