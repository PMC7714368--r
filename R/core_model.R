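# Domain vocabulary shared by every stage: IUCN Red List categories,
# distribution patterns, national-responsibility classes and the run
# configuration.

#' IUCN Red List category codes, most to least threatened
#' @export
IUCN_CODES <- c("EW", "CR", "EN", "VU", "NT", "LC", "DD", "NE")

IUCN_NAMES <- c(
  EW = "Extinct in the Wild",
  CR = "Critically Endangered",
  EN = "Endangered",
  VU = "Vulnerable",
  NT = "Near Threatened",
  LC = "Least Concern",
  DD = "Data Deficient",
  NE = "Not Evaluated"
)

#' Distribution pattern levels, narrowest to widest
#' @export
PATTERN_LEVELS <- c("local", "regional", "wide")

#' National-responsibility classes, lowest to highest
#'
#' `"none"` is reserved for species absent from the focal area.
#' @export
NR_LEVELS <- c("none", "basic", "medium", "high", "very_high")

#' Parse an IUCN Red List category
#'
#' Accepts two-letter codes ("EN") or full category names ("Endangered"),
#' case-insensitively. `DD` and `NE` are valid categories but are flagged as
#' not evaluable for conservation-priority scoring.
#'
#' @param text a single character string.
#' @return the canonical two-letter code, with attribute `evaluable`.
#' @examples
#' parse_iucn_category("Endangered")  # "EN"
#' parse_iucn_category("lc")          # "LC"
#' @export
parse_iucn_category <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("IUCN category must be a non-empty string")
  key <- toupper(trimws(text))
  code <- if (key %in% IUCN_CODES) {
    key
  } else {
    hit <- match(key, toupper(IUCN_NAMES))
    if (is.na(hit)) stop(sprintf("unrecognized IUCN category: '%s'", text))
    IUCN_CODES[hit]
  }
  structure(code, evaluable = iucn_evaluable(code))
}

#' Is an IUCN category evaluable for priority scoring?
#'
#' @param code two-letter IUCN code(s).
#' @return logical; `FALSE` for `DD` and `NE`.
#' @export
iucn_evaluable <- function(code) !(code %in% c("DD", "NE"))

#' Default national-responsibility mapping table
#'
#' The decision tree combines the distribution pattern with whether the
#' observed distribution proportion exceeds the expected one. The default is
#' the unique monotone mapping onto the four responsibility classes: a local
#' species over-represented in a country carries the strongest signal
#' (very high), a widespread species not over-represented the weakest (basic).
#'
#' @return a data.frame with columns `pattern`, `higher`, `nr` (6 rows).
#' @export
default_nr_mapping <- function() {
  data.frame(
    pattern = rep(PATTERN_LEVELS, each = 2L),
    higher  = rep(c(FALSE, TRUE), 3L),
    nr      = c("high", "very_high", "medium", "high", "basic", "medium"),
    stringsAsFactors = FALSE
  )
}

validate_nr_mapping <- function(map) {
  need <- c("pattern", "higher", "nr")
  if (!is.data.frame(map) || !all(need %in% names(map)) || nrow(map) != 6L)
    stop("nr_mapping must be a 6-row data.frame with columns pattern, higher, nr")
  if (!setequal(paste(map$pattern, map$higher), paste(rep(PATTERN_LEVELS, each = 2L), rep(c(FALSE, TRUE), 3L))))
    stop("nr_mapping must cover all 3 patterns x 2 comparison outcomes exactly once")
  if (!all(map$nr %in% setdiff(NR_LEVELS, "none")))
    stop("nr_mapping classes must be basic/medium/high/very_high")
  rk <- function(p, h) match(map$nr[map$pattern == p & map$higher == h], NR_LEVELS)
  for (p in PATTERN_LEVELS) {
    if (rk(p, TRUE) < rk(p, FALSE))
      stop("nr_mapping not monotone: 'higher than expected' must not lower the class")
  }
  for (h in c(FALSE, TRUE)) {
    r <- vapply(PATTERN_LEVELS, rk, 0L, h = h)
    if (any(diff(r) > 0))
      stop("nr_mapping not monotone: class must not increase from local to wide")
  }
  map
}

#' Assessment configuration
#'
#' @param approach `"count"` for the Polygon Count-Approach (PC-A, pattern from
#'   the number of occupied biogeographical units) or `"area"` for the Polygon
#'   Area-Approach (PA-A, pattern from per-unit area proportions).
#' @param pc_local_max PC-A: at most this many occupied units is `local`
#'   (default 1).
#' @param pc_regional_max PC-A: up to this many occupied units is `regional`;
#'   more is `wide` (default 3).
#' @param pa_regional_fraction PA-A: a species with at least this fraction of
#'   its within-reference range in a single unit is `regional` (default 2/3,
#'   inclusive at the boundary).
#' @param strict_comparison if `TRUE` (default) the observed proportion must
#'   strictly exceed the expected one to count as over-represented; ties
#'   resolve to the lower responsibility outcome.
#' @param area_mode `"auto"` (geodesic for geographic CRS, planar for projected
#'   CRS), `"planar"` or `"geodesic"`.
#' @param containment_policy what to do with species ranges not fully inside
#'   the reference area: `"warn_and_clip"` (default) or `"error"`.
#' @param sliver_tolerance overlaps below this fraction of the reference area
#'   are treated as absent (default 1e-9).
#' @param nr_mapping the 3 x 2 decision-tree mapping; see
#'   [default_nr_mapping()]. Validated for monotonicity.
#' @return an object of class `nra_config`.
#' @export
nra_config <- function(approach = c("count", "area"),
                       pc_local_max = 1L,
                       pc_regional_max = 3L,
                       pa_regional_fraction = 2 / 3,
                       strict_comparison = TRUE,
                       area_mode = c("auto", "planar", "geodesic"),
                       containment_policy = c("warn_and_clip", "error"),
                       sliver_tolerance = 1e-9,
                       nr_mapping = default_nr_mapping()) {
  cfg <- structure(list(
    approach = match.arg(approach),
    pc_local_max = as.integer(pc_local_max),
    pc_regional_max = as.integer(pc_regional_max),
    pa_regional_fraction = pa_regional_fraction,
    strict_comparison = isTRUE(strict_comparison),
    area_mode = match.arg(area_mode),
    containment_policy = match.arg(containment_policy),
    sliver_tolerance = sliver_tolerance,
    nr_mapping = nr_mapping
  ), class = "nra_config")
  validate_config(cfg)
}

#' Validate an assessment configuration
#'
#' @param cfg an `nra_config` (or a bare list of the same fields).
#' @return the validated configuration, defaults filled.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "nra_config")) {
    if (!is.list(cfg)) stop("cfg must be an nra_config or a list")
    return(do.call(nra_config, cfg))
  }
  if (!cfg$approach %in% c("count", "area")) stop("approach must be 'count' or 'area'")
  if (cfg$pc_local_max < 1L) stop("pc_local_max must be >= 1")
  if (cfg$pc_regional_max < cfg$pc_local_max)
    stop("pc_regional_max must be >= pc_local_max")
  if (!is.numeric(cfg$pa_regional_fraction) ||
      cfg$pa_regional_fraction <= 0 || cfg$pa_regional_fraction > 1)
    stop("pa_regional_fraction must be in (0, 1]")
  if (!is.numeric(cfg$sliver_tolerance) || cfg$sliver_tolerance < 0 ||
      cfg$sliver_tolerance >= 1)
    stop("sliver_tolerance must be a small non-negative fraction")
  cfg$nr_mapping <- validate_nr_mapping(cfg$nr_mapping)
  cfg
}

approach_label <- function(approach) {
  switch(approach,
         count = "PC-A ('by Biome count')",
         area  = "PA-A ('by biome-area')")
}

#' @export
print.nra_config <- function(x, ...) {
  cat("National responsibility assessment configuration\n")
  cat("  approach:            ", approach_label(x$approach), "\n", sep = "")
  cat("  PC-A thresholds:      n_units <= ", x$pc_local_max, " local; <= ",
      x$pc_regional_max, " regional; else wide\n", sep = "")
  cat("  PA-A regional cutoff: p_max >= ", format(x$pa_regional_fraction),
      " (inclusive)\n", sep = "")
  cat("  comparison:          ", if (x$strict_comparison) "strict (DP_obs > DP_exp)"
      else "non-strict (DP_obs >= DP_exp)", "\n", sep = "")
  cat("  area mode:           ", x$area_mode, "\n", sep = "")
  cat("  containment policy:  ", x$containment_policy, "\n", sep = "")
  cat("  sliver tolerance:    ", format(x$sliver_tolerance), " of reference area\n", sep = "")
  invisible(x)
}

# ---- record tables ---------------------------------------------------------

record_columns <- c(
  "species_id", "focal_id", "area_reference", "area_focal",
  "area_dist_in_reference", "area_dist_in_focal", "dp_exp", "dp_obs",
  "n_units", "p_max", "pattern", "nr", "cp_class", "score", "evaluable",
  "containment_ratio"
)

#' Write an assessment record table to CSV at full precision
#'
#' Numeric columns are serialized with 17 significant digits so that re-reading
#' reproduces areas and proportions to at least 12 significant digits.
#'
#' @param records data.frame of per-(species, focal area) records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  out <- records
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an assessment record table written by [write_records_csv()]
#'
#' @param path CSV file path.
#' @return a data.frame of records.
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c("area_reference", "area_focal", "area_dist_in_reference",
                         "area_dist_in_focal", "dp_exp", "dp_obs", "p_max",
                         "containment_ratio"), names(df))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}
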