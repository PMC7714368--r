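# Orchestration: run the full assessment over every (species, focal area)
# pair, tally per-country class counts, and compare the two
# pattern-classification approaches.

#' Run a national-responsibility assessment
#'
#' For every species: the range is clipped to the reference area, its per-unit
#' occupancy and distribution pattern are computed once, and then for every
#' focal feature the expected and observed distribution proportions are
#' compared to assign a responsibility class and (with the species' IUCN
#' category) a conservation-priority class and score. Deterministic given
#' inputs and configuration.
#'
#' @param ls an [nra_layerset()].
#' @param metadata species IUCN categories: a data.frame with columns
#'   `species_id` and `iucn_category`, or a named character vector. Species
#'   with a layer but no metadata are assessed for responsibility with
#'   priority marked not evaluable (with a warning); metadata entries without
#'   a matching layer are listed as missing.
#' @param cfg an [nra_config()].
#' @return an object of class `nra_run`: `config`, `records` (one row per
#'   species x focal feature), `warnings`, `missing_species`,
#'   `per_country_counts` and the layer-set `check` report.
#' @export
assess <- function(ls, metadata = NULL, cfg = nra_config()) {
  cfg <- validate_config(cfg)
  chk <- check_layerset(ls, cfg)
  warnings <- chk$warnings
  crs <- ls$reference$crs
  mode <- chk$area_mode
  area_ref <- chk$area_reference
  tol <- cfg$sliver_tolerance * area_ref

  meta <- normalize_metadata(metadata)
  sp_feats <- unlist(lapply(ls$species, `[[`, "features"), recursive = FALSE)
  sp_ids <- vapply(sp_feats, `[[`, "", "id")
  if (anyDuplicated(sp_ids)) stop("duplicate species ids across species layers")
  missing_species <- setdiff(names(meta), sp_ids)
  if (length(missing_species))
    warnings <- c(warnings, sprintf(
      "species '%s' listed in metadata but no matching range layer was found; skipped",
      missing_species))
  no_meta <- setdiff(sp_ids, names(meta))
  if (length(no_meta) && !is.null(metadata))
    warnings <- c(warnings, sprintf(
      "species '%s' has no IUCN category in the metadata; priority not evaluable", no_meta))
  if (!length(sp_feats))
    warnings <- c(warnings, "no species layers supplied; empty run")

  rows <- list()
  for (k in seq_along(sp_feats)) {
    sp <- sp_feats[[k]]
    sid <- sp$id
    clipped <- chk$clipped[[sid]]
    a_in_ref <- polygon_area(clipped, crs, mode)
    cratio <- chk$species$containment_ratio[chk$species$species_id == sid][1L]
    category <- if (sid %in% names(meta)) meta[[sid]] else NA_character_

    if (a_in_ref > tol) {
      occ <- compute_occupancy(clipped, ls$units, ls$reference, cfg)
      pattern <- classify_pattern(occ, cfg)
      n_units <- occ$n_units
      p_max <- occ$p_max
    } else {
      warnings <- c(warnings, sprintf(
        "species '%s' has no distribution inside the reference area; responsibility is 'none' everywhere", sid))
      pattern <- NA_character_
      n_units <- 0L
      p_max <- NA_real_
    }
    dp_exp <- clamp01(a_in_ref / area_ref)

    for (f in ls$focal$features) {
      a_f <- chk$focal$area_focal[chk$focal$focal_id == f$id][1L]
      a_int <- polygon_area(geom_intersection(clipped, f$geometry), crs, mode)
      dp_obs <- if (a_f > 0) clamp01(a_int / a_f) else 0
      present <- a_int > tol
      higher <- present && !is.na(pattern) && compare_dp(dp_obs, dp_exp, cfg)
      nr <- if (!present || is.na(pattern)) "none"
            else nr_class(pattern, higher, TRUE, cfg$nr_mapping)
      pri <- cp_lookup(category, nr)
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = sid, focal_id = f$id, iucn_category = category,
        area_reference = area_ref, area_focal = a_f,
        area_dist_in_reference = a_in_ref, area_dist_in_focal = a_int,
        dp_exp = dp_exp, dp_obs = dp_obs, n_units = n_units, p_max = p_max,
        pattern = pattern, higher = higher, nr = nr,
        cp_class = pri$cp_class, score = pri$score, evaluable = pri$evaluable,
        containment_ratio = cratio, stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else empty_records()
  run <- structure(list(config = cfg, records = records, warnings = warnings,
                        missing_species = missing_species, check = chk),
                   class = "nra_run")
  run$per_country_counts <- count_by_class(run)
  run
}

normalize_metadata <- function(metadata) {
  if (is.null(metadata)) return(stats::setNames(character(0), character(0)))
  if (is.data.frame(metadata)) {
    if (!all(c("species_id", "iucn_category") %in% names(metadata)))
      stop("metadata must have columns species_id and iucn_category")
    v <- stats::setNames(as.character(metadata$iucn_category),
                         as.character(metadata$species_id))
  } else if (is.character(metadata) && !is.null(names(metadata))) {
    v <- metadata
  } else {
    stop("metadata must be a data.frame or a named character vector")
  }
  vapply(v, function(x) as.character(parse_iucn_category(x)), "")
}

empty_records <- function() {
  data.frame(species_id = character(0), focal_id = character(0),
             iucn_category = character(0), area_reference = numeric(0),
             area_focal = numeric(0), area_dist_in_reference = numeric(0),
             area_dist_in_focal = numeric(0), dp_exp = numeric(0),
             dp_obs = numeric(0), n_units = integer(0), p_max = numeric(0),
             pattern = character(0), higher = logical(0), nr = character(0),
             cp_class = integer(0), score = integer(0), evaluable = logical(0),
             containment_ratio = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.nra_run <- function(x, ...) {
  cat(sprintf("<nra_run: %d records (%d species x %d focal areas), %d warning(s)>\n",
              nrow(x$records), length(unique(x$records$species_id)),
              length(unique(x$records$focal_id)), length(x$warnings)))
  invisible(x)
}

#' Per-country class counts
#'
#' Tallies, for every focal area, the number of species per
#' national-responsibility class and per conservation-priority class.
#'
#' @param run an `nra_run` (or a bare record data.frame).
#' @return a list with data.frames `responsibility` (`focal_id`, `nr`, `n`)
#'   and `priority` (`focal_id`, `cp_class`, `n`); `"none"` rows are included
#'   so that responsibility counts per country sum to the species total.
#' @export
count_by_class <- function(run) {
  records <- if (inherits(run, "nra_run")) run$records else run
  if (!nrow(records)) {
    return(list(
      responsibility = data.frame(focal_id = character(0), nr = character(0),
                                  n = integer(0), stringsAsFactors = FALSE),
      priority = data.frame(focal_id = character(0), cp_class = integer(0),
                            n = integer(0), stringsAsFactors = FALSE)))
  }
  resp <- as.data.frame(table(focal_id = records$focal_id, nr = records$nr),
                        stringsAsFactors = FALSE)
  names(resp)[3L] <- "n"
  resp <- resp[resp$n > 0L, , drop = FALSE]
  resp$n <- as.integer(resp$n)
  resp <- resp[order(resp$focal_id, match(resp$nr, NR_LEVELS)), , drop = FALSE]
  rownames(resp) <- NULL
  ev <- records[!is.na(records$cp_class), , drop = FALSE]
  pri <- if (nrow(ev)) {
    p <- as.data.frame(table(focal_id = ev$focal_id, cp_class = ev$cp_class),
                       stringsAsFactors = FALSE)
    names(p)[3L] <- "n"
    p <- p[p$n > 0L, , drop = FALSE]
    p$cp_class <- as.integer(p$cp_class)
    p$n <- as.integer(p$n)
    p <- p[order(p$focal_id, p$cp_class), , drop = FALSE]
    rownames(p) <- NULL
    p
  } else {
    data.frame(focal_id = character(0), cp_class = integer(0), n = integer(0),
               stringsAsFactors = FALSE)
  }
  list(responsibility = resp, priority = pri)
}

#' Compare the count- and area-approach runs
#'
#' Counts, per country, the species reaching at least `min_class`
#' responsibility under each approach; reports per-country deltas (PA-A minus
#' PC-A), summary statistics of the species-per-country counts
#' (min/quartiles/median/max/mean/SD; quartiles are inclusive linear
#' interpolation, `stats::quantile` type 7), and per-quartile-range rank
#' agreement between the two approaches. Countries are ranked by descending
#' PC-A count (ties share the smallest rank; ties broken by id for ordering)
#' and partitioned into four ranges by rank position.
#'
#' @param run_count the PC-A `nra_run` (or its record data.frame).
#' @param run_area the PA-A `nra_run` (or its record data.frame).
#' @param min_class minimum responsibility class counted (default
#'   `"medium"`).
#' @return a list of class `nra_comparison`: `per_country`, `summary_stats`,
#'   `thresholds` (rounded quartile thresholds of the PC-A counts) and
#'   `rank_agreement`.
#' @export
compare_approaches <- function(run_count, run_area, min_class = "medium") {
  rc <- if (inherits(run_count, "nra_run")) run_count$records else run_count
  ra <- if (inherits(run_area, "nra_run")) run_area$records else run_area
  min_class <- match.arg(min_class, NR_LEVELS)
  if (!setequal(unique(rc$species_id), unique(ra$species_id)) ||
      !setequal(unique(rc$focal_id), unique(ra$focal_id)))
    stop("the two runs must share the same species and focal-area sets")
  if (inherits(run_count, "nra_run") && inherits(run_area, "nra_run")) {
    ca <- run_count$config; cb <- run_area$config
    same <- identical(ca[setdiff(names(ca), "approach")],
                      cb[setdiff(names(cb), "approach")])
    if (!same) stop("the two runs must share all non-approach configuration")
  }
  rank_min <- match(min_class, NR_LEVELS)
  count_at <- function(rec) {
    keep <- match(rec$nr, NR_LEVELS) >= rank_min
    tapply(keep, rec$focal_id, sum)
  }
  ids <- sort(unique(rc$focal_id))
  n_pc <- as.integer(count_at(rc)[ids])
  n_pa <- as.integer(count_at(ra)[ids])
  per_country <- data.frame(focal_id = ids, n_pc = n_pc, n_pa = n_pa,
                            delta = n_pa - n_pc, stringsAsFactors = FALSE)

  qs <- function(x) {
    q <- stats::quantile(x, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    data.frame(min = q[1L], q25 = q[2L], median = q[3L], q75 = q[4L],
               max = q[5L], mean = mean(x), sd = stats::sd(x))
  }
  summary_stats <- rbind(cbind(approach = "PC-A", qs(n_pc)),
                         cbind(approach = "PA-A", qs(n_pa)),
                         cbind(approach = "PA-A - PC-A", qs(per_country$delta)))
  thresholds <- round(stats::quantile(n_pc, c(0, .25, .5, .75, 1),
                                      type = 7, names = FALSE))

  ord <- order(-per_country$n_pc, per_country$focal_id)
  pos <- integer(length(ids)); pos[ord] <- seq_along(ids)
  per_country$rank_pc <- rank(-per_country$n_pc, ties.method = "min")
  per_country$rank_pa <- rank(-per_country$n_pa, ties.method = "min")
  per_country$rank_equal <- per_country$rank_pc == per_country$rank_pa
  breaks <- unique(stats::quantile(seq_along(ids), c(0, .25, .5, .75, 1), type = 7))
  per_country$quartile_range <- as.character(
    cut(pos, breaks = breaks, include.lowest = TRUE,
        labels = c("0-25%", "25-50%", "50-75%", "75-100%")[seq_len(length(breaks) - 1L)]))
  agg <- split(per_country$rank_equal, per_country$quartile_range)
  rank_agreement <- data.frame(
    range = names(agg),
    n_true = vapply(agg, sum, 0L),
    n_false = vapply(agg, function(v) sum(!v), 0L),
    stringsAsFactors = FALSE)
  rank_agreement <- rank_agreement[order(match(rank_agreement$range,
                                               c("0-25%", "25-50%", "50-75%", "75-100%"))), ]
  rownames(rank_agreement) <- NULL
  structure(list(per_country = per_country, summary_stats = summary_stats,
                 thresholds = thresholds, rank_agreement = rank_agreement,
                 min_class = min_class),
            class = "nra_comparison")
}

#' @export
print.nra_comparison <- function(x, ...) {
  cat(sprintf("Approach comparison at responsibility >= %s\n", x$min_class))
  cat(sprintf("  countries: %d; mean delta (PA-A - PC-A): %.3f\n",
              nrow(x$per_country), mean(x$per_country$delta)))
  cat(sprintf("  rank agreement: %d identical / %d total\n",
              sum(x$per_country$rank_equal), nrow(x$per_country)))
  invisible(x)
}
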