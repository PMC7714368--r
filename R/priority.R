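# Conservation priority: the cross of national responsibility with the
# species' global IUCN Red List category. The class/score table is shipped as
# literal data — the scores are irregular by design and are not modelled by
# any formula. Data Deficient and Not Evaluated species, and species with no
# responsibility, are not evaluable for priority.

#' The conservation-priority class/score matrix
#'
#' 24 entries: six evaluable IUCN categories (EW, CR, EN, VU, NT, LC) crossed
#' with the four responsibility classes (very_high, high, medium, basic).
#' Scores increase with threat severity within a responsibility class and
#' decrease from very-high to basic responsibility within a category; priority
#' class 1 is reachable only for highly threatened, high-responsibility
#' combinations.
#'
#' @return a data.frame with columns `category`, `nr`, `cp_class`, `score`.
#' @examples
#' m <- build_priority_matrix()
#' m[m$category == "EN" & m$nr == "very_high", ]  # class 1, score 20
#' @export
build_priority_matrix <- function() {
  nr_cols <- c("very_high", "high", "medium", "basic")
  rows <- list(
    EW = list(cls = c(1L, 1L, 2L, 2L), sc = c(25L, 20L, 17L, 16L)),
    CR = list(cls = c(1L, 2L, 2L, 2L), sc = c(22L, 17L, 14L, 13L)),
    EN = list(cls = c(1L, 2L, 3L, 3L), sc = c(20L, 15L, 12L, 11L)),
    VU = list(cls = c(2L, 2L, 3L, 4L), sc = c(18L, 13L, 10L, 9L)),
    NT = list(cls = c(2L, 3L, 4L, 4L), sc = c(16L, 11L, 8L, 7L)),
    LC = list(cls = c(3L, 4L, 4L, 4L), sc = c(11L, 6L, 3L, 2L))
  )
  data.frame(
    category = rep(names(rows), each = 4L),
    nr = rep(nr_cols, times = 6L),
    cp_class = unlist(lapply(rows, `[[`, "cls"), use.names = FALSE),
    score = unlist(lapply(rows, `[[`, "sc"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Look up a conservation priority
#'
#' @param category two-letter IUCN code (see [parse_iucn_category()]).
#' @param nr responsibility class, one of [NR_LEVELS].
#' @param matrix the priority matrix (default [build_priority_matrix()]).
#' @return a list with `evaluable` (logical), `cp_class` and `score` (both
#'   `NA` when not evaluable: DD/NE categories, missing category, or no
#'   responsibility).
#' @export
cp_lookup <- function(category, nr, matrix = build_priority_matrix()) {
  if (is.null(category) || is.na(category) || !iucn_evaluable(category) ||
      identical(nr, "none")) {
    return(list(evaluable = FALSE, cp_class = NA_integer_, score = NA_integer_))
  }
  hit <- matrix[matrix$category == category & matrix$nr == nr, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop(sprintf("no priority entry for category '%s' x responsibility '%s'", category, nr))
  list(evaluable = TRUE, cp_class = hit$cp_class, score = hit$score)
}

#' Export the priority matrix as CSV
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_priority_matrix <- function(path) {
  utils::write.csv(build_priority_matrix(), path, row.names = FALSE)
  invisible(path)
}
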