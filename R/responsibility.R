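# The decision tree: distribution pattern x (observed vs expected proportion)
# -> national-responsibility class. A species absent from the focal area gives
# class "none"; otherwise the narrower the pattern and the more
# over-represented the species, the higher the responsibility.

#' Compare observed against expected distribution proportion
#'
#' @param dp_obs,dp_exp proportions in \[0, 1\].
#' @param cfg an [nra_config()]; under the default strict comparison, ties do
#'   not count as over-representation.
#' @return `TRUE` when the focal area holds a higher-than-expected share.
#' @export
compare_dp <- function(dp_obs, dp_exp, cfg = nra_config()) {
  cfg <- validate_config(cfg)
  stopifnot(dp_obs >= 0, dp_obs <= 1, dp_exp >= 0, dp_exp <= 1)
  if (cfg$strict_comparison) dp_obs > dp_exp else dp_obs >= dp_exp
}

#' National-responsibility class from the decision tree
#'
#' @param pattern `"local"`, `"regional"` or `"wide"`.
#' @param higher logical: does the observed proportion exceed the expected
#'   one (see [compare_dp()])?
#' @param present_in_focal logical: does the species occur in the focal area
#'   (overlap above sliver tolerance)? If `FALSE`, the class is `"none"`.
#' @param mapping the 3 x 2 mapping table (default [default_nr_mapping()]),
#'   validated for monotonicity.
#' @return one of [NR_LEVELS].
#' @export
nr_class <- function(pattern, higher, present_in_focal = TRUE,
                     mapping = default_nr_mapping()) {
  if (!isTRUE(present_in_focal)) return("none")
  pattern <- match.arg(pattern, PATTERN_LEVELS)
  mapping <- validate_nr_mapping(mapping)
  mapping$nr[mapping$pattern == pattern & mapping$higher == isTRUE(higher)]
}
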