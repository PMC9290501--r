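#' Prevalence of inadequate and excessive intake (EAR cut-point method)
#'
#' Applies the EAR cut-point method to a usual-intake distribution: the
#' prevalence of inadequacy is the survey-weighted share of the distribution
#' strictly below the group EAR, and the prevalence of excess the share
#' strictly above the UL. Values exactly at the EAR are counted adequate and
#' values exactly at the UL are counted safe (ties fall in neither tail).
#'
#' @param dist A `"usual_intake"` object or a numeric vector of usual
#'   intakes in mg/day.
#' @param ear_mg,ul_mg Reference values for the group (mg/day).
#' @param weights Optional weights when `dist` is a plain numeric vector.
#' @return A one-row tibble: `pct_below_ear`, `pct_above_ul`, `mean_mg`,
#'   `sd_mg`.
#' @export
#' @examples
#' prevalence(c(300, 500, 900, 2600), ear_mg = 800, ul_mg = 2500)
prevalence <- function(dist, ear_mg, ul_mg, weights = NULL) {
  if (inherits(dist, "usual_intake")) {
    x <- dist$values_mg
    w <- dist$weights
  } else {
    x <- dist
    w <- weights %||% rep(1, length(x))
  }
  if (length(x) == 0) {
    abort_calfort("cannot compute prevalence on an empty distribution",
                  "calfort_validation_error")
  }
  W <- sum(w)
  tibble::tibble(
    pct_below_ear = 100 * sum(w[x < ear_mg]) / W,
    pct_above_ul = 100 * sum(w[x > ul_mg]) / W,
    mean_mg = wtd_mean(x, w),
    sd_mg = wtd_sd(x, w)
  )
}

#' Target prevalence of inadequacy for fortification planning
#'
#' Step rule mapping the current prevalence of inadequate intake to the
#' post-intervention prevalence a fortification program aims for: 50% when
#' the current prevalence is above 50%, 10% when it lies between 10% and 50%
#' (both endpoints included), and 0% when it is below 10%.
#'
#' @param pct_below_ear Current prevalence of inadequacy, in `[0, 100]`
#'   (vectorized).
#' @return Target prevalence, one of 0, 10, or 50 (percent).
#' @export
#' @examples
#' target_prevalence(c(97.6, 28.9, 3.1, 50, 10))
target_prevalence <- function(pct_below_ear) {
  if (any(!is.finite(pct_below_ear)) || any(pct_below_ear < 0) || any(pct_below_ear > 100)) {
    abort_calfort("prevalence must lie in [0, 100]", "calfort_validation_error")
  }
  ifelse(pct_below_ear > 50, 50, ifelse(pct_below_ear >= 10, 10, 0))
}

#' Initial nutrient gap at the target prevalence
#'
#' The initial gap is the amount of additional daily calcium (mg/day) needed
#' for the usual-intake percentile corresponding to the target prevalence to
#' reach the EAR: `max(0, EAR - percentile(dist, target))`, with the target
#' chosen by [target_prevalence()] from the group's current prevalence of
#' inadequacy. A gap of 0 means the target is already met.
#'
#' @inheritParams prevalence
#' @return A one-row tibble: `target_prevalence` (percent),
#'   `initial_gap_mg` (mg/day).
#' @export
initial_gap <- function(dist, ear_mg, ul_mg, weights = NULL) {
  prev <- prevalence(dist, ear_mg, ul_mg, weights)
  tp <- target_prevalence(prev$pct_below_ear)
  at_target <- percentile(dist, tp, weights)
  tibble::tibble(
    target_prevalence = tp,
    initial_gap_mg = max(0, ear_mg - at_target)
  )
}

#' Convert a daily intake gap into a flour fortification level
#'
#' Convenience conversion of an initial gap (mg/day of calcium) into the
#' equivalent fortification level (mg calcium per 100 g flour) for a group
#' with a given mean flour intake: `gap / mean_flour_g * 100`. Returns `NA`
#' when the group eats no flour (no fortification level can close the gap
#' through this vehicle).
#'
#' @param gap_mg Initial gap in mg/day.
#' @param mean_flour_g Group mean flour intake in g/day.
#' @return Level in mg per 100 g flour, or `NA` if `mean_flour_g` is 0.
#' @export
gap_to_level <- function(gap_mg, mean_flour_g) {
  ifelse(mean_flour_g > 0, gap_mg / mean_flour_g * 100, NA_real_)
}
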