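# Independent oracles used across tests.

# Expand integer-weighted data into the equivalent unweighted sample.
expand_weights <- function(x, w) rep(x, times = w)

# Brute-force cut-point prevalence by direct counting (expansion for
# integer weights); independent of the package's weighted-sum route.
brute_prevalence <- function(x, w = NULL, ear, ul) {
  if (!is.null(w)) x <- expand_weights(x, w)
  c(below = 100 * sum(x < ear) / length(x),
    above = 100 * sum(x > ul) / length(x))
}

# Type-7 quantile of the expanded sample; the reference for the weighted
# percentile rule.
expand_percentile <- function(x, w, p) {
  unname(stats::quantile(expand_weights(x, w), p / 100, type = 7))
}

# Minimal hand-built inputs: two subjects, one day each.
tiny_inputs <- function() {
  list(
    subjects = tibble::tibble(
      subject_id = c("s1", "s2"),
      age_years = c(25, 35),
      sex = "female",
      pregnant = FALSE,
      weight = 1
    ),
    recalls = tibble::tibble(
      subject_id = c("s1", "s1", "s2", "s2"),
      day = 1L,
      food_code = c("bread", "milk", "bread", "milk"),
      amount_g = c(100, 200, 150, 100),
      calcium_mg = c(30, 240, 45, 120),
      is_tablet_supplement = FALSE
    ),
    flour_map = tibble::tibble(
      food_code = c("bread", "milk"),
      flour_type = c("wheat", "other"),
      fraction = c(0.65, 0)
    )
  )
}

# A small two-group synthetic survey used by scenario-level tests.
small_cohort <- function(seed, n = 150, p_flour = 1, within = 0.4) {
  specs <- dplyr::bind_rows(
    group_spec("npw 19 to <31", n = n, sex = "female", age_min = 19, age_max = 31,
               usual_log_mean = log(420), usual_log_sd = 0.45,
               within_log_sd = within, p_flour_consumer = p_flour,
               flour_mean_g = 110, n_days = 2),
    group_spec("men 31 to <51", n = n, sex = "male", age_min = 31, age_max = 51,
               usual_log_mean = log(700), usual_log_sd = 0.5,
               within_log_sd = within, p_flour_consumer = p_flour,
               flour_mean_g = 150, n_days = 2)
  )
  generate_cohort(specs, seed = seed)
}
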