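test_that("flour fraction sums all flour types of a food", {
  map <- tibble::tibble(
    food_code = c("mix", "mix", "flour", "cake"),
    flour_type = c("rice", "wheat", "wheat", "other"),
    fraction = c(0.30, 0.40, 1.0, 0)
  )
  expect_equal(flour_fraction("mix", map), 0.70)
  expect_equal(flour_fraction("flour", map), 1.0)
  expect_equal(flour_fraction("cake", map), 0)
  expect_equal(flour_fraction("unknown", map), 0) # absent code, fraction 0
  expect_equal(flour_fraction(c("flour", "mix"), map), c(1.0, 0.70))
})

test_that("flour map validation rejects fractions summing above 1", {
  bad <- tibble::tibble(
    food_code = c("mix", "mix"),
    flour_type = c("rice", "wheat"),
    fraction = c(0.7, 0.6)
  )
  expect_error(validate_flour_map(bad), "sum", class = "calfort_validation_error")
  expect_error(
    validate_flour_map(tibble::tibble(food_code = "x", flour_type = "spelt", fraction = 0.5)),
    class = "calfort_validation_error"
  )
})

test_that("daily totals sum calcium over all records but flour over non-tablets", {
  inp <- tiny_inputs()
  d <- daily_totals(inp$recalls, inp$subjects, inp$flour_map)
  s1 <- d[d$subject_id == "s1", ]
  expect_equal(s1$calcium_mg, 30 + 240)
  expect_equal(s1$flour_g, 100 * 0.65)

  # a calcium tablet with starch: counts for calcium, never for flour
  rec <- dplyr::bind_rows(
    inp$recalls,
    tibble::tibble(subject_id = "s1", day = 1L, food_code = "ca_tablet",
                   amount_g = 2, calcium_mg = 500, is_tablet_supplement = TRUE)
  )
  map <- dplyr::bind_rows(
    inp$flour_map,
    tibble::tibble(food_code = "ca_tablet", flour_type = "other", fraction = 1.0)
  )
  d2 <- daily_totals(rec, inp$subjects, map)
  s1b <- d2[d2$subject_id == "s1", ]
  expect_equal(s1b$calcium_mg, 270 + 500)
  expect_equal(s1b$flour_g, 65) # unchanged
})

test_that("orphan subject ids are a data error and unmapped codes a notice", {
  inp <- tiny_inputs()
  rec <- dplyr::mutate(inp$recalls, subject_id = dplyr::if_else(
    dplyr::row_number() == 1, "ghost", .data$subject_id
  ))
  expect_error(daily_totals(rec, inp$subjects, inp$flour_map), "ghost",
               class = "calfort_data_error")

  rec2 <- dplyr::mutate(inp$recalls, food_code = dplyr::if_else(
    dplyr::row_number() == 1, "unlisted_food", .data$food_code
  ))
  expect_message(daily_totals(rec2, inp$subjects, inp$flour_map), "flour map")
})

test_that("aggregation is additive: splitting records leaves totals unchanged", {
  co <- small_cohort(seed = 21, n = 40)
  base <- daily_totals(co$recalls, co$subjects, co$flour_map)
  halves <- dplyr::bind_rows(
    dplyr::mutate(co$recalls, amount_g = amount_g / 2, calcium_mg = calcium_mg / 2),
    dplyr::mutate(co$recalls, amount_g = amount_g / 2, calcium_mg = calcium_mg / 2)
  )
  split <- daily_totals(halves, co$subjects, co$flour_map)
  expect_equal(split, base)

  # shuffling record order does not change totals
  shuffled <- daily_totals(co$recalls[sample(nrow(co$recalls)), ], co$subjects, co$flour_map)
  expect_equal(shuffled, base)
})

test_that("fortifiable flour never exceeds total grams eaten that day", {
  co <- small_cohort(seed = 22, n = 60)
  totals_g <- co$recalls |>
    dplyr::group_by(subject_id, day) |>
    dplyr::summarise(grams = sum(amount_g), .groups = "drop")
  d <- daily_totals(co$recalls, co$subjects, co$flour_map) |>
    dplyr::inner_join(totals_g, by = c("subject_id", "day"))
  expect_true(all(d$flour_g <= d$grams + 1e-9))
})

test_that("flour summary weights subjects and includes non-consumers", {
  subj <- tibble::tibble(subject_id = c("a", "b"), age_years = 25, sex = "female",
                         pregnant = FALSE, weight = c(1, 1))
  daily <- tibble::tibble(subject_id = c("a", "b"), day = 1L,
                          calcium_mg = 300, flour_g = c(0, 100))
  s <- flour_summary(daily, subj)
  expect_equal(s$pct_consuming, 50)
  expect_equal(s$mean_flour_g, 50)

  subj$weight <- c(1, 3)
  s <- flour_summary(daily, subj)
  expect_equal(s$pct_consuming, 75)
  expect_equal(s$mean_flour_g, 75)

  # all consumers
  daily$flour_g <- c(40, 100)
  expect_equal(flour_summary(daily, subj)$pct_consuming, 100)

  # unit weights equal unweighted statistics
  subj$weight <- 1
  s <- flour_summary(daily, subj)
  expect_equal(s$mean_flour_g, mean(daily$flour_g))
  expect_equal(s$sd_flour_g, sqrt(mean((daily$flour_g - 70)^2)))
})

test_that("flour summary uses each subject's first recall day only", {
  subj <- tibble::tibble(subject_id = "a", age_years = 25, sex = "female",
                         pregnant = FALSE, weight = 1)
  daily <- tibble::tibble(subject_id = "a", day = c(1L, 2L),
                          calcium_mg = 300, flour_g = c(0, 80))
  expect_equal(flour_summary(daily, subj)$pct_consuming, 0)
})

test_that("input files round-trip and are validated with helpful errors", {
  inp <- tiny_inputs()
  sp <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(inp$subjects, sp)
  readr::write_csv(inp$recalls, rp)
  readr::write_csv(inp$flour_map, mp)
  expect_equal(read_subjects(sp), inp$subjects)
  expect_equal(read_recalls(rp), inp$recalls)
  expect_equal(read_flour_map(mp), inp$flour_map)

  # weight column optional, defaults to 1
  readr::write_csv(inp$subjects[, 1:4], sp)
  expect_equal(read_subjects(sp)$weight, c(1, 1))

  # missing required column
  readr::write_csv(inp$recalls[, -3], rp)
  expect_error(read_recalls(rp), "food_code", class = "calfort_validation_error")

  # row-level validation mentions the offending rows
  bad <- inp$subjects
  bad$weight <- c(1, -2)
  readr::write_csv(bad, sp)
  expect_error(read_subjects(sp), "rows: 2", class = "calfort_validation_error")
})
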