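#' Read a subjects file
#'
#' Subjects are survey participants. The file must contain columns
#' `subject_id`, `age_years`, `sex` (`female`/`male`), `pregnant`
#' (TRUE/FALSE); a `weight` column of positive survey weights is optional
#' and defaults to 1 (self-weighting sample).
#'
#' @param path CSV or TSV file with a header.
#' @return A tibble with columns `subject_id`, `age_years`, `sex`,
#'   `pregnant`, `weight`.
#' @export
read_subjects <- function(path) {
  tbl <- read_delim_checked(path, c("subject_id", "age_years", "sex", "pregnant"))
  if (!"weight" %in% names(tbl)) tbl$weight <- 1
  tbl <- dplyr::mutate(
    tbl,
    subject_id = as.character(.data$subject_id),
    age_years = as.numeric(.data$age_years),
    sex = as.character(.data$sex),
    pregnant = as.logical(.data$pregnant),
    weight = as.numeric(.data$weight)
  )
  validate_subjects(tbl)
  tbl[, c("subject_id", "age_years", "sex", "pregnant", "weight")]
}

validate_subjects <- function(tbl) {
  problems <- character()
  dup <- duplicated(tbl$subject_id)
  if (any(dup)) {
    problems <- c(problems, paste0(
      "duplicated subject_id at rows: ",
      paste(head(which(dup), 5), collapse = ", ")
    ))
  }
  bad_w <- !is.finite(tbl$weight) | tbl$weight <= 0
  if (any(bad_w)) {
    problems <- c(problems, paste0(
      "non-positive survey weights at rows: ",
      paste(head(which(bad_w), 5), collapse = ", ")
    ))
  }
  bad_age <- !is.finite(tbl$age_years) | tbl$age_years < 0
  if (any(bad_age)) {
    problems <- c(problems, paste0(
      "invalid age_years at rows: ",
      paste(head(which(bad_age), 5), collapse = ", ")
    ))
  }
  bad_sex <- !(tbl$sex %in% c("female", "male"))
  if (any(bad_sex)) {
    problems <- c(problems, paste0(
      "sex must be female/male at rows: ",
      paste(head(which(bad_sex), 5), collapse = ", ")
    ))
  }
  if (length(problems) > 0) {
    abort_calfort(
      paste0("invalid subjects data:\n  - ", paste(problems, collapse = "\n  - ")),
      "calfort_validation_error"
    )
  }
  invisible(tbl)
}

#' Read a dietary recall file
#'
#' One row per food item reported on a recall day. Required columns:
#' `subject_id`, `day` (positive integer recall-day index), `food_code`,
#' `amount_g` (grams consumed), `calcium_mg` (calcium contributed by that
#' item). An `is_tablet_supplement` logical column is optional (default
#' FALSE): tablet/pill supplements count toward calcium intake but never
#' toward fortifiable flour.
#'
#' @param path CSV or TSV file with a header.
#' @return A tibble of recall records.
#' @export
read_recalls <- function(path) {
  tbl <- read_delim_checked(path, c("subject_id", "day", "food_code", "amount_g", "calcium_mg"))
  if (!"is_tablet_supplement" %in% names(tbl)) tbl$is_tablet_supplement <- FALSE
  tbl <- dplyr::mutate(
    tbl,
    subject_id = as.character(.data$subject_id),
    day = as.integer(.data$day),
    food_code = as.character(.data$food_code),
    amount_g = as.numeric(.data$amount_g),
    calcium_mg = as.numeric(.data$calcium_mg),
    is_tablet_supplement = as.logical(.data$is_tablet_supplement)
  )
  problems <- character()
  bad_day <- !is.finite(tbl$day) | tbl$day < 1
  if (any(bad_day)) {
    problems <- c(problems, paste0(
      "day must be a positive integer at rows: ",
      paste(head(which(bad_day), 5), collapse = ", ")
    ))
  }
  bad_amt <- !is.finite(tbl$amount_g) | tbl$amount_g < 0 |
    !is.finite(tbl$calcium_mg) | tbl$calcium_mg < 0
  if (any(bad_amt)) {
    problems <- c(problems, paste0(
      "negative or missing amount_g/calcium_mg at rows: ",
      paste(head(which(bad_amt), 5), collapse = ", ")
    ))
  }
  if (length(problems) > 0) {
    abort_calfort(
      paste0("invalid recall data:\n  - ", paste(problems, collapse = "\n  - ")),
      "calfort_validation_error"
    )
  }
  tbl[, c("subject_id", "day", "food_code", "amount_g", "calcium_mg", "is_tablet_supplement")]
}

#' Read a food-to-flour-fraction map
#'
#' Maps food codes to the mass fraction of each flour type they contain.
#' Multiple rows per food are allowed (e.g. a food that is 30% rice flour
#' and 40% wheat flour); the fortifiable fraction of a food is the sum over
#' its flour types, which must not exceed 1.
#'
#' @param path CSV or TSV file with columns `food_code`, `flour_type`
#'   (`wheat`, `maize`, `rice`, `cassava`, or `other`), `fraction` in
#'   `[0, 1]`.
#' @return A validated tibble.
#' @export
read_flour_map <- function(path) {
  tbl <- read_delim_checked(path, c("food_code", "flour_type", "fraction"))
  tbl <- dplyr::mutate(
    tbl,
    food_code = as.character(.data$food_code),
    flour_type = as.character(.data$flour_type),
    fraction = as.numeric(.data$fraction)
  )
  validate_flour_map(tbl)
  tbl[, c("food_code", "flour_type", "fraction")]
}

flour_types_known <- c("wheat", "maize", "rice", "cassava", "other")

validate_flour_map <- function(tbl) {
  problems <- character()
  bad_type <- !(tbl$flour_type %in% flour_types_known)
  if (any(bad_type)) {
    problems <- c(problems, paste0(
      "unknown flour_type at rows: ",
      paste(head(which(bad_type), 5), collapse = ", "),
      " (expected ", paste(flour_types_known, collapse = "/"), ")"
    ))
  }
  bad_frac <- !is.finite(tbl$fraction) | tbl$fraction < 0 | tbl$fraction > 1
  if (any(bad_frac)) {
    problems <- c(problems, paste0(
      "fraction outside [0, 1] at rows: ",
      paste(head(which(bad_frac), 5), collapse = ", ")
    ))
  }
  sums <- tapply(tbl$fraction, tbl$food_code, sum)
  over <- names(sums)[sums > 1 + 1e-9]
  if (length(over) > 0) {
    problems <- c(problems, paste0(
      "flour fractions sum to more than 1 for foods: ",
      paste(head(over, 5), collapse = ", ")
    ))
  }
  if (length(problems) > 0) {
    abort_calfort(
      paste0("invalid flour map:\n  - ", paste(problems, collapse = "\n  - ")),
      "calfort_validation_error"
    )
  }
  invisible(tbl)
}

#' Total flour fraction of foods
#'
#' Returns, for each food code, the total fortifiable-flour mass fraction:
#' the sum of its per-type fractions in the map. When several flour types are
#' present all of them are assumed fortified, so a food with 30% rice flour
#' and 40% wheat flour has fraction 0.70. Codes absent from the map get
#' fraction 0 (callers aggregate and report how many codes were unmapped).
#'
#' @param food_code Character vector of food codes.
#' @param map A flour map (see [read_flour_map()]).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   food_code = c("bread", "mix", "mix"),
#'   flour_type = c("wheat", "rice", "wheat"),
#'   fraction = c(0.65, 0.30, 0.40)
#' )
#' flour_fraction(c("bread", "mix", "milk"), m)
flour_fraction <- function(food_code, map) {
  validate_flour_map(map)
  sums <- tapply(map$fraction, map$food_code, sum)
  out <- unname(sums[food_code])
  out[is.na(out)] <- 0
  as.numeric(out)
}

#' Aggregate recall records into per-subject-day totals
#'
#' Computes, for every observed subject-day, total calcium intake (mg/day,
#' all records including powder/liquid supplements) and total fortifiable
#' flour (g/day, `amount_g * flour_fraction` summed over non-tablet records).
#' Tablet or pill supplements may contain starch but are never fortified, so
#' they are excluded from the flour total while still counting toward
#' calcium.
#'
#' @param records Recall records (see [read_recalls()]).
#' @param subjects Subjects table; every `subject_id` in `records` must
#'   appear here.
#' @param map A flour map (see [read_flour_map()]).
#' @return A tibble with columns `subject_id`, `day`, `calcium_mg`,
#'   `flour_g`, one row per observed subject-day.
#' @export
daily_totals <- function(records, subjects, map) {
  orphans <- setdiff(unique(records$subject_id), subjects$subject_id)
  if (length(orphans) > 0) {
    abort_calfort(
      paste0(
        "recall records reference unknown subject_id(s): ",
        paste(head(orphans, 10), collapse = ", "),
        if (length(orphans) > 10) " ..." else ""
      ),
      "calfort_data_error"
    )
  }
  frac <- flour_fraction(records$food_code, map)
  unmapped <- unique(records$food_code[!(records$food_code %in% map$food_code)])
  if (length(unmapped) > 0) {
    message(
      length(unmapped), " food code(s) absent from the flour map were treated ",
      "as containing no flour (e.g. ", paste(head(unmapped, 3), collapse = ", "), ")"
    )
  }
  tablet <- records$is_tablet_supplement %||% rep(FALSE, nrow(records))
  records |>
    dplyr::mutate(
      .flour = .data$amount_g * frac * !tablet
    ) |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::summarise(
      calcium_mg = sum(.data$calcium_mg),
      flour_g = sum(.data$.flour),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$subject_id, .data$day)
}

# First observed recall day per subject (day-1 snapshot used for
# distributional statistics, keeping subjects with different day counts
# comparable).
first_day_intakes <- function(daily) {
  daily |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_min(.data$day, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Summarize flour consumption for a group of subjects
#'
#' Uses each subject's first recall day. The share of the population
#' consuming flour is the survey-weighted percentage of subjects with any
#' fortifiable flour on that day; mean and SD of flour intake include
#' non-consumers (zeros), matching how fortification planning summarizes the
#' vehicle's coverage. Subjects without any recall day are omitted.
#'
#' @param daily Per-subject-day totals from [daily_totals()].
#' @param subjects Subjects in the group (their `weight` column is used).
#' @return A tibble with `pct_consuming`, `mean_flour_g`, `sd_flour_g`.
#' @export
flour_summary <- function(daily, subjects) {
  day1 <- first_day_intakes(daily) |>
    dplyr::inner_join(subjects[, c("subject_id", "weight")], by = "subject_id")
  if (nrow(day1) == 0) {
    abort_calfort("no recall data for any subject in the group", "calfort_data_error")
  }
  tibble::tibble(
    pct_consuming = 100 * sum(day1$weight[day1$flour_g > 0]) / sum(day1$weight),
    mean_flour_g = wtd_mean(day1$flour_g, day1$weight),
    sd_flour_g = wtd_sd(day1$flour_g, day1$weight)
  )
}

# Shared delimited reader: infer delimiter from extension, require columns.
read_delim_checked <- function(path, required) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort_calfort(paste0("input file not found: ", path), "calfort_config_error")
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(), progress = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort_calfort(
      paste0(basename(path), " is missing required columns: ",
             paste(missing_cols, collapse = ", ")),
      "calfort_validation_error"
    )
  }
  tbl
}
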