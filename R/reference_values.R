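#' Dietary reference intake (DRI) tables for calcium
#'
#' A DRI table maps life-stage groups — strata defined by sex, pregnancy
#' status, and a half-open age interval `[age_min, age_max)` in years — to
#' their calcium Estimated Average Requirement (EAR) and Tolerable Upper
#' Intake Level (UL), both in mg/day. The EAR is the intake estimated to meet
#' the requirement of half of the healthy individuals in a group; the UL is
#' the highest usual intake posing no risk of adverse effects.
#'
#' `dri_calcium()` returns the default table shipped with the package: 18
#' life-stage groups covering ages 0.5 years and older (children under 9 are
#' not sex-differentiated; pregnant groups span ages 14 to <51). The table is
#' stored as a plain CSV so that other nutrients or country-specific
#' references can be swapped in via [read_dri_table()].
#'
#' @return A tibble with columns `label`, `sex` (`"female"`, `"male"`, or
#'   `"any"`), `pregnant`, `age_min`, `age_max`, `ear_mg`, `ul_mg`.
#' @export
#' @examples
#' dri_calcium()
dri_calcium <- function() {
  read_dri_table(system.file("extdata", "dri_calcium.csv", package = "calfort"))
}

#' Read and validate a DRI table from a delimited file
#'
#' @param path Path to a CSV/TSV file with columns `label`, `sex`,
#'   `pregnant`, `age_min`, `age_max` (years; interval is `[min, max)`,
#'   `Inf` allowed for open-ended groups), `ear_mg`, `ul_mg`.
#' @return A validated tibble (see [dri_calcium()]).
#' @export
read_dri_table <- function(path) {
  if (!file.exists(path)) {
    abort_calfort(paste0("DRI table file not found: ", path), "calfort_config_error")
  }
  tbl <- readr::read_delim(
    path,
    delim = if (grepl("\\.tsv$", path)) "\t" else ",",
    col_types = readr::cols(
      label = readr::col_character(),
      sex = readr::col_character(),
      pregnant = readr::col_logical(),
      age_min = readr::col_double(),
      age_max = readr::col_double(),
      ear_mg = readr::col_double(),
      ul_mg = readr::col_double()
    ),
    progress = FALSE
  )
  validate_dri_table(tbl)
  tbl
}

validate_dri_table <- function(tbl) {
  req <- c("label", "sex", "pregnant", "age_min", "age_max", "ear_mg", "ul_mg")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols) > 0) {
    abort_calfort(
      paste0("DRI table is missing columns: ", paste(missing_cols, collapse = ", ")),
      "calfort_validation_error"
    )
  }
  bad <- character()
  if (!all(tbl$sex %in% c("female", "male", "any"))) {
    bad <- c(bad, "sex must be one of female/male/any")
  }
  if (any(tbl$age_min < 0) || any(tbl$age_min >= tbl$age_max)) {
    bad <- c(bad, "age intervals must satisfy 0 <= age_min < age_max")
  }
  if (any(tbl$ear_mg <= 0) || any(tbl$ul_mg <= tbl$ear_mg)) {
    bad <- c(bad, "reference values must satisfy 0 < ear_mg < ul_mg")
  }
  if (any(tbl$pregnant & tbl$sex != "female")) {
    bad <- c(bad, "pregnant groups must have sex = female")
  }
  # groups within one (sex, pregnant) stratum must not overlap
  for (s in c("female", "male")) {
    for (p in c(FALSE, TRUE)) {
      rows <- tbl[(tbl$sex == s | tbl$sex == "any") & tbl$pregnant == p, ]
      if (nrow(rows) < 2) next
      rows <- rows[order(rows$age_min), ]
      if (any(rows$age_max[-nrow(rows)] > rows$age_min[-1] + 1e-12)) {
        bad <- c(bad, paste0("overlapping age groups in stratum sex=", s, ", pregnant=", p))
      }
    }
  }
  if (length(bad) > 0) {
    abort_calfort(
      paste0("invalid DRI table:\n  - ", paste(bad, collapse = "\n  - ")),
      "calfort_validation_error"
    )
  }
  invisible(tbl)
}

#' Classify subjects into DRI life-stage groups
#'
#' Assigns each subject the unique life-stage group whose half-open age
#' interval `[age_min, age_max)` contains the subject's age within the
#' matching sex/pregnancy stratum, and returns the group's reference values.
#'
#' @param age_years Numeric vector of ages in years; must be `>= 0.5` (the
#'   default table starts at 6 months).
#' @param sex Character vector, `"female"` or `"male"` (recycled).
#' @param pregnant Logical vector (recycled, default `FALSE`).
#' @param table A DRI table, by default [dri_calcium()].
#' @param subject_id Optional identifiers used in error messages.
#' @return A tibble with one row per input: `label`, `ear_mg`, `ul_mg`.
#' @export
#' @examples
#' assign_group(c(2, 55), c("female", "male"))
assign_group <- function(age_years, sex, pregnant = FALSE,
                         table = dri_calcium(), subject_id = NULL) {
  n <- max(length(age_years), length(sex), length(pregnant))
  age_years <- rep_len(age_years, n)
  sex <- rep_len(sex, n)
  pregnant <- rep_len(pregnant, n)
  if (is.null(subject_id)) subject_id <- as.character(seq_len(n))
  subject_id <- rep_len(as.character(subject_id), n)

  bad_sex <- !(sex %in% c("female", "male"))
  if (any(bad_sex)) {
    abort_calfort(
      paste0(
        "sex must be 'female' or 'male' for subjects: ",
        paste(head(subject_id[bad_sex], 5), collapse = ", ")
      ),
      "calfort_classification_error"
    )
  }

  idx <- rep(NA_integer_, n)
  for (j in seq_len(nrow(table))) {
    hit <- (table$sex[j] == "any" | table$sex[j] == sex) &
      (table$pregnant[j] == pregnant) &
      age_years >= table$age_min[j] & age_years < table$age_max[j]
    idx[hit & is.na(idx)] <- j
  }
  if (anyNA(idx)) {
    miss <- is.na(idx)
    detail <- paste0(
      subject_id[miss], " (age ", signif(age_years[miss], 4), ", ", sex[miss],
      ifelse(pregnant[miss], ", pregnant", ""), ")"
    )
    abort_calfort(
      paste0(
        "no matching life-stage group for ", sum(miss), " subject(s): ",
        paste(head(detail, 5), collapse = "; "),
        if (sum(miss) > 5) " ..." else ""
      ),
      "calfort_classification_error"
    )
  }
  tibble::tibble(
    label = table$label[idx],
    ear_mg = table$ear_mg[idx],
    ul_mg = table$ul_mg[idx]
  )
}
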