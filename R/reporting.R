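#' Format scenario results at table precision
#'
#' Rounds percentages, means, and SDs to one decimal, matching the precision
#' fortification-planning tables are usually printed at.
#'
#' @param scenario A `"scenario_result"` from [run_scenario()].
#' @return A tibble ready for printing or CSV export.
#' @export
format_results <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_result"))
  scenario$results |>
    dplyr::mutate(dplyr::across(dplyr::where(is.double) & !dplyr::any_of(
      c("age_min", "age_max")
    ), ~ round(.x, 1)))
}

#' Density plot of pre- and post-fortification usual intake
#'
#' Survey-weighted density of the usual calcium intake distribution before
#' and after fortification for each group, with the group's EAR and UL as
#' vertical reference lines.
#'
#' @param scenario A `"scenario_result"` from [run_scenario()].
#' @param groups Optional character vector of group labels to include.
#' @return A ggplot object.
#' @export
plot_scenario <- function(scenario, groups = NULL) {
  stopifnot(inherits(scenario, "scenario_result"))
  labs <- names(scenario$distributions)
  if (!is.null(groups)) labs <- intersect(labs, groups)
  dat <- purrr::map_dfr(labs, function(lab) {
    d <- scenario$distributions[[lab]]
    dplyr::bind_rows(
      tibble::tibble(group = lab, phase = "pre",
                     usual_mg = d$pre$values_mg, weight = d$pre$weights),
      tibble::tibble(group = lab, phase = "post",
                     usual_mg = d$post$values_mg, weight = d$post$weights)
    )
  })
  refs <- scenario$results[scenario$results$group %in% labs,
                           c("group", "ear_mg", "ul_mg")]
  ggplot2::ggplot(dat, ggplot2::aes(.data$usual_mg,
                                    weight = .data$weight,
                                    colour = .data$phase)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(data = refs, ggplot2::aes(xintercept = .data$ear_mg),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = refs, ggplot2::aes(xintercept = .data$ul_mg),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::labs(x = "usual calcium intake (mg/day)", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write scenario outputs to a directory
#'
#' Writes `results.csv` (one row per group), per-group adjusted-distribution
#' CSVs under `distributions/`, a `run_metadata.json` recording the
#' configuration, package version, and every warning raised during the run,
#' and optionally a density plot per the figures convention.
#'
#' @param scenario A `"scenario_result"`.
#' @param dir Output directory (created if needed).
#' @param plots Write `distributions.png`? Default FALSE.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir, plots = FALSE) {
  stopifnot(inherits(scenario, "scenario_result"))
  dir.create(file.path(dir, "distributions"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(scenario$results, file.path(dir, "results.csv"))
  for (lab in names(scenario$distributions)) {
    slug <- gsub("[^a-z0-9]+", "_", tolower(lab))
    d <- scenario$distributions[[lab]]
    write_usual_intake(d$pre, file.path(dir, "distributions", paste0(slug, "_pre.csv")))
    write_usual_intake(d$post, file.path(dir, "distributions", paste0(slug, "_post.csv")))
  }
  meta <- list(
    package = "calfort",
    version = as.character(utils::packageVersion("calfort")),
    config = scenario$config,
    groups = scenario$results$group,
    warnings = scenario$warnings
  )
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (plots) {
    p <- plot_scenario(scenario)
    ggplot2::ggsave(file.path(dir, "distributions.png"), p,
                    width = 10, height = 7, dpi = 150)
  }
  invisible(dir)
}

# Parse a YAML scenario configuration into the pieces run_scenario() needs.
parse_config <- function(path) {
  if (is.null(path)) {
    return(list(
      spec = fortification_spec(),
      variance = variance_ratio_spec("internal"),
      transformation = "log", offset = 1, min_n = 10, dri_table = dri_calcium()
    ))
  }
  if (!file.exists(path)) {
    abort_calfort(paste0("config file not found: ", path), "calfort_config_error")
  }
  cfg <- yaml::read_yaml(path)
  vmode <- cfg$variance$mode %||% "internal"
  variance <- if (identical(vmode, "external")) {
    variance_ratio_spec("external", cfg$variance$ratio)
  } else {
    variance_ratio_spec("internal")
  }
  list(
    spec = fortification_spec(
      level_mg_per_100g = cfg$level_mg_per_100g %||% 156,
      flour_types = cfg$flour_types
    ),
    variance = variance,
    transformation = cfg$transformation %||% "log",
    offset = cfg$offset %||% 1,
    min_n = cfg$min_n %||% 10,
    dri_table = if (is.null(cfg$dri_table)) dri_calcium() else read_dri_table(cfg$dri_table)
  )
}

#' Run a fortification simulation from files
#'
#' Thin command-style wrapper over the pipeline: reads and validates the
#' three input files (all inputs are checked before anything is written, so
#' a configuration error leaves no partial outputs), runs [run_scenario()],
#' and writes results, distributions, and run metadata to `out`.
#'
#' @param recalls,subjects,flour_map Paths to the input files.
#' @param out Output directory.
#' @param config Optional YAML config path (keys `level_mg_per_100g`,
#'   `variance: {mode, ratio}`, `transformation`, `offset`, `min_n`,
#'   `flour_types`, `dri_table`).
#' @param plots Also write a density plot? Default FALSE.
#' @param quiet Suppress progress messages.
#' @return Exit status 0, invisibly; signals a classed error on any
#'   validation failure.
#' @export
cmd_simulate <- function(recalls, subjects, flour_map, out,
                         config = NULL, plots = FALSE, quiet = FALSE) {
  cfg <- parse_config(config)
  rec <- read_recalls(recalls)
  sub <- read_subjects(subjects)
  map <- read_flour_map(flour_map)
  scenario <- run_scenario(
    rec, sub, map,
    dri_table = cfg$dri_table, spec = cfg$spec, variance = cfg$variance,
    transformation = cfg$transformation, offset = cfg$offset, min_n = cfg$min_n
  )
  write_scenario(scenario, out, plots = plots)
  if (!quiet) {
    message(sprintf(
      "simulated fortification at %g mg/100 g for %d group(s); results in %s",
      cfg$spec$level_mg_per_100g, nrow(scenario$results), out
    ))
    for (w in scenario$warnings) message("warning: ", w)
  }
  invisible(0L)
}

#' Generate synthetic survey input files
#'
#' Writes `subjects.csv`, `recalls.csv`, `flour_map.csv`, the analytic
#' ground truth as `truth.json`, and the latent per-subject usual intakes as
#' `latent_usual.csv` into `out`. Identical preset/spec and seed give
#' identical files.
#'
#' @param preset Name of a paper-like preset (see [paperlike_presets()]).
#' @param spec_file Alternatively, a CSV of [group_spec()] columns.
#' @param seed Integer seed.
#' @param out Output directory.
#' @param quiet Suppress progress messages.
#' @return Exit status 0, invisibly.
#' @export
cmd_generate <- function(preset = NULL, spec_file = NULL, seed = 1, out,
                         quiet = FALSE) {
  if (is.null(preset) == is.null(spec_file)) {
    abort_calfort("supply exactly one of preset or spec_file", "calfort_config_error")
  }
  specs <- if (!is.null(preset)) {
    presets <- paperlike_presets()
    if (!preset %in% names(presets)) {
      abort_calfort(
        paste0("unknown preset '", preset, "'; available: ",
               paste(names(presets), collapse = ", ")),
        "calfort_config_error"
      )
    }
    presets[[preset]]
  } else {
    spec_tbl <- read_delim_checked(spec_file, c("label", "n"))
    do.call(dplyr::bind_rows, purrr::pmap(spec_tbl, group_spec))
  }
  cohort <- generate_cohort(specs, seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$subjects, file.path(out, "subjects.csv"))
  readr::write_csv(cohort$recalls, file.path(out, "recalls.csv"))
  readr::write_csv(cohort$flour_map, file.path(out, "flour_map.csv"))
  readr::write_csv(cohort$latent, file.path(out, "latent_usual.csv"))
  jsonlite::write_json(cohort$truth, file.path(out, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!quiet) {
    message(sprintf(
      "generated %d subjects / %d recall records in %s",
      nrow(cohort$subjects), nrow(cohort$recalls), out
    ))
  }
  invisible(0L)
}

#' Re-render the results table from a scenario output directory
#'
#' @param results_dir Directory previously written by [cmd_simulate()] /
#'   [write_scenario()].
#' @return The results tibble, invisibly.
#' @export
cmd_report <- function(results_dir) {
  path <- file.path(results_dir, "results.csv")
  if (!file.exists(path)) {
    abort_calfort(paste0("no results.csv under ", results_dir), "calfort_config_error")
  }
  res <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  print(res |>
          dplyr::mutate(dplyr::across(dplyr::where(is.double) &
                                        !dplyr::any_of(c("age_min", "age_max")),
                                      ~ round(.x, 1))), n = Inf)
  invisible(res)
}
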