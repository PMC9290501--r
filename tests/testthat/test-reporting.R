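test_that("generated input files are deterministic given the seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cmd_generate(preset = "bangladesh-like", seed = 7, out = d1, quiet = TRUE)
  cmd_generate(preset = "bangladesh-like", seed = 7, out = d2, quiet = TRUE)
  for (f in c("subjects.csv", "recalls.csv", "flour_map.csv", "truth.json",
              "latent_usual.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("simulate runs end-to-end on generated files and round-trips", {
  gen <- withr::local_tempdir()
  out <- withr::local_tempdir()
  spec_file <- file.path(gen, "specs.csv")
  readr::write_csv(
    dplyr::bind_rows(
      group_spec("npw 19 to <31", n = 120, sex = "female", age_min = 19,
                 age_max = 31, usual_log_mean = log(350), usual_log_sd = 0.45,
                 flour_mean_g = 250, n_days = 2),
      group_spec("children 1 to <4", n = 120, sex = "any", age_min = 1,
                 age_max = 4, usual_log_mean = log(250), usual_log_sd = 0.4,
                 flour_mean_g = 150, n_days = 2)
    ),
    spec_file
  )
  cmd_generate(spec_file = spec_file, seed = 3, out = gen, quiet = TRUE)
  status <- cmd_simulate(
    recalls = file.path(gen, "recalls.csv"),
    subjects = file.path(gen, "subjects.csv"),
    flour_map = file.path(gen, "flour_map.csv"),
    out = out, quiet = TRUE
  )
  expect_identical(status, 0L)

  res <- readr::read_csv(file.path(out, "results.csv"),
                         col_types = readr::cols(), progress = FALSE)
  expect_equal(nrow(res), 2L)
  # flour-consuming groups improve
  expect_true(all(res$post_pct_below_ear <= res$pre_pct_below_ear))

  # round-trip: the CSV equals the in-memory results
  sc <- run_scenario(
    read_recalls(file.path(gen, "recalls.csv")),
    read_subjects(file.path(gen, "subjects.csv")),
    read_flour_map(file.path(gen, "flour_map.csv"))
  )
  expect_equal(as.data.frame(res), as.data.frame(sc$results), tolerance = 1e-8)

  # per-group adjusted distributions exported for audit
  expect_true(length(list.files(file.path(out, "distributions"))) == 4L)

  # metadata records the configuration
  meta <- jsonlite::read_json(file.path(out, "run_metadata.json"))
  expect_equal(meta$config$level_mg_per_100g, 156)
  expect_equal(meta$config$variance_mode, "internal")
})

test_that("a zero-level scenario leaves pre and post columns identical", {
  gen <- withr::local_tempdir()
  out <- withr::local_tempdir()
  cfg <- file.path(gen, "cfg.yaml")
  writeLines("level_mg_per_100g: 0", cfg)
  spec_file <- file.path(gen, "specs.csv")
  readr::write_csv(group_spec("npw 19 to <31", n = 60, n_days = 2), spec_file)
  cmd_generate(spec_file = spec_file, seed = 5, out = gen, quiet = TRUE)
  cmd_simulate(
    recalls = file.path(gen, "recalls.csv"),
    subjects = file.path(gen, "subjects.csv"),
    flour_map = file.path(gen, "flour_map.csv"),
    out = out, config = cfg, quiet = TRUE
  )
  res <- readr::read_csv(file.path(out, "results.csv"),
                         col_types = readr::cols(), progress = FALSE)
  expect_equal(res$post_pct_below_ear, res$pre_pct_below_ear)
  expect_equal(res$post_mean_mg, res$pre_mean_mg)
  expect_equal(res$post_sd_mg, res$pre_sd_mg)
})

test_that("a missing input file is a configuration error with no partial output", {
  gen <- withr::local_tempdir()
  spec_file <- file.path(gen, "specs.csv")
  readr::write_csv(group_spec("npw 19 to <31", n = 30, n_days = 2), spec_file)
  cmd_generate(spec_file = spec_file, seed = 6, out = gen, quiet = TRUE)
  out <- file.path(gen, "never_created")
  expect_error(
    cmd_simulate(
      recalls = file.path(gen, "recalls.csv"),
      subjects = file.path(gen, "subjects.csv"),
      flour_map = file.path(gen, "no_such_map.csv"),
      out = out, quiet = TRUE
    ),
    class = "calfort_config_error"
  )
  expect_false(dir.exists(out))
})

test_that("unknown presets are rejected by name", {
  expect_error(
    cmd_generate(preset = "atlantis-like", seed = 1, out = withr::local_tempdir()),
    "atlantis", class = "calfort_config_error"
  )
  expect_error(
    cmd_generate(seed = 1, out = withr::local_tempdir()),
    class = "calfort_config_error"
  )
})

test_that("every warning raised in a run lands in the metadata JSON", {
  specs <- group_spec("npw 19 to <31", n = 5, n_days = 1) # small n, no repeats
  co <- generate_cohort(specs, seed = 8)
  sc <- run_scenario(co$recalls, co$subjects, co$flour_map,
                     variance = variance_ratio_spec("external"), min_n = 10)
  expect_true(any(grepl("placeholder", sc$warnings)))
  expect_true(any(grepl("min_n", sc$warnings)))
  out <- withr::local_tempdir()
  write_scenario(sc, out)
  meta <- jsonlite::read_json(file.path(out, "run_metadata.json"))
  expect_setequal(unlist(meta$warnings), sc$warnings)
})

test_that("formatted results are rounded to table precision", {
  co <- small_cohort(seed = 47, n = 60)
  sc <- run_scenario(co$recalls, co$subjects, co$flour_map)
  fr <- format_results(sc)
  expect_equal(fr$pre_mean_mg, round(sc$results$pre_mean_mg, 1))
  expect_equal(fr$post_pct_below_ear, round(sc$results$post_pct_below_ear, 1))
})

test_that("scenario plots build from the stored distributions", {
  co <- small_cohort(seed = 48, n = 60)
  sc <- run_scenario(co$recalls, co$subjects, co$flour_map)
  p <- plot_scenario(sc)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gte(length(built$data), 3L)
})
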