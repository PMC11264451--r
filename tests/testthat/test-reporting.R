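make_small_report <- function() {
  ch <- simulate_cohort(sparse_scenario(), n = 220, seed = 14)
  suppressWarnings(run_cause_specific_analysis(
    ch, target_cause = 1, lambda = c(0.25, 0.08, 0.02)
  ))
}

test_that("the markdown report mirrors the cure/latency table layout", {
  rep <- make_small_report()
  md <- render_report(rep)
  expect_true(any(grepl("^# Cause-specific mixture cure analysis", md)))
  expect_true(any(grepl("^## Full model$", md)))
  expect_true(any(grepl("^## SCAD penalty$", md)))
  expect_true(any(grepl("^## LASSO penalty$", md)))
  expect_true(any(grepl("^### Cure \\(incidence\\)$", md)))
  expect_true(any(grepl("hazard \\(latency\\)$", md)))
  expect_true(any(grepl("^## Model comparison$", md)))
  # intercept row always present in the cure sections
  expect_true(sum(grepl("^\\| \\(Intercept\\)", md)) >= 3)
})

test_that("report serialization round-trips byte-identically", {
  rep <- make_small_report()
  md <- render_report(rep)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "comparison.csv")))
  core <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  expect_identical(render_report(core), md)
  expect_identical(readLines(file.path(dir, "report.md")), md)
})

test_that("the command-line front end runs its subcommands and signals
          usage errors", {
  expect_output(expect_equal(cli_main(character(0)), 2L), "usage")
  expect_output(expect_equal(cli_main("frobnicate"), 2L), "usage")
  expect_output(expect_equal(suppressMessages(cli_main(c("fit", "--oops"))),
                             2L), "usage")

  dir <- withr::local_tempdir()
  cohort_csv <- file.path(dir, "cohort.csv")
  truth_json <- file.path(dir, "truth.json")
  code <- cli_main(c("simulate", "--scenario", "sparse", "--n", "150",
                     "--seed", "7", "--out", cohort_csv,
                     "--truth-out", truth_json))
  expect_equal(code, 0L)
  expect_true(file.exists(cohort_csv))
  tj <- jsonlite::read_json(truth_json)
  expect_equal(tj$seed, 7L)

  # schema for the simulated file
  schema <- file.path(dir, "schema.yaml")
  writeLines(c(
    "time: time", "cause: cause",
    "causes: {censored: 0, event: 1}",
    paste0("covariates: {", paste0("x", 1:6, ": numeric", collapse = ", "),
           "}")
  ), schema)
  out1 <- file.path(dir, "describe")
  expect_equal(cli_main(c("describe", "--data", cohort_csv, "--config",
                          schema, "--cause", "event", "--out", out1)), 0L)
  expect_true(file.exists(file.path(out1, "km.csv")))
  expect_true(file.exists(file.path(out1, "maller_zhou.csv")))

  out2 <- file.path(dir, "fit")
  expect_equal(cli_main(c("fit", "--data", cohort_csv, "--config", schema,
                          "--cause", "event", "--nlambda", "4",
                          "--seed", "3", "--out", out2)), 0L)
  expect_true(file.exists(file.path(out2, "report.json")))

  out_md <- file.path(dir, "again.md")
  expect_equal(cli_main(c("report", "--in",
                          file.path(out2, "report.json"),
                          "--out", out_md)), 0L)
  expect_identical(readLines(out_md),
                   readLines(file.path(out2, "report.md")))

  # data/validation problems exit 1
  expect_equal(suppressMessages(
    cli_main(c("describe", "--data", file.path(dir, "missing.csv"),
               "--config", schema, "--cause", "event", "--out", out1))
  ), 1L)
})

test_that("autoplot methods return ggplot objects", {
  ch <- simulate_cohort(sparse_scenario(), n = 150, seed = 2)
  expect_s3_class(autoplot(kaplan_meier(ch, 1)), "ggplot")
  chr <- simulate_cohort(leukemia_scenario(), seed = 4)
  expect_s3_class(autoplot(aalen_johansen_cif(chr)), "ggplot")
  fit <- suppressWarnings(fit_cure_model(ch))
  expect_s3_class(autoplot(fit), "ggplot")
  tn <- suppressWarnings(tune_cure_model(ch, family = "lasso",
                                         lambda = c(0.2, 0.05)))
  expect_s3_class(autoplot(tn), "ggplot")
})
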