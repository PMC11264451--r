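test_that("CSV round-trip is the identity on validated cohorts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("months,status,mut", "5,1,1", "10,0,0", "2,2,1"), path)
  schema <- cohort_schema(
    time = "months", cause = "status",
    causes = c(censored = 0, relapse = 1, death = 2),
    covariates = list(mut = "numeric")
  )
  ch <- read_cohort(path, schema)
  expect_s3_class(ch, "cohort")
  expect_equal(nrow(ch), 3L)
  expect_equal(ch$time, c(5, 10, 2))
  expect_equal(ch$cause, c(1L, 0L, 2L))
  expect_equal(attr(ch, "covariates"), "mut")

  out <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, out)
  schema2 <- cohort_schema(
    time = "time", cause = "cause",
    causes = c(censored = 0, relapse = 1, death = 2),
    covariates = list(mut = "numeric"), id = "id"
  )
  ch2 <- read_cohort(out, schema2)
  expect_equal(tibble::as_tibble(ch2), tibble::as_tibble(ch))
})

test_that("categorical covariates expand to reference-coded indicators", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "t,ev,plt",
    "3,1,<150k", "6,0,150k-400k", "9,2,>400k", "1,1,>400k"
  ), path)
  schema <- cohort_schema(
    time = "t", cause = "ev", causes = c(censored = 0, relapse = 1, death = 2),
    covariates = list(
      plt = list(levels = c("<150k", "150k-400k", ">400k"), ref = ">400k")
    )
  )
  ch <- read_cohort(path, schema)
  covs <- attr(ch, "covariates")
  # 3 levels -> exactly 2 indicator columns
  expect_length(covs, 2L)
  # reference-level rows are the all-zeros pattern
  expect_equal(unname(rowSums(ch[covs])), c(1, 1, 0, 0))
  expect_equal(unname(unlist(ch[1, covs])), c(1, 0))
  expect_equal(unname(unlist(ch[2, covs])), c(0, 1))
  coding <- attr(ch, "coding")
  expect_equal(nrow(coding), 2L)
  expect_true(all(coding$ref == ">400k"))
})

test_that("validation rejects bad schemas, causes and times", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ev,x", "3,1,0", "6,7,1"), path)
  schema <- cohort_schema(time = "t", cause = "ev",
                          causes = c(censored = 0, relapse = 1, death = 2),
                          covariates = list(x = "numeric"))
  expect_error(read_cohort(path, schema), "unknown cause code")

  schema_bad <- cohort_schema(time = "followup", cause = "ev",
                              causes = c(censored = 0, relapse = 1),
                              covariates = list(x = "numeric"))
  expect_error(read_cohort(path, schema_bad), "schema error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ev,x", "-3,1,0"), path2)
  expect_error(read_cohort(path2, schema), "negative follow-up")

  expect_error(cohort_schema(time = "t", cause = "ev",
                             causes = c(relapse = 1),
                             covariates = list(x = "numeric")),
               "0 \\(censored\\)")
})

test_that("rows with missing values are dropped with a reported count", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ev,x", "3,1,0", "6,0,", "9,1,1"), path)
  schema <- cohort_schema(time = "t", cause = "ev",
                          causes = c(censored = 0, relapse = 1),
                          covariates = list(x = "numeric"))
  expect_message(ch <- read_cohort(path, schema), "1 row")
  expect_equal(nrow(ch), 2L)
})

test_that("cause-specific recoding follows the censoring-of-competitors rule", {
  ch <- tiny_cohort(c(5, 10, 2, 7), c(0, 1, 2, 1))
  r1 <- recode_cause_specific(ch, 1)
  expect_equal(r1$cause, c(0L, 1L, 0L, 1L))
  r2 <- recode_cause_specific(ch, 2)
  expect_equal(r2$cause, c(0L, 0L, 1L, 0L))
  # times and row count unchanged
  expect_equal(r1$time, ch$time)
  expect_equal(nrow(r2), nrow(ch))
  # labels resolve to codes
  r1b <- recode_cause_specific(ch, "event")
  expect_equal(r1b$cause, r1$cause)
  expect_error(recode_cause_specific(ch, 5), "not a declared")
  expect_error(recode_cause_specific(ch, 0), "not a declared")
})

test_that("event indicators over all target causes partition the events", {
  for (seed in 1:5) {
    ch <- random_cr_cohort(seed)
    n1 <- sum(recode_cause_specific(ch, 1)$cause)
    n2 <- sum(recode_cause_specific(ch, 2)$cause)
    expect_equal(n1 + n2, sum(ch$cause >= 1))
  }
})

test_that("an all-censored cohort is rejected by the fitters", {
  ch <- tiny_cohort(c(1, 2, 3), c(0, 2, 0), x = c(1, 0, 1))
  r <- recode_cause_specific(ch, 1)
  expect_equal(sum(r$cause), 0L)
  expect_error(fit_cure_model(r), "no events")
})

test_that("yaml schema config loads and drives read_cohort", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "time: t", "cause: ev",
    "causes:", "  censored: 0", "  relapse: 1",
    "covariates:", "  x: numeric",
    "  grp:", "    levels: [a, b]", "    ref: b"
  ), yml)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ev,x,grp", "3,relapse,0,a", "6,censored,1,b"), path)
  ch <- read_cohort(path, schema_from_yaml(yml))
  expect_equal(ch$cause, c(1L, 0L))
  expect_equal(attr(ch, "covariates"), c("x", "grp_a"))
  expect_equal(ch$grp_a, c(1, 0))
})
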