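test_that("CSV round trip preserves every field and row order", {
  co <- study_cohort(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_identical(co$participant_id, co2$participant_id)
  expect_identical(co$time_minutes, co2$time_minutes)
  expect_identical(co$eti_prior_year, co2$eti_prior_year)
  expect_identical(co$dlt_prior_year, co2$dlt_prior_year)
  expect_identical(co$completed, co2$completed)
})

test_that("ingestion errors are specific", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("participant_id,time_minutes,eti_prior_year,completed",
               "a,2.1,10,TRUE"), path)
  expect_error(read_cohort(path), "dlt_prior_year")

  writeLines(c("participant_id,time_minutes,eti_prior_year,dlt_prior_year,completed",
               "a,2.1,10,0,TRUE", "b,fast,12,0,TRUE"), path)
  expect_error(read_cohort(path), "row 2")

  writeLines(c("participant_id,time_minutes,eti_prior_year,dlt_prior_year,completed",
               "a,2.1,10,0,TRUE", "a,2.3,12,0,TRUE"), path)
  expect_error(read_cohort(path), "duplicate")

  writeLines("participant_id,time_minutes,eti_prior_year,dlt_prior_year,completed",
             path)
  expect_error(read_cohort(path), "no data rows")

  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("m:ss times are parsed to decimal minutes on ingestion", {
  expect_equal(parse_time_minutes(c("2:30", "0:45", "2.5", "10:06")),
               c(2.5, 0.75, 2.5, 10.1))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,time_minutes,eti_prior_year,dlt_prior_year,completed",
               "a,2:30,10,0,TRUE"), path)
  expect_equal(read_cohort(path)$time_minutes, 2.5)
})

test_that("experience filter retains the study-structured subset", {
  co <- make_synthetic_study_cohort()
  expect_equal(nrow(co), 52)
  expect_equal(sum(co$eti_prior_year < 5), 6)
  f <- filter_by_experience(co, 5)
  expect_equal(nrow(f), 46)
  # identity at 0, empty above the maximum, idempotence, monotonicity
  expect_equal(nrow(filter_by_experience(co, 0)), 52)
  expect_equal(nrow(filter_by_experience(co, max(co$eti_prior_year) + 1)), 0)
  ff <- as.data.frame(filter_by_experience(f, 5))
  attr(ff, "provenance") <- NULL
  fd <- as.data.frame(f)
  attr(fd, "provenance") <- NULL
  expect_identical(ff, fd)
  sizes <- vapply(c(0, 1, 5, 10, 50), function(k) {
    nrow(filter_by_experience(co, k))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("summary statistics follow the documented conventions", {
  s <- summarize_times(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sd(c(1, 2, 3, 4)))   # n-1 denominator
  # type-7 quantiles: linear interpolation at p(k) = (k-1)/(n-1)
  expect_equal(s$q25, 1.75)
  expect_equal(s$median, 2.5)
  expect_equal(s$q75, 3.25)

  s0 <- summarize_times(rep(2, 5))
  expect_equal(s0$sd, 0)
  expect_equal(s0$cv, 0)
  expect_equal(c(s0$q25, s0$median, s0$q75, s0$min, s0$max), rep(2, 5))

  expect_error(summarize_times(numeric(0)), "empty")
  expect_error(summarize_times(c(1, -2)), "positive")
})

test_that("summaries are scale equivariant with invariant CV", {
  set.seed(11)
  for (i in 1:5) {
    x <- rlnorm(30, 0.5, 0.3)
    a <- summarize_times(x)
    b <- summarize_times(10 * x)
    for (f in c("mean", "sd", "q25", "median", "q75", "min", "max")) {
      expect_equal(b[[f]], 10 * a[[f]])
    }
    expect_equal(b$cv, a$cv)
    expect_true(a$min <= a$q25 && a$q25 <= a$median &&
                a$median <= a$q75 && a$q75 <= a$max)
  }
})

test_that("cohort validation rejects malformed records", {
  df <- data.frame(participant_id = "a", time_minutes = 2.0,
                   eti_prior_year = -1L, dlt_prior_year = 0L, completed = TRUE)
  expect_error(as_cohort(df), "non-negative")
  df$eti_prior_year <- 1L
  df$time_minutes <- 0
  expect_error(as_cohort(df), "time_minutes > 0")
})
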