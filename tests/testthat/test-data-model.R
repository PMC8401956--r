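test_that("CSV round trip parses records, histories and medians", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,DV,AGE", "1,0,0,40", "1,10,1,40", "1,50,1,40",
               "1,100,0,40", "2,0,0,41", "2,80,0,41",
               "3,0,0,90", "3,60,0,90"), f)
  sch <- covariate_schema(continuous = "AGE")
  ds <- read_dataset(f, sch)
  hh <- subject_histories(ds)
  expect_length(hh, 3)
  expect_equal(hh[["1"]]$event_times, c(10, 50))
  expect_equal(hh[["1"]]$terminal_time, 100)
  expect_equal(length(hh[["2"]]$event_times), 0)
  # odd-n median over one baseline value per subject
  expect_equal(unname(compute_medians(ds, "AGE")), 41)

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f2)
  expect_identical(read_dataset(f2, sch)$records, ds$records)
})

test_that("malformed datasets are rejected with clear errors", {
  sch <- covariate_schema(continuous = "AGE")
  ok <- data.frame(ID = 1, TIME = c(0, 10), DV = c(0, 0), AGE = 40)
  expect_s3_class(rtte_data(ok, sch), "rtte_data")
  # out-of-order times
  bad <- data.frame(ID = 1, TIME = c(30, 10, 40), DV = c(0, 1, 0), AGE = 40)
  expect_error(rtte_data(bad, sch), "non-decreasing")
  # no terminal censor record
  bad <- data.frame(ID = 1, TIME = c(0, 10), DV = c(0, 1), AGE = 40)
  expect_error(rtte_data(bad, sch), "terminal")
  # negative time
  bad <- data.frame(ID = 1, TIME = c(-1, 10), DV = c(0, 0), AGE = 40)
  expect_error(rtte_data(bad, sch), "negative")
  # missing declared covariate column
  expect_error(rtte_data(data.frame(ID = 1, TIME = 0, DV = 0), sch),
               "absent")
  # medians are undefined for categorical covariates
  sch2 <- covariate_schema(categorical = "AAP")
  ds2 <- rtte_data(data.frame(ID = 1, TIME = c(0, 5), DV = c(0, 0), AAP = 1),
                   sch2)
  expect_error(compute_medians(ds2, "AAP"), "continuous")
})

test_that("covariate paths carry the last observation forward", {
  sch <- covariate_schema(categorical = "AAP")
  ds <- rtte_data(data.frame(ID = 1, TIME = c(0, 20, 60), DV = c(0, 0, 0),
                             AAP = c(0, 1, 1)), sch)
  h <- subject_histories(ds)[[1]]
  expect_equal(unname(covariate_value(h, "AAP", c(0, 19, 20, 59))),
               c(0, 0, 1, 1))
})

test_that("tied event times are perturbed and event counts are conserved", {
  sch <- covariate_schema()
  ds <- rtte_data(data.frame(ID = 1, TIME = c(0, 12, 12, 30), DV = c(0, 1, 1, 0)),
                  sch)
  h <- subject_histories(ds)[[1]]
  expect_true(all(diff(h$event_times) > 0))
  expect_equal(h$event_times[1], 12)
  expect_equal(h$event_times[2], 12 + 1e-6)

  coh <- small_cohort(n = 25, seed = 7)
  hh <- subject_histories(coh$data)
  expect_equal(sum(coh$data$records$DV == 1),
               sum(vapply(hh, function(x) length(x$event_times), numeric(1))))
})

test_that("generated cohorts pass validation and subject counts match", {
  coh <- small_cohort(n = 30, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(coh$data, f)
  ds <- read_dataset(f, coh$data$schema)
  expect_length(subject_histories(ds), 30)
})
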