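test_that("cohort marginals match the specified distributions", {
  coh <- generate_cohort(cohort_spec(n_subjects = 1000), seed = 81)
  cv <- coh$covariates
  se <- function(s) s / sqrt(1000)
  expect_lt(abs(mean(cv$AGE) - 41.4), 3 * se(12.2))
  expect_lt(abs(mean(cv$SEXF) - 0.560), 3 * se(0.5))
  expect_lt(abs(mean(cv$AAP) - 0.181), 3 * se(0.39))
  expect_true(all(cv$AGE >= 9.2 & cv$AGE <= 78.4))
  expect_true(all(cv$TDD >= 6.25 & cv$TDD <= 825))
  expect_true(all(rowSums(cv[, c("MALAY", "CHIN", "INDI")]) == 1))
  # censoring: mean 306 weeks, range within (8, 800)
  term <- coh$truth$censor_times
  expect_lt(abs(mean(term) - 306), 3 * se(210))
  expect_true(all(term > 8 & term < 800))
  # cumulative six-month dose calibrated to a median of about 34 g
  expect_lt(abs(stats::median(cv$CTDD) - 34), 3)
})

test_that("cohorts are deterministic under a seed and vary across seeds", {
  a <- generate_cohort(cohort_spec(n_subjects = 20), seed = 5)
  b <- generate_cohort(cohort_spec(n_subjects = 20), seed = 5)
  c <- generate_cohort(cohort_spec(n_subjects = 20), seed = 6)
  expect_identical(a$data$records, b$data$records)
  expect_false(identical(a$data$records, c$data$records))
})

test_that("a vanishing hazard yields an event-free cohort", {
  sp <- cohort_spec(n_subjects = 15,
                    model = hazard_model("weibull", 1e-12, 0.853, omega2 = 0))
  coh <- generate_cohort(sp, seed = 2)
  expect_equal(sum(coh$data$records$DV), 0)
  hh <- subject_histories(coh$data)
  expect_true(all(vapply(hh, function(h) length(h$event_times), numeric(1)) == 0))
})

test_that("cohort summaries cover every covariate and are duplication-stable", {
  coh <- small_cohort(n = 25, seed = 83)
  sm <- summarize_cohort(coh)
  expect_true(all(coh$data$schema$name %in% sm$characteristic))
  expect_true("Subjects with >= 1 event" %in% sm$characteristic)
  one <- generate_cohort(cohort_spec(n_subjects = 1), seed = 9)
  sm1 <- summarize_cohort(one)
  age <- as.numeric(sub(" .*", "", sm1$value[sm1$characteristic == "AGE"]))
  expect_equal(age, round(one$covariates$AGE, 1))
})

test_that("ground truth round-trips through the sidecar files", {
  coh <- small_cohort(n = 10, seed = 84)
  stem <- withr::local_tempfile()
  write_cohort(coh, stem)
  truth <- jsonlite::read_json(paste0(stem, "_truth.json"),
                               simplifyVector = TRUE)
  expect_true(truth$synthetic)
  expect_equal(truth$model$theta1, 0.0022)
  expect_equal(truth$eta, coh$truth$eta)
  ds <- read_dataset(paste0(stem, ".csv"), coh$data$schema)
  expect_equal(nrow(ds$records), nrow(coh$data$records))
})
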