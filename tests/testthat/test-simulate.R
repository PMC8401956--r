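test_that("simulated event histories respect basic process properties", {
  m <- hazard_model("weibull", 1e-12, 0.853)
  expect_length(simulate_subject(m, terminal_time = 800), 0)

  set.seed(55)
  m <- hazard_model("weibull", 0.01, 0.5)
  for (i in 1:20) {
    ev <- simulate_subject(m, terminal_time = 300)
    expect_true(all(ev > 0 & ev <= 300))
    expect_true(all(diff(ev) > 0))
  }
  expect_error(
    simulate_subject(hazard_model("constant", 5), terminal_time = 1e4,
                     max_events = 100),
    "max_events")
})

test_that("constant-hazard counts are Poisson with mean lambda*T", {
  set.seed(66)
  lam <- 0.1; Tc <- 100; n <- 2000
  m <- hazard_model("constant", lam)
  cnt <- vapply(seq_len(n), function(i)
    length(simulate_subject(m, terminal_time = Tc)), numeric(1))
  mc_se <- sqrt(lam * Tc / n)
  expect_lt(abs(mean(cnt) - lam * Tc), 3 * mc_se)
})

test_that("inverse-transform sampler agrees with a thinning oracle", {
  set.seed(88)
  m <- hazard_model("weibull", 0.0022, 0.853,
                    effects = list(covariate_effect("AAP", 1.39, 0)))
  cov <- c(AAP = 1)
  path <- data.frame(time = 0, AAP = 1)
  n <- 800
  first1 <- vapply(seq_len(n), function(i) {
    ev <- simulate_subject(m, path, terminal_time = 400)
    if (length(ev)) ev[1] else NA_real_
  }, numeric(1))
  first2 <- vapply(seq_len(n), function(i) {
    ev <- sim_thinning(m, 400, cov = cov)
    if (length(ev)) ev[1] else NA_real_
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(stats::na.omit(first1),
                                        stats::na.omit(first2)))
  expect_gt(ks$p.value, 0.001)
})

test_that("first-event times follow the analytic survival function", {
  # median first-event time under the published parameters matches the
  # numerical inversion of S(t) = 0.5
  set.seed(99)
  m <- hazard_model("weibull", 0.0022, 0.853)
  n <- 4000
  first <- vapply(seq_len(n), function(i) {
    ev <- simulate_subject(m, terminal_time = 2000)
    if (length(ev)) ev[1] else NA_real_
  }, numeric(1))
  med_obs <- stats::median(first, na.rm = TRUE)
  med_true <- stats::uniroot(function(t) survival_prob(m, t) - 0.5,
                             c(1, 500))$root
  # MC error on the sample median: ~1/(2 f(med) sqrt(n))
  dens <- hazard(m, med_true) * 0.5
  expect_lt(abs(med_obs - med_true), 3 / (2 * dens * sqrt(n)))
})

test_that("product-limit estimator matches closed forms and survfit", {
  h1 <- make_hist(1, 1); h2 <- make_hist(2, 2)
  km <- kaplan_meier(list(h1, h2))
  expect_equal(km$steps$surv, c(0.5, 0))
  expect_equal(km_at(km, c(0.5, 1.5, 2.5)), c(1, 0.5, 0))

  cens <- list(make_hist(numeric(0), 5), make_hist(numeric(0), 8))
  km2 <- kaplan_meier(cens)
  expect_equal(nrow(km2$steps), 0)
  expect_equal(km_at(km2, c(1, 10)), c(1, 1))
  expect_equal(km2$censor_times, c(5, 8))
  expect_error(kaplan_meier(list()), "empty")

  skip_if_not_installed("survival")
  set.seed(111)
  tt <- round(rexp(40, 0.05), 1); ev <- runif(40) < 0.6
  hh <- lapply(seq_along(tt), function(i)
    make_hist(if (ev[i]) tt[i] else numeric(0), tt[i]))
  km3 <- kaplan_meier(hh)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(km3$steps$time, sf$time[sf$n.event > 0])
  expect_equal(km3$steps$surv, sf$surv[sf$n.event > 0], tolerance = 1e-12)
})

test_that("second-event curves sit below first-event curves", {
  coh <- small_cohort(n = 50, seed = 13)
  hh <- subject_histories(coh$data)
  k1 <- kaplan_meier(hh, event_number = 1)
  k2 <- kaplan_meier(hh, event_number = 2)
  grid <- seq(0, 400, by = 10)
  expect_true(all(km_at(k2, grid) >= km_at(k1, grid) - 1e-12))
})
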