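test_that("conditional subject log-likelihood matches closed forms", {
  cst <- hazard_model("constant", theta1 = 0.5)
  expect_equal(subject_loglik(cst, make_hist(numeric(0), 2)), -1)
  expect_equal(subject_loglik(cst, make_hist(1, 2)), log(0.5) - 1)
  # frailty shifts the event terms linearly and the hazard exponentially
  h <- make_hist(c(1, 1.5), 2)
  expect_equal(subject_loglik(cst, h, eta = 0.4),
               2 * log(0.5) + 2 * 0.4 - exp(0.4) * 1)
})

test_that("log-likelihood with covariates matches a quadrature oracle", {
  m <- hazard_model("weibull", 0.0022, 0.853,
                    effects = list(covariate_effect("AGE", -0.0438, 41),
                                   covariate_effect("AAP", 1.39, 0)),
                    omega2 = 0)
  cov <- c(AGE = 30, AAP = 1)
  h <- make_hist(c(20, 90), 300, cov = cov)
  manual <- log(hazard(m, 20, cov)) + log(hazard(m, 90, cov)) -
    quad_cumhaz(m, 0, 300, cov)
  expect_equal(subject_loglik(m, h), manual, tolerance = 1e-8)
})

test_that("likelihood splits the integral at covariate change points", {
  sch <- covariate_schema(categorical = "AAP")
  ds <- rtte_data(data.frame(ID = 1, TIME = c(0, 40, 120), DV = c(0, 1, 0),
                             AAP = c(0, 1, 1)), sch)
  h <- subject_histories(ds)[[1]]
  m <- hazard_model("weibull", 0.002, 0.8,
                    effects = list(covariate_effect("AAP", 1.39, 0)))
  # event at 40 happens with AAP = 1 (record value at the event time)
  manual <- log(hazard(m, 40, c(AAP = 1))) -
    quad_cumhaz(m, 0, 40, c(AAP = 0)) - quad_cumhaz(m, 40, 120, c(AAP = 1))
  expect_equal(subject_loglik(m, h), manual, tolerance = 1e-8)
})

test_that("Laplace marginal agrees with 64-node Gauss-Hermite quadrature", {
  expect_equal(
    laplace_marginal(hazard_model("constant", 0.5, omega2 = 0),
                     make_hist(1, 2)),
    subject_loglik(hazard_model("constant", 0.5), make_hist(1, 2)))
  set.seed(202)
  for (i in 1:20) {
    w2 <- runif(1, 0.05, 2)
    fam <- sample(c("constant", "weibull"), 1)
    m <- hazard_model(fam, theta1 = exp(runif(1, -6, -2)),
                      theta2 = if (fam == "weibull") runif(1, 0, 1.5),
                      omega2 = w2)
    Tc <- runif(1, 50, 500)
    nev <- sample(0:5, 1)
    h <- make_hist(sort(runif(nev, 1, Tc)), Tc)
    # the Laplace method's intrinsic error grows with the frailty
    # variance; at omega2 near 2 it is of order 1e-2 in log-likelihood
    expect_equal(laplace_marginal(m, h), gh_marginal(m, h),
                 tolerance = 0.02)
    expect_lte(laplace_marginal(m, make_hist(numeric(0), Tc)), 0)
  }
})

test_that("OFV is additive, order-invariant and minimal near the truth", {
  ds1 <- toy_ds()
  m0 <- hazard_model("constant", 0.02, omega2 = 0)
  expect_equal(total_ofv(m0, ds1),
               -2 * subject_loglik(m0, subject_histories(ds1)[[1]]))
  # duplicated subjects double the OFV exactly
  rec <- ds1$records
  rec2 <- rbind(rec, transform(rec, ID = 2))
  ds2 <- rtte_data(rec2, ds1$schema)
  m <- hazard_model("constant", 0.02, omega2 = 0.5)
  expect_equal(total_ofv(m, ds2), 2 * total_ofv(m, ds1))
  # subject order does not matter
  coh <- small_cohort(n = 20, seed = 9)
  rec <- coh$data$records
  ids <- unique(rec$ID)
  perm <- do.call(rbind, lapply(rev(ids), function(i) rec[rec$ID == i, ]))
  dsp <- rtte_data(perm, coh$data$schema)
  mm <- reference_model()
  expect_equal(total_ofv(mm, dsp), total_ofv(mm, coh$data))
  # time rescaling t -> ct with lambda -> lambda/c shifts the OFV by the
  # analytic Jacobian term 2 * n_events * log(c) (constant hazard)
  cfac <- 2
  rec_c <- transform(coh$data$records, TIME = TIME * cfac)
  dsc <- rtte_data(rec_c, coh$data$schema)
  lam <- 0.01
  mc1 <- hazard_model("constant", lam, omega2 = 0.3)
  mc2 <- hazard_model("constant", lam / cfac, omega2 = 0.3)
  nev <- sum(coh$data$records$DV)
  expect_equal(total_ofv(mc2, dsc), total_ofv(mc1, coh$data) +
                 2 * nev * log(cfac), tolerance = 1e-8)
  # OFV at the generating parameters beats a doubled scale parameter
  mm2 <- mm; mm2$theta1 <- mm$theta1 * 2
  expect_lt(total_ofv(mm, coh$data), total_ofv(mm2, coh$data))
})

test_that("maximum likelihood recovers a constant hazard without frailty", {
  set.seed(77)
  lam <- 0.05; n <- 200
  recs <- lapply(seq_len(n), function(i) {
    Tc <- runif(1, 20, 120)
    ev <- sort(runif(rpois(1, lam * Tc), 0, Tc))
    data.frame(ID = i, TIME = c(0, ev, Tc), DV = c(0, rep(1, length(ev)), 0))
  })
  ds <- rtte_data(do.call(rbind, recs), covariate_schema())
  f <- fit_rtte(fit_spec("constant", frailty = FALSE), ds)
  expect_true(f$converged)
  mc_se <- lam / sqrt(sum(ds$records$DV))   # Poisson-count information
  expect_lt(abs(f$model$theta1 - lam), 3 * mc_se)
  # two different starts land on the same optimum
  f2 <- fit_rtte(fit_spec("constant", frailty = FALSE), ds,
                 start = hazard_model("constant", 0.5))
  expect_lt(abs(f$ofv - f2$ofv), 0.01)
})

test_that("fit reporting transforms are internally consistent", {
  coh <- small_cohort(n = 40, seed = 12)
  f <- fit_rtte(fit_spec("weibull", covariates = c("AGE", "AAP"),
                         centers = c(AGE = 41)), coh$data)
  tab <- f$table
  expect_true(f$converged)
  expect_true(all(tab$rse >= 0))
  age <- tab[tab$parameter == "AGE", ]
  expect_equal(age$ahr, exp(age$estimate))
  expect_equal(age$ahr_lo, exp(age$estimate - 1.96 * age$se))
  iiv <- tab[tab$parameter == "IIV_pct", ]
  expect_equal(iiv$estimate, 100 * sqrt(f$model$omega2))
  # refit from the truth reaches an OFV at least as good (within tolerance)
  f3 <- fit_rtte(fit_spec("weibull", covariates = c("AGE", "AAP"),
                          centers = c(AGE = 41)), coh$data,
                 start = reference_model())
  expect_lt(abs(f3$ofv - f$ofv), 0.01)
})
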