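test_that("hazard families evaluate their closed forms", {
  wb <- hazard_model("weibull", theta1 = 0.0022, theta2 = 0.853)
  expect_equal(hazard(wb, 0), 0)            # Weibull hazard vanishes at t = 0
  expect_equal(hazard(wb, 1), 0.0022)       # 1^theta2 = 1
  cst <- hazard_model("constant", theta1 = 0.5)
  expect_equal(hazard(cst, c(0, 7, 1e3)), rep(0.5, 3))
  expect_equal(survival_prob(hazard_model("constant", 0.01), 100),
               exp(-1))
  expect_error(hazard(wb, -1), ">= 0")
  gz <- hazard_model("gompertz", theta1 = 0.01, theta2 = 0.002)
  expect_equal(hazard(gz, 100), 0.01 * exp(0.2))
})

test_that("cumulative hazard matches adaptive quadrature across families", {
  set.seed(101)
  for (i in 1:25) {
    fam <- sample(c("constant", "gompertz", "weibull"), 1)
    th2 <- switch(fam, constant = NULL, gompertz = runif(1, -0.02, 0.02),
                  weibull = runif(1, -0.9, 2))
    m <- hazard_model(fam, theta1 = exp(runif(1, -7, -1)), theta2 = th2,
                      effects = list(covariate_effect("X", runif(1, -1, 1),
                                                      center = 0.5)),
                      omega2 = 0)
    cov <- c(X = runif(1))
    eta <- rnorm(1, 0, 0.7)
    tt <- sort(runif(2, 0.01, 400))
    expect_equal(cumulative_hazard(m, tt[1], tt[2], cov = cov, eta = eta),
                 quad_cumhaz(m, tt[1], tt[2], cov = cov, eta = eta),
                 tolerance = 1e-6)
  }
  # degenerate cases
  m <- hazard_model("weibull", 0.1, 0.5)
  expect_equal(cumulative_hazard(m, 30, 30), 0)
  expect_error(cumulative_hazard(m, 10, 5), ">=")
})

test_that("gompertz shape tends continuously to the constant hazard", {
  near <- hazard_model("gompertz", theta1 = 0.05, theta2 = 1e-12)
  flat <- hazard_model("constant", theta1 = 0.05)
  expect_equal(cumulative_hazard(near, 0, 250), cumulative_hazard(flat, 0, 250),
               tolerance = 1e-9)
})

test_that("frailty and centered covariates factorize exactly", {
  m <- hazard_model("weibull", 0.003, 0.9,
                    effects = list(covariate_effect("AGE", -0.04, center = 41)),
                    omega2 = 1)
  t <- c(1, 10, 100)
  expect_equal(hazard(m, t, cov = c(AGE = 30), eta = 1.3),
               exp(1.3) * hazard(m, t, cov = c(AGE = 30), eta = 0),
               tolerance = 1e-14)
  # covariate at its center contributes a factor of exactly 1
  expect_identical(hazard(m, t, cov = c(AGE = 41)),
                   0.003 * t^0.9)
  expect_error(hazard(m, 1, cov = c(BMI = 20)), "missing covariate")
})

test_that("survival is a proper monotone survival function", {
  m <- hazard_model("weibull", 0.0022, 0.853)
  tt <- seq(0, 800, by = 5)
  s <- survival_prob(m, tt)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 0))
  expect_lt(survival_prob(m, 1e5), 1e-12)
})

test_that("hazard ratios reproduce the exponential transform", {
  expect_equal(hazard_ratio(1.39), 4.01, tolerance = 5e-3)
  expect_equal(round(hazard_ratio(-0.0438), 2), 0.96)
  expect_equal(hazard_ratio(covariate_effect("AAP", 1.39)), exp(1.39))
  expect_equal(hazard_ratio(123, delta = 0), 1)
})
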