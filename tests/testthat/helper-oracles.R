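# Shared fixtures and independent oracles used across the suite.

# Single-subject toy dataset: improvement events at 10 and 50 weeks,
# censored at 100 weeks, no covariates.
toy_ds <- function() {
  rtte_data(data.frame(ID = 1, TIME = c(10, 50, 100), DV = c(1, 1, 0)),
            covariate_schema())
}

# Build a subject_history directly from event times and a censoring time,
# optionally with a static covariate row.
make_hist <- function(event_times, terminal, cov = NULL) {
  covm <- if (is.null(cov))
            matrix(numeric(0), 1, 0, dimnames = list(NULL, character(0)))
          else matrix(cov, 1, dimnames = list(NULL, names(cov)))
  structure(list(subject_id = "t1", event_times = event_times,
                 terminal_time = terminal, cov_times = 0,
                 cov_values = covm),
            class = "subject_history")
}

# Cumulative hazard by adaptive numerical quadrature of the hazard.
quad_cumhaz <- function(model, t0, t1, cov = NULL, eta = 0) {
  stats::integrate(function(u) hazard(model, u, cov = cov, eta = eta),
                   t0, t1, rel.tol = 1e-10, abs.tol = 0)$value
}

# Marginal log-likelihood by 64-node adaptive Gauss-Hermite quadrature,
# centered at the mode found by golden-section search (independent of the
# package's Newton-based Laplace path).
gh_marginal <- function(model, hist, n = 64) {
  w2 <- model$omega2
  joint <- function(eta) subject_loglik(model, hist, eta) +
    stats::dnorm(eta, 0, sqrt(w2), log = TRUE)
  mode <- stats::optimize(joint, c(-15, 15), maximum = TRUE)$maximum
  h <- 1e-4
  curv <- (joint(mode + h) - 2 * joint(mode) + joint(mode - h)) / h^2
  sig <- 1 / sqrt(-curv)
  gh <- pracma::gaussHermite(n)
  eta <- mode + sqrt(2) * sig * gh$x
  lg <- vapply(eta, joint, numeric(1)) + gh$x^2
  m <- max(lg)
  m + log(sum(gh$w * exp(lg - m))) + log(sqrt(2) * sig)
}

# Thinning (rejection) sampler for the nonhomogeneous Poisson process with
# a monotone hazard on (0, horizon]; independent of the package's
# inverse-transform sampler.
sim_thinning <- function(model, horizon, cov = NULL, eta = 0) {
  hmax <- max(hazard(model, c(horizon, 1e-6, horizon / 2), cov = cov,
                     eta = eta)) * 1.0000001
  t <- 0; out <- numeric(0)
  repeat {
    t <- t + stats::rexp(1, hmax)
    if (t > horizon) break
    if (stats::runif(1) < hazard(model, t, cov = cov, eta = eta) / hmax)
      out <- c(out, t)
  }
  out
}

# Small synthetic cohort for module-level tests (full study conditions are
# exercised in the acceptance suite).
small_cohort <- function(n = 60, seed = 42) {
  generate_cohort(cohort_spec(n_subjects = n), seed = seed)
}
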