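## Recurrent-event likelihood.
##
## Each subject is continuously at risk of improvement events from first dose
## until censoring, so conditional on the frailty eta the event history is a
## nonhomogeneous Poisson process on calendar time with intensity
## h(t | cov(t), eta). The conditional log-likelihood is
##     sum_j log h(t_j) - int_0^T h(u) du,
## with the covariate path piecewise constant between records (the integral
## splits into covariate-constant segments with closed-form cumulative
## hazard). Because eta enters multiplicatively, the conditional
## log-likelihood reduces to S0 + n*eta - exp(eta)*H0 where S0 and H0 are the
## eta = 0 event-term sum and cumulative hazard: the frailty integral is then
## one-dimensional per subject and its Laplace mode has a strictly concave
## objective, so the inner Newton search is globally convergent.

EVENT_TIME_CLAMP <- 1e-6   # events at recorded time 0 are moved here

## Breakpoints of the piecewise-constant covariate path: only the record
## times at which some covariate actually changes (plus 0 and the terminal
## time). Subjects with static covariates collapse to a single segment.
covariate_breaks <- function(hist) {
  ct <- hist$cov_times
  keep <- if (nrow(hist$cov_values) > 1L)
    c(TRUE, rowSums(abs(diff(hist$cov_values))) > 0) else TRUE
  brk <- ct[keep]
  sort(unique(c(0, brk[brk > 0 & brk < hist$terminal_time],
                hist$terminal_time)))
}

## S0, H0 and event count for one subject history under a model (eta = 0).
subject_parts <- function(model, hist) {
  stopifnot(inherits(model, "hazard_model"), inherits(hist, "subject_history"))
  ev <- pmax(hist$event_times, EVENT_TIME_CLAMP)
  if (any(ev > hist$terminal_time + 1e-9))
    stop("event time after terminal time for subject ", hist$subject_id)
  nm <- model$effects$name
  S0 <- 0
  if (length(ev)) {
    idx <- pmax(findInterval(ev + 1e-12, hist$cov_times), 1L)
    covm <- hist$cov_values[idx, nm, drop = FALSE]
    h <- model$theta1 * baseline_g(model$family, model$theta2, ev) *
      effect_multiplier(model$effects, covm)
    if (any(!is.finite(h)) || any(h <= 0))
      stop("non-finite or zero hazard at an event time for subject ",
           hist$subject_id)
    S0 <- sum(log(h))
  }
  ## covariate-constant segments of (0, T]
  brk <- covariate_breaks(hist)
  a <- brk[-length(brk)]; b <- brk[-1]
  idx <- pmax(findInterval(a + 1e-12, hist$cov_times), 1L)
  covm <- hist$cov_values[idx, nm, drop = FALSE]
  mult <- effect_multiplier(model$effects, covm)
  if (length(mult) == 1L) mult <- rep(mult, length(a))
  dG <- baseline_G(model$family, model$theta2, b) -
        baseline_G(model$family, model$theta2, a)
  H0 <- model$theta1 * sum(mult * dG)
  list(S0 = S0, H0 = H0, n = length(ev))
}

#' Conditional subject log-likelihood
#'
#' Nonhomogeneous-Poisson (counting process) log-likelihood of one subject's
#' recurrent-event history, conditional on the frailty deviate `eta`:
#' sum of log-hazards at the event times minus the cumulative hazard over
#' the whole follow-up, with the covariate path carried forward between
#' records.
#'
#' @param model a [hazard_model()].
#' @param hist a `subject_history` (see [subject_histories()]).
#' @param eta frailty deviate.
#' @return log-likelihood (finite for valid inputs).
#' @export
subject_loglik <- function(model, hist, eta = 0) {
  p <- subject_parts(model, hist)
  p$S0 + p$n * eta - exp(eta) * p$H0
}

## Vectorized Newton search for the frailty mode:
## maximize  n*eta - exp(eta)*H - eta^2/(2 w2)  over eta (per subject).
## The objective is strictly concave; steps are damped for safety.
solve_eta_mode <- function(n, H, omega2, tol = 1e-10, maxit = 100L) {
  eta <- numeric(length(n))
  for (it in seq_len(maxit)) {
    g <- n - exp(eta) * H - eta / omega2
    if (all(abs(g) < tol)) break
    hss <- -exp(eta) * H - 1 / omega2
    step <- -g / hss
    step <- pmin(pmax(step, -5), 5)
    eta <- eta + step
  }
  if (any(abs(n - exp(eta) * H - eta / omega2) > 1e-6))
    stop("frailty mode search failed to converge")
  eta
}

## Laplace marginal log-likelihood from (S0, H0, n) vectors.
laplace_from_parts <- function(S0, H0, n, omega2) {
  if (omega2 == 0) return(list(marginal = S0 - H0, eta = rep(0, length(n))))
  eta <- solve_eta_mode(n, H0, omega2)
  curv <- exp(eta) * H0 + 1 / omega2         # -d2 joint / d eta2
  marg <- S0 + n * eta - exp(eta) * H0 - eta^2 / (2 * omega2) -
    0.5 * log(omega2) - 0.5 * log(curv)
  list(marginal = marg, eta = eta)
}

#' Laplace-approximated marginal subject log-likelihood
#'
#' Integrates the conditional likelihood over the frailty distribution
#' eta ~ Normal(0, omega2) by Laplace approximation: the joint log-density
#' is maximized over eta by a damped Newton search (the objective is
#' strictly concave) and expanded to second order at the mode. For
#' `omega2 = 0` this degenerates to [subject_loglik()] at `eta = 0`.
#'
#' @inheritParams subject_loglik
#' @return marginal log-likelihood.
#' @export
laplace_marginal <- function(model, hist) {
  p <- subject_parts(model, hist)
  laplace_from_parts(p$S0, p$H0, p$n, model$omega2)$marginal
}

## ---- dataset-level likelihood context --------------------------------------
## Sufficient statistics that do not depend on the parameters: per subject the
## event count, sum of log event times and of event times, per-covariate sums
## over events, and the covariate-constant segments of the follow-up. Every
## OFV evaluation is then O(subjects + segments) regardless of event count.
ll_context <- function(ds) {
  stopifnot(inherits(ds, "rtte_data"))
  hists <- subject_histories(ds)
  covn <- ds$schema$name
  ns <- length(hists)
  n <- integer(ns); slt <- numeric(ns); st <- numeric(ns)
  Tcens <- numeric(ns)
  evX <- matrix(0, ns, length(covn), dimnames = list(NULL, covn))
  seg_subj <- list(); seg_a <- list(); seg_b <- list(); seg_X <- list()
  for (i in seq_len(ns)) {
    h <- hists[[i]]
    ev <- pmax(h$event_times, EVENT_TIME_CLAMP)
    n[i] <- length(ev)
    Tcens[i] <- h$terminal_time
    if (n[i]) {
      slt[i] <- sum(log(ev)); st[i] <- sum(ev)
      idx <- pmax(findInterval(ev + 1e-12, h$cov_times), 1L)
      evX[i, ] <- colSums(h$cov_values[idx, covn, drop = FALSE])
    }
    brk <- covariate_breaks(h)
    a <- brk[-length(brk)]; b <- brk[-1]
    idx <- pmax(findInterval(a + 1e-12, h$cov_times), 1L)
    seg_subj[[i]] <- rep(i, length(a)); seg_a[[i]] <- a; seg_b[[i]] <- b
    seg_X[[i]] <- h$cov_values[idx, covn, drop = FALSE]
  }
  list(ids = vapply(hists, `[[`, "", "subject_id"),
       n = n, sum_log_t = slt, sum_t = st, ev_X = evX,
       terminal = Tcens, n_subj = ns, covnames = covn,
       seg_subj = unlist(seg_subj), seg_a = unlist(seg_a),
       seg_b = unlist(seg_b), seg_X = do.call(rbind, seg_X))
}

## Marginal log-likelihood vector from a context.
ctx_marginal <- function(ctx, family, theta1, theta2, beta, centers, omega2) {
  shape_term <- switch(family,
    constant = 0,
    weibull  = theta2 * ctx$sum_log_t,
    gompertz = theta2 * ctx$sum_t)
  S0 <- ctx$n * log(theta1) + shape_term
  seg_lin <- 0
  if (length(beta)) {
    nm <- names(beta)
    S0 <- S0 + drop(ctx$ev_X[, nm, drop = FALSE] %*% beta) -
      ctx$n * sum(beta * centers[nm])
    seg_lin <- drop(sweep(ctx$seg_X[, nm, drop = FALSE], 2, centers[nm]) %*% beta)
  }
  dG <- baseline_G(family, theta2, ctx$seg_b) -
        baseline_G(family, theta2, ctx$seg_a)
  H0 <- theta1 * as.numeric(
    rowsum(exp(seg_lin) * dG, ctx$seg_subj, reorder = TRUE))
  laplace_from_parts(S0, H0, ctx$n, omega2)
}

#' Total objective function value (OFV)
#'
#' -2 times the sum over subjects of the Laplace-approximated marginal
#' log-likelihood. Differences in OFV between nested models are the
#' likelihood-ratio statistic; absolute OFVs keep all normalizing constants.
#'
#' @param model a [hazard_model()].
#' @param ds an [rtte_data()].
#' @return objective function value (scalar).
#' @export
total_ofv <- function(model, ds) {
  ctx <- ll_context(ds)
  beta <- stats::setNames(model$effects$theta, model$effects$name)
  centers <- stats::setNames(model$effects$center, model$effects$name)
  th2 <- if (is.null(model$theta2)) 0 else model$theta2
  -2 * sum(ctx_marginal(ctx, model$family, model$theta1, th2,
                        beta, centers, model$omega2)$marginal)
}
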