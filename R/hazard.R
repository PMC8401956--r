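#' Parametric hazard model with covariate effects and frailty
#'
#' Constructs a hazard model for repeated time-to-event analysis. Three
#' baseline families are supported, all parameterized by a scale `theta1`
#' (hazard per week) and, for the time-varying families, a shape `theta2`:
#'
#' * `constant`:  h(t) = theta1
#' * `gompertz`:  h(t) = theta1 * exp(theta2 * t)
#' * `weibull`:   h(t) = theta1 * t^theta2
#'
#' Covariates act multiplicatively through an exponential model,
#' exp(sum theta_cov * (cov - center)), with continuous covariates centered
#' at their cohort median and categorical covariates centered at 0. A
#' subject-level frailty eta ~ Normal(0, omega2) multiplies the hazard by
#' exp(eta), so the subject-specific scale is theta1 * exp(eta).
#'
#' @param family one of `"constant"`, `"gompertz"`, `"weibull"`.
#' @param theta1 scale parameter (> 0), hazard per week.
#' @param theta2 shape parameter; ignored for `constant`. For `weibull`,
#'   must be > -1 so the cumulative hazard is finite near zero.
#' @param effects list of [covariate_effect()] objects (or a data.frame with
#'   columns `name`, `theta`, `center`).
#' @param omega2 frailty variance (>= 0).
#' @return an object of class `hazard_model`.
#' @examples
#' m <- hazard_model("weibull", theta1 = 0.0022, theta2 = 0.853,
#'                   effects = list(covariate_effect("AGE", -0.0438, 41)),
#'                   omega2 = 1.02)
#' hazard(m, t = 52, cov = c(AGE = 41))
#' @export
hazard_model <- function(family = c("weibull", "gompertz", "constant"),
                         theta1, theta2 = NULL, effects = list(),
                         omega2 = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(theta1), length(theta1) == 1L, is.finite(theta1))
  if (theta1 <= 0) stop("`theta1` must be > 0")
  if (family == "constant") {
    theta2 <- NULL
  } else {
    if (is.null(theta2)) stop("`theta2` is required for family '", family, "'")
    stopifnot(is.numeric(theta2), length(theta2) == 1L, is.finite(theta2))
    if (family == "weibull" && theta2 <= -1)
      stop("weibull shape `theta2` must be > -1")
  }
  if (!is.numeric(omega2) || length(omega2) != 1L || omega2 < 0)
    stop("`omega2` must be a single non-negative number")
  effects <- as_effects(effects)
  structure(list(family = family, theta1 = theta1, theta2 = theta2,
                 effects = effects, omega2 = omega2),
            class = "hazard_model")
}

#' Covariate effect on the hazard
#'
#' @param name covariate name (must match a dataset column).
#' @param theta coefficient on the log-hazard scale, per covariate unit.
#' @param center centering value: the cohort median for continuous
#'   covariates, 0 for categorical ones.
#' @return a one-row data.frame with columns `name`, `theta`, `center`.
#' @export
covariate_effect <- function(name, theta, center = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(theta), length(theta) == 1L,
            is.numeric(center), length(center) == 1L)
  data.frame(name = name, theta = theta, center = center,
             stringsAsFactors = FALSE)
}

as_effects <- function(effects) {
  if (is.data.frame(effects)) {
    stopifnot(all(c("name", "theta", "center") %in% names(effects)))
    eff <- effects[c("name", "theta", "center")]
  } else if (is.list(effects)) {
    eff <- if (length(effects)) do.call(rbind, effects) else
      data.frame(name = character(), theta = numeric(), center = numeric())
  } else stop("`effects` must be a list of covariate_effect() or a data.frame")
  if (anyDuplicated(eff$name)) stop("covariate effect names must be unique")
  rownames(eff) <- NULL
  eff
}

#' @export
print.hazard_model <- function(x, ...) {
  shape <- if (is.null(x$theta2)) "" else sprintf(", theta2 = %g", x$theta2)
  cat(sprintf("<hazard_model> %s: theta1 = %g%s, omega2 = %g\n",
              x$family, x$theta1, shape, x$omega2))
  if (nrow(x$effects)) {
    cat("covariate effects:\n")
    print(x$effects, row.names = FALSE)
  }
  invisible(x)
}

## Baseline time course g(t) (h(t) = theta1 * g(t) * covariate/frailty terms),
## its integral G(t) = int_0^t g, and the inverse of G. Closed forms exist for
## all three families, which the simulator and likelihood rely on.
baseline_g <- function(family, theta2, t) {
  switch(family,
    constant = rep(1, length(t)),
    gompertz = exp(theta2 * t),
    weibull  = {
      out <- t^theta2
      if (theta2 > 0) out[t == 0] <- 0
      if (theta2 == 0) out[t == 0] <- 1
      if (theta2 < 0 && any(t == 0))
        stop("weibull hazard diverges at t = 0 for theta2 < 0")
      out
    })
}

baseline_G <- function(family, theta2, t) {
  switch(family,
    constant = t,
    gompertz = if (abs(theta2) < 1e-12) t * (1 + theta2 * t / 2)
               else expm1(theta2 * t) / theta2,
    weibull  = t^(theta2 + 1) / (theta2 + 1))
}

baseline_Ginv <- function(family, theta2, G) {
  switch(family,
    constant = G,
    gompertz = if (abs(theta2) < 1e-12) G * (1 - theta2 * G / 2)
               else log1p(theta2 * G) / theta2,
    weibull  = ((theta2 + 1) * G)^(1 / (theta2 + 1)))
}

## exp(sum theta_k (cov_k - center_k)); `cov` is a named vector or a matrix
## with covariates in columns. Returns scalar or one value per row.
effect_multiplier <- function(effects, cov) {
  if (!nrow(effects)) return(1)
  if (is.null(cov)) stop("model has covariate effects but `cov` is missing")
  if (is.matrix(cov) || is.data.frame(cov)) {
    miss <- setdiff(effects$name, colnames(cov))
    if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
    x <- as.matrix(cov[, effects$name, drop = FALSE])
    exp(drop(sweep(x, 2, effects$center) %*% effects$theta))
  } else {
    miss <- setdiff(effects$name, names(cov))
    if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
    exp(sum(effects$theta * (cov[effects$name] - effects$center)))
  }
}

#' Hazard rate
#'
#' Evaluates h(t) = theta1 * exp(eta) * g(t; theta2) *
#' exp(sum theta_cov (cov - center)), in events per week.
#'
#' @param model a [hazard_model()].
#' @param t time(s) in weeks since first dose (>= 0); vectorized.
#' @param cov named numeric vector of covariate values (required when the
#'   model carries covariate effects).
#' @param eta frailty deviate (0 = typical subject).
#' @return hazard rate(s), per week.
#' @export
hazard <- function(model, t, cov = NULL, eta = 0) {
  stopifnot(inherits(model, "hazard_model"))
  if (any(t < 0)) stop("`t` must be >= 0")
  model$theta1 * exp(eta) * baseline_g(model$family, model$theta2, t) *
    effect_multiplier(model$effects, cov)
}

#' Cumulative hazard over an interval
#'
#' Closed-form integral of [hazard()] from `t0` to `t1` (dimensionless).
#'
#' @inheritParams hazard
#' @param t0,t1 interval bounds in weeks, 0 <= t0 <= t1.
#' @export
cumulative_hazard <- function(model, t0, t1, cov = NULL, eta = 0) {
  stopifnot(inherits(model, "hazard_model"))
  if (any(t0 < 0)) stop("`t0` must be >= 0")
  if (any(t1 < t0)) stop("`t1` must be >= `t0`")
  dG <- baseline_G(model$family, model$theta2, t1) -
        baseline_G(model$family, model$theta2, t0)
  model$theta1 * exp(eta) * effect_multiplier(model$effects, cov) * dG
}

#' Survival function
#'
#' S(t) = exp(-cumulative hazard over (0, t]): the probability of not
#' experiencing a (first) improvement event by time `t`.
#'
#' @inheritParams hazard
#' @export
survival_prob <- function(model, t, cov = NULL, eta = 0) {
  exp(-cumulative_hazard(model, 0, t, cov = cov, eta = eta))
}

#' Hazard ratio for a covariate effect
#'
#' exp(theta * delta): the multiplicative change in hazard for a `delta`-unit
#' increase in the covariate (e.g. the adjusted hazard ratio for delta = 1).
#'
#' @param effect a [covariate_effect()] (or a bare coefficient).
#' @param delta change in covariate units.
#' @export
hazard_ratio <- function(effect, delta = 1) {
  theta <- if (is.data.frame(effect)) effect$theta else effect
  exp(theta * delta)
}
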