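#' Fit specification
#'
#' Describes one model to estimate: the baseline hazard family, the
#' covariate effects to include, whether a frailty variance is estimated,
#' and optional fixed centering constants.
#'
#' @param family baseline family: `"weibull"`, `"gompertz"` or `"constant"`.
#' @param covariates character vector of covariate names to include as
#'   exponential effects on the hazard.
#' @param frailty logical; estimate the frailty variance omega2? When
#'   `FALSE`, omega2 is fixed at 0.
#' @param centers optional named vector of centering constants overriding
#'   the dataset medians (continuous) / 0 (categorical).
#' @param control list of optimizer controls: `iter_max` (default 500),
#'   `rel_tol` (default 1e-10) for the outer search.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(family = c("weibull", "gompertz", "constant"),
                     covariates = character(), frailty = TRUE,
                     centers = NULL, control = list()) {
  family <- match.arg(family)
  ctrl <- utils::modifyList(list(iter_max = 500L, rel_tol = 1e-10), control)
  stopifnot(ctrl$rel_tol > 0, ctrl$iter_max > 0)
  structure(list(family = family, covariates = covariates,
                 frailty = frailty, centers = centers, control = ctrl),
            class = "fit_spec")
}

resolve_centers <- function(spec, ds) {
  covn <- spec$covariates
  kind <- ds$schema$kind[match(covn, ds$schema$name)]
  if (any(is.na(kind)))
    stop("covariate(s) not in dataset schema: ",
         paste(covn[is.na(kind)], collapse = ", "))
  cen <- ifelse(kind == "continuous", ds$medians[covn], 0)
  names(cen) <- covn
  if (!is.null(spec$centers)) {
    nm <- intersect(names(spec$centers), covn)
    cen[nm] <- spec$centers[nm]
  }
  cen
}

## Transformed parameter vector: log(theta1), theta2 (non-constant families),
## one coefficient per covariate, log(omega2) when frailty is estimated.
make_objective <- function(ctx, spec, centers) {
  family <- spec$family
  covn <- spec$covariates
  has_shape <- family != "constant"
  nm <- c("lt1", if (has_shape) "t2", covn, if (spec$frailty) "lo2")
  decode <- function(x) {
    x <- stats::setNames(x, nm)
    list(theta1 = exp(x[["lt1"]]),
         theta2 = if (has_shape) x[["t2"]] else 0,
         beta = stats::setNames(x[covn], covn),
         omega2 = if (spec$frailty) exp(x[["lo2"]]) else 0)
  }
  negll <- function(x) {
    p <- decode(x)
    val <- tryCatch(
      -sum(ctx_marginal(ctx, family, p$theta1, p$theta2, p$beta,
                        centers, p$omega2)$marginal),
      error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  lower <- rep(-Inf, length(nm)); upper <- rep(Inf, length(nm))
  names(lower) <- names(upper) <- nm
  lower["lt1"] <- -30; upper["lt1"] <- 10
  if (has_shape) {
    lower["t2"] <- if (family == "weibull") -0.99 else -10
    upper["t2"] <- 10
  }
  if (spec$frailty) { lower["lo2"] <- -12; upper["lo2"] <- 6 }
  list(negll = negll, decode = decode, names = nm,
       lower = lower, upper = upper)
}

default_start <- function(ctx, spec) {
  rate <- max(sum(ctx$n), 0.5) / sum(ctx$terminal)
  meanT <- mean(ctx$terminal)
  th2 <- switch(spec$family, constant = NULL, gompertz = 1e-3, weibull = 0.5)
  th1 <- switch(spec$family,
    constant = rate,
    gompertz = rate,
    weibull  = rate * (th2 + 1) / meanT^th2)
  x <- c(lt1 = log(th1), if (!is.null(th2)) c(t2 = th2),
         stats::setNames(rep(0, length(spec$covariates)), spec$covariates),
         if (spec$frailty) c(lo2 = log(0.3)))
  x
}

start_from_model <- function(model, spec) {
  beta <- stats::setNames(rep(0, length(spec$covariates)), spec$covariates)
  if (nrow(model$effects)) {
    nm <- intersect(model$effects$name, spec$covariates)
    beta[nm] <- model$effects$theta[match(nm, model$effects$name)]
  }
  c(lt1 = log(model$theta1),
    if (spec$family != "constant")
      c(t2 = if (is.null(model$theta2)) 0 else model$theta2),
    beta,
    if (spec$frailty) c(lo2 = log(max(model$omega2, 1e-4))))
}

#' Maximum-likelihood fit of a repeated time-to-event model
#'
#' Maximizes the Laplace-approximated marginal likelihood over the scale,
#' shape, covariate coefficients and frailty variance. The search runs on a
#' transformed scale (log scale for `theta1` and `omega2`); standard errors
#' come from the inverse numerical Hessian of the negative log-likelihood at
#' the optimum, mapped back to the natural scale by the delta method.
#' Relative standard errors are 100*SE/|estimate|; 95% intervals use the
#' normal approximation (estimate +/- 1.96 SE, exponentiated for hazard
#' ratios); inter-individual variability is reported as 100*sqrt(omega2).
#'
#' @param spec a [fit_spec()].
#' @param ds an [rtte_data()].
#' @param start optional starting values: a [hazard_model()] or a named
#'   vector on the transformed scale.
#' @param ctx precomputed likelihood context (internal; lets screening and
#'   stepwise selection reuse the dataset's sufficient statistics).
#' @return object of class `rtte_fit` with elements `model` (the estimated
#'   [hazard_model()]), `ofv`, `table` (parameter summary mirroring the
#'   standard reporting layout), `vcov_trans` (covariance on the transformed
#'   scale), `eta_modes`, `converged`.
#' @export
fit_rtte <- function(spec, ds, start = NULL, ctx = NULL) {
  stopifnot(inherits(spec, "fit_spec"), inherits(ds, "rtte_data"))
  if (is.null(ctx)) ctx <- ll_context(ds)
  centers <- resolve_centers(spec, ds)
  obj <- make_objective(ctx, spec, centers)
  x0 <- if (is.null(start)) default_start(ctx, spec)
        else if (inherits(start, "hazard_model")) start_from_model(start, spec)
        else start[obj$names]
  x0 <- pmin(pmax(x0, obj$lower), obj$upper)
  ctrl <- list(iter.max = spec$control$iter_max,
               eval.max = 4 * spec$control$iter_max,
               rel.tol = spec$control$rel_tol)
  opt <- stats::nlminb(x0, obj$negll, lower = obj$lower, upper = obj$upper,
                       control = ctrl)
  conv <- opt$convergence == 0
  ## "false convergence" restarts: rerun from the terminal point; if the
  ## objective no longer moves we are at the optimum despite the code
  for (r in 1:2) {
    if (conv) break
    prev <- opt$objective
    opt <- stats::nlminb(opt$par, obj$negll, lower = obj$lower,
                         upper = obj$upper, control = ctrl)
    conv <- opt$convergence == 0 || abs(prev - opt$objective) < 1e-7
  }
  xhat <- stats::setNames(opt$par, obj$names)
  p <- obj$decode(xhat)
  effects <- if (length(spec$covariates))
    data.frame(name = spec$covariates,
               theta = unname(p$beta[spec$covariates]),
               center = unname(centers[spec$covariates]),
               stringsAsFactors = FALSE)
    else list()
  model <- hazard_model(spec$family, theta1 = p$theta1,
                        theta2 = if (spec$family == "constant") NULL else p$theta2,
                        effects = effects, omega2 = p$omega2)
  marg <- ctx_marginal(ctx, spec$family, p$theta1, p$theta2, p$beta,
                       centers, p$omega2)
  ofv <- -2 * sum(marg$marginal)

  vcov_trans <- NULL; se_trans <- rep(NA_real_, length(xhat))
  hess_ok <- FALSE
  hs <- tryCatch(pracma::hessian(obj$negll, xhat), error = function(e) NULL)
  if (!is.null(hs)) {
    vc <- tryCatch(solve(hs), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
      dimnames(vc) <- list(obj$names, obj$names)
      vcov_trans <- vc
      se_trans <- sqrt(diag(vc))
      hess_ok <- TRUE
    }
  }
  names(se_trans) <- obj$names

  tab <- fit_table(spec, p, centers, se_trans)
  structure(list(model = model, spec = spec, ofv = ofv, table = tab,
                 par_trans = xhat, vcov_trans = vcov_trans,
                 se_trans = se_trans, centers = centers,
                 eta_modes = stats::setNames(marg$eta, ctx$ids),
                 converged = conv,
                 cov_available = hess_ok,
                 n_subjects = ctx$n_subj, n_events = sum(ctx$n),
                 message = opt$message),
            class = "rtte_fit")
}

## Natural-scale parameter summary (delta method from the transformed scale).
fit_table <- function(spec, p, centers, se_trans) {
  rows <- list()
  se1 <- p$theta1 * se_trans[["lt1"]]
  rows$theta1 <- data.frame(parameter = "theta1", estimate = p$theta1,
                            se = se1, ahr = NA_real_,
                            ahr_lo = NA_real_, ahr_hi = NA_real_)
  if (spec$family != "constant") {
    se2 <- se_trans[["t2"]]
    rows$theta2 <- data.frame(parameter = "theta2", estimate = p$theta2,
                              se = se2, ahr = NA_real_,
                              ahr_lo = NA_real_, ahr_hi = NA_real_)
  }
  for (nm in spec$covariates) {
    se <- se_trans[[nm]]
    rows[[nm]] <- data.frame(parameter = nm, estimate = p$beta[[nm]], se = se,
                             ahr = exp(p$beta[[nm]]),
                             ahr_lo = exp(p$beta[[nm]] - 1.96 * se),
                             ahr_hi = exp(p$beta[[nm]] + 1.96 * se))
  }
  if (spec$frailty) {
    omega <- sqrt(p$omega2)
    se_om <- omega * se_trans[["lo2"]] / 2
    rows$iiv <- data.frame(parameter = "IIV_pct", estimate = 100 * omega,
                           se = 100 * se_om, ahr = NA_real_,
                           ahr_lo = NA_real_, ahr_hi = NA_real_)
  }
  tab <- do.call(rbind, rows)
  tab$rse <- 100 * tab$se / abs(tab$estimate)
  tab$ci_lo <- tab$estimate - 1.96 * tab$se
  tab$ci_hi <- tab$estimate + 1.96 * tab$se
  rownames(tab) <- NULL
  tab[c("parameter", "estimate", "rse", "ci_lo", "ci_hi",
        "ahr", "ahr_lo", "ahr_hi", "se")]
}

#' @export
print.rtte_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<rtte_fit> %s hazard, %d subjects, %d events\n",
              x$spec$family, x$n_subjects, x$n_events))
  cat(sprintf("OFV: %.2f   converged: %s\n", x$ofv, x$converged))
  tab <- x$table
  out <- data.frame(Parameter = tab$parameter,
                    Estimate = signif(tab$estimate, digits),
                    `RSE%` = round(tab$rse, 1),
                    aHR = ifelse(is.na(tab$ahr), "-",
                                 formatC(tab$ahr, digits = 3, format = "fg")),
                    `95% CI` = ifelse(is.na(tab$ahr),
                      sprintf("%.4g-%.4g", tab$ci_lo, tab$ci_hi),
                      sprintf("%.3g-%.3g", tab$ahr_lo, tab$ahr_hi)),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Serialize a fit as JSON
#'
#' @param fit an [fit_rtte()] result.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "rtte_fit"))
  out <- list(family = fit$spec$family, ofv = fit$ofv,
              converged = fit$converged,
              n_subjects = fit$n_subjects, n_events = fit$n_events,
              parameters = fit$table, centers = as.list(fit$centers))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Normal-approximation confidence interval from a relative standard error
#'
#' The reporting transform estimate * (1 +/- z * RSE/100) used for scale and
#' shape parameters in the standard parameter table.
#'
#' @param estimate point estimate.
#' @param rse relative standard error, percent.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lo, hi)`.
#' @export
rse_ci <- function(estimate, rse, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  estimate * (1 + c(-1, 1) * z * rse / 100)
}
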