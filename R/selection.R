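#' Likelihood-ratio p-value
#'
#' Upper-tail chi-square probability of an OFV reduction between nested
#' models (the likelihood-ratio statistic).
#'
#' @param delta_ofv OFV(reduced) - OFV(full), must be >= 0.
#' @param df degrees of freedom (number of added parameters).
#' @export
chi2_pvalue <- function(delta_ofv, df = 1L) {
  if (any(delta_ofv < 0)) stop("`delta_ofv` must be >= 0 (order the models)")
  stopifnot(df >= 1)
  stats::pchisq(delta_ofv, df = df, lower.tail = FALSE)
}

#' OFV threshold for a likelihood-ratio test
#'
#' The chi-square quantile giving the minimum OFV reduction that is
#' significant at level `alpha` (3.84 at alpha = 0.05, df = 1; 5.99 at
#' df = 2; 6.63 at alpha = 0.01, df = 1). Exact quantiles are used in all
#' comparisons; rounding is for display only.
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom.
#' @export
lrt_threshold <- function(alpha, df = 1L) {
  stopifnot(alpha > 0, alpha < 1, df >= 1)
  stats::qchisq(1 - alpha, df = df)
}

#' Univariate covariate screen
#'
#' Fits each candidate covariate alone on top of the same base model and
#' tabulates the OFV change (negative = improvement over base), the
#' likelihood-ratio p-value, the coefficient RSE, the unadjusted hazard
#' ratio with its 95% CI, and the re-estimated inter-individual variability.
#' Individual fit failures are recorded per row and the screen continues.
#'
#' @param base_spec a [fit_spec()] for the base (covariate-free) model.
#' @param ds an [rtte_data()].
#' @param candidates character vector of covariate names to screen.
#' @param base_fit optional pre-computed base fit (refitted when omitted).
#' @return data.frame of class `rtte_screen`, one row per candidate, sorted
#'   by OFV drop; the base fit is attached as attribute `base_fit`.
#' @export
univariate_screen <- function(base_spec, ds, candidates, base_fit = NULL) {
  stopifnot(inherits(base_spec, "fit_spec"))
  ctx <- ll_context(ds)
  if (is.null(base_fit)) base_fit <- fit_rtte(base_spec, ds, ctx = ctx)
  rows <- lapply(candidates, function(cand) {
    sp <- base_spec; sp$covariates <- unique(c(base_spec$covariates, cand))
    f <- tryCatch(fit_rtte(sp, ds, start = base_fit$model, ctx = ctx),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warning("screen fit failed for ", cand, ": ", conditionMessage(f))
      return(data.frame(covariate = cand, delta_ofv = NA_real_,
                        p_value = NA_real_, rse = NA_real_, hr = NA_real_,
                        hr_lo = NA_real_, hr_hi = NA_real_, iiv = NA_real_,
                        ok = FALSE))
    }
    d <- f$ofv - base_fit$ofv
    if (cand %in% base_spec$covariates) d <- 0  # candidate already in base
    r <- f$table[f$table$parameter == cand, ]
    iiv <- f$table$estimate[f$table$parameter == "IIV_pct"]
    data.frame(covariate = cand, delta_ofv = d,
               p_value = chi2_pvalue(max(-d, 0), 1L),
               rse = r$rse, hr = r$ahr, hr_lo = r$ahr_lo, hr_hi = r$ahr_hi,
               iiv = if (length(iiv)) iiv else NA_real_, ok = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$delta_ofv), ]
  rownames(out) <- NULL
  attr(out, "base_fit") <- base_fit
  class(out) <- c("rtte_screen", class(out))
  out
}

#' Stepwise covariate selection
#'
#' Forward addition followed by backward elimination, both by likelihood
#' ratio. Forward: at each round every remaining candidate is added to the
#' current model in turn and the one with the largest significant OFV drop
#' (p < `alpha_forward`) enters; rounds repeat until no candidate qualifies.
#' Backward: from the full model each retained covariate is removed in turn
#' and refitted; any covariate whose removal raises the OFV by less than the
#' `alpha_backward` threshold is dropped, iterating to stability. Exact
#' chi-square quantiles decide every comparison.
#'
#' @inheritParams univariate_screen
#' @param alpha_forward inclusion level (default 0.05).
#' @param alpha_backward retention level (default 0.01).
#' @return list with `spec` (final [fit_spec()]), `fit` (final model fit)
#'   and `trace` (data.frame of every evaluated step).
#' @export
stepwise_selection <- function(base_spec, ds, candidates,
                               alpha_forward = 0.05, alpha_backward = 0.01,
                               base_fit = NULL) {
  stopifnot(inherits(base_spec, "fit_spec"))
  ctx <- ll_context(ds)
  if (is.null(base_fit)) base_fit <- fit_rtte(base_spec, ds, ctx = ctx)
  trace <- list()
  note <- function(phase, cand, included, d, p, decision)
    data.frame(phase = phase, candidate = cand,
               model = paste(c(base_spec$family, included), collapse = "+"),
               delta_ofv = d, p_value = p, decision = decision)

  current <- base_spec
  current_fit <- base_fit
  remaining <- setdiff(candidates, base_spec$covariates)
  ## forward addition, greedy by OFV drop
  repeat {
    if (!length(remaining)) break
    cand_fits <- lapply(remaining, function(cand) {
      sp <- current; sp$covariates <- c(current$covariates, cand)
      tryCatch(fit_rtte(sp, ds, start = current_fit$model, ctx = ctx),
               error = function(e) e)
    })
    drops <- vapply(cand_fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$ofv - current_fit$ofv,
      numeric(1))
    pvals <- ifelse(is.na(drops), NA, chi2_pvalue(pmax(-drops, 0), 1L))
    best <- which.min(drops)
    if (!length(best) || all(is.na(drops))) break
    sig <- !is.na(pvals) & pvals < alpha_forward
    for (k in seq_along(remaining)) {
      dec <- if (is.na(drops[k])) "failed"
             else if (k == best && sig[k]) "add"
             else if (sig[k]) "significant, not best" else "not significant"
      trace[[length(trace) + 1L]] <-
        note("forward", remaining[k], current$covariates, drops[k], pvals[k], dec)
    }
    if (!sig[best]) break
    current$covariates <- c(current$covariates, remaining[best])
    current_fit <- cand_fits[[best]]
    remaining <- remaining[-best]
  }
  ## backward elimination at the stricter level
  thr <- lrt_threshold(alpha_backward, 1L)
  added <- setdiff(current$covariates, base_spec$covariates)
  repeat {
    if (!length(added)) break
    rises <- vapply(added, function(cand) {
      sp <- current; sp$covariates <- setdiff(current$covariates, cand)
      f <- tryCatch(fit_rtte(sp, ds, start = current_fit$model, ctx = ctx),
                    error = function(e) e)
      if (inherits(f, "error")) NA_real_ else f$ofv - current_fit$ofv
    }, numeric(1))
    pvals <- ifelse(is.na(rises), NA, chi2_pvalue(pmax(rises, 0), 1L))
    worst <- which.min(rises)
    drop_it <- !is.na(rises[worst]) && rises[worst] < thr
    for (k in seq_along(added)) {
      dec <- if (is.na(rises[k])) "failed"
             else if (k == worst && drop_it) "drop" else "keep"
      trace[[length(trace) + 1L]] <-
        note("backward", added[k], current$covariates, rises[k], pvals[k], dec)
    }
    if (!drop_it) break
    current$covariates <- setdiff(current$covariates, added[worst])
    current_fit <- fit_rtte(current, ds, start = current_fit$model, ctx = ctx)
    added <- added[-worst]
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(phase = character(), candidate = character(),
               model = character(), delta_ofv = numeric(),
               p_value = numeric(), decision = character())
  rownames(trace) <- NULL
  list(spec = current, fit = current_fit, trace = trace)
}
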