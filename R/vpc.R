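## Kaplan-Meier visual predictive check machinery.

## Per-subject simulation covariate paths on a weekly grid: continuous
## covariates are linearly interpolated between the subject's records,
## categorical ones carried forward; consecutive identical rows are then
## collapsed so static subjects reduce to a single segment.
build_sim_paths <- function(ds, grid_step = 1) {
  hists <- subject_histories(ds)
  cont <- ds$schema$name[ds$schema$kind == "continuous"]
  covn <- ds$schema$name
  lapply(hists, function(h) {
    tt <- unique(c(seq(0, h$terminal_time, by = grid_step), h$terminal_time))
    vals <- matrix(NA_real_, length(tt), length(covn),
                   dimnames = list(NULL, covn))
    for (nm in covn) {
      v <- h$cov_values[, nm]
      if (nm %in% cont && length(unique(v)) > 1L) {
        vals[, nm] <- stats::approx(h$cov_times, v, xout = tt, rule = 2)$y
      } else {
        idx <- pmax(findInterval(tt, h$cov_times), 1L)
        vals[, nm] <- v[idx]
      }
    }
    keep <- c(TRUE, rowSums(abs(diff(vals))) > 0)
    list(time = tt[keep], values = vals[keep, , drop = FALSE],
         terminal = h$terminal_time)
  })
}

## Flattened covariate-constant segments for fast replicate simulation:
## base_lam is the eta = 0 cumulative hazard of each segment.
vpc_segments <- function(model, paths) {
  nm <- model$effects$name
  th2 <- model$theta2
  segs <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    brk <- unique(c(p$time[p$time < p$terminal], p$terminal))
    brk <- sort(c(0, brk[brk > 0]))
    a <- brk[-length(brk)]; b <- brk[-1]
    idx <- pmax(findInterval(a + 1e-12, p$time), 1L)
    mult <- if (length(nm))
      effect_multiplier(model$effects, p$values[idx, nm, drop = FALSE])
    else rep(1, length(a))
    if (length(mult) == 1L) mult <- rep(mult, length(a))
    cbind(subj = i, a = a, b = b, mult = mult)
  })
  seg <- do.call(rbind, segs)
  Ga <- baseline_G(model$family, th2, seg[, "a"])
  Gb <- baseline_G(model$family, th2, seg[, "b"])
  list(subj = seg[, "subj"], Ga = Ga, Gb = Gb,
       base_lam = model$theta1 * seg[, "mult"] * (Gb - Ga),
       n_subj = length(paths),
       terminal = vapply(paths, `[[`, numeric(1), "terminal"))
}

## One replicate of first-event times (NA where no event): exact sampling.
## Segment counts are Poisson; the first event falls in the first non-empty
## segment and its position is the minimum of `count` uniforms (Beta(1, n)).
simulate_first_events <- function(model, seg, eta) {
  lam <- seg$base_lam * exp(eta[seg$subj])
  cnt <- stats::rpois(length(lam), lam)
  t1 <- rep(NA_real_, seg$n_subj)
  pos <- which(cnt > 0L)
  if (length(pos)) {
    sel <- pos[!duplicated(seg$subj[pos])]
    u <- stats::rbeta(length(sel), 1, cnt[sel])
    t1[seg$subj[sel]] <- baseline_Ginv(model$family, model$theta2,
                                       seg$Ga[sel] + u * (seg$Gb[sel] - seg$Ga[sel]))
  }
  t1
}

#' Kaplan-Meier visual predictive check
#'
#' Simulates `n_sim` replicate datasets from the model, preserving each
#' subject's covariates (interpolated on a weekly grid) and censoring time,
#' computes the time-to-first-improvement Kaplan-Meier curve of each
#' replicate on a common weekly grid, and returns the observed curve with
#' pointwise 95% prediction bands (2.5th/97.5th percentiles across
#' replicates). Optionally stratified (e.g. cumulative six-month dose
#' >= 50 g versus < 50 g).
#'
#' @param model a fitted [hazard_model()].
#' @param ds the observed [rtte_data()].
#' @param n_sim number of simulated replicates (default 1000).
#' @param horizon grid horizon in weeks (default 800).
#' @param grid_step grid resolution in weeks (default 1).
#' @param strata optional: a factor with one level per subject (in dataset
#'   subject order), or a function taking the baseline covariate data.frame
#'   and returning such a factor.
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `rtte_vpc` whose `table` element is a tidy
#'   data.frame (stratum, time, observed, pi_lo, pi_med, pi_hi).
#' @export
km_vpc <- function(model, ds, n_sim = 1000, horizon = 800, grid_step = 1,
                   strata = NULL, seed = NULL) {
  stopifnot(inherits(model, "hazard_model"), inherits(ds, "rtte_data"))
  if (!is.null(seed)) set.seed(seed)
  hists <- subject_histories(ds)
  if (horizon < max(vapply(hists, `[[`, numeric(1), "terminal_time")))
    warning("`horizon` is below the last observed time")
  grid <- seq(0, horizon, by = grid_step)
  paths <- build_sim_paths(ds, grid_step = grid_step)
  seg <- vpc_segments(model, paths)
  base <- baseline_covariates(ds)
  strat <- resolve_strata(strata, base)
  lev <- levels(strat)
  empty <- table(strat) == 0
  if (any(empty)) {
    warning("stratum with 0 subjects skipped: ",
            paste(lev[empty], collapse = ", "))
    lev <- lev[!empty]
  }
  omega <- sqrt(model$omega2)

  obs_t <- vapply(hists, function(h)
    if (length(h$event_times)) h$event_times[1] else h$terminal_time,
    numeric(1))
  obs_e <- vapply(hists, function(h) length(h$event_times) > 0, logical(1))

  sim <- lapply(lev, function(s)
    matrix(NA_real_, n_sim, length(grid)))
  names(sim) <- lev
  for (r in seq_len(n_sim)) {
    eta <- stats::rnorm(seg$n_subj, 0, omega)
    t1 <- simulate_first_events(model, seg, eta)
    evt <- !is.na(t1)
    tt <- ifelse(evt, t1, seg$terminal)
    for (s in lev) {
      m <- strat == s
      sim[[s]][r, ] <- km_at(km_from_times(tt[m], evt[m]), grid)
    }
  }
  tabs <- lapply(lev, function(s) {
    m <- strat == s
    okm <- km_from_times(obs_t[m], obs_e[m])
    qs <- apply(sim[[s]], 2, stats::quantile,
                probs = c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(stratum = s, time = grid, observed = km_at(okm, grid),
               pi_lo = qs[1, ], pi_med = qs[2, ], pi_hi = qs[3, ])
  })
  censors <- lapply(lev, function(s) obs_t[strat == s & !obs_e])
  names(censors) <- lev
  structure(list(table = do.call(rbind, tabs), n_sim = n_sim, grid = grid,
                 strata = lev, censor_times = censors),
            class = "rtte_vpc")
}

## Baseline (first-record) covariate values, one row per subject.
baseline_covariates <- function(ds) {
  first <- !duplicated(ds$records$ID)
  out <- ds$records[first, c("ID", ds$schema$name)]
  rownames(out) <- NULL
  out
}

resolve_strata <- function(strata, base) {
  if (is.null(strata)) return(factor(rep("all", nrow(base))))
  if (is.function(strata)) strata <- strata(base)
  if (length(strata) != nrow(base))
    stop("`strata` must give one label per subject")
  if (is.factor(strata)) strata else factor(strata)
}

#' Dichotomous stratification rule on a baseline covariate
#'
#' Returns a strata function splitting subjects at a cutoff, e.g.
#' `covariate_strata("CTDD", 50)` for cumulative six-month dose >= 50 g.
#'
#' @param name covariate name.
#' @param cutoff threshold; subjects with value >= cutoff form the upper
#'   stratum.
#' @export
covariate_strata <- function(name, cutoff) {
  force(name); force(cutoff)
  function(base) {
    if (!name %in% names(base)) stop("no covariate ", name)
    factor(ifelse(base[[name]] >= cutoff,
                  paste0(name, ">=", cutoff), paste0(name, "<", cutoff)))
  }
}

#' Fraction of grid points where the observed curve is inside the band
#'
#' @param vpc an `rtte_vpc`.
#' @export
vpc_coverage <- function(vpc) {
  stopifnot(inherits(vpc, "rtte_vpc"))
  with(vpc$table, mean(observed >= pi_lo & observed <= pi_hi))
}

#' @export
print.rtte_vpc <- function(x, ...) {
  cat(sprintf("<rtte_vpc> %d simulations, grid 0-%g weeks, strata: %s\n",
              x$n_sim, max(x$grid), paste(x$strata, collapse = ", ")))
  cat(sprintf("observed-in-band fraction: %.3f\n", vpc_coverage(x)))
  invisible(x)
}

#' Plot a Kaplan-Meier VPC
#'
#' Observed curve (solid line), censoring ticks, and the shaded 95%
#' prediction band from the simulated replicates; one panel per stratum.
#'
#' @param x an `rtte_vpc`.
#' @param ... ignored.
#' @export
plot.rtte_vpc <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tab <- x$table
  cens <- do.call(rbind, lapply(names(x$censor_times), function(s) {
    ct <- x$censor_times[[s]]
    if (!length(ct)) return(NULL)
    sub <- tab[tab$stratum == s, ]
    data.frame(stratum = s, time = ct,
               surv = km_at_interp(sub$time, sub$observed, ct))
  }))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pi_lo, ymax = .data$pi_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$observed)) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Weeks since first clozapine dose",
                  y = "Fraction without improvement") +
    ggplot2::theme_minimal()
  if (!is.null(cens))
    p <- p + ggplot2::geom_point(data = cens,
                                 ggplot2::aes(y = .data$surv), shape = 3)
  p
}

km_at_interp <- function(grid, surv, t) {
  idx <- pmax(findInterval(t, grid), 1L)
  surv[idx]
}
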