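#' Simulate one subject's recurrent event history
#'
#' Draws improvement events on (0, terminal] from the nonhomogeneous Poisson
#' process with intensity h(t | cov(t), eta). The covariate path is treated
#' as piecewise constant; on each covariate-constant segment the cumulative
#' hazard has a closed form, so events are produced by exact inversion: the
#' segment's event count is Poisson with mean equal to the segment cumulative
#' hazard, and the event times are the inverse cumulative hazard evaluated
#' at uniform draws (the order-statistics form of inverse-transform
#' sampling).
#'
#' @param model a [hazard_model()].
#' @param cov_path data.frame with column `time` (weeks, starting at or
#'   before 0 coverage) and one column per model covariate; values are
#'   carried forward between rows. May be `NULL` for covariate-free models.
#' @param terminal_time censoring time (weeks).
#' @param eta frailty deviate for this subject (draw from
#'   Normal(0, omega2) once per subject).
#' @param max_events guard against pathological parameter sets; exceeding
#'   it is an error.
#' @return sorted numeric vector of event times in (0, terminal].
#' @export
simulate_subject <- function(model, cov_path = NULL, terminal_time,
                             eta = 0, max_events = 1e4) {
  stopifnot(inherits(model, "hazard_model"), terminal_time >= 0)
  nm <- model$effects$name
  if (length(nm)) {
    if (is.null(cov_path)) stop("model has covariate effects; `cov_path` required")
    miss <- setdiff(nm, names(cov_path))
    if (length(miss)) stop("cov_path missing covariate(s): ",
                           paste(miss, collapse = ", "))
    brk <- sort(unique(c(0, cov_path$time[cov_path$time > 0 &
                                          cov_path$time < terminal_time],
                         terminal_time)))
    idx <- pmax(findInterval(brk[-length(brk)] + 1e-12, cov_path$time), 1L)
    mult <- effect_multiplier(model$effects,
                              as.matrix(cov_path[idx, nm, drop = FALSE]))
    if (length(mult) == 1L) mult <- rep(mult, length(brk) - 1L)
  } else {
    brk <- c(0, terminal_time)
    mult <- 1
  }
  th2 <- model$theta2
  a <- brk[-length(brk)]; b <- brk[-1]
  Ga <- baseline_G(model$family, th2, a)
  Gb <- baseline_G(model$family, th2, b)
  lam <- model$theta1 * exp(eta) * mult * (Gb - Ga)
  if (terminal_time == 0 || sum(lam) == 0) return(numeric(0))
  counts <- stats::rpois(length(lam), lam)
  if (sum(counts) > max_events)
    stop("simulated event count exceeds max_events (", max_events,
         "); pathological parameters?")
  if (sum(counts) == 0) return(numeric(0))
  times <- unlist(lapply(which(counts > 0), function(s) {
    u <- stats::runif(counts[s])
    baseline_Ginv(model$family, th2, Ga[s] + u * (Gb[s] - Ga[s]))
  }))
  out <- sort(times)
  ## guarantee strictly increasing jump times (ties have probability zero
  ## but finite precision can produce them)
  d <- which(diff(out) <= 0)
  if (length(d)) for (j in d + 1L) out[j] <- out[j - 1L] + 1e-9
  pmin(out, terminal_time)
}

#' Kaplan-Meier curve for time to k-th improvement
#'
#' Product-limit estimator on the time to the `event_number`-th improvement
#' per subject (default: first). Subjects with fewer events are censored at
#' their terminal time.
#'
#' @param histories list of `subject_history` objects (see
#'   [subject_histories()]).
#' @param event_number which event per subject to time (default 1).
#' @return object of class `km_curve`: data.frame `steps` with columns
#'   `time`, `n_risk`, `n_event`, `surv`, plus `censor_times`.
#' @export
kaplan_meier <- function(histories, event_number = 1L) {
  if (!length(histories)) stop("empty input: at least one subject required")
  tt <- vapply(histories, function(h) {
    if (length(h$event_times) >= event_number) h$event_times[event_number]
    else h$terminal_time
  }, numeric(1))
  ev <- vapply(histories, function(h)
    length(h$event_times) >= event_number, logical(1))
  km_from_times(tt, ev)
}

km_from_times <- function(time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time[event])
  n <- length(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(steps = data.frame(time = ut, n_risk = n_risk,
                                    n_event = n_event, surv = surv),
                 censor_times = time[!event], n_subjects = n),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve on a time grid
#'
#' Right-continuous step-function evaluation (S = 1 before the first event).
#'
#' @param km a `km_curve`.
#' @param times evaluation times.
#' @export
km_at <- function(km, times) {
  stopifnot(inherits(km, "km_curve"))
  if (!nrow(km$steps)) return(rep(1, length(times)))
  idx <- findInterval(times, km$steps$time)
  c(1, km$steps$surv)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d subjects, %d event times, %d censored\n",
              x$n_subjects, nrow(x$steps), length(x$censor_times)))
  invisible(x)
}
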