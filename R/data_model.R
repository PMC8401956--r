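#' Covariate schema
#'
#' Declares which dataset columns are covariates and whether each is
#' continuous (centered at the cohort median in covariate models) or
#' categorical (0/1, centered at 0).
#'
#' @param continuous character vector of continuous covariate names.
#' @param categorical character vector of categorical (0/1) covariate names.
#' @param units optional named character vector of units for continuous
#'   covariates (documentation only).
#' @return data.frame with columns `name`, `kind`, `units`.
#' @export
covariate_schema <- function(continuous = character(),
                             categorical = character(),
                             units = NULL) {
  nm <- c(continuous, categorical)
  if (anyDuplicated(nm)) stop("covariate names must be unique")
  un <- rep("", length(nm))
  if (!is.null(units)) un[match(names(units), nm)] <- units
  data.frame(name = nm,
             kind = c(rep("continuous", length(continuous)),
                      rep("categorical", length(categorical))),
             units = un, stringsAsFactors = FALSE)
}

#' Event-record dataset
#'
#' Builds a validated long-format recurrent-event dataset. Each row is one
#' record for one subject: `ID`, `TIME` (weeks since first clozapine dose),
#' `DV` (1 = positive-symptom improvement event, 0 = non-event observation),
#' plus one column per covariate. The last record of every subject must be a
#' `DV = 0` row: it marks the end of follow-up and is treated as right
#' censoring.
#'
#' @param records data.frame with columns `ID`, `TIME`, `DV` and the
#'   covariate columns named in `schema`.
#' @param schema a [covariate_schema()].
#' @param medians optional named vector of centering medians for continuous
#'   covariates; computed from the data (one baseline value per subject)
#'   when omitted. Supply e.g. `c(AGE = 41, CTDD = 34)` to fix the published
#'   centering constants.
#' @return object of class `rtte_data`.
#' @export
rtte_data <- function(records, schema, medians = NULL) {
  req <- c("ID", "TIME", "DV")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(schema$name, names(records))
  if (length(miss))
    stop("schema covariate(s) absent from records: ",
         paste(miss, collapse = ", "))
  records <- as.data.frame(records)[, c(req, schema$name)]
  if (!is.numeric(records$TIME) || any(!is.finite(records$TIME)))
    stop("TIME must be finite numeric")
  if (any(records$TIME < 0)) stop("negative TIME is invalid")
  if (!all(records$DV %in% c(0, 1))) stop("DV must be 0 or 1")
  sid <- as.character(records$ID)
  ## per-subject: times non-decreasing, last record is a DV = 0 censor row
  same <- sid[-1] == sid[-length(sid)]
  bad <- same & diff(records$TIME) < 0
  if (any(bad))
    stop("times are not non-decreasing for subject ", sid[which(bad)[1] + 1L])
  last <- !duplicated(sid, fromLast = TRUE)
  if (any(records$DV[last] != 0))
    stop("subject ", sid[last][records$DV[last] != 0][1],
         " has no terminal censoring record (last DV must be 0)")
  ds <- structure(list(records = records, schema = schema, medians = NULL),
                  class = "rtte_data")
  cont <- schema$name[schema$kind == "continuous"]
  med <- compute_medians(ds, cont)
  if (!is.null(medians)) med[names(medians)] <- medians
  ds$medians <- med
  ds
}

#' Read a long-format event dataset from CSV
#'
#' @param path CSV file with header `ID,TIME,DV` plus covariate columns.
#' @inheritParams rtte_data
#' @export
read_dataset <- function(path, schema, medians = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rtte_data(rec, schema, medians = medians)
}

#' Write a dataset back to CSV
#'
#' @param ds an [rtte_data()] object.
#' @param path output file.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "rtte_data"))
  utils::write.csv(ds$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.rtte_data <- function(x, ...) {
  ns <- length(unique(x$records$ID))
  ne <- sum(x$records$DV == 1)
  cat(sprintf("<rtte_data> %d subjects, %d records, %d improvement events\n",
              ns, nrow(x$records), ne))
  cat("covariates:", paste(x$schema$name, collapse = ", "), "\n")
  invisible(x)
}

#' Per-subject centering medians
#'
#' Median of one baseline (first-record) value per subject, for continuous
#' covariates only -- the centering constants of the exponential covariate
#' model.
#'
#' @param ds an [rtte_data()].
#' @param names continuous covariate names.
#' @return named numeric vector of medians.
#' @export
compute_medians <- function(ds, names) {
  stopifnot(inherits(ds, "rtte_data"))
  if (!length(names)) return(stats::setNames(numeric(), character()))
  kind <- ds$schema$kind[match(names, ds$schema$name)]
  if (any(is.na(kind))) stop("unknown covariate(s): ",
                             paste(names[is.na(kind)], collapse = ", "))
  if (any(kind != "continuous"))
    stop("medians are defined for continuous covariates only: ",
         paste(names[kind != "continuous"], collapse = ", "))
  first <- !duplicated(ds$records$ID)
  vapply(names, function(nm) stats::median(ds$records[[nm]][first]),
         numeric(1))
}

#' Per-subject event histories
#'
#' Splits a dataset into one history per subject: ordered improvement event
#' times, the terminal (censoring) time, and the covariate path as a
#' last-observation-carried-forward step function of the record times.
#' Tied event times within a subject are perturbed by +1e-6 weeks (repeated
#' events need distinct jump times; exact ties are artifacts of the weekly
#' recording resolution).
#'
#' @param ds an [rtte_data()].
#' @return list of `subject_history` objects.
#' @export
subject_histories <- function(ds) {
  stopifnot(inherits(ds, "rtte_data"))
  rec <- ds$records
  covn <- ds$schema$name
  lapply(split(rec, factor(as.character(rec$ID),
                           levels = unique(as.character(rec$ID)))),
         function(r) {
    ev <- r$TIME[r$DV == 1]
    if (length(ev) > 1) {            # break exact ties
      for (j in 2:length(ev))
        if (ev[j] <= ev[j - 1]) ev[j] <- ev[j - 1] + 1e-6
    }
    structure(list(
      subject_id   = as.character(r$ID[1]),
      event_times  = ev,
      terminal_time = r$TIME[nrow(r)],
      cov_times    = r$TIME,
      cov_values   = as.matrix(r[, covn, drop = FALSE])),
      class = "subject_history")
  })
}

#' Covariate value at a time point (step-function lookup)
#'
#' Last observation carried forward from the subject's records; the value at
#' times before the first record is the first record's value.
#'
#' @param hist a `subject_history`.
#' @param name covariate name.
#' @param t time(s) in weeks.
#' @export
covariate_value <- function(hist, name, t) {
  stopifnot(inherits(hist, "subject_history"))
  v <- hist$cov_values[, name]
  idx <- findInterval(t, hist$cov_times)
  v[pmax(idx, 1L)]
}

#' @export
print.subject_history <- function(x, ...) {
  cat(sprintf("<subject_history> %s: %d events, censored at %.6g weeks\n",
              x$subject_id, length(x$event_times), x$terminal_time))
  invisible(x)
}
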