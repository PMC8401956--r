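#' Base hazard-family comparison
#'
#' Fits the constant, Gompertz and Weibull frailty models to the same data
#' and tabulates parameter counts, OFVs, OFV drops versus the constant
#' model, and likelihood-ratio p-values; the lowest-OFV family is flagged.
#'
#' @param ds an [rtte_data()].
#' @param frailty estimate a frailty variance (default TRUE).
#' @return data.frame of class `rtte_base_models` (fits attached as
#'   attribute `fits`).
#' @export
run_base_models <- function(ds, frailty = TRUE) {
  fams <- c("constant", "gompertz", "weibull")
  fits <- lapply(fams, function(f)
    tryCatch(fit_rtte(fit_spec(f, frailty = frailty), ds),
             error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  ofv <- ifelse(ok, vapply(fits, function(f)
    if (inherits(f, "error")) NA_real_ else f$ofv, numeric(1)), NA_real_)
  npar <- ifelse(fams == "constant", 1L, 2L) + as.integer(frailty)
  dofv <- ofv - ofv[1]
  p <- c(NA, vapply(2:3, function(i)
    if (is.na(dofv[i])) NA_real_ else chi2_pvalue(max(-dofv[i], 0), 1L),
    numeric(1)))
  out <- data.frame(family = fams, n_parameters = npar, ofv = ofv,
                    delta_ofv = dofv, p_value = p,
                    selected = seq_along(fams) == which.min(ofv))
  attr(out, "fits") <- stats::setNames(fits, fams)
  class(out) <- c("rtte_base_models", class(out))
  out
}

#' Pipeline configuration
#'
#' @param dataset path to an event-record CSV, or `NULL` to generate a
#'   synthetic cohort from `cohort`.
#' @param cohort a [cohort_spec()] used when `dataset` is `NULL`.
#' @param schema [covariate_schema()] for reading `dataset` (ignored for
#'   generated cohorts).
#' @param candidates covariate names entering screening and stepwise
#'   selection.
#' @param alpha_forward,alpha_backward stepwise significance levels.
#' @param n_sim VPC replicate count (default 1000).
#' @param horizon VPC grid horizon in weeks (default 800).
#' @param vpc_strata named list of strata rules (each as for the `strata`
#'   argument of [km_vpc()]); an unstratified VPC is always produced.
#' @param sir_n_proposal,sir_m_resample SIR sample sizes.
#' @param centers optional fixed centering constants (e.g.
#'   `c(AGE = 41, CTDD = 34)`).
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory for tables and the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(dataset = NULL, cohort = cohort_spec(),
                       schema = NULL,
                       candidates = c("AGE", "AAP", "CTDD", "STATIN",
                                      "SEXF", "SMOK", "BMI"),
                       alpha_forward = 0.05, alpha_backward = 0.01,
                       n_sim = 1000, horizon = 800,
                       vpc_strata = list(CTDD50 = covariate_strata("CTDD", 50)),
                       sir_n_proposal = 5000, sir_m_resample = 1000,
                       centers = NULL, seed = 1L, out_dir = tempfile("rtte_run_")) {
  stopifnot(alpha_forward > 0, alpha_forward < 1,
            alpha_backward > 0, alpha_backward < 1)
  if (!is.null(dataset) && is.null(schema))
    stop("`schema` is required when reading a dataset from file")
  structure(list(dataset = dataset, cohort = cohort, schema = schema,
                 candidates = candidates, alpha_forward = alpha_forward,
                 alpha_backward = alpha_backward, n_sim = n_sim,
                 horizon = horizon, vpc_strata = vpc_strata,
                 sir_n_proposal = sir_n_proposal,
                 sir_m_resample = sir_m_resample, centers = centers,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [run_config()] can be set from a flat YAML file;
#' list-valued fields (cohort spec, strata rules) keep their defaults.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("yaml package required to read YAML configs")
  y <- yaml::read_yaml(path)
  keep <- intersect(names(y), c("dataset", "candidates", "alpha_forward",
                                "alpha_backward", "n_sim", "horizon",
                                "sir_n_proposal", "sir_m_resample",
                                "seed", "out_dir"))
  cfg <- do.call(run_config, y[keep])
  if (!is.null(y$centers)) cfg$centers <- unlist(y$centers)
  if (!is.null(y$n_subjects)) cfg$cohort$n_subjects <- y$n_subjects
  cfg
}

## deterministic stage seeds below 2^31
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + sum(utf8ToInt(stage)) * 9973) %% 2147483629 + 1
}

#' Run the full analysis workflow
#'
#' Executes the complete model-development sequence on an observed or
#' generated cohort: base hazard-family comparison, univariate covariate
#' screen, stepwise forward addition / backward elimination, final fit, SIR
#' uncertainty, and Kaplan-Meier VPCs (overall and stratified). All tables
#' are written as CSV under `cfg$out_dir` together with a JSON manifest
#' carrying the seed and configuration; a stage failure aborts downstream
#' stages but retains the partial outputs and records the failure in the
#' manifest.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every stage result.
#' @export
run_full_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  status <- list(); res <- list()
  wtab <- function(x, f) utils::write.csv(
    x, file.path(cfg$out_dir, f), row.names = FALSE)
  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) e)
    status[[name]] <<- if (inherits(out, "error"))
      paste("failed:", conditionMessage(out)) else "ok"
    if (inherits(out, "error")) {
      say("stage ", name, " failed: ", conditionMessage(out))
      NULL
    } else out
  }

  say("stage: data")
  res$data <- run_stage("data", {
    if (!is.null(cfg$dataset)) {
      read_dataset(cfg$dataset, cfg$schema, medians = cfg$centers)
    } else {
      coh <- generate_cohort(cfg$cohort, seed = derive_seed(cfg$seed, "cohort"))
      res$cohort <- coh
      wtab(summarize_cohort(coh), "cohort_summary.csv")
      ds <- coh$data
      if (!is.null(cfg$centers)) ds$medians[names(cfg$centers)] <- cfg$centers
      ds
    }
  })

  if (!is.null(res$data)) {
    say("stage: base models")
    res$base_models <- run_stage("base_models", run_base_models(res$data))
    if (!is.null(res$base_models))
      wtab(as.data.frame(res$base_models), "base_models.csv")
  }

  base_fit <- NULL
  if (!is.null(res$base_models)) {
    fam <- res$base_models$family[res$base_models$selected]
    res$base_spec <- fit_spec(fam, centers = cfg$centers)
    base_fit <- attr(res$base_models, "fits")[[fam]]
    say("stage: univariate screen (", fam, " base)")
    res$screen <- run_stage("screen",
      univariate_screen(res$base_spec, res$data, cfg$candidates,
                        base_fit = base_fit))
    if (!is.null(res$screen)) wtab(as.data.frame(res$screen), "screen.csv")
  }

  if (!is.null(res$screen)) {
    say("stage: stepwise selection")
    res$stepwise <- run_stage("stepwise",
      stepwise_selection(res$base_spec, res$data, cfg$candidates,
                         alpha_forward = cfg$alpha_forward,
                         alpha_backward = cfg$alpha_backward,
                         base_fit = base_fit))
    if (!is.null(res$stepwise)) {
      wtab(res$stepwise$trace, "stepwise.csv")
      res$final_fit <- res$stepwise$fit
      wtab(res$final_fit$table, "final_fit.csv")
      write_fit_json(res$final_fit, file.path(cfg$out_dir, "final_fit.json"))
    }
  }

  if (!is.null(res$final_fit)) {
    say("stage: SIR uncertainty")
    res$sir <- run_stage("sir",
      sir(res$final_fit, res$data, n_proposal = cfg$sir_n_proposal,
          m_resample = cfg$sir_m_resample,
          seed = derive_seed(cfg$seed, "sir")))
    if (!is.null(res$sir)) wtab(res$sir$summary, "sir.csv")
  }

  if (!is.null(res$final_fit)) {
    say("stage: KM-VPC")
    res$vpc <- run_stage("vpc", {
      vpcs <- list(overall = km_vpc(res$final_fit$model, res$data,
                                    n_sim = cfg$n_sim, horizon = cfg$horizon,
                                    seed = derive_seed(cfg$seed, "vpc")))
      for (nm in names(cfg$vpc_strata))
        vpcs[[nm]] <- km_vpc(res$final_fit$model, res$data,
                             n_sim = cfg$n_sim, horizon = cfg$horizon,
                             strata = cfg$vpc_strata[[nm]],
                             seed = derive_seed(cfg$seed, paste0("vpc_", nm)))
      vpcs
    })
    if (!is.null(res$vpc)) {
      tab <- do.call(rbind, lapply(names(res$vpc), function(nm)
        cbind(panel = nm, res$vpc[[nm]]$table)))
      wtab(tab, "vpc.csv")
    }
  }

  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("rtteclz")),
    r_version = R.version.string,
    n_subjects = if (!is.null(res$data)) length(unique(res$data$records$ID)),
    candidates = cfg$candidates,
    alpha = c(forward = cfg$alpha_forward, backward = cfg$alpha_backward),
    n_sim = cfg$n_sim, horizon = cfg$horizon,
    sir = c(n_proposal = cfg$sir_n_proposal, m_resample = cfg$sir_m_resample),
    status = status)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("outputs in ", cfg$out_dir)
  invisible(res)
}
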