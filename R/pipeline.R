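#' Utility estimation stage: GRM fit, scoring, calibration, interpolation
#'
#' Runs the whole utility-estimation step on the ADL assessment records of
#' a registry: screens unidimensionality of the polychoric correlation
#' matrix, fits the graded response model by marginal ML, scores every
#' assessment by EAP, calibrates the raw scores onto the EQ-5D-3L anchors
#' (-0.53, 1.00) with the min/max anchors frozen over all assessment
#' records, and linearly interpolates daily utility per patient.
#'
#' @param adl the ADL assessment table (columns `patient_id`, `day`,
#'   `adl1`..`adl6`), or a `"registry"` whose `adl` table is used.
#' @param patient_ids optional subset of patients (e.g. the analysis
#'   cohort) whose records are analyzed.
#' @param n_quad,tol,max_iter GRM fitting controls, see [grm()].
#' @return list of class `"irt_stage"`: `grm` (the fit), `unidim` (eigen
#'   report), `scored` (per assessment: `patient_id`, `day`, `eap`, `sd`,
#'   `utility`), `anchors` (frozen raw min/max), `trajectories` (daily
#'   utility per patient).
#' @export
fit_irt_stage <- function(adl, patient_ids = NULL, n_quad = 41L, tol = 1e-4,
                          max_iter = 500L) {
  if (inherits(adl, "registry")) adl <- adl$adl
  if (!is.null(patient_ids)) adl <- adl[adl$patient_id %in% patient_ids, ]
  if (nrow(adl) == 0L) stop("no ADL assessment records to analyze")
  X <- as.matrix(adl[, paste0("adl", 1:6)])
  fit <- grm(X, n_quad = n_quad, tol = tol, max_iter = max_iter,
             check_unidim = TRUE)
  sc <- predict(fit, X)
  anchors <- range(sc$eap)
  scored <- data.frame(patient_id = adl$patient_id, day = adl$day,
                       eap = sc$eap, sd = sc$sd,
                       utility = calibrate_utility(sc$eap, anchors = anchors))
  traj <- build_trajectories(scored)
  structure(list(grm = fit, unidim = fit$unidim, scored = scored,
                 anchors = anchors, trajectories = traj),
            class = "irt_stage")
}

#' @export
print.irt_stage <- function(x, ...) {
  cat(sprintf("Utility estimation stage: %d assessments, %d patients, %d daily estimates\n",
              nrow(x$scored), length(unique(x$scored$patient_id)), nrow(x$trajectories)))
  cat(sprintf("  calibrated utility mean %.3f, median %.3f\n",
              mean(x$scored$utility), stats::median(x$scored$utility)))
  print(x$grm)
  invisible(x)
}

#' Pipeline run configuration
#'
#' Validates and normalizes the configuration of an end-to-end run. Either
#' `simulation` (arguments for [sim_config()]) or `registry_dir` (a
#' directory of registry CSVs) must be given; `censor_day` and `seed` are
#' required. The resolved configuration is written beside the outputs of
#' every run.
#'
#' @param config a named list or the path of a YAML file.
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("censor_day", "seed", "output_dir")
  for (f in required)
    if (is.null(config[[f]])) stop("run config is missing required field `", f, "`")
  if (is.null(config$simulation) && is.null(config$registry_dir))
    stop("run config needs either `simulation` or `registry_dir`")
  defaults <- list(boot_reps = 200L, n_quad = 41L, grm_tol = 1e-4,
                   grm_max_iter = 500L, conditional_imputation = FALSE,
                   cohort = list())
  for (f in names(defaults)) if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  config$seed <- as.integer(config$seed)
  config$censor_day <- as.integer(config$censor_day)
  structure(config, class = "run_config")
}

# per-stage seeds derived from the run seed, kept within 32-bit range
stage_seed <- function(seed, stage) (seed * 7L + stage * 1009L) %% .Machine$integer.max

#' Run the full HSU estimation pipeline
#'
#' Executes the four analysis steps in order — simulate (or load) the
#' registry, select the incident cohort, build health-state timelines with
#' survival and admission analyses, estimate daily utility by IRT, and
#' estimate selection-corrected HSU by state and month — writing every
#' stage's outputs under `output_dir`. Identical configuration and seed
#' give identical outputs.
#'
#' @param config a [run_config()], a named list, or a YAML path.
#' @return invisibly, a list with every stage result and the run report
#'   (stage timings and record counts). The report is also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 2))
    val
  }

  # Stage 0: registry
  registry <- t_stage("registry", {
    if (!is.null(cfg$simulation)) {
      sim_args <- cfg$simulation
      sim_args$seed <- stage_seed(cfg$seed, 0L)
      reg <- generate_registry(do.call(sim_config, sim_args))
      write_registry(reg, file.path(cfg$output_dir, "registry"))
      reg
    } else read_registry(cfg$registry_dir)
  })
  report$stages$registry$n_patients <- nrow(registry$patients)
  report$stages$registry$n_adl <- nrow(registry$adl)

  # Step I: cohort
  cohort <- t_stage("cohort", {
    spec <- do.call(cohort_spec, cfg$cohort)
    ch <- build_cohort(registry, spec)
    utils::write.csv(ch, file.path(cfg$output_dir, "cohort.csv"), row.names = FALSE)
    jsonlite::write_json(attr(ch, "flow"), file.path(cfg$output_dir, "cohort_flow.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    ch
  })
  report$stages$cohort$n <- nrow(cohort)

  # Step II: health states, survival, admission
  states <- t_stage("states", {
    tl <- build_timelines(cohort, registry, censor_day = cfg$censor_day)
    utils::write.csv(tl$intervals, file.path(cfg$output_dir, "timelines.csv"),
                     row.names = FALSE)
    km <- km_by_state(tl)
    km_tab <- do.call(rbind, lapply(names(km), function(s)
      cbind(state = s, as.data.frame(km[[s]]))))
    utils::write.csv(km_tab, file.path(cfg$output_dir, "survival_by_state.csv"),
                     row.names = FALSE)
    adm <- admission_analysis_data(tl, registry)
    cr <- suppressWarnings(
      fit_competing_admission(adm$time, adm$event, covariate = factor(adm$state)))
    utils::write.csv(cr$cif, file.path(cfg$output_dir, "admission_cif.csv"),
                     row.names = FALSE)
    list(timelines = tl, km = km, admission = cr)
  })
  report$stages$states$n_intervals <- nrow(states$timelines$intervals)

  # Step III: IRT utility
  irt <- t_stage("irt", {
    st <- fit_irt_stage(registry, patient_ids = cohort$patient_id,
                        n_quad = cfg$n_quad, tol = cfg$grm_tol,
                        max_iter = cfg$grm_max_iter)
    jsonlite::write_json(list(alpha = unname(st$grm$alpha),
                              beta = unname(st$grm$beta),
                              logLik = st$grm$logLik,
                              converged = st$grm$convergence$converged,
                              anchors_raw = st$anchors),
                         file.path(cfg$output_dir, "grm_parameters.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(st$unidim))
      jsonlite::write_json(st$unidim[c("eigenvalues", "variance_share", "ratio", "pass")],
                           file.path(cfg$output_dir, "eigenreport.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(st$trajectories, file.path(cfg$output_dir, "daily_utility.csv"),
                     row.names = FALSE)
    st
  })
  report$stages$irt$n_assessments <- nrow(irt$scored)
  report$stages$irt$n_daily <- nrow(irt$trajectories)

  # Step IV: HSU by state and month
  hsu <- t_stage("hsu", {
    set.seed(stage_seed(cfg$seed, 4L))
    sp <- build_subpopulations(states$timelines, irt$trajectories, registry)
    est <- estimate_hsu(sp, boot_reps = cfg$boot_reps,
                        conditional_imputation = isTRUE(cfg$conditional_imputation))
    utils::write.csv(est$by_state_month, file.path(cfg$output_dir, "hsu_by_state_month.csv"),
                     row.names = FALSE)
    obs <- est$by_state_month[, c("state", "month", "n_admitted", "mean_observed")]
    utils::write.csv(obs, file.path(cfg$output_dir, "hsu_observed_only.csv"),
                     row.names = FALSE)
    lam <- est$by_state_month[, c("state", "month", "lambda", "lambda_p")]
    utils::write.csv(lam, file.path(cfg$output_dir, "lambda_tests.csv"),
                     row.names = FALSE)
    bd <- hsu_breakdown(est, hsu_covariates(cohort, registry))
    utils::write.csv(bd, file.path(cfg$output_dir, "hsu_summary_breakdown.csv"),
                     row.names = FALSE)
    est
  })
  report$stages$hsu$n_cells <- nrow(hsu$by_state_month)

  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "resolved_config.yaml"))
  jsonlite::write_json(report, file.path(cfg$output_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(registry = registry, cohort = cohort, states = states,
                 irt = irt, hsu = hsu, report = report, config = cfg))
}
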