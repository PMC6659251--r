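#' Monthly per-patient HSU from daily utility estimates
#'
#' The health-state utility of a patient in a month is the arithmetic mean
#' of the available daily utility estimates in the 30-day month window:
#' with complete coverage (30 values) this is the area-under-the-curve
#' estimate; with a single value the patient's utility is taken as uniform
#' over the month.
#'
#' @param values numeric vector of daily utility estimates falling in the
#'   month window; must be non-empty (a patient with no estimate is
#'   non-admitted for the month and has no observed value).
#' @return the mean daily utility.
#' @export
monthly_patient_hsu <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("no daily utility estimates in the month: patient is non-admitted")
  mean(values)
}

# the 48 (state, month) subpopulations: months 1-6 in the initial early /
# locally-advanced states, 1-12 in the other three; follow-up states are
# clocked from day 180 (period entry), initial states from day 0
subpop_definitions <- function() {
  rbind(
    expand.grid(state = c("early", "locally_advanced"), month = 1:6,
                stringsAsFactors = FALSE),
    expand.grid(state = c("metastatic", "relapse", "relapse_free"), month = 1:12,
                stringsAsFactors = FALSE)
  ) -> d
  d$entry <- ifelse(d$state %in% c("relapse", "relapse_free"), 180L, 0L)
  d[order(d$state, d$month), ]
}

#' Baseline covariates for the selection and outcome equations
#'
#' Assembles the covariate vectors used in Step IV: age band, sex and
#' comorbidity count from the patients table, hospital type (the
#' exclusion-restriction covariate, used in the selection equation only),
#' and depression / palliative-care flags derived from the diagnosis codes.
#'
#' @param cohort a `"cohort"` data frame.
#' @param registry the registry.
#' @return data frame, one row per cohort patient.
#' @export
hsu_covariates <- function(cohort, registry) {
  codes <- registry_codes()
  ev <- diagnosis_events(registry)
  depressed <- unique(ev$patient_id[ev$code == codes$depression])
  palliative <- unique(ev$patient_id[ev$code == codes$palliative])
  data.frame(patient_id = cohort$patient_id,
             age_band = factor(cohort$age_band),
             sex = factor(cohort$sex),
             comorbidity_count = cohort$comorbidity_count,
             hospital_type = factor(cohort$hospital_type),
             depression = as.integer(cohort$patient_id %in% depressed),
             palliative = as.integer(cohort$patient_id %in% palliative))
}

#' Build the 48 monthly subpopulations
#'
#' For each health state and month of follow-up, the subpopulation holds
#' every patient alive at the start of that month of the state period
#' (strictly: a death on the boundary day excludes) and in that state on
#' that day. The admitted-in-month indicator marks patients with at least
#' one daily utility estimate inside the half-open 30-day window, and the
#' observed monthly HSU is the mean of those daily estimates.
#'
#' @param timelines an `"hs_timelines"` object.
#' @param trajectories daily utility trajectories (columns `patient_id`,
#'   `day` on the calendar scale, `utility`), see [build_trajectories()].
#' @param registry the registry (for covariates).
#' @return named list (`"state:month"`) of data frames with `patient_id`,
#'   `admitted`, `hsu`, and the covariate columns.
#' @export
build_subpopulations <- function(timelines, trajectories, registry) {
  defs <- subpop_definitions()
  cov <- hsu_covariates(timelines$cohort, registry)
  iv <- timelines$intervals
  dx <- timelines$cohort$diagnosis_day
  names(dx) <- timelines$cohort$patient_id
  end <- vapply(timelines$timelines, `[[`, 0, "end_day")
  names(end) <- names(timelines$timelines)

  # trajectories on the diagnosis-relative day scale
  tr <- trajectories
  tr$rel_day <- tr$day - dx[as.character(tr$patient_id)]

  out <- vector("list", nrow(defs))
  names(out) <- paste0(defs$state, ":", defs$month)
  for (r in seq_len(nrow(defs))) {
    wstart <- defs$entry[r] + 30 * (defs$month[r] - 1L)
    wend <- wstart + 30
    at_start <- iv$start <= wstart & wstart < iv$end & iv$state == defs$state[r]
    ids <- iv$patient_id[at_start]
    alive <- wstart < end[as.character(ids)]
    ids <- ids[alive]
    if (length(ids) == 0L) { out[r] <- list(NULL); next }
    trw <- tr[tr$patient_id %in% ids & tr$rel_day >= wstart & tr$rel_day < wend, ]
    hsu <- tapply(trw$utility, trw$patient_id, monthly_patient_hsu)
    df <- data.frame(patient_id = ids)
    df$admitted <- df$patient_id %in% as.integer(names(hsu))
    df$hsu <- as.numeric(hsu[as.character(df$patient_id)])
    df <- merge(df, cov, by = "patient_id", sort = TRUE)
    out[[r]] <- df
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Impute HSU for patients unrecorded in post-acute care
#'
#' Uses the outcome equation of a fitted two-step selection model to impute
#' HSU for the non-admitted patients of a subpopulation: the
#' population-level linear prediction \eqn{\gamma Y_i} (no inverse-Mills
#' term; `conditional = TRUE` instead subtracts the non-selected correction
#' \eqn{\lambda \phi/(1-\Phi)} for sensitivity analysis). Predictions are
#' clipped to the utility scale `[-0.53, 1.00]` and the number of clipped
#' values is attached as attribute `n_clipped`.
#'
#' @param fit a `"heckit2"` fit for the subpopulation.
#' @param newdata covariate rows of the non-admitted patients (must contain
#'   a `patient_id` column and complete covariates).
#' @param conditional use the non-selected conditional expectation.
#' @param worst,best utility-scale bounds for clipping.
#' @return numeric imputed utilities, one per row of `newdata`.
#' @export
impute_hsu <- function(fit, newdata, conditional = FALSE,
                       worst = -0.53, best = 1.00) {
  if (nrow(newdata) == 0L) return(numeric(0))
  vars <- all.vars(stats::delete.response(stats::terms(fit$outcome)))
  miss <- !stats::complete.cases(newdata[, vars, drop = FALSE])
  if (any(miss))
    stop("missing covariates for patient(s): ",
         paste(newdata$patient_id[miss], collapse = ", "))
  p <- predict(fit, newdata,
               type = if (conditional) "conditional" else "unconditional")
  clipped <- p < worst | p > best
  out <- pmin(pmax(p, worst), best)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

# drop unusable factor covariates (single observed level) from a formula
prune_formula <- function(formula, data) {
  vars <- all.vars(formula[[3]])
  drop <- vars[vapply(vars, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) < 2L
  }, TRUE)]
  if (length(drop))
    formula <- stats::update(formula,
                             stats::as.formula(paste(". ~ . -", paste(drop, collapse = " - "))))
  formula
}

#' Selection-corrected HSU estimation over all subpopulations
#'
#' Runs, in every (state, month) subpopulation, the Heckman two-step model
#' — probit of post-acute admission on the large covariate set X, outcome
#' OLS of observed monthly HSU on the reduced set Y plus the inverse Mills
#' ratio — then imputes HSU for the non-admitted patients from the outcome
#' equation and aggregates observed, imputed and combined means. The
#' combined mean is the patient-count-weighted average of the observed and
#' imputed components. Standard errors are bootstrap over patients.
#'
#' In subpopulations where the two-step model cannot be fitted (no
#' non-admitted patients, no admitted patients, or too few observations for
#' the covariate design), the imputation falls back to the observed mean
#' and the cell is flagged in `fallback`; cells with no patients are
#' reported as missing.
#'
#' @param subpops list from [build_subpopulations()].
#' @param selection right-hand side of the selection equation (default: the
#'   large covariate set including the hospital-type exclusion covariate).
#' @param outcome right-hand side of the outcome equation (default: the
#'   selection set minus hospital type).
#' @param conditional_imputation impute with the non-selected conditional
#'   expectation instead of the plain linear prediction.
#' @param boot_reps bootstrap replicates for the combined-mean SE
#'   (default 200; 0 disables).
#' @param min_fit minimum numbers of admitted and non-admitted patients
#'   required to attempt the two-step fit.
#' @return object of class `"hsu_table"`: list with `by_state_month` (one
#'   row per subpopulation: n, n_admitted, means and SEs for observed /
#'   imputed / combined, lambda and its p-value, fallback flag, n_clipped),
#'   `by_state` (overall per-state means with age-band and
#'   comorbidity-count breakdowns), `patient_values` (per patient-month
#'   values with their source), and `models` (the per-subpopulation fits).
#' @export
estimate_hsu <- function(subpops,
                         selection = admitted ~ age_band + sex + comorbidity_count +
                           hospital_type + depression + palliative,
                         outcome = hsu ~ age_band + sex + comorbidity_count +
                           depression + palliative,
                         conditional_imputation = FALSE,
                         boot_reps = 200L,
                         min_fit = 10L) {
  rows <- list(); values <- list(); models <- list()
  for (key in names(subpops)) {
    df <- subpops[[key]]
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    st <- parts[1]; mo <- as.integer(parts[2])
    n <- nrow(df); nadm <- sum(df$admitted)
    obs <- df$hsu[df$admitted]
    fallback <- FALSE; lam <- NA_real_; lam_p <- NA_real_; n_clip <- 0L
    imputed <- numeric(0)
    if (nadm == 0L) {
      rows[[key]] <- data.frame(state = st, month = mo, n = n, n_admitted = 0L,
                                mean_observed = NA_real_, mean_imputed = NA_real_,
                                mean_combined = NA_real_, se_combined = NA_real_,
                                lambda = NA_real_, lambda_p = NA_real_,
                                fallback = TRUE, n_clipped = 0L)
      next
    }
    nonadm <- df[!df$admitted, , drop = FALSE]
    if (nadm >= min_fit && nrow(nonadm) >= min_fit) {
      fit <- tryCatch({
        selp <- prune_formula(selection, df)
        outp <- prune_formula(outcome, df[df$admitted, , drop = FALSE])
        heckit2(selp, outp, df)
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        models[[key]] <- fit
        lam <- fit$lambda; lam_p <- fit$lambda_p
        imputed <- tryCatch(impute_hsu(fit, nonadm, conditional = conditional_imputation),
                            error = function(e) NULL)
        if (is.null(imputed)) { imputed <- numeric(0); fallback <- TRUE }
        else n_clip <- attr(imputed, "n_clipped") %||% 0L
      } else fallback <- TRUE
    } else fallback <- nrow(nonadm) > 0L
    if (fallback && nrow(nonadm) > 0L && length(imputed) == 0L)
      imputed <- rep(mean(obs), nrow(nonadm))

    vals <- data.frame(
      state = st, month = mo,
      patient_id = c(df$patient_id[df$admitted], nonadm$patient_id),
      value = c(obs, as.numeric(imputed)),
      source = c(rep("observed", nadm), rep("imputed", length(imputed))))
    values[[key]] <- vals
    comb <- mean(vals$value)
    se <- NA_real_
    if (boot_reps > 0L && nrow(vals) > 1L) {
      bm <- vapply(seq_len(boot_reps), function(b)
        mean(vals$value[sample.int(nrow(vals), replace = TRUE)]), 0)
      se <- stats::sd(bm)
    }
    rows[[key]] <- data.frame(
      state = st, month = mo, n = n, n_admitted = nadm,
      mean_observed = mean(obs),
      mean_imputed = if (length(imputed)) mean(imputed) else NA_real_,
      mean_combined = comb, se_combined = se,
      lambda = lam, lambda_p = lam_p, fallback = fallback, n_clipped = n_clip)
  }
  by_sm <- do.call(rbind, rows)
  rownames(by_sm) <- NULL
  pv <- do.call(rbind, values)
  rownames(pv) <- NULL

  by_state <- NULL
  if (!is.null(pv) && nrow(pv)) {
    agg <- function(d) data.frame(n = nrow(d), mean = mean(d$value), sd = stats::sd(d$value))
    by_state <- do.call(rbind, lapply(split(pv, pv$state), agg))
    by_state <- cbind(state = rownames(by_state), by_state)
    rownames(by_state) <- NULL
  }
  structure(list(by_state_month = by_sm, by_state = by_state,
                 patient_values = pv, models = models),
            class = "hsu_table")
}

#' Per-state HSU breakdowns by age band and comorbidity count
#'
#' Summary analog of an overall HSU table: pooled patient-month values per
#' state, broken down by age band and by comorbidity count.
#'
#' @param hsu an `"hsu_table"` from [estimate_hsu()].
#' @param covariates data frame from [hsu_covariates()].
#' @return data frame with `state`, `group_type`, `group`, `n`, `mean`, `sd`.
#' @export
hsu_breakdown <- function(hsu, covariates) {
  pv <- merge(hsu$patient_values, covariates, by = "patient_id")
  blocks <- list(age_band = pv$age_band, comorbidity_count = pv$comorbidity_count)
  out <- lapply(names(blocks), function(g) {
    sp <- split(pv$value, list(state = pv$state, group = blocks[[g]]), drop = TRUE)
    keys <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
    data.frame(state = keys[, 1], group_type = g, group = keys[, 2],
               n = vapply(sp, length, 0L),
               mean = vapply(sp, mean, 0), sd = vapply(sp, stats::sd, 0))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.hsu_table <- function(x, ...) {
  cat("Health-state utility by state and month of follow-up\n")
  cat(sprintf("  %d subpopulation cells, %d with a fitted selection model\n",
              nrow(x$by_state_month), length(x$models)))
  if (!is.null(x$by_state)) {
    cat("Overall per-state combined HSU:\n")
    print(transform(x$by_state, mean = round(mean, 3), sd = round(sd, 3)))
  }
  invisible(x)
}
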