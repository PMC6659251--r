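#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit survival estimator (via [survival::survfit()]) with the
#' Greenwood variance of the survival probability.
#'
#' @param durations positive follow-up durations.
#' @param events event indicator (1 = event, 0 = censored).
#' @return object of class `"km_curve"`: data frame `time`, `n_risk`,
#'   `n_event`, `surv`, `var_greenwood`, plus attributes `n` and `fit`.
#' @export
km_estimate <- function(durations, events) {
  if (length(durations) == 0L) stop("empty input: no durations")
  if (any(durations <= 0)) stop("durations must be positive")
  stopifnot(length(durations) == length(events))
  fit <- survival::survfit(survival::Surv(durations, events) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    surv = fit$surv,
                    var_greenwood = (fit$surv * fit$std.err)^2)
  structure(out, class = c("km_curve", "data.frame"), n = length(durations), fit = fit)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a `"km_curve"`.
#' @param times times at which to read the step function (right-continuous).
#' @return numeric survival probabilities.
#' @export
km_surv_at <- function(curve, times) {
  stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)(times)
}

#' Per-state Kaplan-Meier survival curves
#'
#' Survival from entry into each health state, capped at 12 months of
#' within-state follow-up, as a test of the association of health state
#' with survival.
#'
#' @param timelines an `"hs_timelines"` object.
#' @param max_days follow-up cap in days (default 360).
#' @return named list of `"km_curve"` objects, one per health state present.
#' @export
km_by_state <- function(timelines, max_days = 360) {
  d <- state_survival_data(timelines, max_days = max_days)
  d <- d[d$time > 0, ]
  lapply(split(d, d$state), function(s) km_estimate(s$time, s$event))
}

#' Time to first post-acute admission with death as competing event
#'
#' Builds, from timelines and the registry's stays, one row per patient per
#' state entry: the time from state entry to the first post-acute admission
#' on or after entry, with death without post-acute care as the competing
#' event and administrative censoring otherwise, capped at `max_days`.
#'
#' @param timelines an `"hs_timelines"` object.
#' @param registry the registry (for post-acute stay days).
#' @param max_days follow-up cap within the state (default 360).
#' @return data frame `patient_id`, `state`, `time`, `event` with `event`
#'   in `c("censored", "admission", "death")`.
#' @export
admission_analysis_data <- function(timelines, registry, max_days = 360) {
  pa <- registry$stays[registry$stays$care_type == "post_acute", ]
  dx <- timelines$cohort$diagnosis_day[match(pa$patient_id, timelines$cohort$patient_id)]
  pa <- pa[!is.na(dx), ]; dx <- dx[!is.na(dx)]
  pa_rel <- data.frame(patient_id = pa$patient_id, day = pa$admission_day - dx)

  iv <- timelines$intervals
  first <- !duplicated(iv[, c("patient_id", "state")])
  iv <- iv[first, ]
  key <- as.character(iv$patient_id)
  end <- vapply(timelines$timelines, `[[`, 0, "end_day")[key]
  dead <- vapply(timelines$timelines, `[[`, TRUE, "death_flag")[key]

  rows <- lapply(seq_len(nrow(iv)), function(i) {
    entry <- iv$start[i]
    horizon <- min(end[i] - entry, max_days)
    if (horizon <= 0) return(NULL)
    adm <- pa_rel$day[pa_rel$patient_id == iv$patient_id[i]] - entry
    adm <- adm[adm >= 0 & adm < horizon]
    if (length(adm)) {
      data.frame(patient_id = iv$patient_id[i], state = iv$state[i],
                 time = max(min(adm), 0.5), event = "admission")
    } else if (dead[i] && (end[i] - entry) <= max_days) {
      data.frame(patient_id = iv$patient_id[i], state = iv$state[i],
                 time = end[i] - entry, event = "death")
    } else {
      data.frame(patient_id = iv$patient_id[i], state = iv$state[i],
                 time = horizon, event = "censored")
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no follow-up available for any state entry")
  rownames(out) <- NULL
  out
}

#' Competing-risks analysis of post-acute admission
#'
#' Aalen-Johansen cumulative incidence functions for admission and for
#' death without post-acute care (via multi-state [survival::survfit()],
#' which enforces CIF/survival conservation), and a Fine-Gray
#' subdistribution-hazard regression of admission on a covariate (via
#' [cmprsk::crr()]), reporting the hazard ratio with a 95% CI.
#'
#' @param time time to first event (positive).
#' @param event factor or character in `c("censored", "admission", "death")`.
#' @param covariate covariate for the Fine-Gray regression (numeric vector
#'   or a factor; model matrix columns are contrasts against the first
#'   level). `NULL` fits CIFs only.
#' @return object of class `"cr_admission"`: list with `cif` (data frame
#'   `time`, `state`, `estimate` where state `(s0)` is overall survival),
#'   `fg` (`NULL` or list `coef`, `se`, `hr`, `ci`, `p`), `n`, `events`.
#' @export
fit_competing_admission <- function(time, event, covariate = NULL) {
  if (length(time) == 0L) stop("empty input")
  if (any(time <= 0)) stop("zero or negative follow-up time")
  ev <- factor(as.character(event), levels = c("censored", "admission", "death"))
  if (anyNA(ev)) stop("event must be one of censored/admission/death")
  fit <- survival::survfit(survival::Surv(time, ev) ~ 1)
  cif <- data.frame(time = rep(fit$time, ncol(fit$pstate)),
                    state = rep(fit$states, each = length(fit$time)),
                    estimate = as.vector(fit$pstate))
  fg <- NULL
  if (!is.null(covariate)) {
    if (sum(ev == "admission") == 0L) {
      warning("no admission events; Fine-Gray regression skipped")
    } else {
      X <- stats::model.matrix(~z, data.frame(z = covariate))[, -1, drop = FALSE]
      status <- as.integer(ev) - 1L  # 0 censored, 1 admission, 2 death
      cr <- cmprsk::crr(ftime = time, fstatus = status, cov1 = X,
                        failcode = 1, cencode = 0)
      se <- sqrt(diag(cr$var))
      fg <- list(coef = cr$coef, se = se, hr = exp(cr$coef),
                 ci = exp(cbind(lower = cr$coef - 1.96 * se,
                                upper = cr$coef + 1.96 * se)),
                 p = 2 * stats::pnorm(-abs(cr$coef / se)))
    }
  }
  structure(list(cif = cif, fg = fg, n = length(time), events = table(ev),
                 fit = fit), class = "cr_admission")
}

#' @export
print.cr_admission <- function(x, ...) {
  cat("Competing-risks analysis of post-acute admission\n")
  print(x$events)
  if (!is.null(x$fg)) {
    cat("Fine-Gray subdistribution hazard ratios (admission):\n")
    tab <- cbind(HR = x$fg$hr, x$fg$ci, p = x$fg$p)
    print(round(tab, 4))
  }
  invisible(x)
}
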