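#' Cohort selection specification
#'
#' Windows and diagnosis-code sets for incident-case selection: patients
#' whose first qualifying diagnosis falls inside the incident window, with
#' no qualifying record during the preceding washout window, and no
#' personal-history exclusion code at or before diagnosis.
#'
#' @param incident_window half-open day window `[start, end)` of incident
#'   diagnoses.
#' @param washout_window half-open day window `[start, end)` preceding the
#'   incident window; must end exactly where the incident window begins.
#' @param qualifying_codes diagnosis codes defining the condition (primary
#'   or associated position both qualify).
#' @param exclusion_codes codes marking a personal history of the condition.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(incident_window = c(730L, 1825L),
                        washout_window = c(0L, 730L),
                        qualifying_codes = c("SITE_A", "SITE_B"),
                        exclusion_codes = "HISTORY_OF_CANCER") {
  if (washout_window[2] != incident_window[1])
    stop("washout window must end where the incident window begins")
  if (incident_window[2] <= incident_window[1] || washout_window[2] <= washout_window[1])
    stop("windows must be non-empty half-open intervals [start, end)")
  if (length(intersect(qualifying_codes, exclusion_codes)))
    stop("qualifying and exclusion code sets must be disjoint")
  structure(list(incident_window = as.integer(incident_window),
                 washout_window = as.integer(washout_window),
                 qualifying_codes = qualifying_codes,
                 exclusion_codes = exclusion_codes),
            class = "cohort_spec")
}

# long table of (patient_id, day, code, position): diagnoses dated by the
# admission day of their stay
diagnosis_events <- function(registry) {
  m <- match(registry$diagnoses$stay_id, registry$stays$stay_id)
  data.frame(patient_id = registry$stays$patient_id[m],
             day = registry$stays$admission_day[m],
             code = registry$diagnoses$code,
             position = registry$diagnoses$position)
}

#' Select incident patients
#'
#' Returns the patients whose first qualifying diagnosis day falls inside
#' the incident window and who have no qualifying record during the washout
#' window (prevalent cases are excluded). The diagnosis day of each
#' selected patient is that first qualifying day.
#'
#' @param registry a `"registry"` object.
#' @param spec a [cohort_spec()].
#' @return a data frame (class `"cohort"`) with `patient_id`,
#'   `diagnosis_day`, and the baseline covariate columns of the patients
#'   table; attribute `flow` records counts at each selection step.
#' @export
select_incident <- function(registry, spec) {
  stopifnot(inherits(registry, "registry"), inherits(spec, "cohort_spec"))
  ev <- diagnosis_events(registry)
  q <- ev[ev$code %in% spec$qualifying_codes, ]
  first_day <- tapply(q$day, q$patient_id, min)
  ids <- as.integer(names(first_day))
  in_washout <- q$day >= spec$washout_window[1] & q$day < spec$washout_window[2]
  prevalent_ids <- unique(q$patient_id[in_washout])
  incident <- is.finite(first_day) &
    first_day >= spec$incident_window[1] & first_day < spec$incident_window[2] &
    !(ids %in% prevalent_ids)
  out <- data.frame(patient_id = ids[incident],
                    diagnosis_day = as.integer(first_day[incident]))
  out <- merge(out, registry$patients, by = "patient_id", sort = TRUE)
  out <- out[order(out$patient_id), ]
  rownames(out) <- NULL
  attr(out, "flow") <- list(
    n_registry = nrow(registry$patients),
    n_with_qualifying = length(ids),
    n_prevalent_excluded = sum(ids %in% prevalent_ids),
    n_incident = nrow(out))
  class(out) <- c("cohort", "data.frame")
  out
}

#' Exclude incident patients with a personal history of the condition
#'
#' Removes patients carrying any exclusion code dated at or before their
#' diagnosis day (a history code recorded only later is read as a
#' consequence of the incident disease itself and does not exclude).
#'
#' @param cohort a cohort from [select_incident()].
#' @param registry the registry the cohort was built from.
#' @param spec the same [cohort_spec()].
#' @return the filtered cohort; attribute `flow` gains
#'   `n_history_excluded` and `n_final`.
#' @export
apply_history_exclusion <- function(cohort, registry, spec) {
  stopifnot(inherits(cohort, "cohort"))
  flow <- attr(cohort, "flow")
  ev <- diagnosis_events(registry)
  h <- ev[ev$code %in% spec$exclusion_codes, ]
  dx <- cohort$diagnosis_day[match(h$patient_id, cohort$patient_id)]
  bad <- unique(h$patient_id[!is.na(dx) & h$day <= dx])
  out <- cohort[!(cohort$patient_id %in% bad), ]
  rownames(out) <- NULL
  flow$n_history_excluded <- length(bad)
  flow$n_final <- nrow(out)
  attr(out, "flow") <- flow
  class(out) <- c("cohort", "data.frame")
  out
}

#' Build the analysis cohort in one call
#'
#' Convenience wrapper: [select_incident()] followed by
#' [apply_history_exclusion()].
#'
#' @inheritParams select_incident
#' @return a `"cohort"` data frame with the selection flow-chart attached
#'   as attribute `flow`.
#' @export
build_cohort <- function(registry, spec = cohort_spec()) {
  apply_history_exclusion(select_incident(registry, spec), registry, spec)
}
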