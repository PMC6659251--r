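#' Assign the cancer stage at initial treatment
#'
#' Stage is read from all diagnosis events recorded during the
#' initial-treatment phase (the first 180 days after diagnosis), with
#' precedence metastatic > locally advanced > early: any record of distant
#' metastasis identifies a metastatic stage; otherwise any diagnosis of
#' locoregional extension or any initial treatment excluding an early stage
#' (chemotherapy) identifies a locally advanced stage; early stage is the
#' default.
#'
#' @param events data frame with columns `day` (relative to diagnosis) and
#'   `code`; only events with `day` in `[0, 180)` are considered.
#' @return one of `"metastatic"`, `"locally_advanced"`, `"early"`.
#' @export
assign_initial_stage <- function(events) {
  codes <- registry_codes()
  ev <- events[!is.na(events$day) & events$day >= 0 & events$day < 180, , drop = FALSE]
  if (any(ev$code == codes$metastasis)) return("metastatic")
  if (any(ev$code %in% c(codes$locoregional, codes$chemo))) return("locally_advanced")
  "early"
}

#' Detect relapse in the follow-up period
#'
#' For a patient initially treated at early or locally advanced stage,
#' relapse is the first record, on or after day 180, of either a local
#' relapse (a diagnosis in *primary* position identical to the original
#' cancer site) or a new event indicative of extension (distant metastasis,
#' locoregional extension, or chemotherapy, in any position).
#'
#' @param events data frame with columns `day` (relative to diagnosis),
#'   `code`, `position`.
#' @param initial_stage the stage from [assign_initial_stage()]; calling
#'   this on a metastatic patient is an error (metastatic is absorbing).
#' @param primary_site the original cancer site code of the patient.
#' @return the relapse day (integer) or `NA` if no qualifying event.
#' @export
detect_relapse <- function(events, initial_stage, primary_site) {
  if (initial_stage == "metastatic")
    stop("relapse detection does not apply to metastatic patients")
  codes <- registry_codes()
  ev <- events[!is.na(events$day) & events$day >= 180, , drop = FALSE]
  local <- ev$code == primary_site & ev$position == "primary"
  extension <- ev$code %in% c(codes$metastasis, codes$locoregional, codes$chemo)
  hit <- ev$day[local | extension]
  if (length(hit)) as.integer(min(hit)) else NA_integer_
}

#' Build a patient's health-state timeline
#'
#' Partitions a patient's follow-up, in days relative to diagnosis, into
#' contiguous half-open health-state intervals over the two periods:
#' the initial stage covers `[0, min(180, end))`; metastatic patients stay
#' in the metastatic state until end of follow-up (absorbing); other
#' patients enter the relapse-free state at day 180 and, if a relapse
#' occurs, the absorbing relapse state from the relapse day. Follow-up ends
#' at the earlier of death and administrative censoring.
#'
#' @param patient_id patient identifier carried through.
#' @param events diagnosis events of the patient (columns `day`, `code`,
#'   `position`; days relative to diagnosis).
#' @param primary_site the patient's original cancer site code.
#' @param death_day death day relative to diagnosis, or `NA`.
#' @param censor_day administrative censoring day relative to diagnosis.
#' @return an object of class `"hs_timeline"`: list with `patient_id`,
#'   `initial_stage`, `relapse_day`, `intervals` (data frame `state`,
#'   `start`, `end`, half-open), `end_day`, `death_flag`.
#' @export
build_timeline <- function(patient_id, events, primary_site, death_day, censor_day) {
  if (!is.na(death_day) && death_day < 0) stop("death before day 0")
  if (is.na(censor_day) || censor_day < 0) stop("censoring day must be >= 0")
  end_day <- if (is.na(death_day)) censor_day else min(death_day, censor_day)
  death_flag <- !is.na(death_day) && death_day <= censor_day
  stage <- assign_initial_stage(events)
  relapse_day <- NA_integer_
  iv <- data.frame(state = character(), start = numeric(), end = numeric())
  add <- function(state, start, end) {
    if (end > start) iv <<- rbind(iv, data.frame(state = state, start = start, end = end))
  }
  if (stage == "metastatic") {
    add("metastatic", 0, end_day)
  } else {
    add(stage, 0, min(180, end_day))
    if (end_day > 180) {
      relapse_day <- detect_relapse(events, stage, primary_site)
      if (!is.na(relapse_day) && relapse_day < end_day) {
        add("relapse_free", 180, relapse_day)
        add("relapse", relapse_day, end_day)
      } else {
        relapse_day <- NA_integer_
        add("relapse_free", 180, end_day)
      }
    }
  }
  structure(list(patient_id = patient_id, initial_stage = stage,
                 relapse_day = relapse_day, intervals = iv,
                 end_day = end_day, death_flag = death_flag),
            class = "hs_timeline")
}

#' @export
print.hs_timeline <- function(x, ...) {
  cat(sprintf("Health-state timeline, patient %s: %s at initial treatment, %s, end day %d (%s)\n",
              x$patient_id, x$initial_stage,
              if (is.na(x$relapse_day)) "no relapse" else paste0("relapse day ", x$relapse_day),
              as.integer(x$end_day), if (x$death_flag) "death" else "censored"))
  print(x$intervals)
  invisible(x)
}

#' Health-state timelines for a whole cohort
#'
#' Applies [build_timeline()] to every cohort patient, using the registry's
#' diagnosis and death records and a common administrative censoring day.
#'
#' @param cohort a `"cohort"` data frame (see [build_cohort()]).
#' @param registry the registry.
#' @param censor_day administrative censoring day on the calendar scale.
#' @return a list of class `"hs_timelines"`: `timelines` (named list of
#'   `"hs_timeline"`), `intervals` (long data frame with `patient_id`,
#'   `state`, `start`, `end`), `cohort`, `censor_day`.
#' @export
build_timelines <- function(cohort, registry, censor_day) {
  ev <- diagnosis_events(registry)
  ev <- ev[ev$patient_id %in% cohort$patient_id, ]
  site_codes <- registry_codes()$sites
  death <- registry$deaths$day[match(cohort$patient_id, registry$deaths$patient_id)]
  tls <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    dx <- cohort$diagnosis_day[i]
    e <- ev[ev$patient_id == pid, ]
    e$day <- e$day - dx
    site <- e$code[e$code %in% site_codes & e$day == 0 & e$position == "primary"][1]
    if (is.na(site)) site <- e$code[e$code %in% site_codes][1]
    tls[[i]] <- build_timeline(pid, e, site,
                               death_day = if (is.na(death[i])) NA else death[i] - dx,
                               censor_day = censor_day - dx)
  }
  names(tls) <- cohort$patient_id
  intervals <- do.call(rbind, lapply(tls, function(t)
    if (nrow(t$intervals)) cbind(patient_id = t$patient_id, t$intervals) else NULL))
  rownames(intervals) <- NULL
  structure(list(timelines = tls, intervals = intervals, cohort = cohort,
                 censor_day = censor_day), class = "hs_timelines")
}

#' @export
print.hs_timelines <- function(x, ...) {
  cat(sprintf("Health-state timelines for %d patients (censor day %d)\n",
              length(x$timelines), as.integer(x$censor_day)))
  stage <- vapply(x$timelines, `[[`, "", "initial_stage")
  print(table(initial_stage = stage))
  invisible(x)
}

#' Per-state survival data from timelines
#'
#' One row per state entry: time from entry into the state to death or
#' censoring, capped at `max_days` of follow-up within the state.
#'
#' @param timelines an `"hs_timelines"` object.
#' @param max_days maximum analyzed follow-up within a state (default 360).
#' @return data frame `patient_id`, `state`, `entry`, `time`, `event`
#'   (1 = death within the window).
#' @export
state_survival_data <- function(timelines, max_days = 360) {
  iv <- timelines$intervals
  end <- vapply(timelines$timelines, `[[`, 0, "end_day")[as.character(iv$patient_id)]
  dead <- vapply(timelines$timelines, `[[`, TRUE, "death_flag")[as.character(iv$patient_id)]
  # a state entry is the first interval of each (patient, state)
  first <- !duplicated(iv[, c("patient_id", "state")])
  iv <- iv[first, ]; end <- end[first]; dead <- dead[first]
  time <- pmin(end - iv$start, max_days)
  event <- as.integer(dead & (end - iv$start) <= max_days)
  data.frame(patient_id = iv$patient_id, state = iv$state, entry = iv$start,
             time = time, event = event)
}
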