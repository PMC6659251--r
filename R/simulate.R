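#' Simulation configuration for the synthetic hospital registry
#'
#' Bundles and validates every parameter of the synthetic discharge-registry
#' generator: calendar windows, the ground-truth graded response model and
#' latent-trait structure, per-state daily death hazards, the probit
#' post-acute admission model (whose latent-trait coefficient `delta`
#' controls the strength of selection), stage mix at diagnosis, relapse
#' hazard, ADL assessment cadence, and covariate distributions.
#'
#' The defaults encode the study conditions the generator emulates: a
#' day-indexed calendar with a two-year washout window followed by a
#' three-year incident window and administrative censoring at day 2007;
#' ~70% late-stage diagnoses; six ADLs with slopes spanning roughly 1.1-5.5
#' and mostly negative thresholds; admission into post-acute care more
#' likely for patients in poor latent health (`delta < 0`).
#'
#' @param n_patients number of patients to simulate.
#' @param calendar_span_days administrative censoring day (calendar end).
#' @param washout_days end of the prevalent-history washout window
#'   `[0, washout_days)`.
#' @param incident_end end of the incident window
#'   `[washout_days, incident_end)`.
#' @param seed integer seed; the seed fully determines the output.
#' @param true_grm list with `alpha` (6 positive slopes), `beta` (6 x 3
#'   strictly increasing rows), `state_shift` (named latent-mean shift per
#'   health state), `covariate_shift` (list `age`, `comorbidity`:
#'   per-unit latent shifts).
#' @param state_hazards named per-state daily death hazard (1/day).
#' @param admission_model list of probit coefficients: `intercept`, `age`
#'   (per age-band step), `comorbidity` (per count), `hospital` (named
#'   vector over hospital types), `delta` (coefficient of the latent trait;
#'   negative means sicker patients are admitted more).
#' @param stage_mix probabilities of (early, locally_advanced, metastatic)
#'   stage at diagnosis; must sum to 1.
#' @param relapse_hazard daily relapse hazard for early/locally-advanced
#'   survivors after day 180.
#' @param adl_cadence_days days between ADL assessments within a post-acute
#'   stay (default 7: scored at admission and then weekly).
#' @param prevalent_frac fraction of patients with a qualifying diagnosis
#'   already inside the washout window.
#' @param history_frac fraction of incident patients carrying a
#'   personal-history-of-cancer code at or before diagnosis.
#' @param theta_sd_patient,theta_sd_month standard deviations of the
#'   patient-level and month-level latent noise.
#' @param theta_fixed if non-`NULL`, override every latent trait value with
#'   this constant (used for closed-form checks).
#' @param postacute_los integer range (min, max) of post-acute length of
#'   stay in days.
#' @param covariate_model list of sampling probabilities: `sex_male`,
#'   `age_band` (named), `comorbidity` (probabilities for counts 0..3),
#'   `hospital` (named), `depression`, `palliative_metastatic`.
#' @return a validated object of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 1000L,
                       calendar_span_days = 2007L,
                       washout_days = 730L,
                       incident_end = 1825L,
                       seed = 1L,
                       true_grm = list(
                         alpha = c(5.5, 3.5, 1.1, 2.2, 2.8, 1.6),
                         beta = rbind(c(-2.5, -0.9, 1.0),
                                      c(-2.0, -0.8, 0.8),
                                      c(-1.2, -0.1, 1.0),
                                      c(-2.2, -1.2, -0.3),
                                      c(-1.8, -0.6, 0.6),
                                      c(-1.9, -0.7, -0.1)),
                         state_shift = c(early = 0.2, locally_advanced = 0,
                                         metastatic = -0.9, relapse = -0.7,
                                         relapse_free = 0.45),
                         covariate_shift = list(age = -0.12, comorbidity = -0.18)
                       ),
                       state_hazards = c(early = 4e-4, locally_advanced = 8e-4,
                                         metastatic = 4e-3, relapse = 3e-3,
                                         relapse_free = 2.5e-4),
                       admission_model = list(
                         intercept = -1.0, age = 0.12, comorbidity = 0.15,
                         hospital = c(public = 0, cancer_center = 0.35,
                                      private = -0.15),
                         delta = -0.6),
                       stage_mix = c(early = 0.30, locally_advanced = 0.55,
                                     metastatic = 0.15),
                       relapse_hazard = 1.2e-3,
                       adl_cadence_days = 7L,
                       prevalent_frac = 0.25,
                       history_frac = 0.05,
                       theta_sd_patient = 0.5,
                       theta_sd_month = 0.3,
                       theta_fixed = NULL,
                       postacute_los = c(7L, 28L),
                       covariate_model = list(
                         sex_male = 0.75,
                         age_band = c(`18-49` = 0.14, `50-59` = 0.20,
                                      `60-69` = 0.30, `70-79` = 0.22,
                                      `80+` = 0.14),
                         comorbidity = c(0.45, 0.27, 0.15, 0.13),
                         hospital = c(public = 0.5, cancer_center = 0.2,
                                      private = 0.3),
                         depression = 0.15,
                         palliative_metastatic = 0.25)) {
  cfg <- list(n_patients = as.integer(n_patients),
              calendar_span_days = as.integer(calendar_span_days),
              washout_days = as.integer(washout_days),
              incident_end = as.integer(incident_end),
              seed = as.integer(seed), true_grm = true_grm,
              state_hazards = state_hazards, admission_model = admission_model,
              stage_mix = stage_mix, relapse_hazard = relapse_hazard,
              adl_cadence_days = as.integer(adl_cadence_days),
              prevalent_frac = prevalent_frac, history_frac = history_frac,
              theta_sd_patient = theta_sd_patient,
              theta_sd_month = theta_sd_month, theta_fixed = theta_fixed,
              postacute_los = as.integer(postacute_los),
              covariate_model = covariate_model)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) stop("invalid sim_config field `", field, "`: ", why,
                                    call. = FALSE)
  if (is.na(cfg$n_patients) || cfg$n_patients < 0L) fail("n_patients", "must be >= 0")
  if (cfg$washout_days <= 0L) fail("washout_days", "must be positive")
  if (cfg$incident_end <= cfg$washout_days)
    fail("incident_end", "incident window must follow the washout window")
  if (cfg$calendar_span_days < cfg$incident_end)
    fail("calendar_span_days", "must extend beyond the incident window")
  g <- cfg$true_grm
  if (length(g$alpha) != 6L || any(g$alpha <= 0)) fail("true_grm$alpha", "six positive slopes required")
  if (!is.matrix(g$beta) || nrow(g$beta) != 6L ||
      any(apply(g$beta, 1, function(b) is.unsorted(b, strictly = TRUE))))
    fail("true_grm$beta", "6 rows of strictly increasing thresholds required")
  if (!all(names(cfg$state_hazards) %in% health_state_levels()) ||
      any(cfg$state_hazards < 0))
    fail("state_hazards", "named non-negative daily hazards per health state required")
  if (abs(sum(cfg$stage_mix) - 1) > 1e-8) fail("stage_mix", "must sum to 1")
  if (cfg$relapse_hazard < 0) fail("relapse_hazard", "must be >= 0")
  if (cfg$adl_cadence_days < 1L) fail("adl_cadence_days", "must be >= 1 day")
  if (cfg$prevalent_frac < 0 || cfg$prevalent_frac > 1) fail("prevalent_frac", "must lie in [0,1]")
  if (length(cfg$postacute_los) != 2L || cfg$postacute_los[1] < 1L ||
      cfg$postacute_los[2] < cfg$postacute_los[1])
    fail("postacute_los", "must be an increasing (min, max) day range")
  invisible(cfg)
}

#' Health state labels
#'
#' The five health states over the two analysis periods: three stages at
#' initial treatment and two follow-up states.
#' @return character vector of state labels.
#' @export
health_state_levels <- function() {
  c("early", "locally_advanced", "metastatic", "relapse", "relapse_free")
}

# diagnosis vocabulary of the synthetic registry
registry_codes <- function() {
  list(sites = c("SITE_A", "SITE_B"),
       metastasis = "METASTASIS", locoregional = "LOCOREGIONAL",
       chemo = "CHEMO", history = "HISTORY_OF_CANCER",
       comorbid = paste0("COMORBID_", 1:3),
       depression = "DEPRESSION", palliative = "PALLIATIVE")
}

# state of a patient at relative day t (vectorized over t)
state_at <- function(t, stage, relapse_rel) {
  ifelse(t < 180, stage,
         ifelse(stage == "metastatic", "metastatic",
                ifelse(t >= relapse_rel, "relapse", "relapse_free")))
}

# death time from a piecewise-constant hazard with breakpoints at 180 and
# the relapse day; returns relative day (possibly Inf)
sim_death_time <- function(stage, relapse_rel, hz) {
  if (stage == "metastatic") {
    if (hz[["metastatic"]] <= 0) return(Inf)
    return(stats::rexp(1, hz[["metastatic"]]))
  }
  bounds <- c(0, 180, relapse_rel, Inf)
  states <- c(stage, "relapse_free", "relapse")
  if (!is.finite(relapse_rel)) { bounds <- c(0, 180, Inf); states <- states[1:2] }
  t0 <- 0
  for (s in seq_along(states)) {
    h <- hz[[states[s]]]
    len <- bounds[s + 1L] - bounds[s]
    if (h <= 0) { t0 <- bounds[s + 1L]; next }
    d <- stats::rexp(1, h)
    if (d < len) return(bounds[s] + d)
  }
  Inf
}

#' Generate a synthetic hospital discharge registry
#'
#' Simulates the five long-format registry tables (patients, stays,
#' diagnoses, ADL assessments, deaths) with the statistical structure the
#' downstream pipeline assumes: incident and prevalent cancer patients; a
#' small diagnosis vocabulary distinguishing cancer site, locoregional
#' extension, distant metastasis, chemotherapy, comorbidities and personal
#' history of cancer; a latent health trait that is constant within 30-day
#' months and shifts with health state and covariates; weekly ADL scoring in
#' post-acute care drawn category-wise from the ground-truth graded response
#' model; per-state daily death hazards; and a monthly probit post-acute
#' admission process correlated with the latent trait, which induces the
#' selection bias the Heckman stage corrects.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `"registry"`: a list of the five data frames
#'   plus a `truth` component (ground-truth parameters and the per
#'   patient-month latent trait, state, and admission draws) that is
#'   withheld by [write_registry()] and used only for validation.
#' @export
generate_registry <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  cm <- config$covariate_model
  codes <- registry_codes()
  n <- config$n_patients
  empty <- empty_registry()
  if (n == 0L) return(empty)

  bands <- names(cm$age_band)
  band_lo <- c(18, 50, 60, 70, 80); band_hi <- c(49, 59, 69, 79, 92)

  pid <- seq_len(n)
  sex <- ifelse(stats::runif(n) < cm$sex_male, "M", "F")
  band_idx <- sample.int(length(bands), n, replace = TRUE, prob = cm$age_band)
  age <- band_lo[band_idx] + floor(stats::runif(n) * (band_hi[band_idx] - band_lo[band_idx] + 1))
  comorb <- sample(0:3, n, replace = TRUE, prob = cm$comorbidity)
  hosp <- sample(names(cm$hospital), n, replace = TRUE, prob = cm$hospital)
  depr <- stats::runif(n) < cm$depression
  prevalent <- stats::runif(n) < config$prevalent_frac
  site <- sample(codes$sites, n, replace = TRUE)
  stage <- sample(names(config$stage_mix), n, replace = TRUE, prob = config$stage_mix)

  # diagnosis day: washout window for prevalent patients, incident window otherwise
  dx <- integer(n)
  dx[prevalent] <- sample.int(config$washout_days, sum(prevalent), replace = TRUE) - 1L
  dx[!prevalent] <- config$washout_days +
    sample.int(config$incident_end - config$washout_days, sum(!prevalent), replace = TRUE) - 1L
  history <- !prevalent & stats::runif(n) < config$history_frac
  # some prevalent patients also show up with a qualifying stay in the incident window
  prev_reappear <- prevalent & stats::runif(n) < 0.7
  reappear_day <- ifelse(prev_reappear,
                         config$washout_days +
                           floor(stats::runif(n) * (config$incident_end - config$washout_days)),
                         NA_integer_)

  birth_year <- 2008L + dx %/% 365L - age

  # relapse and death (relative to diagnosis day)
  relapse_rel <- rep(Inf, n)
  at_risk <- stage != "metastatic"
  if (config$relapse_hazard > 0)
    relapse_rel[at_risk] <- 180 + stats::rexp(sum(at_risk), config$relapse_hazard)
  death_rel <- vapply(seq_len(n), function(i)
    sim_death_time(stage[i], relapse_rel[i], config$state_hazards), 0)
  censor_rel <- config$calendar_span_days - dx
  end_rel <- pmin(death_rel, censor_rel)
  relapse_rel[relapse_rel >= end_rel] <- Inf

  # ---- patient-month grid: latent trait and admission draws ----------------
  n_months <- pmin(pmax(ceiling(end_rel / 30), 1L), 18L)
  gp <- rep(pid, n_months)
  gm <- unlist(lapply(n_months, seq_len), use.names = FALSE)
  gstart <- 30L * (gm - 1L)
  galive <- gstart < end_rel[gp]
  gstate <- state_at(gstart, stage[gp], relapse_rel[gp])
  sshift <- config$true_grm$state_shift[gstate]
  cshift <- config$true_grm$covariate_shift$age * (band_idx[gp] - 1L) +
    config$true_grm$covariate_shift$comorbidity * comorb[gp]
  b_i <- stats::rnorm(n, 0, config$theta_sd_patient)
  gtheta <- sshift + cshift + b_i[gp] + stats::rnorm(length(gp), 0, config$theta_sd_month)
  if (!is.null(config$theta_fixed)) gtheta <- rep(config$theta_fixed, length(gp))

  am <- config$admission_model
  glin <- am$intercept + am$age * (band_idx[gp] - 1L) + am$comorbidity * comorb[gp] +
    am$hospital[hosp[gp]] + am$delta * gtheta
  gadmit <- stats::runif(length(gp)) < stats::pnorm(glin)
  gadmit <- gadmit & galive & !prevalent[gp]

  months <- data.frame(patient_id = gp, month = gm, state = gstate,
                       theta = gtheta, alive = galive,
                       admitted = gadmit, lin_index = unname(glin))

  # ---- stays and diagnoses -------------------------------------------------
  stay_list <- list(); diag_list <- list()
  add_stay <- function(patient, adm, dis, care, htype) {
    stay_list[[length(stay_list) + 1L]] <<- data.frame(
      patient_id = patient, admission_day = as.integer(adm),
      discharge_day = as.integer(dis), care_type = care, hospital_type = htype)
    length(stay_list)
  }
  # index acute stay at diagnosis
  los0 <- 5L + sample.int(11L, n, replace = TRUE) - 1L
  for (i in seq_len(n)) {
    sid <- add_stay(pid[i], dx[i], pmin(dx[i] + los0[i], dx[i] + end_rel[i]), "acute", hosp[i])
    dg <- data.frame(stay_ref = sid, code = site[i], position = "primary")
    if (stage[i] == "metastatic") {
      dg <- rbind(dg, data.frame(stay_ref = sid, code = codes$metastasis, position = "associated"))
      if (stats::runif(1) < 0.5)
        dg <- rbind(dg, data.frame(stay_ref = sid, code = codes$chemo, position = "associated"))
      if (stats::runif(1) < cm$palliative_metastatic)
        dg <- rbind(dg, data.frame(stay_ref = sid, code = codes$palliative, position = "associated"))
    } else if (stage[i] == "locally_advanced") {
      if (stats::runif(1) < 0.6) {
        dg <- rbind(dg, data.frame(stay_ref = sid, code = codes$locoregional, position = "associated"))
      } else if (end_rel[i] > 21) {
        day2 <- dx[i] + 20L + sample.int(max(1L, min(100L, floor(end_rel[i]) - 21L)), 1L)
        sid2 <- add_stay(pid[i], day2, day2 + 3L, "acute", hosp[i])
        dg <- rbind(dg, data.frame(stay_ref = sid2, code = codes$chemo, position = "associated"))
      } else {
        dg <- rbind(dg, data.frame(stay_ref = sid, code = codes$chemo, position = "associated"))
      }
    }
    if (comorb[i] > 0)
      dg <- rbind(dg, data.frame(stay_ref = sid, code = codes$comorbid[seq_len(comorb[i])],
                                 position = "associated"))
    if (depr[i])
      dg <- rbind(dg, data.frame(stay_ref = sid, code = codes$depression, position = "associated"))
    if (history[i]) {
      hday <- max(0L, dx[i] - 30L - sample.int(370L, 1L))
      sidh <- add_stay(pid[i], hday, hday + 2L, "acute", hosp[i])
      dg <- rbind(dg, data.frame(stay_ref = sidh, code = codes$history, position = "associated"))
    }
    if (prev_reappear[i]) {
      sidr <- add_stay(pid[i], reappear_day[i], reappear_day[i] + 4L, "acute", hosp[i])
      dg <- rbind(dg, data.frame(stay_ref = sidr, code = site[i], position = "primary"))
    }
    if (is.finite(relapse_rel[i])) {
      rday <- dx[i] + floor(relapse_rel[i])
      sidr <- add_stay(pid[i], rday, rday + 4L, "acute", hosp[i])
      u <- stats::runif(1)
      dg <- rbind(dg, if (u < 1 / 3)
        data.frame(stay_ref = sidr, code = site[i], position = "primary")
        else if (u < 2 / 3)
          data.frame(stay_ref = sidr, code = codes$metastasis, position = "associated")
        else data.frame(stay_ref = sidr, code = codes$chemo, position = "associated"))
    }
    diag_list[[length(diag_list) + 1L]] <- dg
  }

  # ---- post-acute stays and ADL assessments --------------------------------
  adm_rows <- which(months$admitted)
  month_row0 <- cumsum(c(0L, n_months))  # months grid is contiguous per patient
  adl_list <- list()
  for (r in adm_rows) {
    i <- months$patient_id[r]
    start_rel <- 30 * (months$month[r] - 1L) + sample.int(15L, 1L) - 1L
    if (start_rel >= end_rel[i]) next
    los <- config$postacute_los[1] +
      sample.int(config$postacute_los[2] - config$postacute_los[1] + 1L, 1L) - 1L
    dis_rel <- min(start_rel + los, floor(end_rel[i]))
    if (dis_rel <= start_rel) dis_rel <- start_rel + 1L
    adm_abs <- dx[i] + start_rel
    sid <- add_stay(i, adm_abs, dx[i] + dis_rel, "post_acute", hosp[i])
    days_rel <- seq.int(start_rel, dis_rel, by = config$adl_cadence_days)
    midx <- pmin(pmax(days_rel %/% 30L + 1L, 1L), n_months[i])
    th <- months$theta[month_row0[i] + midx]
    sc <- rgrm(th, config$true_grm$alpha, config$true_grm$beta)
    colnames(sc) <- paste0("adl", 1:6)
    adl_list[[length(adl_list) + 1L]] <-
      data.frame(patient_id = i, stay_ref = sid, day = dx[i] + days_rel, sc)
  }

  stays <- do.call(rbind, stay_list)
  stays$stay_id <- seq_len(nrow(stays))
  stays <- stays[, c("stay_id", "patient_id", "admission_day", "discharge_day",
                     "care_type", "hospital_type")]
  diagnoses <- do.call(rbind, diag_list)
  diagnoses <- data.frame(stay_id = diagnoses$stay_ref, code = diagnoses$code,
                          position = diagnoses$position)
  adl <- if (length(adl_list)) {
    a <- do.call(rbind, adl_list)
    data.frame(patient_id = a$patient_id, stay_id = a$stay_ref, day = a$day,
               a[, paste0("adl", 1:6)])
  } else empty$adl
  rownames(adl) <- NULL

  patients <- data.frame(patient_id = pid, sex = sex, birth_year = birth_year,
                         age_band = bands[band_idx], comorbidity_count = comorb,
                         hospital_type = hosp)
  died <- is.finite(death_rel) & death_rel <= censor_rel
  deaths <- data.frame(patient_id = pid[died],
                       day = as.integer(dx[died] + floor(death_rel[died])))

  structure(list(patients = patients, stays = stays, diagnoses = diagnoses,
                 adl = adl, deaths = deaths,
                 truth = list(grm = config$true_grm, config = config,
                              months = months,
                              patients = data.frame(
                                patient_id = pid, diagnosis_day = dx,
                                stage = stage, prevalent = prevalent,
                                history = history,
                                relapse_rel = relapse_rel,
                                death_rel = death_rel, censor_rel = censor_rel))),
            class = "registry")
}

empty_registry <- function() {
  structure(list(
    patients = data.frame(patient_id = integer(), sex = character(),
                          birth_year = integer(), age_band = character(),
                          comorbidity_count = integer(), hospital_type = character()),
    stays = data.frame(stay_id = integer(), patient_id = integer(),
                       admission_day = integer(), discharge_day = integer(),
                       care_type = character(), hospital_type = character()),
    diagnoses = data.frame(stay_id = integer(), code = character(),
                           position = character()),
    adl = data.frame(patient_id = integer(), stay_id = integer(), day = integer(),
                     adl1 = integer(), adl2 = integer(), adl3 = integer(),
                     adl4 = integer(), adl5 = integer(), adl6 = integer()),
    deaths = data.frame(patient_id = integer(), day = integer()),
    truth = NULL), class = "registry")
}

#' @export
print.registry <- function(x, ...) {
  cat("Synthetic hospital discharge registry\n")
  cat(sprintf("  %d patients, %d stays (%d post-acute), %d diagnosis rows, %d ADL assessments, %d deaths\n",
              nrow(x$patients), nrow(x$stays), sum(x$stays$care_type == "post_acute"),
              nrow(x$diagnoses), nrow(x$adl), nrow(x$deaths)))
  if (!is.null(x$truth)) cat("  ground truth attached (withheld on write)\n")
  invisible(x)
}
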