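# Hand-built miniature registry for cohort / health-state unit tests.
# Windows: washout [0, 100), incident [100, 300), censor day 400.
tiny_spec <- function() {
  cohort_spec(incident_window = c(100L, 300L), washout_window = c(0L, 100L))
}

# patients:
#  1 prevalent: qualifying at day 50 and again at 150
#  2 incident at day 100 (first day of window, boundary inclusion)
#  3 incident at 120 with HISTORY_OF_CANCER at 110 (before dx -> excluded)
#  4 incident at 130 with HISTORY_OF_CANCER at 140 (after dx -> retained)
#  5 no qualifying diagnosis at all
tiny_registry <- function() {
  patients <- data.frame(
    patient_id = 1:5, sex = c("M", "F", "M", "M", "F"),
    birth_year = rep(1950L, 5),
    age_band = rep("60-69", 5), comorbidity_count = c(0L, 1L, 0L, 2L, 0L),
    hospital_type = rep("public", 5))
  stays <- data.frame(
    stay_id = 1:7,
    patient_id = c(1L, 1L, 2L, 3L, 3L, 4L, 4L),
    admission_day = c(50L, 150L, 100L, 110L, 120L, 130L, 140L),
    discharge_day = c(55L, 155L, 105L, 112L, 125L, 135L, 142L),
    care_type = "acute", hospital_type = "public")
  diagnoses <- data.frame(
    stay_id = c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
    code = c("SITE_A", "SITE_A", "SITE_B", "HISTORY_OF_CANCER", "SITE_A",
             "SITE_B", "HISTORY_OF_CANCER"),
    position = c("primary", "primary", "primary", "associated", "primary",
                 "primary", "associated"))
  adl <- data.frame(patient_id = integer(), stay_id = integer(), day = integer(),
                    adl1 = integer(), adl2 = integer(), adl3 = integer(),
                    adl4 = integer(), adl5 = integer(), adl6 = integer())
  deaths <- data.frame(patient_id = integer(), day = integer())
  structure(list(patients = patients, stays = stays, diagnoses = diagnoses,
                 adl = adl, deaths = deaths, truth = NULL), class = "registry")
}

# brute-force incident selection: per-patient scan of every diagnosis record
brute_force_cohort <- function(registry, spec) {
  ev <- merge(registry$diagnoses, registry$stays[, c("stay_id", "patient_id", "admission_day")],
              by = "stay_id")
  keep <- integer(0); dx <- integer(0)
  for (p in sort(unique(registry$patients$patient_id))) {
    e <- ev[ev$patient_id == p, ]
    q <- e[e$code %in% spec$qualifying_codes, ]
    if (nrow(q) == 0) next
    first <- min(q$admission_day)
    if (first < spec$incident_window[1] || first >= spec$incident_window[2]) next
    if (any(q$admission_day >= spec$washout_window[1] &
            q$admission_day < spec$washout_window[2])) next
    h <- e[e$code %in% spec$exclusion_codes, ]
    if (nrow(h) && any(h$admission_day <= first)) next
    keep <- c(keep, p); dx <- c(dx, first)
  }
  data.frame(patient_id = keep, diagnosis_day = dx)
}

# bivariate-normal selection data for Heckman tests: selection s = 1{a0 + a1*w + u > 0},
# outcome y = g0 + g1*x + e observed when s = 1, cor(u, e) = rho.
simulate_heckman <- function(n, rho, g = c(0.5, 0.3), a = c(-0.3, 1, 0.8),
                             sigma_e = 0.2) {
  x <- stats::rnorm(n)
  w <- stats::rnorm(n)  # exclusion-restriction instrument
  u <- stats::rnorm(n)
  e <- sigma_e * (rho * u + sqrt(1 - rho^2) * stats::rnorm(n))
  s <- (a[1] + a[2] * x + a[3] * w + u) > 0
  y <- g[1] + g[2] * x + e
  data.frame(x = x, w = w, s = as.integer(s), y = ifelse(s, y, NA))
}

# Fine-Gray data with a binary covariate and true subdistribution HR exp(beta)
# for cause 1: F1(t; z) = 1 - (1 - p(1 - e^-t))^exp(beta z)
simulate_finegray <- function(n, beta, p = 0.4, cens_max = 6) {
  z <- stats::rbinom(n, 1, 0.5)
  ebz <- exp(beta * z)
  p1 <- 1 - (1 - p)^ebz
  cause1 <- stats::runif(n) < p1
  t <- numeric(n)
  u <- stats::runif(n)
  # invert F1(t)/P(cause1) for cause-1 subjects
  inner <- 1 - (1 - u[cause1] * p1[cause1])^(1 / ebz[cause1])
  t[cause1] <- -log(1 - inner / p)
  t[!cause1] <- stats::rexp(sum(!cause1), rate = 1)
  cens <- stats::runif(n, 0, cens_max)
  obs <- pmin(t, cens)
  status <- ifelse(t <= cens, ifelse(cause1, 1L, 2L), 0L)
  data.frame(time = pmax(obs, 1e-8), status = status, z = z)
}

# dense trapezoid-grid EAP oracle, independent of the quadrature path
eap_oracle <- function(scores, alpha, beta, lo = -10, hi = 10, step = 2e-3) {
  th <- seq(lo, hi, by = step)
  logpost <- stats::dnorm(th, log = TRUE)
  for (j in seq_along(alpha)) {
    if (is.na(scores[j])) next
    p <- grm_cat_prob(th, alpha[j], beta[j, ])
    logpost <- logpost + log(pmax(p[, scores[j] + 1L], 1e-300))
  }
  w <- exp(logpost - max(logpost))
  sum(w * th) / sum(w)
}
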