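ev <- function(day, code, position = "associated")
  data.frame(day = day, code = code,
             position = rep(position, length.out = length(day)))

test_that("initial stage follows the metastatic > locally advanced > early precedence", {
  expect_equal(assign_initial_stage(ev(c(10, 20), c("METASTASIS", "CHEMO"))),
               "metastatic")
  expect_equal(assign_initial_stage(ev(100, "CHEMO")), "locally_advanced")
  expect_equal(assign_initial_stage(ev(50, "LOCOREGIONAL")), "locally_advanced")
  expect_equal(assign_initial_stage(ev(numeric(0), character(0))), "early")
  # events at day >= 180 do not contribute to the initial stage
  expect_equal(assign_initial_stage(ev(200, "METASTASIS")), "early")
})

test_that("relapse detection needs a primary-position site code or an extension event", {
  expect_equal(detect_relapse(ev(300, "CHEMO"), "early", "SITE_A"), 300L)
  expect_true(is.na(detect_relapse(ev(250, "SITE_A", "associated"), "early", "SITE_A")))
  expect_equal(detect_relapse(ev(250, "SITE_A", "primary"), "early", "SITE_A"), 250L)
  expect_true(is.na(detect_relapse(ev(numeric(0), character(0)), "early", "SITE_A")))
  # events before day 180 never qualify as relapse
  expect_true(is.na(detect_relapse(ev(100, "METASTASIS"), "early", "SITE_A")))
  expect_error(detect_relapse(ev(300, "CHEMO"), "metastatic", "SITE_A"),
               "metastatic")
})

test_that("timelines compose the quoted rules into contiguous intervals", {
  # metastatic patient dying at day 90: a single absorbing interval
  t1 <- build_timeline(1, ev(10, "METASTASIS"), "SITE_A", death_day = 90, censor_day = 400)
  expect_equal(t1$intervals,
               data.frame(state = "metastatic", start = 0, end = 90))
  expect_true(t1$death_flag)

  # early-stage, no relapse, censored at 360
  t2 <- build_timeline(2, ev(numeric(0), character(0)), "SITE_A",
                       death_day = NA, censor_day = 360)
  expect_equal(t2$intervals$state, c("early", "relapse_free"))
  expect_equal(t2$intervals$start, c(0, 180))
  expect_equal(t2$intervals$end, c(180, 360))

  # locally advanced, relapse at 200, alive at censor 360
  t3 <- build_timeline(3, ev(c(50, 200), c("LOCOREGIONAL", "CHEMO")), "SITE_A",
                       death_day = NA, censor_day = 360)
  expect_equal(t3$intervals$state, c("locally_advanced", "relapse_free", "relapse"))
  expect_equal(t3$intervals$start, c(0, 180, 200))
  expect_equal(t3$intervals$end, c(180, 200, 360))
  expect_equal(t3$relapse_day, 200L)

  expect_error(build_timeline(4, ev(10, "CHEMO"), "SITE_A",
                              death_day = -1, censor_day = 100),
               "death before day 0")
})

test_that("timelines partition alive time and keep absorbing states terminal", {
  reg <- generate_registry(sim_config(n_patients = 150, seed = 13))
  ch <- build_cohort(reg)
  tl <- build_timelines(ch, reg, censor_day = 2007)
  for (t in tl$timelines) {
    iv <- t$intervals
    if (nrow(iv) == 0) { expect_equal(t$end_day, 0); next }
    # contiguous, non-overlapping, covering [0, end)
    expect_equal(iv$start[1], 0)
    expect_equal(iv$end[nrow(iv)], t$end_day)
    if (nrow(iv) > 1) expect_equal(iv$start[-1], iv$end[-nrow(iv)])
    # every alive day within the first analysis year is in exactly one interval
    horizon <- min(t$end_day, 360)
    if (horizon > 0) {
      days <- 0:(ceiling(horizon) - 1)
      hits <- vapply(days, function(d) sum(iv$start <= d & d < iv$end), 0L)
      expect_true(all(hits == 1L))
    }
    # absorbing: nothing follows metastatic or relapse
    absorbing <- which(iv$state %in% c("metastatic", "relapse"))
    if (length(absorbing)) expect_equal(max(absorbing), nrow(iv))
    # follow-up states never start before day 180
    fu <- iv$state %in% c("relapse", "relapse_free")
    if (any(fu)) expect_true(all(iv$start[fu] >= 180))
  }
})

test_that("Kaplan-Meier estimates match closed forms", {
  # no censoring: KM is 1 - empirical CDF
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: survival stays at 1
  km2 <- km_estimate(c(5, 7), c(0, 0))
  expect_true(all(km2$surv == 1))
  # exponential(0.01/day): S(100) ~ exp(-1) within 3 binomial SEs
  set.seed(31)
  n <- 2000
  tt <- rexp(n, 0.01)
  km3 <- km_estimate(tt, rep(1, n))
  s100 <- km_surv_at(km3, 100)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(s100 - exp(-1)), 3 * se)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("Greenwood variance matches the direct formula", {
  set.seed(5)
  tt <- rexp(50, 0.1); st <- rbinom(50, 1, 0.7)
  km <- km_estimate(tt, st)
  gw <- km$surv^2 * cumsum(km$n_event / (km$n_risk * (km$n_risk - km$n_event)))
  expect_equal(km$var_greenwood[is.finite(gw)], gw[is.finite(gw)], tolerance = 1e-10)
})

test_that("competing-risk CIFs conserve probability and collapse to 1 - KM", {
  set.seed(17)
  n <- 300
  t1 <- rexp(n, 0.02); t2 <- rexp(n, 0.01); cens <- runif(n, 0, 80)
  time <- pmin(t1, t2, cens)
  event <- ifelse(t1 <= pmin(t2, cens), "admission",
                  ifelse(t2 <= cens, "death", "censored"))
  fit <- fit_competing_admission(time, event)
  # Aalen-Johansen conservation: states sum to 1 at every time
  tot <- tapply(fit$cif$estimate, fit$cif$time, sum)
  expect_true(all(abs(tot - 1) < 1e-10))
  # single event type: CIF(admission) equals 1 - KM
  only <- fit_competing_admission(time, ifelse(event == "death", "censored", event))
  cif1 <- only$cif[only$cif$state == "admission", ]
  km <- km_estimate(time, as.integer(event == "admission"))
  expect_equal(cif1$estimate[match(km$time, cif1$time)], 1 - km$surv,
               tolerance = 1e-10)
  expect_error(fit_competing_admission(numeric(0), character(0)), "empty")
  expect_error(fit_competing_admission(c(0, 1), c("admission", "death")),
               "zero or negative")
  expect_warning(fit_competing_admission(c(1, 2), c("censored", "death"),
                                         covariate = c(0, 1)),
                 "no admission events")
})

test_that("Fine-Gray regression recovers a known subdistribution hazard ratio", {
  set.seed(23)
  d <- simulate_finegray(3000, beta = log(3.5))
  fit <- fit_competing_admission(d$time,
                                 c("censored", "admission", "death")[d$status + 1L],
                                 covariate = d$z)
  expect_false(is.null(fit$fg))
  expect_gt(fit$fg$hr, 2.5)
  expect_lt(fit$fg$hr, 5)
  expect_true(fit$fg$ci[1, "lower"] < 3.5 && 3.5 < fit$fg$ci[1, "upper"])
})
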