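# shared small end-to-end fixture for the Step IV machinery
fix_reg <- generate_registry(sim_config(n_patients = 350, seed = 77))
fix_ch <- build_cohort(fix_reg)
fix_tl <- build_timelines(fix_ch, fix_reg, censor_day = 2007)
fix_irt <- suppressWarnings(fit_irt_stage(fix_reg, patient_ids = fix_ch$patient_id))
fix_sp <- build_subpopulations(fix_tl, fix_irt$trajectories, fix_reg)

test_that("monthly HSU is the mean of available daily estimates", {
  expect_equal(monthly_patient_hsu(rep(0.5, 30)), 0.5)
  expect_equal(monthly_patient_hsu(0.47), 0.47)
  expect_equal(monthly_patient_hsu(c(rep(0.2, 15), rep(0.6, 15))), 0.4)
  expect_error(monthly_patient_hsu(numeric(0)), "non-admitted")
})

test_that("subpopulation membership respects the strict alive-at-month-start rule", {
  # hand-built timeline set: patient 1 dies exactly on day 30 (start of month 2)
  mk <- function(pid, events, death, censor) {
    build_timeline(pid, events, "SITE_A", death_day = death, censor_day = censor)
  }
  e_met <- data.frame(day = 5, code = "METASTASIS", position = "associated")
  tls <- list(`1` = mk(1, e_met, 30, 400), `2` = mk(2, e_met, NA, 400))
  iv <- do.call(rbind, lapply(tls, function(t) cbind(patient_id = t$patient_id, t$intervals)))
  fake <- list(timelines = tls, intervals = iv,
               cohort = data.frame(patient_id = 1:2, diagnosis_day = c(0L, 0L),
                                   sex = "M", birth_year = 1950L, age_band = "60-69",
                                   comorbidity_count = 0L, hospital_type = "public"),
               censor_day = 400)
  class(fake) <- "hs_timelines"
  class(fake$cohort) <- c("cohort", "data.frame")
  traj <- data.frame(patient_id = 2L, day = 10L, utility = 0.5)
  reg0 <- generate_registry(sim_config(n_patients = 0, seed = 1))
  sp <- build_subpopulations(fake, traj, reg0)
  # month 1: both alive at day 0; month 2: patient 1 died on the boundary -> excluded
  expect_setequal(sp[["metastatic:1"]]$patient_id, 1:2)
  expect_equal(sp[["metastatic:2"]]$patient_id, 2L)
  # metastatic patient alive a year appears in all 12 monthly subpopulations
  in_months <- vapply(1:12, function(m) 2L %in% sp[[paste0("metastatic:", m)]]$patient_id, TRUE)
  expect_true(all(in_months))
})

test_that("initial-stage patients appear in at most six monthly subpopulations", {
  keys <- names(fix_sp)
  early_keys <- grep("^(early|locally_advanced):", keys, value = TRUE)
  months <- as.integer(sub(".*:", "", early_keys))
  expect_true(all(months <= 6))
  # patients admitted in a month have an observed monthly value in [-0.53, 1]
  for (k in keys[1:min(6, length(keys))]) {
    df <- fix_sp[[k]]
    expect_true(all(is.na(df$hsu) | (df$hsu >= -0.53 & df$hsu <= 1)))
    expect_true(all(df$admitted == !is.na(df$hsu)))
  }
})

test_that("combined means are patient-count-weighted averages, conserved exactly", {
  est <- suppressWarnings(estimate_hsu(fix_sp, boot_reps = 0))
  bsm <- est$by_state_month
  pv <- est$patient_values
  for (r in which(!is.na(bsm$mean_combined))) {
    sub <- pv[pv$state == bsm$state[r] & pv$month == bsm$month[r], ]
    # conservation: cell mean equals the pooled mean of per-patient values
    expect_equal(bsm$mean_combined[r], mean(sub$value), tolerance = 1e-12)
    n_obs <- sum(sub$source == "observed"); n_imp <- sum(sub$source == "imputed")
    if (n_imp > 0 && n_obs > 0) {
      w <- (n_obs * bsm$mean_observed[r] + n_imp * bsm$mean_imputed[r]) / (n_obs + n_imp)
      expect_equal(bsm$mean_combined[r], w, tolerance = 1e-12)
    }
  }
  # weighted-average example: 10 observed at 0.4 and 30 imputed at 0.6 -> 0.55
  expect_equal((10 * 0.4 + 30 * 0.6) / 40, 0.55)
})

test_that("selection correction moves monthly HSU toward the full population", {
  est <- suppressWarnings(estimate_hsu(fix_sp, boot_reps = 0))
  bsm <- est$by_state_month
  fitted_cells <- bsm[!bsm$fallback & !is.na(bsm$mean_combined), ]
  expect_gt(nrow(fitted_cells), 5)
  # with delta < 0 the sicker are over-represented in post-acute care, so the
  # combined mean exceeds the observed-only mean on average and in most cells
  expect_gt(mean(fitted_cells$mean_combined - fitted_cells$mean_observed), 0)
  expect_gt(mean(fitted_cells$mean_combined > fitted_cells$mean_observed), 0.5)
})

test_that("empty subpopulations are reported missing, not zero", {
  sp2 <- fix_sp["metastatic:12"]
  sp2[[1]]$admitted <- FALSE
  sp2[[1]]$hsu <- NA_real_
  est <- estimate_hsu(sp2, boot_reps = 0)
  expect_true(is.na(est$by_state_month$mean_combined))
  expect_equal(est$by_state_month$n_admitted, 0L)
})

test_that("per-state breakdowns cover age bands and comorbidity counts", {
  est <- suppressWarnings(estimate_hsu(fix_sp, boot_reps = 0))
  bd <- hsu_breakdown(est, hsu_covariates(fix_tl$cohort, fix_reg))
  expect_setequal(unique(bd$group_type), c("age_band", "comorbidity_count"))
  expect_true(all(bd$n > 0))
  pooled <- sum(bd$n[bd$group_type == "age_band"])
  expect_equal(pooled, nrow(est$patient_values))
})
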