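test_that("an empty configuration yields five empty tables", {
  reg <- generate_registry(sim_config(n_patients = 0, seed = 1))
  for (tab in c("patients", "stays", "diagnoses", "adl", "deaths"))
    expect_equal(nrow(reg[[tab]]), 0L)
})

test_that("the seed fully determines the registry", {
  cfg <- sim_config(n_patients = 120, seed = 11)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  for (tab in c("patients", "stays", "diagnoses", "adl", "deaths"))
    expect_identical(r1[[tab]], r2[[tab]])
  r3 <- generate_registry(sim_config(n_patients = 120, seed = 12))
  expect_false(identical(r1$adl, r3$adl))
})

test_that("ADL scores follow the graded-response closed form at fixed theta", {
  cfg <- sim_config(
    n_patients = 1400, seed = 5, theta_fixed = 0,
    true_grm = list(alpha = rep(2, 6),
                    beta = matrix(rep(c(-1, 0, 1), each = 6), 6, 3),
                    state_shift = c(early = 0, locally_advanced = 0, metastatic = 0,
                                    relapse = 0, relapse_free = 0),
                    covariate_shift = list(age = 0, comorbidity = 0)))
  reg <- generate_registry(cfg)
  n <- nrow(reg$adl)
  expect_gt(n, 10000)
  for (j in 1:6) {
    x <- reg$adl[[paste0("adl", j)]]
    # P(X >= 2) = logistic(2 * (0 - 0)) = 0.5; P(X >= 1) = logistic(2)
    for (k in 1:3) {
      p_true <- plogis(2 * (0 - c(-1, 0, 1)[k]))
      se <- sqrt(p_true * (1 - p_true) / n)
      expect_lt(abs(mean(x >= k) - p_true), 3 * se + 1e-12)
    }
  }
})

test_that("negative delta selects low-theta patients into post-acute care", {
  reg <- generate_registry(sim_config(n_patients = 700, seed = 21))
  m <- reg$truth$months
  m <- m[m$alive, ]
  expect_gt(nrow(m), 5000)
  expect_lt(mean(m$theta[m$admitted]), mean(m$theta[!m$admitted]))
  expect_lt(t.test(m$theta[!m$admitted], m$theta[m$admitted],
                   alternative = "greater")$p.value, 0.05)
})

test_that("delta = 0 makes admission independent of the latent trait", {
  cfg <- sim_config(n_patients = 700, seed = 22,
                    admission_model = list(intercept = -0.5, age = 0,
                                           comorbidity = 0,
                                           hospital = c(public = 0, cancer_center = 0,
                                                        private = 0),
                                           delta = 0))
  reg <- generate_registry(cfg)
  m <- reg$truth$months
  m <- m[m$alive & !reg$truth$patients$prevalent[m$patient_id], ]
  expect_gt(nrow(m), 5000)
  r <- cor(m$theta, as.numeric(m$admitted))
  expect_lt(abs(r), 3 / sqrt(nrow(m)))
})

test_that("registries round-trip losslessly through CSV, truth withheld", {
  reg <- generate_registry(sim_config(n_patients = 100, seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_registry(reg, dir)
  expect_length(paths, 5)
  back <- read_registry(dir)
  expect_null(back$truth)
  for (tab in c("patients", "stays", "diagnoses", "adl", "deaths"))
    expect_equal(back[[tab]], reg[[tab]], ignore_attr = TRUE)
  # files carry no ground-truth columns
  expect_false(any(grepl("theta", readLines(file.path(dir, "patients.csv"), n = 1))))
  # an empty registry still writes five header-only files
  dir2 <- withr::local_tempdir()
  write_registry(generate_registry(sim_config(n_patients = 0, seed = 1)), dir2)
  expect_equal(nrow(read_registry(dir2)$stays), 0L)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(stage_mix = c(0.5, 0.2, 0.2)), "stage_mix")
  expect_error(sim_config(state_hazards = c(early = -1e-4, locally_advanced = 1e-4,
                                            metastatic = 1e-3, relapse = 1e-3,
                                            relapse_free = 1e-4)), "state_hazards")
  expect_error(sim_config(incident_end = 10), "incident_end")
  expect_error(sim_config(adl_cadence_days = 0), "adl_cadence_days")
})

test_that("a clean synthetic registry satisfies every registry invariant", {
  reg <- generate_registry(sim_config(n_patients = 150, seed = 8))
  expect_equal(nrow(validate_registry(reg)), 0L)
})
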