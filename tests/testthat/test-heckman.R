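test_that("the inverse Mills ratio matches analytic values and limits", {
  expect_equal(inverse_mills(0), 2 * dnorm(0), tolerance = 1e-14)
  # independent oracle at z = -2: numerator/denominator from direct quadrature
  phi2 <- exp(-2) / sqrt(2 * pi)
  Phi2 <- integrate(dnorm, -Inf, -2, rel.tol = 1e-13)$value
  expect_equal(inverse_mills(-2), phi2 / Phi2, tolerance = 1e-10)
  # strictly positive and strictly decreasing, limit 0
  z <- seq(-40, 8, by = 0.25)
  v <- inverse_mills(z)
  expect_true(all(v > 0))
  expect_true(all(diff(v) < 0))
  expect_lt(inverse_mills(8), 1e-14)
  # far left tail: lambda(z) ~ -z stays finite where the direct ratio underflows
  expect_equal(inverse_mills(-40) / 40, 1, tolerance = 1e-2)
  expect_true(is.finite(inverse_mills(-300)))
})

test_that("the selection probit recovers known coefficients", {
  # intercept only, half admitted -> beta0 = qnorm(0.5) = 0
  d0 <- data.frame(s = rep(c(0L, 1L), 50))
  f0 <- fit_selection_probit(s ~ 1, d0)
  expect_equal(unname(f0$coef), 0, tolerance = 1e-8)
  # simulated probit data, n = 5000: recovery within 3 SE
  set.seed(61)
  n <- 5000
  x <- rnorm(n)
  b <- c(-0.4, 0.7)
  s <- as.integer(runif(n) < pnorm(b[1] + b[2] * x))
  fit <- fit_selection_probit(s ~ x, data.frame(s = s, x = x))
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coef - b) < 3 * se))
  expect_false(fit$stabilized)
  # degenerate: everyone admitted
  expect_error(fit_selection_probit(s ~ x, data.frame(s = 1L, x = rnorm(10))),
               "both selected and non-selected")
})

test_that("quasi-separated probits fall back to a ridge-stabilized fit", {
  d <- data.frame(s = c(rep(0L, 20), rep(1L, 20)),
                  x = c(rnorm(20, -3), rnorm(20, 3)))
  expect_warning(fit <- fit_selection_probit(s ~ x, d), "quasi-separation")
  expect_true(fit$stabilized)
  expect_true(all(is.finite(fit$coef)))
})

test_that("the two-step estimator corrects selection bias that OLS inherits", {
  set.seed(71)
  g <- c(0.5, 0.3)
  d <- simulate_heckman(5000, rho = 0.6, g = g)
  fit <- heckit2(s ~ x + w, y ~ x, d)
  # gamma recovered within 3 robust SE
  V <- sandwich::vcovHC(fit$ols, type = "HC1")
  se <- sqrt(diag(V))[c("(Intercept)", "x")]
  expect_lt(abs(fit$gamma[["(Intercept)"]] - g[1]), 3 * se[1])
  expect_lt(abs(fit$gamma[["x"]] - g[2]), 3 * se[2])
  # positive error correlation -> positive lambda, detected
  expect_gt(fit$lambda, 0)
  expect_lt(fit$lambda_p, 0.05)
  # naive OLS intercept is biased upward relative to the corrected one
  naive <- coef(lm(y ~ x, d[d$s == 1, ]))
  expect_gt(abs(naive[1] - g[1]), abs(fit$gamma[["(Intercept)"]] - g[1]))
  # IMR is positive for every selected observation
  expect_true(all(fit$imr > 0))
})

test_that("predictions and imputation follow the outcome equation", {
  set.seed(72)
  d <- simulate_heckman(2000, rho = 0.5)
  d$patient_id <- seq_len(nrow(d))
  fit <- heckit2(s ~ x + w, y ~ x, d)
  non <- d[d$s == 0, ][1:5, ]
  # unconditional prediction is the plain linear index gamma * Y
  manual <- fit$gamma[["(Intercept)"]] + fit$gamma[["x"]] * non$x
  expect_equal(predict(fit, non), manual, tolerance = 1e-12)
  # identical covariates -> imputed value equals the admitted patient's gamma-part
  adm <- d[d$s == 1, ][1, ]
  expect_equal(predict(fit, adm), fit$gamma[["(Intercept)"]] + fit$gamma[["x"]] * adm$x,
               tolerance = 1e-12)
  # conditional variant subtracts the non-selected Mills term
  cond <- predict(fit, non, type = "conditional")
  expect_true(all(cond < predict(fit, non)))  # lambda > 0 here
  # impute_hsu clips and reports, errors on missing covariates, empty in -> empty out
  fit$outcome <- y ~ x
  imp <- impute_hsu(fit, non)
  expect_true(all(imp >= -0.53 & imp <= 1))
  non_bad <- non; non_bad$x[2] <- NA
  expect_error(impute_hsu(fit, non_bad), as.character(non_bad$patient_id[2]))
  expect_length(impute_hsu(fit, non[0, ]), 0)
})

test_that("the lambda test holds its nominal size under no selection on unobservables", {
  set.seed(73)
  reps <- 200
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    d <- simulate_heckman(800, rho = 0)
    fit <- heckit2(s ~ x + w, y ~ x, d)
    rej[r] <- fit$lambda_p < 0.05
  }
  # binomial(200, 0.05): within 3 SE of the nominal level
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})
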