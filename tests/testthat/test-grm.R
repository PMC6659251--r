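test_that("the cumulative probability is exactly 0.5 at theta = beta_jk", {
  for (alpha in c(0.3, 1, 2.7, 5.5)) {
    beta <- c(-1.3, 0.2, 2.1)
    p <- grm_cum_prob(beta, alpha, beta)
    expect_equal(diag(p), rep(0.5, 3), tolerance = 1e-12)
  }
})

test_that("category probabilities are a proper distribution for any theta", {
  th <- seq(-6, 6, by = 0.5)
  p <- grm_cat_prob(th, 2.3, c(-1, 0, 1.5))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, length(th)), tolerance = 1e-12)
})

test_that("degenerate response sets are rejected", {
  X <- matrix(2L, 50, 6)  # all six scores identical for every record
  expect_error(grm(X, check_unidim = FALSE), "single observed category")
  X2 <- cbind(rep(0:3, 10), 1L)  # one informative item, one constant
  expect_error(grm(X2, check_unidim = FALSE), "single observed category")
})

test_that("marginal ML recovers generating parameters and the EM ascends", {
  set.seed(101)
  alpha <- c(2.5, 1.4, 3.2, 1.9)
  beta <- rbind(c(-1.6, -0.5, 0.6), c(-1.1, 0, 1.1), c(-0.9, 0.1, 1.2),
                c(-1.8, -0.7, 0.4))
  X <- rgrm(rnorm(3000), alpha, beta)
  fit <- grm(X, check_unidim = FALSE)
  expect_true(fit$convergence$converged)
  # observed-data log-likelihood is non-decreasing across EM iterations
  expect_true(all(diff(fit$convergence$loglik_trace) > -1e-6))
  expect_true(all(abs(fit$alpha / alpha - 1) < 0.2))
  expect_true(all(abs(fit$beta - beta) < 0.2))
  # threshold ordering is enforced
  expect_true(all(apply(fit$beta, 1, diff) > 0))
})

test_that("EAP scores are monotone in the responses and symmetric when the model is", {
  alpha <- rep(2, 4)
  beta <- matrix(rep(c(-1, 0, 1), each = 4), 4, 3)  # antisymmetric thresholds
  lo <- score_eap(matrix(0L, 1, 4), alpha, beta)
  hi <- score_eap(matrix(3L, 1, 4), alpha, beta)
  expect_lt(lo$eap, 0)
  expect_gt(hi$eap, 0)
  expect_equal(lo$eap, -hi$eap, tolerance = 1e-10)
  # raising one item score never lowers the EAP
  base <- c(1L, 2L, 0L, 1L)
  e0 <- score_eap(matrix(base, 1), alpha, beta)$eap
  for (j in 1:4) {
    up <- base; up[j] <- up[j] + 1L
    expect_gte(score_eap(matrix(up, 1), alpha, beta)$eap, e0)
  }
})

test_that("EAP agrees with a dense trapezoid-grid oracle", {
  set.seed(7)
  alpha <- c(2.1, 1.2, 3.4, 1.7, 2.6, 1.1)
  beta <- rbind(c(-2.1, -0.8, 0.9), c(-1.5, -0.2, 1.3), c(-1.0, 0.1, 1.1),
                c(-2.0, -1.0, 0.2), c(-1.6, -0.4, 0.7), c(-1.7, -0.6, 0.1))
  X <- rgrm(rnorm(25), alpha, beta)
  got <- score_eap(X, alpha, beta)
  want <- vapply(seq_len(nrow(X)), function(i) eap_oracle(X[i, ], alpha, beta), 0)
  expect_equal(got$eap, want, tolerance = 1e-4)
  # missing items are skipped, not treated as a category
  Xna <- X[1, , drop = FALSE]; Xna[1, 3] <- NA
  expect_equal(score_eap(Xna, alpha, beta)$eap,
               eap_oracle(Xna[1, ], alpha, beta), tolerance = 1e-4)
})

test_that("simulate() round-trips through the fitted object deterministically", {
  set.seed(3)
  X <- rgrm(rnorm(500), c(2, 2), rbind(c(-1, 0, 1), c(-1, 0, 1)))
  # convergence to full tolerance is not the property under test here; a
  # two-item fit crawls near the optimum and may hit the iteration cap
  fit <- suppressWarnings(grm(X, check_unidim = FALSE))
  s1 <- simulate(fit, nsim = 20, seed = 9)
  s2 <- simulate(fit, nsim = 20, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% 0:3))
})
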