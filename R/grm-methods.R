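#' @export
print.grm <- function(x, ...) {
  cat("Graded response model (marginal ML, theta ~ N(0,1))\n")
  cat(sprintf("  %d items, %d categories, %d assessments\n", x$n_items, x$n_cat, x$n))
  cat(sprintf("  log-likelihood %.2f; %s after %d EM iterations\n", x$logLik,
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations))
  invisible(x)
}

#' @export
summary.grm <- function(object, ...) {
  tab <- cbind(slope = object$alpha, object$beta,
               threshold_range = object$beta[, ncol(object$beta)] - object$beta[, 1])
  structure(list(table = tab, logLik = object$logLik,
                 convergence = object$convergence, unidim = object$unidim,
                 n = object$n), class = "summary.grm")
}

#' @export
print.summary.grm <- function(x, ...) {
  cat("Graded response model parameter estimates\n")
  print(round(x$table, 3))
  cat(sprintf("\nlog-likelihood %.2f on %d assessments\n", x$logLik, x$n))
  if (!is.null(x$unidim))
    cat(sprintf("unidimensionality screen: %s (lambda1 = %.2f, %.1f%% variance, ratio %.2f)\n",
                if (x$unidim$pass) "pass" else "FAIL",
                x$unidim$eigenvalues[1], 100 * x$unidim$variance_share[1], x$unidim$ratio))
  invisible(x)
}

#' @export
coef.grm <- function(object, ...) {
  cbind(alpha = object$alpha, object$beta)
}

#' @export
logLik.grm <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- length(object$alpha) + length(object$beta)
  attr(val, "nobs") <- object$n
  class(val) <- "logLik"
  val
}

#' Expected a posteriori (EAP) scoring of latent health state
#'
#' Posterior mean and standard deviation of the latent trait \eqn{\theta}
#' under the standard normal prior and the GRM likelihood of the observed
#' scores, computed on the model's Gauss-Hermite quadrature grid. Missing
#' item scores are skipped in the likelihood.
#'
#' @param object a fitted [grm()] object.
#' @param newdata matrix or data frame of item scores to score (defaults are
#'   not kept from the fit; always supply the records to score).
#' @param type `"eap"` (the only type).
#' @param ... unused.
#' @return data frame with columns `eap` and `sd`, one row per record.
#' @export
predict.grm <- function(object, newdata, type = "eap", ...) {
  type <- match.arg(type)
  score_eap(newdata, alpha = object$alpha, beta = object$beta)
}

#' @rdname predict.grm
#' @param alpha,beta item parameters (as in a `"grm"` fit) when scoring
#'   without a fitted object.
#' @param grid integration grid, a list with `nodes` and `weights` (weights
#'   summing to 1 under the N(0,1) prior). The default is a dense
#'   equispaced grid (step 0.02 over \[-8, 8\]): the posterior of a
#'   six-item response pattern can be sharply peaked, and the coarse
#'   Gauss-Hermite grid that is ample for the marginal-likelihood fit
#'   leaves visible error in posterior means.
#' @export
score_eap <- function(newdata, alpha, beta, grid = score_grid()) {
  X <- as.matrix(newdata)
  beta <- as.matrix(beta)
  stopifnot(ncol(X) == length(alpha))
  n <- nrow(X); Q <- length(grid$nodes)
  ll <- matrix(0, n, Q)
  for (j in seq_along(alpha)) {
    pj <- t(grm_cat_prob(grid$nodes, alpha[j], beta[j, ]))   # K x Q
    xj <- X[, j]
    ok <- !is.na(xj)
    if (any(ok))
      ll[ok, ] <- ll[ok, ] + log(pmax(pj[xj[ok] + 1L, , drop = FALSE], 1e-300))
  }
  m <- apply(ll, 1, max)
  w <- exp(ll - m) * rep(grid$weights, each = n)
  w <- w / rowSums(w)
  eap <- as.vector(w %*% grid$nodes)
  e2 <- as.vector(w %*% grid$nodes^2)
  data.frame(eap = eap, sd = sqrt(pmax(e2 - eap^2, 0)))
}

#' Simulate responses from a fitted graded response model
#'
#' @param object a fitted [grm()] object.
#' @param nsim number of assessment rows to draw.
#' @param seed optional seed, as in [stats::simulate()].
#' @param theta latent trait values; default draws `nsim` from N(0,1).
#' @param ... unused.
#' @return integer score matrix `nsim x n_items`.
#' @export
simulate.grm <- function(object, nsim = 1, seed = NULL, theta = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) theta <- stats::rnorm(nsim)
  rgrm(theta, object$alpha, object$beta)
}

#' Item characteristic curves of a fitted graded response model
#'
#' Plots, for each item, the category response curves
#' \eqn{P(X = k \mid \theta)} over a grid of latent-trait values. Tightly
#' concentrated curves indicate a highly discriminating item.
#'
#' @param x a fitted [grm()] object.
#' @param theta_range range of the latent axis.
#' @param items which items to plot (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.grm <- function(x, theta_range = c(-4, 4), items = seq_along(x$alpha), ...) {
  th <- seq(theta_range[1], theta_range[2], length.out = 201)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(items)))
  on.exit(graphics::par(old))
  for (j in items) {
    p <- grm_cat_prob(th, x$alpha[j], x$beta[j, ])
    graphics::matplot(th, p, type = "l", lty = 1, ylim = c(0, 1),
                      xlab = expression(theta), ylab = "P(X = k)",
                      main = names(x$alpha)[j], ...)
  }
  invisible(x)
}
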