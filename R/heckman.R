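#' Inverse Mills ratio
#'
#' \eqn{\lambda(z) = \phi(z)/\Phi(z)}, the selection-bias correction factor
#' of the Heckman two-step estimator evaluated at the probit linear index.
#' Computed on the log scale (`dnorm(log = TRUE)` minus
#' `pnorm(log.p = TRUE)`), which remains accurate arbitrarily far into the
#' left tail where the direct ratio underflows; there
#' \eqn{\lambda(z) \to -z}.
#'
#' @param z numeric vector of probit linear indices.
#' @return strictly positive values, strictly decreasing in `z`, tending to
#'   0 as `z` grows.
#' @examples
#' inverse_mills(0)    # 2 * dnorm(0) = 0.7978846
#' @export
inverse_mills <- function(z) {
  exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
}

#' Probit selection equation
#'
#' Maximum-likelihood probit for the probability of being observed
#' (recorded in post-acute care in the month), fitted with
#' [stats::glm()]. If the fit is quasi-separated (fitted probabilities
#' numerically at 0/1 or non-convergence), a ridge-stabilized refit
#' (penalized log-likelihood, small quadratic penalty on the slopes) is
#' used and flagged.
#'
#' @param formula model formula with the selection indicator on the left.
#' @param data data frame.
#' @param ridge penalty used in the stabilized refit.
#' @return list with `coef`, `vcov`, `linear_index` (per row of `data`),
#'   `glm` (the fit, `NULL` if ridge), `stabilized` flag.
#' @export
fit_selection_probit <- function(formula, data, ridge = 1e-2) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2L)
    stop("selection indicator must have both selected and non-selected observations")
  X <- stats::model.matrix(formula, mf)
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::binomial(link = "probit")))
  # separation makes the ML coefficients diverge; legitimate fits with a few
  # extreme-but-finite linear indices are left alone
  sep <- !fit$converged || any(!is.finite(stats::coef(fit))) ||
    any(abs(stats::coef(fit)) > 15)
  if (!sep) {
    co <- stats::coef(fit)
    return(list(coef = co, vcov = stats::vcov(fit),
                linear_index = as.vector(X %*% co), glm = fit, stabilized = FALSE))
  }
  # ridge-stabilized penalized probit
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    -sum(y * stats::pnorm(eta, log.p = TRUE) +
           (1 - y) * stats::pnorm(-eta, log.p = TRUE)) +
      ridge / 2 * sum(b[-1]^2)
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 500), hessian = TRUE)
  co <- stats::setNames(opt$par, colnames(X))
  warning("quasi-separation in the selection probit; ridge-stabilized fit used")
  list(coef = co, vcov = tryCatch(solve(opt$hessian), error = function(e) NULL),
       linear_index = as.vector(X %*% co), glm = NULL, stabilized = TRUE)
}

#' Heckman two-step sample-selection model
#'
#' Two-step estimator of an outcome observed only for a selected subsample:
#' a probit selection equation \eqn{P(s_i = 1) = \Phi(\beta X_i)} on all
#' observations, followed by least squares of the outcome on its covariates
#' plus the inverse Mills ratio evaluated at \eqn{\beta X_i},
#' \eqn{y_i = \gamma Y_i + \lambda \mathrm{IMR}_i + e_i}, on the selected
#' observations. A non-zero \eqn{\lambda} indicates selection on
#' unobservables; it is tested two-sided against 0 with
#' heteroskedasticity-robust (HC1) standard errors, since the two-step
#' residuals are heteroskedastic by construction.
#'
#' @param selection formula of the selection equation (binary indicator on
#'   the left).
#' @param outcome formula of the outcome equation; its covariates should be
#'   a subset of the selection covariates (exclusion restriction).
#' @param data data frame containing all variables; outcome values may be
#'   `NA` for non-selected rows.
#' @return object of class `"heckit2"`: list with `probit` (see
#'   [fit_selection_probit()]), `ols` (the [stats::lm()] outcome fit),
#'   `gamma` (outcome coefficients), `lambda`, `lambda_se`, `lambda_p`
#'   (robust test of no selection bias), `imr` (per selected row),
#'   `imr_unreliable` flag (collinearity of the IMR with the outcome
#'   covariates), `n`, `n_selected`, plus the formulas and data reference.
#' @export
heckit2 <- function(selection, outcome, data) {
  sel <- fit_selection_probit(selection, data)
  s <- as.logical(stats::model.response(stats::model.frame(selection, data)))
  imr_all <- inverse_mills(sel$linear_index)
  dsel <- data[s, , drop = FALSE]
  dsel$.imr <- imr_all[s]
  of <- stats::update(outcome, . ~ . + .imr)
  ols <- stats::lm(of, data = dsel)
  co <- stats::coef(ols)
  # robust lambda test
  V <- sandwich::vcovHC(ols, type = "HC1")
  ct <- lmtest::coeftest(ols, vcov. = V)
  lam <- unname(co[".imr"])
  lam_se <- ct[".imr", "Std. Error"]
  lam_p <- ct[".imr", "Pr(>|t|)"]
  # collinearity screen: condition number of the outcome design incl. IMR
  Xo <- stats::model.matrix(of, dsel)
  sv <- svd(scale(Xo[, colnames(Xo) != "(Intercept)", drop = FALSE]))$d
  kappa_ <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  unreliable <- !is.finite(kappa_) || kappa_ > 1e3
  if (unreliable)
    warning("IMR nearly collinear with outcome covariates; lambda test unreliable")
  structure(list(probit = sel, ols = ols,
                 gamma = co[names(co) != ".imr"],
                 lambda = lam, lambda_se = lam_se, lambda_p = lam_p,
                 imr = dsel$.imr, imr_unreliable = unreliable,
                 n = nrow(data), n_selected = sum(s),
                 selection = selection, outcome = outcome),
            class = "heckit2")
}

#' @export
print.heckit2 <- function(x, ...) {
  cat("Heckman two-step selection model\n")
  cat(sprintf("  %d observations, %d selected\n", x$n, x$n_selected))
  cat("Outcome coefficients (gamma):\n")
  print(round(x$gamma, 4))
  cat(sprintf("lambda (IMR) = %.4f (robust SE %.4f, p = %.4g)%s\n",
              x$lambda, x$lambda_se, x$lambda_p,
              if (x$imr_unreliable) " [unreliable: collinearity]" else ""))
  invisible(x)
}

#' @export
coef.heckit2 <- function(object, part = c("outcome", "selection"), ...) {
  part <- match.arg(part)
  if (part == "outcome") c(object$gamma, lambda = object$lambda)
  else object$probit$coef
}

#' @export
summary.heckit2 <- function(object, ...) {
  V <- sandwich::vcovHC(object$ols, type = "HC1")
  structure(list(outcome = lmtest::coeftest(object$ols, vcov. = V),
                 selection = object$probit$coef,
                 lambda = object$lambda, lambda_p = object$lambda_p,
                 n = object$n, n_selected = object$n_selected),
            class = "summary.heckit2")
}

#' @export
print.summary.heckit2 <- function(x, ...) {
  cat("Heckman two-step selection model\n\nSelection probit coefficients:\n")
  print(round(x$selection, 4))
  cat("\nOutcome equation (robust SEs):\n")
  print(x$outcome)
  invisible(x)
}

#' Predict from the outcome equation of a two-step fit
#'
#' Population-level linear prediction \eqn{\gamma Y_i} from the outcome
#' equation (no inverse-Mills term), the quantity used to impute the
#' outcome for non-selected observations. `type = "conditional"` instead
#' returns the expectation conditional on *not* being selected,
#' \eqn{\gamma Y_i - \lambda\,\phi(\beta X_i)/(1 - \Phi(\beta X_i))},
#' available for sensitivity analysis.
#'
#' @param object a `"heckit2"` fit.
#' @param newdata data frame with the outcome (and, for
#'   `type = "conditional"`, selection) covariates.
#' @param type `"unconditional"` (default) or `"conditional"`.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.heckit2 <- function(object, newdata,
                            type = c("unconditional", "conditional"), ...) {
  type <- match.arg(type)
  Xy <- stats::model.matrix(stats::delete.response(stats::terms(object$outcome)),
                            newdata)
  pred <- as.vector(Xy %*% object$gamma[colnames(Xy)])
  if (type == "conditional") {
    Xs <- stats::model.matrix(stats::delete.response(stats::terms(object$selection)),
                              newdata)
    z <- as.vector(Xs %*% object$probit$coef[colnames(Xs)])
    # Mills ratio of the non-selected: phi(z) / (1 - Phi(z)) = imr(-z)
    pred <- pred - object$lambda * inverse_mills(-z)
  }
  pred
}

#' @export
residuals.heckit2 <- function(object, ...) stats::residuals(object$ols)
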