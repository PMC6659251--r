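#' Graded response model probabilities
#'
#' Cumulative ("operating characteristic") and category probabilities of the
#' two-parameter graded response model (GRM). For item \eqn{j} with slope
#' \eqn{\alpha_j > 0} and ordered thresholds \eqn{\beta_{j1} < \beta_{j2} <
#' \beta_{j3}}, the probability of scoring category \eqn{k} or above is the
#' logistic \deqn{P(X_j \ge k \mid \theta) =
#'   \frac{e^{\alpha_j(\theta - \beta_{jk})}}{1 + e^{\alpha_j(\theta - \beta_{jk})}}.}
#' Thresholds are on the same standard-normal latent scale as \eqn{\theta};
#' no 1.7 scaling constant is applied.
#'
#' @param theta numeric vector of latent trait values.
#' @param alpha positive slope (scalar).
#' @param beta increasing vector of thresholds (one per category boundary).
#' @return `grm_cum_prob`: a `length(theta) x length(beta)` matrix of
#'   \eqn{P(X \ge k)}; `grm_cat_prob`: a `length(theta) x (length(beta)+1)`
#'   matrix of category probabilities \eqn{P(X = k)}, rows summing to 1.
#' @examples
#' grm_cum_prob(0, 2, c(-1, 0, 1))
#' rowSums(grm_cat_prob(c(-2, 0, 2), 1.5, c(-1, 0, 1)))
#' @export
grm_cum_prob <- function(theta, alpha, beta) {
  stopifnot(alpha > 0, !is.unsorted(beta, strictly = TRUE))
  m <- outer(theta, beta, function(t, b) stats::plogis(alpha * (t - b)))
  dimnames(m) <- list(NULL, paste0("ge", seq_along(beta)))
  m
}

#' @rdname grm_cum_prob
#' @export
grm_cat_prob <- function(theta, alpha, beta) {
  cum <- grm_cum_prob(theta, alpha, beta)
  p <- cbind(1, cum) - cbind(cum, 0)
  dimnames(p) <- list(NULL, paste0("k", 0:length(beta)))
  p
}

#' Sample graded responses at given latent trait values
#'
#' Draws one ordinal score per element of `theta` for each item, category-wise
#' from the GRM. Used by the synthetic registry generator and by
#' parameter-recovery tests.
#'
#' @param theta numeric vector of latent trait values (one draw per value).
#' @param alpha vector of item slopes.
#' @param beta matrix of thresholds, one row per item, columns increasing.
#' @return integer matrix `length(theta) x nrow(beta)` with scores in
#'   `0:ncol(beta)`.
#' @export
rgrm <- function(theta, alpha, beta) {
  beta <- as.matrix(beta)
  stopifnot(length(alpha) == nrow(beta), all(alpha > 0))
  n <- length(theta)
  out <- matrix(0L, n, nrow(beta))
  for (j in seq_len(nrow(beta))) {
    cum <- grm_cum_prob(theta, alpha[j], beta[j, ])
    u <- stats::runif(n)
    # P(X >= k) is decreasing in k, so counting thresholds passed gives the score
    out[, j] <- rowSums(u <= cum)
  }
  colnames(out) <- rownames(beta) %||% paste0("adl", seq_len(nrow(beta)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gauss-Hermite grid transformed for a N(0,1) prior: nodes t and weights w
# with sum(w) = 1 and sum(w * f(t)) ~ E[f(theta)], theta ~ N(0,1).
gh_grid <- function(n_quad) {
  gh <- pracma::gaussHermite(n_quad)
  list(nodes = sqrt(2) * gh$x, weights = gh$w / sqrt(pi))
}

# dense equispaced grid with normalized N(0,1) weights, used for EAP scoring
score_grid <- function(step = 0.02, span = 8) {
  nodes <- seq(-span, span, by = step)
  w <- stats::dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

# category-probability array: list over items of K x Q matrices P(X=k | theta_q)
grm_prob_table <- function(alpha, beta, nodes) {
  lapply(seq_along(alpha), function(j) {
    t(grm_cat_prob(nodes, alpha[j], beta[j, ]))  # K x Q
  })
}

# item parameters <-> unconstrained vector (log alpha, beta1, log increments)
grm_par_pack <- function(alpha, beta_row) {
  c(log(alpha), beta_row[1], log(diff(beta_row)))
}
grm_par_unpack <- function(par) {
  # clamp so optimizer excursions can't overflow/underflow the exp transforms
  b1 <- min(max(par[2], -50), 50)
  inc <- pmin(pmax(exp(pmin(par[-(1:2)], 50)), 1e-6), 1e3)
  list(alpha = min(max(exp(min(par[1], 50)), 1e-4), 1e4),
       beta = cumsum(c(b1, inc)))
}

#' Fit a graded response model by marginal maximum likelihood
#'
#' Fits the two-parameter graded response model to a matrix of ordinal item
#' scores by marginal maximum likelihood (Bock-Aitkin EM) with a standard
#' normal latent-trait distribution and Gauss-Hermite quadrature. The latent
#' scale is identified by fixing \eqn{\theta \sim N(0,1)}; threshold ordering
#' is enforced by parameterizing each item's thresholds as a first threshold
#' plus log-increments.
#'
#' Incomplete rows (any `NA`) are dropped before fitting, with a warning.
#' An item observed in fewer than two categories carries no information about
#' its thresholds and is rejected.
#'
#' @param responses matrix or data frame of integer scores `0..n_cat-1`,
#'   one row per assessment, one column per item.
#' @param n_cat number of categories per item (default 4, scores 0-3).
#' @param n_quad number of Gauss-Hermite quadrature nodes (default 41).
#' @param tol EM convergence tolerance on the maximum absolute parameter
#'   change (default 1e-4).
#' @param max_iter EM iteration cap (default 500).
#' @param check_unidim if `TRUE` (default), screen unidimensionality of the
#'   polychoric correlation matrix first and warn (not fail) if it fails.
#' @return an object of class `"grm"` with components `alpha` (slopes),
#'   `beta` (threshold matrix), `logLik`, `convergence` (list: converged flag,
#'   iterations, final max parameter change, log-likelihood trace), `quad`
#'   (node/weight grid), `n`, `n_items`, `unidim` (eigen report or `NULL`).
#' @seealso [predict.grm()] for EAP scoring, [simulate.grm()], [plot.grm()]
#' @examples
#' set.seed(1)
#' th <- rnorm(400)
#' X <- rgrm(th, alpha = c(2, 2), beta = rbind(c(-1, 0, 1), c(-1, 0, 1)))
#' fit <- grm(X, check_unidim = FALSE)
#' coef(fit)
#' @export
grm <- function(responses, n_cat = 4L, n_quad = 41L, tol = 1e-4,
                max_iter = 500L, check_unidim = TRUE) {
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  if (anyNA(X)) {
    keep <- stats::complete.cases(X)
    warning(sprintf("dropping %d incomplete assessment rows", sum(!keep)))
    X <- X[keep, , drop = FALSE]
  }
  n <- nrow(X); J <- ncol(X)
  if (n == 0L) stop("no complete assessment rows")
  if (any(X < 0L | X >= n_cat)) stop("scores must lie in 0..", n_cat - 1L)
  item_names <- colnames(X) %||% paste0("adl", seq_len(J))
  ncat_obs <- apply(X, 2, function(x) length(unique(x)))
  if (any(ncat_obs < 2L))
    stop("degenerate item(s) with a single observed category: ",
         paste(item_names[ncat_obs < 2L], collapse = ", "))

  unidim <- NULL
  if (isTRUE(check_unidim) && all(ncat_obs >= 2L)) {
    unidim <- tryCatch({
      rep_ <- unidimensionality_check(polychoric_matrix(X, n_cat = n_cat))
      if (!rep_$pass)
        warning("unidimensionality screening failed; fitting a unidimensional GRM anyway")
      rep_
    }, error = function(e) NULL)
  }

  K <- n_cat
  grid <- gh_grid(n_quad)
  Q <- n_quad

  # collapse to unique response patterns
  key <- as.vector(X %*% K^(seq_len(J) - 1L))
  tab <- sort(unique(key))
  pat_id <- match(key, tab)
  counts <- tabulate(pat_id, nbins = length(tab))
  U <- X[match(tab, key), , drop = FALSE]      # npat x J
  npat <- nrow(U)

  # starting values from marginal cumulative proportions at alpha = 1
  alpha <- rep(1, J)
  beta <- matrix(0, J, K - 1L)
  for (j in seq_len(J)) {
    pge <- vapply(seq_len(K - 1L), function(k) mean(X[, j] >= k), 0)
    pge <- pmin(pmax(pge, 1e-3), 1 - 1e-3)
    b <- -stats::qlogis(pge)
    beta[j, ] <- b + cumsum(c(0, pmax(0, -diff(b)) + 1e-3)) # enforce strict order
  }

  pat_loglik <- function(Ptab) {
    # npat x Q matrix of log f(pattern | theta_q)
    ll <- matrix(0, npat, Q)
    for (j in seq_len(J)) {
      pj <- Ptab[[j]]                       # K x Q; row-index by category
      ll <- ll + log(pmax(pj[U[, j] + 1L, , drop = FALSE], 1e-300))
    }
    ll
  }

  obs_loglik <- function(ll) {
    m <- apply(ll, 1, max)
    sum(counts * (m + log(as.vector(exp(ll - m) %*% grid$weights))))
  }

  par_vec <- function() c(log(alpha), as.vector(beta))
  ll_trace <- numeric(0)
  converged <- FALSE
  delta <- NA_real_
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    old <- par_vec()
    Ptab <- grm_prob_table(alpha, beta, grid$nodes)
    ll <- pat_loglik(Ptab)
    ll_trace <- c(ll_trace, obs_loglik(ll))

    # E-step: posterior weight of node q for each pattern
    m <- apply(ll, 1, max)
    num <- exp(ll - m) * rep(grid$weights, each = npat)
    post <- num / rowSums(num)               # npat x Q
    wpost <- post * counts                   # expected pattern-node counts

    # M-step: per-item multinomial fit over nodes
    for (j in seq_len(J)) {
      r <- matrix(0, K, Q)                   # expected counts category x node
      for (k in 0:(K - 1L)) {
        rows <- U[, j] == k
        if (any(rows)) r[k + 1L, ] <- colSums(wpost[rows, , drop = FALSE])
      }
      nll <- function(par) {
        up <- grm_par_unpack(par)
        p <- t(grm_cat_prob(grid$nodes, up$alpha, up$beta))  # K x Q
        -sum(r * log(pmax(p, 1e-300)))
      }
      fit <- stats::optim(grm_par_pack(alpha[j], beta[j, ]), nll,
                          method = "BFGS", control = list(maxit = 200))
      up <- grm_par_unpack(fit$par)
      alpha[j] <- up$alpha
      beta[j, ] <- up$beta
    }

    delta <- max(abs(par_vec() - old))
    if (delta < tol) { converged <- TRUE; break }
  }

  Ptab <- grm_prob_table(alpha, beta, grid$nodes)
  ll_final <- obs_loglik(pat_loglik(Ptab))
  if (!converged)
    warning(sprintf(
      "GRM EM did not converge in %d iterations (last max parameter change %.2e); returning partial fit",
      max_iter, delta))

  rownames(beta) <- item_names
  colnames(beta) <- paste0("b", seq_len(K - 1L))
  names(alpha) <- item_names
  structure(list(
    alpha = alpha, beta = beta, logLik = ll_final,
    convergence = list(converged = converged, iterations = iter,
                       last_change = delta, loglik_trace = c(ll_trace, ll_final)),
    quad = grid, n = n, n_items = J, n_cat = K, unidim = unidim,
    call = match.call()
  ), class = "grm")
}
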