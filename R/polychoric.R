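#' Polychoric correlation matrix of ordinal items
#'
#' Two-stage polychoric estimator: per-item thresholds are set at the normal
#' quantiles of the cumulative marginal category proportions, then each
#' pairwise correlation maximizes the bivariate-normal likelihood of the
#' observed two-way contingency table, with cell probabilities from
#' [mvtnorm::pmvnorm()].
#'
#' @param responses matrix or data frame of integer scores `0..n_cat-1`.
#' @param n_cat number of categories per item.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(responses, n_cat = 4L) {
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  J <- ncol(X)
  item_names <- colnames(X) %||% paste0("adl", seq_len(J))
  ncats <- apply(X, 2, function(x) length(unique(x[!is.na(x)])))
  if (any(ncats < 2L))
    stop("degenerate item(s) with a single observed category: ",
         paste(item_names[ncats < 2L], collapse = ", "))
  # stage 1: thresholds on the latent normal scale, -Inf/Inf padded
  thr <- lapply(seq_len(J), function(j) {
    p <- cumsum(tabulate(X[, j] + 1L, nbins = n_cat)) / sum(!is.na(X[, j]))
    c(-Inf, stats::qnorm(pmin(pmax(p[-n_cat], 1e-10), 1 - 1e-10)), Inf)
  })
  R <- diag(J)
  for (a in seq_len(J - 1L)) for (b in (a + 1L):J) {
    ok <- !is.na(X[, a]) & !is.na(X[, b])
    tab <- table(factor(X[ok, a], levels = 0:(n_cat - 1L)),
                 factor(X[ok, b], levels = 0:(n_cat - 1L)))
    R[a, b] <- R[b, a] <- polychoric_rho(tab, thr[[a]], thr[[b]])
  }
  dimnames(R) <- list(item_names, item_names)
  R
}

# stage 2: profile the bivariate-normal likelihood over rho for one pair
polychoric_rho <- function(tab, ta, tb) {
  nll <- function(rho) {
    corr <- matrix(c(1, rho, rho, 1), 2)
    ll <- 0
    for (i in which(rowSums(tab) > 0)) for (j in which(tab[i, ] > 0)) {
      p <- mvtnorm::pmvnorm(lower = c(ta[i], tb[j]), upper = c(ta[i + 1L], tb[j + 1L]),
                            corr = corr)
      ll <- ll + tab[i, j] * log(max(as.numeric(p), 1e-300))
    }
    -ll
  }
  stats::optimize(nll, interval = c(-0.999, 0.999), tol = 1e-6)$minimum
}

#' Eigenvalue screen for unidimensionality of the latent scale
#'
#' Examines the eigenvalues of a polychoric correlation matrix to judge
#' whether the items measure a single construct. Three criteria are
#' evaluated: the first eigenvalue dominates (ratio of first to second
#' eigenvalue above 3), the second eigenvalue is below 1.0, and the first
#' component's variance share is reported alongside.
#'
#' @param R a correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite to tolerance 1e-8).
#' @return a list: `eigenvalues`, `variance_share`, `ratio` (first/second),
#'   `criteria` (named logicals `second_below_1`, `ratio_above_3`,
#'   `first_dominant`), and `pass` (all criteria).
#' @export
unidimensionality_check <- function(R) {
  R <- as.matrix(R)
  if (!isSymmetric(unname(R), tol = 1e-8) || any(abs(diag(R) - 1) > 1e-8))
    stop("input must be a correlation matrix (symmetric, unit diagonal)")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("matrix is not positive semi-definite (smallest eigenvalue ",
         format(min(ev)), ")")
  share <- ev / sum(ev)
  ratio <- ev[1] / ev[2]
  criteria <- c(second_below_1 = ev[2] < 1.0,
                ratio_above_3 = ratio > 3,
                first_dominant = share[1] > 0.5)
  list(eigenvalues = ev, variance_share = share, ratio = ratio,
       criteria = criteria, pass = all(criteria))
}
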