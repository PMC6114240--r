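# Proportional-odds (ordered logistic) maximum likelihood, written for the
# imputation engine: Newton-Raphson with analytic gradient and Hessian
# (fast on the small design matrices of chained equations), explicit
# separation / perfect-prediction detection, and a normal approximation at
# the MLE for approximately proper imputation draws.
#
#' Fit a proportional-odds model by maximum likelihood
#'
#' Ordered logistic regression `P(y <= k | x) = plogis(zeta_k - x'beta)`
#' with strictly increasing cutpoints, fitted by Newton-Raphson with
#' analytic gradient and Hessian and step-halving. Intended as the
#' conditional model for item-level imputation, so statistical failure is
#' signalled as a structured non-convergence condition rather than an
#' ordinary error:
#'
#' * a category in `all_levels` with zero observed cases (the typical
#'   zero-cell situation in an arm stratum), fewer than two observed
#'   categories, a non-finite likelihood improvement, or any standardised
#'   coefficient `|beta/se| > 10` (separation) signal reason
#'   `"perfect_prediction"`;
#' * a non-invertible observed information signals
#'   `"singular_information"`;
#' * fewer observed rows than parameters plus two signals `"overfit"`.
#'
#' @param y ordinal response (integer codes; `NA` entries are dropped).
#' @param X numeric predictor matrix (no intercept column; the cutpoints
#'   absorb it).
#' @param all_levels the full set of category codes that must be present
#'   among the observed `y` (defaults to the observed set, disabling the
#'   zero-cell scan).
#' @param start optional warm start, a list with `beta` and `zeta` on the
#'   original predictor scale (typically the previous sweep's fit in a
#'   chained-equations loop); ignored when infeasible.
#' @return an object of class `promice_ologit`: `coefficients`, `zeta`
#'   (cutpoints), `levels`, `theta_z` and `vcov_z` (MLE and covariance in
#'   an unconstrained cutpoint parametrisation used for posterior-style
#'   draws), `logLik`, `n`.
#' @export
fit_ologit <- function(y, X, all_levels = NULL, start = NULL) {
  X <- as.matrix(X)
  keep <- !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  obs_levels <- sort(unique(y))
  if (!is.null(all_levels) && !all(all_levels %in% obs_levels))
    nonconvergence("perfect_prediction",
                   "a category has zero observed cases in this stratum")
  levels <- if (is.null(all_levels)) obs_levels else sort(all_levels)
  K <- length(levels)
  if (K < 2L)
    nonconvergence("perfect_prediction", "fewer than two observed categories")
  yidx <- match(y, levels)
  p <- ncol(X)
  if (length(y) <= p + K)
    nonconvergence("overfit", "too few observed rows for the model size")
  # centre/scale columns for numerical stability; map estimates back
  n_obs <- nrow(X)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(X^2) - ctr^2) * sqrt(n_obs / (n_obs - 1))
  scl[scl < .Machine$double.eps] <- 1
  Xs <- X
  for (j in seq_len(p)) Xs[, j] <- (X[, j] - ctr[j]) / scl[j]
  cum <- cumsum(tabulate(yidx, K))[seq_len(K - 1L)] / length(y)
  cum <- pmin(pmax(cum, 1e-4), 1 - 1e-4)
  beta <- rep(0, p)
  zeta <- stats::qlogis(cum)
  zeta <- cummax(zeta + seq_len(K - 1L) * 1e-8)   # ensure increasing
  # warm start (e.g. the previous sweep's MLE, in original-scale units):
  # Newton then converges in a step or two; fall back if it is infeasible
  if (!is.null(start) && length(start$beta) == p &&
      length(start$zeta) == K - 1L) {
    beta_w <- start$beta * scl
    zeta_w <- start$zeta - sum(start$beta * ctr)
    if (all(is.finite(c(beta_w, zeta_w))) &&
        (K == 2L || all(diff(zeta_w) > 0))) {
      ll_w <- ologit_kernel(beta_w, zeta_w, Xs, yidx, K, FALSE)$negll
      if (is.finite(ll_w)) { beta <- beta_w; zeta <- zeta_w }
    }
  }
  ll <- ologit_kernel(beta, zeta, Xs, yidx, K, FALSE)$negll
  if (!is.finite(ll))
    nonconvergence("perfect_prediction", "non-finite likelihood at start")
  converged <- FALSE
  for (it in 1:30) {
    dv <- ologit_kernel(beta, zeta, Xs, yidx, K, TRUE)
    step <- tryCatch(solve(dv$hessian, dv$gradient), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      nonconvergence("singular_information", "Hessian not invertible")
    lam <- 1
    repeat {
      beta_n <- beta - lam * step[seq_len(p)]
      zeta_n <- zeta - lam * step[p + seq_len(K - 1L)]
      ll_n <- if (K > 2L && any(diff(zeta_n) <= 0)) Inf
              else ologit_kernel(beta_n, zeta_n, Xs, yidx, K, FALSE)$negll
      if (ll_n <= ll + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8)
        nonconvergence("perfect_prediction",
                       "non-finite likelihood improvement")
    }
    improve <- ll - ll_n
    beta <- beta_n; zeta <- zeta_n; ll <- ll_n
    if (!is.finite(improve))
      nonconvergence("perfect_prediction", "non-finite likelihood improvement")
    if (improve < 1e-9 * (abs(ll) + 1)) { converged <- TRUE; break }
  }
  if (!converged)
    nonconvergence("perfect_prediction", "maximum likelihood did not converge")
  dv <- ologit_kernel(beta, zeta, Xs, yidx, K, TRUE)
  V <- tryCatch(chol2inv(chol(dv$hessian)), error = function(e) NULL)
  if (is.null(V))
    nonconvergence("singular_information",
                   "observed information not positive definite")
  # beta is on the unit-variance predictor scale here, so a coefficient of
  # 10 means ten log-odds per predictor sd: separation in all but name
  if (p > 0 && any(abs(beta) > 10))
    nonconvergence("perfect_prediction",
                   "separation detected (|standardized coefficient| > 10)")
  # unconstrained cutpoint parametrisation for draws:
  # z = (zeta_1, log diff(zeta)); vcov mapped by the (inverse) Jacobian
  z <- c(zeta[1], if (K > 2L) log(diff(zeta)))
  J <- matrix(0, K - 1L, K - 1L)          # dzeta/dz, lower triangular
  J[, 1] <- 1
  if (K > 2L) for (k in 2:(K - 1L)) J[k:(K - 1L), k] <- exp(z[k])
  Jinv <- forwardsolve(J, diag(K - 1L))
  Tm <- diag(p + K - 1L)
  Tm[p + seq_len(K - 1L), p + seq_len(K - 1L)] <- Jinv
  vcov_z <- Tm %*% V %*% t(Tm)
  beta_orig <- beta / scl
  zeta_orig <- zeta + sum(beta_orig * ctr)
  structure(list(
    coefficients = stats::setNames(beta_orig, colnames(X)),
    zeta = zeta_orig, levels = levels,
    theta_z = c(beta, z), vcov_z = vcov_z,
    centre = ctr, scale = scl,
    logLik = -ll, n = length(y), iterations = it
  ), class = "promice_ologit")
}

#' @export
print.promice_ologit <- function(x, ...) {
  cat(sprintf("<promice_ologit> %d obs, %d categories, logLik %.2f (%d Newton steps)\n",
              x$n, length(x$levels), x$logLik, x$iterations))
  print(x$coefficients)
  cat("cutpoints:", format(x$zeta, digits = 4), "\n")
  invisible(x)
}

ologit_zeta_from_z <- function(z) cumsum(c(z[1], exp(z[-1])))

ologit_prob_matrix <- function(beta_s, zeta, Xs, K) {
  eta <- drop(Xs %*% beta_s)
  cum <- vapply(zeta, function(t) stats::plogis(t - eta), numeric(length(eta)))
  if (length(eta) == 1L) cum <- matrix(cum, nrow = 1L)
  cbind(cum, 1) - cbind(0, cum)
}

#' Category probabilities from a fitted proportional-odds model
#'
#' @param fit a [fit_ologit()] result.
#' @param X new predictor matrix.
#' @return matrix (rows x categories) of probabilities; each row sums to 1
#'   by construction.
#' @export
predict_ologit <- function(fit, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, fit$centre), 2, fit$scale, "/")
  p <- length(fit$coefficients); K <- length(fit$levels)
  pr <- ologit_prob_matrix(fit$theta_z[seq_len(p)],
                           ologit_zeta_from_z(fit$theta_z[p + seq_len(K - 1L)]),
                           Xs, K)
  colnames(pr) <- fit$levels
  pr
}

#' Draw ordinal imputations from a fitted proportional-odds model
#'
#' Parameters are perturbed by one draw from the normal approximation at
#' the MLE (inverse observed information, in the unconstrained cutpoint
#' parametrisation so cutpoints stay increasing); each missing entry is
#' then drawn from its row's category distribution. Draws are always
#' admissible category codes.
#'
#' @param fit a [fit_ologit()] result.
#' @param X_missing predictor matrix of the rows to impute.
#' @return vector of drawn category codes.
#' @export
impute_ologit <- function(fit, X_missing) {
  X <- as.matrix(X_missing)
  if (!nrow(X)) return(integer(0))
  Xs <- sweep(sweep(X, 2, fit$centre), 2, fit$scale, "/")
  p <- length(fit$coefficients); K <- length(fit$levels)
  L <- tryCatch(chol(fit$vcov_z), error = function(e) NULL)
  if (is.null(L))
    nonconvergence("singular_information",
                   "parameter covariance not positive definite")
  th <- fit$theta_z + drop(crossprod(L, stats::rnorm(length(fit$theta_z))))
  pr <- ologit_prob_matrix(th[seq_len(p)],
                           ologit_zeta_from_z(th[p + seq_len(K - 1L)]),
                           Xs, K)
  u <- stats::runif(nrow(pr))
  cum <- pr %*% upper.tri(diag(K), diag = TRUE)   # row-wise cumulative sums
  idx <- 1L + rowSums(u > cum[, seq_len(K - 1L), drop = FALSE])
  fit$levels[idx]
}
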