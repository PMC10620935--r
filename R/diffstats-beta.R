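# Beta mixed regression for isotopologue fractions.
#
# Model: y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi) with
#   logit(mu_i) = beta_{group(i)} + b_{donor(i)},  b_d ~ N(0, sigma_d^2).
# The marginal likelihood integrates over each donor's random intercept by
# adaptive Gauss-Hermite quadrature: per donor the integrand's mode and
# curvature are found by Newton steps, and the quadrature grid is centered
# and scaled there before summation. ML estimation over
# (beta, log phi, log sigma_d).

# log-density of one beta observation at mean mu, precision phi
ldbeta <- function(y, mu, phi) {
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

# d/db of sum_i log f(y_i | plogis(eta_i + b), phi) + log dnorm(b, 0, sigma)
beta_grad_b <- function(b, y, eta0, phi, sigma) {
  mu <- stats::plogis(eta0 + b)
  sum(phi * mu * (1 - mu) *
        (log(y) - log1p(-y) - digamma(mu * phi) + digamma((1 - mu) * phi))) -
    b / sigma^2
}

beta_joint_b <- function(b, y, eta0, phi, sigma) {
  mu <- stats::plogis(eta0 + b)
  sum(ldbeta(y, mu, phi)) + stats::dnorm(b, 0, sigma, log = TRUE)
}

# Newton search for the per-donor posterior mode; returns mode and curvature
find_mode_b <- function(y, eta0, phi, sigma) {
  b <- 0
  for (iter in 1:50) {
    g <- beta_grad_b(b, y, eta0, phi, sigma)
    eps <- 1e-4 * max(1, abs(b))
    H <- (beta_grad_b(b + eps, y, eta0, phi, sigma) -
            beta_grad_b(b - eps, y, eta0, phi, sigma)) / (2 * eps)
    if (!is.finite(H) || H >= 0) H <- -(1 / sigma^2 + 1)
    step <- g / H
    step <- sign(step) * min(abs(step), 2)
    b <- b - step
    if (abs(step) < 1e-9) break
  }
  eps <- 1e-4 * max(1, abs(b))
  H <- (beta_grad_b(b + eps, y, eta0, phi, sigma) -
          beta_grad_b(b - eps, y, eta0, phi, sigma)) / (2 * eps)
  if (!is.finite(H) || H >= 0) H <- -(1 / sigma^2 + 1)
  list(b = b, H = H)
}

# marginal log-likelihood by adaptive Gauss-Hermite quadrature
betamm_loglik <- function(par, y, X, donor, gh) {
  G <- ncol(X)
  beta <- par[1:G]
  phi <- exp(par[G + 1])
  sigma <- exp(par[G + 2])
  eta0 <- as.vector(X %*% beta)
  ll <- 0
  for (d in levels(donor)) {
    idx <- which(donor == d)
    yd <- y[idx]; ed <- eta0[idx]
    m <- find_mode_b(yd, ed, phi, sigma)
    shat <- sqrt(-1 / m$H)
    bk <- m$b + sqrt(2) * shat * gh$x
    tk <- log(gh$w) + gh$x^2 +
      vapply(bk, beta_joint_b, numeric(1), y = yd, eta0 = ed,
             phi = phi, sigma = sigma)
    M <- max(tk)
    if (!is.finite(M)) return(-Inf)
    ll <- ll + M + log(sum(exp(tk - M))) + 0.5 * log(2) + log(shat)
  }
  ll
}

#' Beta mixed regression for one isotopologue's fractions
#'
#' Maximum-likelihood fit of a beta-response model with logit link,
#' celltype group as fixed effect (cell-means coding) and a donor random
#' intercept, the marginal likelihood being integrated per donor by
#' adaptive Gauss-Hermite quadrature with `nq` nodes. Boundary
#' observations (exact 0 or 1) are shrunk inward by
#' `y' = (y * (N - 1) + 0.5) / N` (N = number of observations); interior
#' values are untouched.
#'
#' @param y named numeric vector of fractions in `[0, 1]` per sample.
#' @param meta sample metadata; non-blank samples of `names(y)` are used.
#' @param nq number of quadrature nodes (>= 3, default 9).
#' @return a `beta_fit`: coefficients on the logit scale named by group
#'   level, their covariance matrix, precision `phi`, donor SD `sigma_d`,
#'   `logLik`, `converged`, `n`. The fitted data and design are retained so
#'   the likelihood can be re-evaluated (see [betareg_loglik()]).
#' @export
fit_mid_betareg <- function(y, meta, nq = 9) {
  meta <- assert_meta(meta)
  smeta <- meta[!meta$is_blank & meta$sample_id %in% names(y), , drop = FALSE]
  yy <- y[smeta$sample_id]
  keep <- is.finite(yy)
  yy <- yy[keep]; smeta <- smeta[keep, , drop = FALSE]
  if (length(yy) < 4) stopf("too few observations to fit")
  if (any(yy < 0 | yy > 1)) stopf("fractions must lie in [0, 1]")
  N <- length(yy)
  bound <- yy == 0 | yy == 1
  yy[bound] <- (yy[bound] * (N - 1) + 0.5) / N
  grp <- droplevels(factor(smeta$group))
  if (nlevels(grp) < 2) stopf("need >= 2 groups with data")
  dnr <- droplevels(factor(smeta$donor))
  X <- stats::model.matrix(~ 0 + grp)
  colnames(X) <- levels(grp)
  gh <- pracma::gaussHermite(nq)

  # starting values: logit group means, moment-matched precision, donor SD
  gm <- tapply(yy, grp, mean)
  beta0 <- stats::qlogis(pmin(pmax(gm, 1e-3), 1 - 1e-3))
  mu0 <- stats::plogis(as.vector(X %*% beta0))
  r <- yy - mu0
  v <- stats::var(r)
  phi0 <- if (is.finite(v) && v > 0) {
    max(min(mean(mu0 * (1 - mu0)) / v - 1, 1e4), 2)
  } else 100
  dm <- tapply(r, dnr, mean)
  sigma0 <- max(stats::sd(dm), 0.05)
  if (!is.finite(sigma0)) sigma0 <- 0.1
  start <- c(beta0, log(phi0), log(sigma0))

  nll <- function(par) -betamm_loglik(par, yy, X, dnr, gh)
  G <- ncol(X)
  opt <- stats::nlminb(start, nll,
                       lower = c(rep(-30, G), log(1e-2), log(1e-6)),
                       upper = c(rep(30, G), log(1e8), log(50)),
                       control = list(eval.max = 2000, iter.max = 500))
  par <- opt$par
  H <- tryCatch(pracma::hessian(nll, par), error = function(e) NULL)
  V <- NULL
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(solve(H), error = function(e) pracma::pinv(H))
  }
  Vb <- if (is.null(V)) {
    matrix(NA_real_, G, G)
  } else {
    V[1:G, 1:G, drop = FALSE]
  }
  dimnames(Vb) <- list(levels(grp), levels(grp))
  converged <- opt$convergence == 0 && all(is.finite(diag(Vb))) &&
    all(diag(Vb) >= 0)
  structure(list(
    coefficients = stats::setNames(par[1:G], levels(grp)),
    vcov = Vb,
    phi = exp(par[G + 1]),
    sigma_d = exp(par[G + 2]),
    logLik = -opt$objective,
    converged = converged,
    n = N, nq = nq,
    internals = list(y = yy, X = X, donor = dnr, par = par)
  ), class = "beta_fit")
}

#' Re-evaluate a beta mixed fit's marginal log-likelihood
#'
#' Evaluates the adaptive Gauss-Hermite marginal log-likelihood of a
#' fitted model at its estimated parameters with a chosen number of
#' quadrature nodes — a quadrature-refinement diagnostic: for a converged
#' fit the value should be stable as `nq` grows.
#'
#' @param fit a `beta_fit`.
#' @param nq number of quadrature nodes.
#' @return the marginal log-likelihood (numeric scalar).
#' @export
betareg_loglik <- function(fit, nq = fit$nq %||% 9) {
  it <- fit$internals
  betamm_loglik(it$par, it$y, it$X, it$donor, pracma::gaussHermite(nq))
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("beta_fit: group means on the logit scale\n")
  print(round(x$coefficients, 4))
  cat(sprintf("phi = %.4g, sigma_donor = %.4g, logLik = %.3f%s\n",
              x$phi, x$sigma_d, x$logLik,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
coef.beta_fit <- function(object, ...) object$coefficients

#' @export
vcov.beta_fit <- function(object, ...) object$vcov

#' @export
logLik.beta_fit <- function(object, ...) {
  structure(object$logLik, class = "logLik")
}
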