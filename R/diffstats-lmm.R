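#' Linear mixed model for one metabolite's abundances
#'
#' Fits `log(y) ~ 0 + group + (1 | donor)` by REML: celltype group as fixed
#' effect (cell-means coding, one coefficient per group level) and donor as
#' random intercept. Zero abundances are replaced by half the smallest
#' positive value of the analyte before logging (half-minimum
#' limit-of-detection rule); positive values are untouched. When fewer than
#' two donor levels are present the model degenerates to ordinary least
#' squares with donor variance zero.
#'
#' @param y named numeric vector of abundances per sample.
#' @param meta sample metadata (non-blank samples of `names(y)` are used).
#' @param transform `"log"` (default, natural log) or `"linear"`.
#' @param keep_model keep the underlying `lmerMod`/`lm` object in the
#'   result (needed for Satterthwaite degrees of freedom); off by default
#'   to keep large screens light.
#' @return an `lmm_fit`: coefficients named by group level, their
#'   covariance matrix, `sigma_d` (donor SD), `sigma_e` (residual SD),
#'   `logLik`, `converged`, `n`.
#' @export
fit_abundance_lmm <- function(y, meta, transform = c("log", "linear"),
                              keep_model = FALSE) {
  transform <- match.arg(transform)
  meta <- assert_meta(meta)
  smeta <- meta[!meta$is_blank & meta$sample_id %in% names(y), , drop = FALSE]
  yy <- y[smeta$sample_id]
  keep <- is.finite(yy)
  yy <- yy[keep]; smeta <- smeta[keep, , drop = FALSE]
  if (length(yy) < 4) stopf("too few observations to fit")
  if (transform == "log") {
    if (any(yy < 0)) stopf("negative abundances")
    pos <- yy[yy > 0]
    if (length(pos) == 0) stopf("all abundances zero")
    yy[yy == 0] <- min(pos) / 2
    yy <- log(yy)
  }
  grp <- droplevels(factor(smeta$group))
  if (nlevels(grp) < 2) stopf("need >= 2 groups with data")
  dnr <- droplevels(factor(smeta$donor))
  dat <- data.frame(resp = yy, group = grp, donor = dnr)

  converged <- TRUE
  if (nlevels(dnr) >= 2) {
    fit <- withCallingHandlers(
      lme4::lmer(resp ~ 0 + group + (1 | donor), data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- lme4::VarCorr(fit)
    sigma_d <- attr(vc$donor, "stddev")[[1]]
    sigma_e <- stats::sigma(fit)
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fit <- stats::lm(resp ~ 0 + group, data = dat)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    sigma_d <- 0
    sigma_e <- stats::sigma(fit)
    ll <- as.numeric(stats::logLik(fit))
  }
  lv <- levels(grp)
  names(beta) <- sub("^group", "", names(beta))
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(
    coefficients = beta[lv], vcov = V[lv, lv, drop = FALSE],
    sigma_d = sigma_d, sigma_e = sigma_e, logLik = ll,
    converged = converged, n = nrow(dat),
    model = if (keep_model) fit else NULL
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("lmm_fit: group means on the (log-)abundance scale\n")
  print(round(x$coefficients, 4))
  cat(sprintf("sigma_donor = %.4g, sigma_resid = %.4g, logLik = %.3f%s\n",
              x$sigma_d, x$sigma_e, x$logLik,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$coefficients

#' @export
vcov.lmm_fit <- function(object, ...) object$vcov

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$logLik, class = "logLik")
}
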