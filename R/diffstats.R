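#' Consecutive-difference contrasts over an ordered set of groups
#'
#' For groups ordered along a differentiation axis (e.g. TN, TSCM, TCM,
#' TEM) builds the contrasts between consecutively sampled subsets:
#' `TSCM-TN`, `TCM-TSCM`, `TEM-TCM`.
#'
#' @param levels character vector of group levels in order.
#' @return named list of contrast vectors (entries sum to zero).
#' @export
consecutive_contrasts <- function(levels) {
  if (length(levels) < 2) return(list())
  out <- list()
  for (i in 2:length(levels)) {
    v <- stats::setNames(numeric(length(levels)), levels)
    v[levels[i]] <- 1
    v[levels[i - 1]] <- -1
    out[[paste0(levels[i], "-", levels[i - 1])]] <- v
  }
  out
}

#' Wald tests of contrasts with per-contrast FDR adjustment
#'
#' For each fitted analyte and each contrast `c`, computes the estimate
#' `c' beta`, its standard error from the coefficient covariance, the Wald
#' z statistic and a two-sided normal p-value. p-values are then
#' Benjamini-Hochberg adjusted within each contrast, across the analytes
#' of the collection (abundance-level and isotopologue-level analyses form
#' separate adjustment families because they are passed in separately).
#'
#' @param fits named list of `lmm_fit` / `beta_fit` objects (entries may
#'   be `NULL` for analytes whose fit failed; they yield missing rows).
#' @param contrasts named list of named numeric contrast vectors over
#'   group levels (see [consecutive_contrasts()]); nonzero weights must
#'   refer to levels present in at least one fit.
#' @param df_method `"z"` (normal approximation, default) or
#'   `"satterthwaite"` (via \pkg{lmerTest}; applies to linear mixed fits
#'   carrying their model object, i.e. fitted with `keep_model = TRUE` —
#'   other fits fall back to z).
#' @return a `diff_result` data frame: `analyte`, `contrast`, `estimate`,
#'   `se`, `statistic`, `p`, `padj`.
#' @export
test_contrasts <- function(fits, contrasts, df_method = c("z", "satterthwaite")) {
  df_method <- match.arg(df_method)
  cols <- c("analyte", "contrast", "estimate", "se", "statistic", "p", "padj")
  empty <- data.frame(analyte = character(0), contrast = character(0),
                      estimate = numeric(0), se = numeric(0),
                      statistic = numeric(0), p = numeric(0),
                      padj = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("diff_result", "data.frame")
  if (length(fits) == 0 || length(contrasts) == 0) return(empty)
  all_levels <- unique(unlist(lapply(fits, function(f) {
    if (is.null(f)) character(0) else names(f$coefficients)
  })))
  rows <- list()
  for (ct in names(contrasts)) {
    cv <- contrasts[[ct]]
    used <- names(cv)[cv != 0]
    absent <- setdiff(used, all_levels)
    if (length(absent) > 0) {
      stopf("contrast '%s' references absent level(s): %s", ct,
            paste(absent, collapse = ", "))
    }
    for (an in names(fits)) {
      f <- fits[[an]]
      res <- c(estimate = NA_real_, se = NA_real_, statistic = NA_real_,
               p = NA_real_)
      if (!is.null(f) && isTRUE(f$converged) &&
          all(used %in% names(f$coefficients))) {
        b <- f$coefficients
        cc <- stats::setNames(numeric(length(b)), names(b))
        cc[names(cv)[names(cv) %in% names(b)]] <-
          cv[names(cv) %in% names(b)]
        est <- sum(cc * b)
        se <- sqrt(as.numeric(t(cc) %*% f$vcov %*% cc))
        if (se == 0) {
          z <- if (est == 0) 0 else sign(est) * Inf
        } else {
          z <- est / se
        }
        p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0
        if (se == 0 && est == 0) p <- 1
        if (df_method == "satterthwaite" && !is.null(f$model) &&
            inherits(f$model, "lmerMod") && se > 0) {
          mod <- lmerTest::as_lmerModLmerTest(f$model)
          L <- stats::setNames(numeric(length(lme4::fixef(f$model))),
                               names(lme4::fixef(f$model)))
          L[paste0("group", names(cc))] <- cc
          sw <- lmerTest::contest1D(mod, L)
          z <- sw[["t value"]]
          p <- sw[["Pr(>|t|)"]]
        }
        res <- c(estimate = est, se = se, statistic = z, p = p)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, contrast = ct, estimate = res[["estimate"]],
        se = res[["se"]], statistic = res[["statistic"]], p = res[["p"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  for (ct in unique(out$contrast)) {
    i <- out$contrast == ct
    out$padj[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  rownames(out) <- NULL
  class(out) <- c("diff_result", "data.frame")
  out[, cols]
}

#' Differential analysis of abundances and isotopologue fractions
#'
#' Runs both differential paths on a normalized table: metabolite
#' abundances through the log-scale linear mixed model and isotopologue
#' fractions (MIDs) through the beta mixed regression, followed by Wald
#' contrast tests with Benjamini-Hochberg adjustment per contrast within
#' each analysis level (metabolite-level and isotopologue-level families
#' are adjusted separately).
#'
#' @param normalized `iso_table` at stage `normalized`.
#' @param meta sample metadata.
#' @param contrasts named list of contrast vectors; defaults to the
#'   consecutive differences of the group levels in metadata order of
#'   appearance.
#' @param testable optional named logical over isotopologue row keys (from
#'   [flag_testable()]); a metabolite enters the abundance analysis when
#'   at least one of its isotopologues is testable, an isotopologue enters
#'   the fraction analysis when itself testable. Default: everything.
#' @param config list of options: `nq` (quadrature nodes, default 9),
#'   `transform` (abundance transform, `"log"`/`"linear"`), `levels`
#'   (which analyses to run: `"abundance"`, `"isotopologue"` or both,
#'   the default).
#' @return a `diff_analysis` list: `abundance` and `isotopologue`
#'   `diff_result` tables plus a `diagnostics` data frame (analyte, level,
#'   converged, variance components).
#' @export
run_differential_analysis <- function(normalized, meta, contrasts = NULL,
                                      testable = NULL, config = list()) {
  meta <- assert_meta(meta)
  if (is.null(contrasts)) {
    grp_levels <- unique(as.character(
      meta$group[!meta$is_blank & !is.na(meta$group)]))
    contrasts <- consecutive_contrasts(grp_levels)
  }
  nq <- config$nq %||% 9
  transform <- config$transform %||% "log"
  levels_run <- config$levels %||% c("abundance", "isotopologue")
  df_method <- config$df_method %||% "z"

  abund <- metabolite_abundance(normalized)
  mid <- compute_mid(normalized)

  keys <- rownames(normalized$values)
  if (is.null(testable)) testable <- stats::setNames(rep(TRUE, length(keys)), keys)
  met_testable <- tapply(testable[keys], normalized$metabolite, any)

  safe_fit <- function(expr) tryCatch(expr, error = function(e) NULL)

  ab_fits <- list()
  if ("abundance" %in% levels_run) {
    for (met in rownames(abund)) {
      if (!isTRUE(met_testable[[met]])) next
      ab_fits[[met]] <- safe_fit(
        fit_abundance_lmm(abund[met, ], meta, transform = transform,
                          keep_model = df_method == "satterthwaite"))
    }
  }
  iso_fits <- list()
  if ("isotopologue" %in% levels_run) {
    for (i in seq_along(keys)) {
      key <- keys[i]
      if (!isTRUE(testable[[key]])) next
      yv <- mid$values[key, ]
      if (sum(is.finite(yv)) < 4) next
      iso_fits[[key]] <- safe_fit(fit_mid_betareg(yv, meta, nq = nq))
    }
  }

  diag_row <- function(an, level, f) {
    data.frame(analyte = an, level = level,
               converged = !is.null(f) && isTRUE(f$converged),
               sigma_d = if (is.null(f)) NA_real_ else f$sigma_d,
               dispersion = if (is.null(f)) NA_real_ else
                 (f$sigma_e %||% f$phi),
               stringsAsFactors = FALSE)
  }
  diagnostics <- rbind(
    do.call(rbind, c(lapply(names(ab_fits), function(a)
      diag_row(a, "metabolite", ab_fits[[a]])), list(NULL))),
    do.call(rbind, c(lapply(names(iso_fits), function(a)
      diag_row(a, "isotopologue", iso_fits[[a]])), list(NULL)))
  )

  structure(list(
    abundance = test_contrasts(ab_fits, contrasts, df_method = df_method),
    isotopologue = test_contrasts(iso_fits, contrasts),
    diagnostics = diagnostics,
    contrasts = contrasts
  ), class = "diff_analysis")
}

#' @export
print.diff_analysis <- function(x, ...) {
  cat("diff_analysis\n")
  cat(sprintf("  abundance tests:    %d rows (%d analytes)\n",
              nrow(x$abundance), length(unique(x$abundance$analyte))))
  cat(sprintf("  isotopologue tests: %d rows (%d analytes)\n",
              nrow(x$isotopologue), length(unique(x$isotopologue$analyte))))
  cat("  contrasts:", paste(names(x$contrasts), collapse = ", "), "\n")
  invisible(x)
}
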