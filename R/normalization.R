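#' Normalize between isotopologues by mean metabolite abundance
#'
#' For each metabolite, the per-sample isotopologue sum is averaged over
#' samples (missing samples excluded) and every isotopologue value of that
#' metabolite is divided by this mean abundance. Afterwards each retained
#' metabolite has an across-sample mean abundance of exactly 1, putting
#' metabolites with very different ionization efficiencies on a common
#' scale. Metabolites whose mean abundance is zero (or entirely missing)
#' are left untouched and reported in the `"skipped_metabolites"`
#' attribute. The operation is idempotent.
#'
#' @param corrected `iso_table` at stage `corrected`.
#' @return the rescaled `iso_table`, still at stage `corrected`.
#' @export
normalize_between_isotopologues <- function(corrected) {
  if (!corrected$stage %in% c("corrected", "normalized")) {
    stopf("expected a corrected table, got stage '%s'", corrected$stage)
  }
  y <- corrected$values
  skipped <- character(0)
  for (met in unique(corrected$metabolite)) {
    idx <- metabolite_rows(corrected, met)
    sums <- colSums(y[idx, , drop = FALSE])  # NA where the vector is missing
    A <- mean(sums, na.rm = TRUE)
    if (!is.finite(A) || A == 0) {
      skipped <- c(skipped, met)
      next
    }
    y[idx, ] <- y[idx, , drop = FALSE] / A
  }
  res <- set_values(corrected, y)
  attr(res, "skipped_metabolites") <- skipped
  res
}

#' Between-sample size factors from inverse-relative-variance weighted sums
#'
#' Each sample's factor is a weighted total of its isotopologue signal:
#' analyte weights are the inverse squared coefficients of variation
#' (`w_k = mean_k^2 / var_k`) across samples, clamped at the 99th
#' percentile of the finite weights so that near-constant analytes cannot
#' dominate. Analytes with missing values or zero mean are excluded from
#' the weighting set. Factors are anchored to geometric mean 1.
#'
#' @param tab `iso_table` (typically corrected and between-isotopologue
#'   normalized).
#' @return a `size_factors` object: list with `s` (named per-sample
#'   factors, geometric mean 1) and `weights` (per-analyte data frame with
#'   relative variance `rv` and weight `w`).
#' @export
compute_size_factors <- function(tab) {
  x <- tab$values
  if (ncol(x) < 2) stopf("size factors need >= 2 samples")
  complete <- rowSums(is.na(x)) == 0
  xs <- x[complete, , drop = FALSE]
  mu <- rowMeans(xs)
  v <- apply(xs, 1, stats::var)
  usable <- mu > 0
  xs <- xs[usable, , drop = FALSE]
  rv <- v[usable] / mu[usable]^2       # squared CV
  w <- 1 / rv                          # Inf where variance is 0
  fin <- is.finite(w)
  if (any(fin)) {
    cap <- stats::quantile(w[fin], 0.99, names = FALSE)
    w <- pmin(w, cap)
  } else {
    # all retained analytes are exactly constant across samples: weights
    # carry no information, fall back to equal weighting
    w <- rep(1, length(w))
  }
  if (length(w) == 0) stopf("no usable analytes for size factors")
  s_tilde <- as.vector(crossprod(w, xs)) / sum(w)
  if (any(s_tilde <= 0)) stopf("non-positive weighted signal for some sample")
  s <- s_tilde / geomean(s_tilde)
  names(s) <- colnames(x)
  structure(list(
    s = s,
    weights = data.frame(analyte = rownames(xs), rv = rv, w = w,
                         stringsAsFactors = FALSE, row.names = NULL)
  ), class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat("size_factors over", length(x$s), "samples (geometric mean 1)\n")
  print(round(x$s, 4))
  invisible(x)
}

#' Apply size factors: divide every sample column by its factor
#'
#' @param tab `iso_table` at stage `corrected`.
#' @param sf a [compute_size_factors()] result (or a named positive
#'   vector covering all samples).
#' @return the `iso_table` at stage `normalized`.
#' @export
apply_size_factors <- function(tab, sf) {
  s <- if (inherits(sf, "size_factors")) sf$s else sf
  miss <- setdiff(colnames(tab$values), names(s))
  if (length(miss) > 0) {
    stopf("no size factor for sample(s): %s", paste(miss, collapse = ", "))
  }
  y <- sweep(tab$values, 2, s[colnames(tab$values)], "/")
  set_values(tab, y, stage = "normalized")
}

#' Write a size-factor report TSV
#'
#' @param sf a `size_factors` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_size_factors <- function(sf, path) {
  df <- data.frame(sample = names(sf$s), size_factor = format_full(sf$s),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
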