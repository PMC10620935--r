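#' Metabolite abundances as isotopologue sums
#'
#' The abundance of a metabolite in a sample is the sum of its isotopologue
#' intensities. A metabolite-sample is missing only when its whole
#' isotopologue vector is missing (after natural-abundance correction,
#' vectors are complete or wholly missing by construction); otherwise the
#' sum runs over the non-missing entries.
#'
#' @param tab `iso_table` (normally at stage `normalized`).
#' @return numeric matrix, metabolites x samples.
#' @export
metabolite_abundance <- function(tab) {
  mets <- unique(tab$metabolite)
  out <- matrix(NA_real_, length(mets), ncol(tab$values),
                dimnames = list(mets, colnames(tab$values)))
  for (met in mets) {
    v <- tab$values[metabolite_rows(tab, met), , drop = FALSE]
    s <- colSums(v, na.rm = TRUE)
    s[colSums(!is.na(v)) == 0] <- NA_real_
    out[met, ] <- s
  }
  out
}

#' Mass isotopomer distributions (MIDs)
#'
#' Fractions of isotopologues relative to the metabolite's isotopologue
#' sum. The sum runs over the non-missing isotopologues (entries removed
#' by group cleaning stay missing in the output); the whole vector is
#' undefined when the sum is zero or everything is missing. The defined
#' entries of a vector lie on the simplex (in `[0, 1]`, summing to 1).
#'
#' @param tab `iso_table` (normally at stage `normalized`; fractions are
#'   invariant to per-sample scaling so size factors do not affect them).
#' @return a `mid_table`: same shape as the input table, values are
#'   fractions; fields `metabolite`, `shift`, `molecules` as in
#'   [iso_table()].
#' @export
compute_mid <- function(tab) {
  y <- tab$values
  for (met in unique(tab$metabolite)) {
    idx <- metabolite_rows(tab, met)
    v <- y[idx, , drop = FALSE]
    s <- colSums(v, na.rm = TRUE)
    bad <- s == 0 | colSums(!is.na(v)) == 0
    v[, bad] <- NA_real_
    ok <- !bad
    if (any(ok)) v[, ok] <- sweep(v[, ok, drop = FALSE], 2, s[ok], "/")
    y[idx, ] <- v
  }
  structure(list(values = y, metabolite = tab$metabolite, shift = tab$shift,
                 molecules = tab$molecules, sep = tab$sep),
            class = "mid_table")
}

#' @export
print.mid_table <- function(x, ...) {
  cat(sprintf("mid_table: %d isotopologue rows (%d metabolites) x %d samples\n",
              nrow(x$values), length(unique(x$metabolite)), ncol(x$values)))
  invisible(x)
}

#' Fractional labeling (mean fraction of labeled carbon atoms)
#'
#' `F = sum_k k * pi_k / n` for a metabolite with `n` carbons and MID
#' `pi`; 0 for an unlabeled metabolite, 1 for a fully labeled one. This is
#' the per-metabolite enrichment rendered as color intensity on tracer
#' flux maps. Isotopologues removed by group cleaning (below the limit of
#' quantification) contribute zero; the value is undefined for metabolites
#' with zero carbons or wholly missing vectors.
#'
#' @param mid a `mid_table` from [compute_mid()].
#' @return numeric matrix, metabolites x samples, values in `[0, 1]`.
#' @export
fractional_labeling <- function(mid) {
  mets <- unique(mid$metabolite)
  out <- matrix(NA_real_, length(mets), ncol(mid$values),
                dimnames = list(mets, colnames(mid$values)))
  for (met in mets) {
    idx <- which(mid$metabolite == met)
    idx <- idx[order(mid$shift[idx])]
    n <- mid$molecules$n_carbons[match(met, mid$molecules$metabolite_id)]
    if (n == 0) next
    k <- mid$shift[idx]
    v <- mid$values[idx, , drop = FALSE]
    f <- colSums(k * v, na.rm = TRUE) / n
    f[colSums(!is.na(v)) == 0] <- NA_real_
    out[met, ] <- f
  }
  out
}

#' Isotopologue fraction ratios (e.g. the anaplerosis marker m+3/m+2)
#'
#' Per metabolite and sample, the ratio `pi_knum / pi_kden` of two
#' isotopologue fractions; missing where the denominator fraction is zero
#' or either fraction is undefined. Group means (and the overall mean) are
#' arithmetic means over samples and the listed metabolites.
#'
#' @param mid a `mid_table`.
#' @param metabolites character vector of metabolites to include.
#' @param k_num,k_den numerator and denominator mass shifts.
#' @param meta optional sample metadata for per-group means.
#' @return list with `per_sample` (long data frame: metabolite, sample,
#'   ratio), `mean` (overall arithmetic mean), and `group_means` (named
#'   vector) when `meta` is given.
#' @export
isotopologue_ratio <- function(mid, metabolites, k_num, k_den, meta = NULL) {
  rows <- lapply(metabolites, function(met) {
    inum <- which(mid$metabolite == met & mid$shift == k_num)
    iden <- which(mid$metabolite == met & mid$shift == k_den)
    if (length(inum) != 1 || length(iden) != 1) {
      stopf("metabolite '%s' lacks shift m+%d or m+%d", met, k_num, k_den)
    }
    num <- mid$values[inum, ]
    den <- mid$values[iden, ]
    r <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
    data.frame(metabolite = met, sample = colnames(mid$values), ratio = r,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  per_sample <- do.call(rbind, rows)
  out <- list(per_sample = per_sample,
              mean = mean(per_sample$ratio, na.rm = TRUE))
  if (!is.null(meta)) {
    meta <- assert_meta(meta)
    grp <- as.character(meta$group[match(per_sample$sample, meta$sample_id)])
    out$group_means <- tapply(per_sample$ratio, grp,
                              function(v) mean(v, na.rm = TRUE))
  }
  out
}

#' Abundance ratio of two metabolites per sample
#'
#' Computed on normalized abundances; numerator and denominator share each
#' sample's size factor, so the result equals the raw-scale ratio. Missing
#' where the denominator is zero or either abundance is missing.
#'
#' @param abund abundance matrix from [metabolite_abundance()].
#' @param num,den metabolite ids.
#' @param log2 return log2 of the ratio instead.
#' @return named numeric vector over samples.
#' @export
metabolite_ratio <- function(abund, num, den, log2 = FALSE) {
  if (!num %in% rownames(abund)) stopf("metabolite '%s' not present", num)
  if (!den %in% rownames(abund)) stopf("metabolite '%s' not present", den)
  r <- ifelse(!is.na(abund[den, ]) & abund[den, ] > 0,
              abund[num, ] / abund[den, ], NA_real_)
  if (log2) r <- base::log2(r)
  r
}
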