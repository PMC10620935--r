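#' Blank-based quantification thresholds
#'
#' For each (metabolite, shift) row and each batch, the blank samples of
#' that batch define a limit of quantification: `T = mean + 2 * sd` of the
#' blank intensities (sample standard deviation, n-1 denominator — blank
#' counts are small, typically three per batch). Rows whose blank values
#' are entirely missing get `mean = sd = T = 0`, i.e. are treated as fully
#' quantifiable, with a warning.
#'
#' @param raw `iso_table` at stage `raw` containing the blank sample
#'   columns (use [bind_samples()] if blanks were read separately).
#' @param meta sample metadata; `is_blank` marks blanks, `batch` assigns
#'   every sample (blank or not) to a batch.
#' @return a `threshold_set`: a data frame with columns `rowkey`,
#'   `metabolite`, `shift`, `batch`, `blank_mean`, `blank_sd`, `threshold`,
#'   plus lookup matrices in attributes.
#' @export
compute_blank_thresholds <- function(raw, meta) {
  meta <- assert_meta(meta)
  blanks <- meta[meta$is_blank, , drop = FALSE]
  if (nrow(blanks) == 0) stopf("no blank samples in metadata")
  batches <- sort(unique(as.character(meta$batch)))
  present <- intersect(blanks$sample_id, colnames(raw$values))
  keys <- rownames(raw$values)
  mu <- sdm <- thr <- matrix(NA_real_, length(keys), length(batches),
                             dimnames = list(keys, batches))
  warned <- FALSE
  for (b in batches) {
    ids <- intersect(blanks$sample_id[as.character(blanks$batch) == b], present)
    if (length(ids) < 2) {
      stopf("batch '%s' has %d blank sample(s); >= 2 required for a blank SD",
            b, length(ids))
    }
    v <- raw$values[, ids, drop = FALSE]
    n_ok <- rowSums(!is.na(v))
    mu[, b] <- rowMeans(v, na.rm = TRUE)
    sdm[, b] <- apply(v, 1, stats::sd, na.rm = TRUE)
    absent <- n_ok < 2
    if (any(absent)) {
      mu[absent, b] <- 0
      sdm[absent, b] <- 0
      warned <- TRUE
    }
    thr[, b] <- mu[, b] + 2 * sdm[, b]
  }
  if (warned) {
    warning("rows without usable blank measurements were assigned threshold 0 ",
            "(fully quantifiable)")
  }
  out <- data.frame(
    rowkey = rep(keys, times = length(batches)),
    metabolite = rep(raw$metabolite, times = length(batches)),
    shift = rep(raw$shift, times = length(batches)),
    batch = rep(batches, each = length(keys)),
    blank_mean = as.vector(mu),
    blank_sd = as.vector(sdm),
    threshold = as.vector(thr),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("threshold_set", "data.frame"),
            mu = mu, threshold = thr)
}

# internal: per-sample threshold/mean matrices aligned to a table's rows
threshold_lookup <- function(tab, thr, meta, samples) {
  mu <- attr(thr, "mu"); tm <- attr(thr, "threshold")
  miss <- setdiff(rownames(tab$values), rownames(mu))
  if (length(miss) > 0) {
    stopf("thresholds missing for rows: %s", paste(utils::head(miss, 5), collapse = ", "))
  }
  batch <- as.character(meta$batch[match(samples, meta$sample_id)])
  if (anyNA(batch)) stopf("samples without metadata: %s",
                          paste(samples[is.na(batch)], collapse = ", "))
  bad <- setdiff(batch, colnames(mu))
  if (length(bad) > 0) stopf("no thresholds for batch: %s", paste(bad, collapse = ", "))
  list(mu = mu[rownames(tab$values), batch, drop = FALSE],
       thr = tm[rownames(tab$values), batch, drop = FALSE])
}

#' Apply blank thresholding with sub-threshold linear correction
#'
#' Intensities below the blank mean are set to zero; intensities between
#' the blank mean and the quantification threshold `T` are mapped linearly
#' from `[mean, T]` onto `[0, T]` (`T * (x - mean) / (T - mean)`), so the
#' map is continuous at `T` and monotone; intensities at or above `T` pass
#' through unchanged. When `T == mean` (zero blank variance) the map
#' degenerates to: zero below `T`, identity at or above.
#'
#' Applying the operation to a table already at stage `thresholded` is a
#' no-op, making the stage-level operation idempotent.
#'
#' @param raw `iso_table` at stage `raw`.
#' @param thr a `threshold_set` from [compute_blank_thresholds()].
#' @param meta sample metadata (supplies each sample's batch).
#' @return the corrected `iso_table` at stage `thresholded`.
#' @export
apply_threshold_correction <- function(raw, thr, meta) {
  if (raw$stage == "thresholded") return(raw)
  if (raw$stage != "raw") stopf("cannot threshold a table at stage '%s'", raw$stage)
  meta <- assert_meta(meta)
  lk <- threshold_lookup(raw, thr, meta, colnames(raw$values))
  x <- raw$values
  mu <- lk$mu; tm <- lk$thr
  y <- x
  below <- !is.na(x) & x < mu
  y[below] <- 0
  mid <- !is.na(x) & x >= mu & x < tm  # implies tm > mu
  y[mid] <- tm[mid] * (x[mid] - mu[mid]) / (tm[mid] - mu[mid])
  set_values(raw, y, stage = "thresholded")
}

#' Flag analytes testable for differential statistics
#'
#' An isotopologue row is testable when at least two non-blank biological
#' samples lie strictly above their batch's quantification threshold.
#'
#' @param thresholded `iso_table` at stage `thresholded`.
#' @param thr a `threshold_set`.
#' @param meta sample metadata.
#' @return named logical vector over isotopologue row keys.
#' @export
flag_testable <- function(thresholded, thr, meta) {
  if (thresholded$stage != "thresholded") stopf("expected a thresholded table")
  meta <- assert_meta(meta)
  ids <- intersect(colnames(thresholded$values),
                   meta$sample_id[!meta$is_blank])
  tab <- subset_samples(thresholded, ids)
  lk <- threshold_lookup(tab, thr, meta, ids)
  above <- !is.na(tab$values) & tab$values > lk$thr
  n_above <- rowSums(above)
  stats::setNames(n_above >= 2, rownames(tab$values))
}

#' Remove sample groups dominated by sub-threshold values
#'
#' For each isotopologue row and each sample group, if strictly more than
#' one third of the group's values lie below the quantification threshold
#' (missing values count as below), all of that group's values for the row
#' are set to missing. Other groups are untouched; blanks are ignored.
#' The comparison uses exact integer arithmetic, so a group of 3 with
#' exactly 1 value below (= 1/3) is kept.
#'
#' The sub-threshold comparison is made on the thresholded-stage table
#' (where intensities and thresholds share a scale); via `apply_to` the
#' resulting mask can be applied to a downstream table with the same rows
#' and samples (e.g. the normalized table, mirroring a workflow where
#' abundances are corrected and normalized first and cleaned last).
#'
#' @param thresholded `iso_table` at stage `thresholded`.
#' @param thr a `threshold_set`.
#' @param meta sample metadata.
#' @param apply_to optional `iso_table` whose values receive the missing
#'   mask; defaults to `thresholded` itself.
#' @return the cleaned `iso_table` (same stage as `apply_to`).
#' @export
clean_groups <- function(thresholded, thr, meta, apply_to = thresholded) {
  if (thresholded$stage != "thresholded") stopf("expected a thresholded table")
  if (!identical(rownames(apply_to$values), rownames(thresholded$values)) ||
      !all(colnames(thresholded$values) %in% colnames(apply_to$values))) {
    stopf("apply_to must cover the rows and samples of the thresholded table")
  }
  meta <- assert_meta(meta)
  smeta <- meta[!meta$is_blank & meta$sample_id %in% colnames(thresholded$values), ]
  y <- apply_to$values
  for (g in unique(as.character(smeta$group))) {
    if (is.na(g)) next
    ids <- smeta$sample_id[!is.na(smeta$group) & as.character(smeta$group) == g]
    lk <- threshold_lookup(thresholded, thr, meta, ids)
    v <- thresholded$values[, ids, drop = FALSE]
    below <- is.na(v) | v < lk$thr
    n_below <- rowSums(below)
    drop <- 3L * n_below > length(ids)  # strictly more than 1/3
    y[drop, ids] <- NA_real_
  }
  set_values(apply_to, y)
}
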