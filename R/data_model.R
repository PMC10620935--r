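#' Construct an isotopologue table
#'
#' The central container of the pipeline: a non-negative intensity matrix
#' whose rows are (metabolite, mass shift) pairs and whose columns are
#' samples. A `stage` tag records how far along the processing chain the
#' values are; operations check it so that stages can only move forward in
#' the order `raw -> thresholded -> corrected -> normalized`.
#'
#' @param values numeric matrix; rownames must be row keys of the form
#'   `<metabolite><sep><shift>` (e.g. `"lac_m0"`), colnames sample ids.
#' @param molecules data frame with columns `metabolite_id`, `n_carbons`
#'   and optionally `formula`.
#' @param stage processing stage tag.
#' @param sep separator between metabolite name and shift in row keys.
#' @return an object of class `iso_table` with fields `values`,
#'   `metabolite`, `shift`, `molecules`, `stage`, `sep`.
#' @export
iso_table <- function(values, molecules,
                      stage = c("raw", "thresholded", "corrected", "normalized"),
                      sep = "_m") {
  stage <- match.arg(stage)
  molecules <- assert_molecules(molecules)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("values must have row keys and sample ids as dimnames")
  }
  if (anyDuplicated(rownames(values))) stopf("duplicate row keys")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids")
  parsed <- parse_rowkey(rownames(values), sep = sep)
  unknown <- setdiff(parsed$metabolite, molecules$metabolite_id)
  if (length(unknown) > 0) {
    stopf("metabolites absent from molecule table: %s",
          paste(unique(unknown), collapse = ", "))
  }
  nc <- molecules$n_carbons[match(parsed$metabolite, molecules$metabolite_id)]
  bad <- parsed$shift > nc
  if (any(bad)) {
    stopf("shift exceeds n_carbons for rows: %s",
          paste(rownames(values)[bad], collapse = ", "))
  }
  if (any(values < 0, na.rm = TRUE)) stopf("negative intensities")
  structure(
    list(values = values, metabolite = parsed$metabolite,
         shift = parsed$shift, molecules = molecules,
         stage = stage, sep = sep),
    class = "iso_table"
  )
}

#' @export
print.iso_table <- function(x, ...) {
  cat(sprintf("iso_table [%s]: %d isotopologue rows (%d metabolites) x %d samples\n",
              x$stage, nrow(x$values), length(unique(x$metabolite)),
              ncol(x$values)))
  if (anyNA(x$values)) {
    cat(sprintf("  missing cells: %d\n", sum(is.na(x$values))))
  }
  invisible(x)
}

#' @export
dim.iso_table <- function(x) dim(x$values)

# internal: replace the value matrix, optionally advancing the stage
set_values <- function(tab, values, stage = tab$stage) {
  tab$values <- values
  tab$stage <- stage
  tab
}

# internal: rows of one metabolite, in shift order
metabolite_rows <- function(tab, met) {
  idx <- which(tab$metabolite == met)
  idx[order(tab$shift[idx])]
}

#' Column-bind two isotopologue tables
#'
#' Joins the sample columns of two tables sharing the same stage (typically
#' measurement samples and blank samples). Row keys are taken from the
#' union; rows absent from one table become missing there.
#'
#' @param a,b `iso_table` objects at the same stage.
#' @return an `iso_table` with the combined sample columns.
#' @export
bind_samples <- function(a, b) {
  if (!identical(a$stage, b$stage)) stopf("stage mismatch in bind_samples")
  if (length(intersect(colnames(a$values), colnames(b$values))) > 0) {
    stopf("overlapping sample ids")
  }
  keys <- union(rownames(a$values), rownames(b$values))
  va <- matrix(NA_real_, length(keys), ncol(a$values),
               dimnames = list(keys, colnames(a$values)))
  vb <- matrix(NA_real_, length(keys), ncol(b$values),
               dimnames = list(keys, colnames(b$values)))
  va[rownames(a$values), ] <- a$values
  vb[rownames(b$values), ] <- b$values
  mols <- unique(rbind(a$molecules, b$molecules))
  iso_table(cbind(va, vb), mols, stage = a$stage, sep = a$sep)
}

# internal: subset sample columns
subset_samples <- function(tab, ids) {
  miss <- setdiff(ids, colnames(tab$values))
  if (length(miss) > 0) stopf("samples not in table: %s", paste(miss, collapse = ", "))
  tab$values <- tab$values[, ids, drop = FALSE]
  tab
}

#' Read an isotopologue intensity table
#'
#' Reads a TSV/CSV exported by peak-integration software: one row-key column
#' (named in the first header field) encoding metabolite and mass shift as
#' `"<met>_m<k>"`, and one column per sample. Rows are validated against the
#' molecule table; unknown metabolites and shifts beyond a metabolite's
#' carbon count are rejected. Empty cells become missing values; zeros are
#' kept as zeros (measured, below blank).
#'
#' @param path file path (`.tsv` or `.csv`).
#' @param molecules molecule table (see [read_molecules()]).
#' @param stage stage tag to assign, default `"raw"`.
#' @param sep_key separator in the row-key dialect, default `"_m"`.
#' @return an [iso_table()].
#' @export
read_isotopologue_table <- function(path, molecules, stage = "raw", sep_key = "_m") {
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  keys <- as.character(df[[1]])
  if (anyDuplicated(keys)) stopf("duplicate row keys in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- keys
  iso_table(m, molecules, stage = stage, sep = sep_key)
}

#' Write an isotopologue table to TSV
#'
#' Values are written at full double precision so that a write/read
#' round-trip is bit-exact. Missing values are written as empty cells.
#'
#' @param tab an [iso_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_isotopologue_table <- function(tab, path) {
  m <- tab$values
  txt <- matrix(format_full(m), nrow(m), ncol(m))
  out <- cbind(rowkey = rownames(m), txt)
  colnames(out) <- c("rowkey", colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expected columns: `sample_id`, `group`, `donor`, `batch`, `is_blank`
#' (logical or 0/1). Blank samples need a batch but no group or donor.
#'
#' @param path TSV/CSV path.
#' @return a data frame with validated columns.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  assert_meta(df)
}

#' Read a molecule (carbon-count) table
#'
#' Expected columns: `metabolite_id`, `n_carbons`, optional `formula`.
#'
#' @param path TSV/CSV path.
#' @return a validated data frame.
#' @export
read_molecules <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  assert_molecules(df)
}

#' Write differential-test results, one TSV per contrast
#'
#' Columns are fixed (`analyte`, `estimate`, `se`, `statistic`, `p`, `padj`)
#' and rows are sorted by analyte so output is deterministic.
#'
#' @param results a `diff_result` data frame (see [test_contrasts()]).
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, default `"results"`.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(results, dir, prefix = "results") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("analyte", "estimate", "se", "statistic", "p", "padj")
  contrasts <- sort(unique(as.character(results$contrast)))
  if (nrow(results) == 0) contrasts <- character(0)
  files <- character(0)
  for (ct in contrasts) {
    sub <- results[results$contrast == ct, cols, drop = FALSE]
    sub <- sub[order(sub$analyte), , drop = FALSE]
    safe <- gsub("[^A-Za-z0-9_.-]+", "_", ct)
    f <- file.path(dir, sprintf("%s_%s.tsv", prefix, safe))
    utils::write.table(sub, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (length(files) == 0) {
    f <- file.path(dir, sprintf("%s_empty.tsv", prefix))
    utils::write.table(results[0, cols, drop = FALSE], f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- f
  }
  invisible(files)
}
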