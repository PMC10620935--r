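# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

geomean <- function(x) exp(mean(log(x)))

# Row keys encode (metabolite, shift) as "<met><sep><k>", e.g. "lac_m3".
make_rowkey <- function(metabolite, shift, sep = "_m") {
  paste0(metabolite, sep, shift)
}

parse_rowkey <- function(keys, sep = "_m") {
  rx <- paste0("^(.*)", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", sep),
               "([0-9]+)$")
  ok <- grepl(rx, keys)
  if (!all(ok)) {
    stop("malformed row keys: ", paste(utils::head(keys[!ok], 5), collapse = ", "))
  }
  data.frame(
    metabolite = sub(rx, "\\1", keys),
    shift = as.integer(sub(rx, "\\2", keys)),
    stringsAsFactors = FALSE
  )
}

# Full-precision TSV writing so that write -> read round-trips bit-exactly.
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_meta <- function(meta) {
  need <- c("sample_id", "group", "donor", "batch", "is_blank")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stopf("sample metadata lacks columns: %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stopf("duplicate sample_id in metadata")
  meta$is_blank <- as.logical(meta$is_blank)
  meta
}

assert_molecules <- function(molecules) {
  need <- c("metabolite_id", "n_carbons")
  miss <- setdiff(need, names(molecules))
  if (length(miss) > 0) {
    stopf("molecule table lacks columns: %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(molecules$metabolite_id)) {
    stopf("duplicate metabolite_id in molecule table")
  }
  if (any(molecules$n_carbons < 0) || any(molecules$n_carbons != round(molecules$n_carbons))) {
    stopf("n_carbons must be non-negative integers")
  }
  molecules$n_carbons <- as.integer(molecules$n_carbons)
  if (is.null(molecules$formula)) molecules$formula <- NA_character_
  molecules[, c("metabolite_id", "n_carbons", "formula")]
}

# Infer field separator from file extension (.csv -> comma, else tab).
infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}
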