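#' Validate pipeline inputs before computation
#'
#' Checks agreement between the intensity table and the sample metadata,
#' blank availability per batch (thresholds are impossible without at
#' least two blanks), and shift completeness per metabolite. Findings are
#' classified as `fatal`, `warning` or `info`.
#'
#' @param raw `iso_table` with the measurement samples.
#' @param meta sample metadata.
#' @param blanks optional separate `iso_table` of blank samples.
#' @return a `validation_report` data frame (`level`, `message`) with a
#'   logical attribute `"fatal"`.
#' @export
validate_inputs <- function(raw, meta, blanks = NULL) {
  meta <- assert_meta(meta)
  findings <- list()
  note <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  all_cols <- c(colnames(raw$values),
                if (!is.null(blanks)) colnames(blanks$values))
  missing_meta <- setdiff(all_cols, meta$sample_id)
  if (length(missing_meta) > 0) {
    note("fatal", sprintf("samples without metadata: %s",
                          paste(missing_meta, collapse = ", ")))
  }
  unused <- setdiff(meta$sample_id, all_cols)
  if (length(unused) > 0) {
    note("warning", sprintf("metadata rows without sample columns: %s",
                            paste(unused, collapse = ", ")))
  }
  blank_ids <- intersect(meta$sample_id[meta$is_blank], all_cols)
  for (b in sort(unique(as.character(meta$batch)))) {
    nb <- sum(meta$batch[match(blank_ids, meta$sample_id)] == b)
    if (nb < 2) {
      note("fatal", sprintf("batch '%s' has %d blank(s); thresholds need >= 2", b, nb))
    }
  }
  for (met in unique(raw$metabolite)) {
    n <- raw$molecules$n_carbons[match(met, raw$molecules$metabolite_id)]
    have <- sort(raw$shift[raw$metabolite == met])
    gap <- setdiff(0:n, have)
    if (length(gap) > 0) {
      note("warning", sprintf(
        "metabolite '%s' lacks shift(s) %s; implicit zero rows will be added",
        met, paste(paste0("m", gap), collapse = ", ")))
    }
  }
  if (length(findings) == 0) note("info", "all checks passed")
  rep <- do.call(rbind, findings)
  structure(rep, class = c("validation_report", "data.frame"),
            fatal = any(rep$level == "fatal"))
}

#' @export
print.validation_report <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("[%s] %s\n", toupper(x$level[i]), x$message[i]))
  }
  invisible(x)
}

#' Complete missing shift rows with implicit zeros
#'
#' Every metabolite must carry a full shift vector `0..n_carbons` for the
#' natural-abundance deconvolution; absent rows (not exported by the peak
#' integrator because never detected) are inserted as zeros.
#'
#' @param tab `iso_table`.
#' @return the completed `iso_table`; added row keys in attribute
#'   `"added_rows"`.
#' @export
complete_shifts <- function(tab) {
  add <- character(0)
  for (met in unique(tab$metabolite)) {
    n <- tab$molecules$n_carbons[match(met, tab$molecules$metabolite_id)]
    gap <- setdiff(0:n, tab$shift[tab$metabolite == met])
    if (length(gap) > 0) add <- c(add, make_rowkey(met, gap, tab$sep))
  }
  if (length(add) > 0) {
    zeros <- matrix(0, length(add), ncol(tab$values),
                    dimnames = list(add, colnames(tab$values)))
    tab <- iso_table(rbind(tab$values, zeros), tab$molecules,
                     stage = tab$stage, sep = tab$sep)
  }
  attr(tab, "added_rows") <- add
  tab
}

# --- configuration ---------------------------------------------------------

pipeline_defaults <- function() {
  list(
    seed = 1,
    outdir = NULL,
    simulate = NULL,  # list(preset=..., n_metabolites=...) or NULL
    inputs = NULL,    # list(table=, meta=, molecules=, blanks=)
    correction = list(p_nat = 0.0107, tracer_purity = 1, solver = "nnls"),
    diffstats = list(enabled = TRUE, contrasts = NULL, nq = 9,
                     transform = "log", df_method = "z", alpha = 0.05)
  )
}

# merge a user config into defaults, rejecting unknown keys
resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  def <- pipeline_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (blk in c("correction", "diffstats")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(bad) > 0) {
        stopf("unknown key(s) in config$%s: %s", blk, paste(bad, collapse = ", "))
      }
      def[[blk]][names(config[[blk]])] <- config[[blk]]
    }
  }
  for (k in setdiff(names(config), c("correction", "diffstats"))) {
    def[[k]] <- config[[k]]
  }
  if (is.null(def$outdir)) stopf("config$outdir is required")
  if (is.null(def$simulate) && is.null(def$inputs)) {
    stopf("config needs either 'simulate' or 'inputs'")
  }
  def
}

write_matrix_tsv <- function(m, path, key = "id") {
  txt <- matrix(format_full(m), nrow(m), ncol(m))
  out <- cbind(rownames(m), txt)
  colnames(out) <- c(key, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — blank thresholding, sub-threshold
#' correction, group cleaning, natural-abundance correction,
#' between-isotopologue normalization, size factors, summaries
#' (abundances, MIDs, fractional labeling) and, if enabled, differential
#' statistics — writing every intermediate table, a human-readable log
#' and a machine-readable manifest (config hash, seed, per-file MD5
#' checksums) into the output directory. Runs are bit-reproducible for a
#' fixed config and seed. Any stage error aborts with the failing stage
#' named; outputs written so far are retained.
#'
#' @param config an R list or YAML file path; see `vignette("midpipe")`.
#'   Required keys: `outdir` plus either `simulate` (a list with `preset`
#'   and optional preset arguments, data generated from `seed`) or
#'   `inputs` (paths `table`, `meta`, `molecules`, optional `blanks`).
#' @return invisibly, a list with the main in-memory artifacts (tables,
#'   size factors, differential results, truth when simulated, manifest
#'   path).
#' @export
run_pipeline <- function(config) {
  cfg <- resolve_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logmsg <- function(...) log_lines <<- c(log_lines, sprintf(...))
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", label, conditionMessage(e))
    })
  }

  cfg_path <- file.path(outdir, "resolved_config.yaml")
  cfg_out <- cfg
  cfg_out$outdir <- NULL  # a location, not part of the scientific run
  yaml::write_yaml(cfg_out, cfg_path)
  emit(cfg_path)

  # -- inputs ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (!is.null(sim_args$preset)) {
      names(sim_args)[names(sim_args) == "preset"] <- "name"
    }
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim <- stage("simulate", do.call(scenario_presets, sim_args))
    dat <- stage("simulate", simulate_experiment(sim))
    raw <- dat$raw; blanks <- dat$blanks; meta <- dat$meta
    molecules <- raw$molecules
    truth <- dat$truth
    truth_path <- file.path(outdir, "truth.json")
    jsonlite::write_json(
      list(scenario = truth$scenario, seed = truth$seed,
           abundance_effects = truth$abundance_effects,
           mid_effects = truth$mid_effects),
      truth_path, auto_unbox = TRUE, digits = NA)
    emit(truth_path)
    logmsg("simulated preset '%s' (seed %d): %d samples + %d blanks",
           truth$scenario, truth$seed, ncol(raw$values), ncol(blanks$values))
  } else {
    inp <- cfg$inputs
    molecules <- stage("read", read_molecules(inp$molecules))
    meta <- stage("read", read_sample_meta(inp$meta))
    tab <- stage("read", read_isotopologue_table(inp$table, molecules))
    if (!is.null(inp$blanks)) {
      blanks <- stage("read", read_isotopologue_table(inp$blanks, molecules))
      raw <- tab
    } else {
      bl_ids <- intersect(meta$sample_id[meta$is_blank], colnames(tab$values))
      blanks <- subset_samples(tab, bl_ids)
      raw <- subset_samples(tab, setdiff(colnames(tab$values), bl_ids))
    }
    logmsg("read %d isotopologue rows, %d samples, %d blanks",
           nrow(raw$values), ncol(raw$values), ncol(blanks$values))
  }

  rep <- stage("validate", validate_inputs(raw, meta, blanks))
  for (i in seq_len(nrow(rep))) logmsg("validate [%s] %s", rep$level[i], rep$message[i])
  if (isTRUE(attr(rep, "fatal"))) {
    stopf("pipeline stage 'validate' failed:\n%s",
          paste(rep$message[rep$level == "fatal"], collapse = "\n"))
  }
  raw <- stage("validate", complete_shifts(raw))
  blanks <- stage("validate", complete_shifts(blanks))

  emit(write_matrix_tsv(raw$values, file.path(outdir, "01_raw.tsv"), "rowkey"))
  emit(write_matrix_tsv(blanks$values, file.path(outdir, "01_blanks.tsv"), "rowkey"))
  utils::write.table(meta, mp <- file.path(outdir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit(mp)
  utils::write.table(molecules, mo <- file.path(outdir, "molecules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit(mo)

  # -- thresholding ---------------------------------------------------------
  combined <- stage("threshold", bind_samples(raw, blanks))
  thr <- stage("threshold", compute_blank_thresholds(combined, meta))
  utils::write.table(as.data.frame(thr),
                     tp <- file.path(outdir, "thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit(tp)
  thresholded <- stage("threshold", apply_threshold_correction(raw, thr, meta))
  testable <- stage("threshold", flag_testable(thresholded, thr, meta))
  logmsg("thresholding: %d/%d analytes testable", sum(testable), length(testable))
  emit(write_isotopologue_table(thresholded, file.path(outdir, "02_thresholded.tsv")))

  # -- natural abundance correction -----------------------------------------
  ccfg <- correction_config(p_nat = cfg$correction$p_nat,
                            tracer_purity = cfg$correction$tracer_purity,
                            solver = cfg$correction$solver)
  corrected <- stage("correct", correct_natural_abundance(thresholded, ccfg))
  emit(write_isotopologue_table(corrected, file.path(outdir, "03_corrected.tsv")))
  logmsg("natural-abundance correction: p_nat=%g purity=%g solver=%s",
         ccfg$p_nat, ccfg$tracer_purity, ccfg$solver)

  # -- normalization --------------------------------------------------------
  nb <- stage("normalize", normalize_between_isotopologues(corrected))
  sk <- attr(nb, "skipped_metabolites")
  if (length(sk) > 0) logmsg("normalize: skipped zero-abundance metabolites: %s",
                             paste(sk, collapse = ", "))
  sf <- stage("normalize", compute_size_factors(nb))
  emit(write_size_factors(sf, file.path(outdir, "size_factors.tsv")))
  normalized <- stage("normalize", apply_size_factors(nb, sf))
  normalized <- stage("normalize",
                      clean_groups(thresholded, thr, meta, apply_to = normalized))
  logmsg("group cleaning: %d cells set missing", sum(is.na(normalized$values)))
  emit(write_isotopologue_table(normalized, file.path(outdir, "04_normalized.tsv")))

  # -- summaries ------------------------------------------------------------
  abund <- stage("summarize", metabolite_abundance(normalized))
  mid <- stage("summarize", compute_mid(normalized))
  frac <- stage("summarize", fractional_labeling(mid))
  emit(write_matrix_tsv(abund, file.path(outdir, "abundance.tsv"), "metabolite"))
  emit(write_matrix_tsv(mid$values, file.path(outdir, "mid.tsv"), "rowkey"))
  emit(write_matrix_tsv(frac, file.path(outdir, "fractional_labeling.tsv"),
                        "metabolite"))

  # -- differential statistics ----------------------------------------------
  diff <- NULL
  if (isTRUE(cfg$diffstats$enabled)) {
    contrasts <- cfg$diffstats$contrasts
    if (!is.null(contrasts)) {
      contrasts <- lapply(contrasts, function(v) unlist(v))
    }
    diff <- stage("diffstats", run_differential_analysis(
      normalized, meta, contrasts = contrasts, testable = testable,
      config = list(nq = cfg$diffstats$nq, transform = cfg$diffstats$transform,
                    df_method = cfg$diffstats$df_method)))
    emit(write_results(diff$abundance, outdir, prefix = "results_abundance"))
    emit(write_results(diff$isotopologue, outdir, prefix = "results_isotopologue"))
    utils::write.table(diff$diagnostics,
                       dp <- file.path(outdir, "model_diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(dp)
    logmsg("diffstats: %d abundance and %d isotopologue tests over %d contrasts",
           nrow(diff$abundance), nrow(diff$isotopologue),
           length(diff$contrasts))
  } else {
    logmsg("diffstats disabled")
  }

  log_path <- file.path(outdir, "log.txt")
  writeLines(log_lines, log_path)
  emit(log_path)

  # -- manifest (no timestamps: manifests are byte-reproducible) ------------
  files <- sort(unique(files))
  sums <- tools::md5sum(files)
  manifest <- list(
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = as.list(stats::setNames(unname(sums), basename(files)))
  )
  manifest$files <- manifest$files[order(names(manifest$files))]
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(
    outdir = outdir, config = cfg, thresholds = thr,
    thresholded = thresholded, corrected = corrected,
    normalized = normalized, size_factors = sf, testable = testable,
    abundance = abund, mid = mid, fractional_labeling = frac,
    diff = diff, truth = truth, manifest = manifest_path
  ))
}
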