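# Shared fixture builders and independent oracles for the test suite.

tiny_molecules <- function() {
  data.frame(metabolite_id = c("lac", "pyr"), n_carbons = c(3L, 3L),
             formula = c("C3H6O3", "C3H4O3"), stringsAsFactors = FALSE)
}

# generic metadata: n samples per group plus blanks, donors crossed
make_meta <- function(groups = c("A", "B"), donors = 3, replicates = 1,
                      n_blanks = 3, batch = "B1") {
  ids <- grp <- dnr <- character(0)
  for (g in groups) for (d in seq_len(donors)) for (r in seq_len(replicates)) {
    ids <- c(ids, sprintf("%s_D%d_R%d", g, d, r))
    grp <- c(grp, g); dnr <- c(dnr, paste0("D", d))
  }
  bl <- if (n_blanks > 0) paste0("BL", seq_len(n_blanks)) else character(0)
  data.frame(
    sample_id = c(ids, bl),
    group = c(grp, rep(NA_character_, n_blanks)),
    donor = c(dnr, rep(NA_character_, n_blanks)),
    batch = batch,
    is_blank = c(rep(FALSE, length(ids)), rep(TRUE, n_blanks)),
    stringsAsFactors = FALSE)
}

# iso_table from a matrix of full shift vectors, one metabolite
one_met_table <- function(values, met = "lac", n = nrow(values) - 1,
                          stage = "raw") {
  rownames(values) <- make_rowkey_pub(met, 0:n)
  mols <- data.frame(metabolite_id = met, n_carbons = n,
                     formula = NA_character_, stringsAsFactors = FALSE)
  iso_table(values, mols, stage = stage)
}

make_rowkey_pub <- function(met, k) paste0(met, "_m", k)

# Independent forward-convolution oracle: brute-force enumeration over all
# per-atom isotope configurations of the unlabeled carbons. Never uses
# dbinom or the package's matrix builder.
nat_matrix_enum <- function(n, p) {
  M <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    nf <- n - j
    if (nf == 0) { M[j + 1, j + 1] <- 1; next }
    for (cfg in 0:(2^nf - 1)) {
      k <- sum(bitwAnd(cfg, 2^(0:(nf - 1))) > 0)
      M[j + 1 + k, j + 1] <- M[j + 1 + k, j + 1] + p^k * (1 - p)^(nf - k)
    }
  }
  M
}

# ranking AUC of p-values against truth labels (1 = real effect)
rank_auc <- function(p, effect) {
  ok <- !is.na(p) & !is.na(effect)
  p <- p[ok]; effect <- as.logical(effect[ok])
  n1 <- sum(effect); n0 <- sum(!effect)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[!effect]) - n0 * (n0 + 1) / 2) / (n1 * n0)
}

# run the processing chain (threshold -> correct -> normalize -> clean) on a
# simulated dataset, returning the pieces tests commonly need
process_sim <- function(dat, cfg = correction_config()) {
  thr <- compute_blank_thresholds(bind_samples(dat$raw, dat$blanks), dat$meta)
  th <- apply_threshold_correction(dat$raw, thr, dat$meta)
  testable <- flag_testable(th, thr, dat$meta)
  cor <- correct_natural_abundance(th, cfg)
  nb <- normalize_between_isotopologues(cor)
  sf <- compute_size_factors(nb)
  norm <- apply_size_factors(nb, sf)
  norm <- clean_groups(th, thr, dat$meta, apply_to = norm)
  list(thr = thr, thresholded = th, testable = testable, corrected = cor,
       size_factors = sf, normalized = norm)
}
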