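#' Define a simulation scenario for tracer LC-MS data
#'
#' A scenario fixes the generative model the pipeline assumes, in forward
#' direction: per-group true MIDs and mean log-abundances, donor random
#' intercepts on the log-abundance scale, binomial natural-13C convolution
#' (the same kernel the corrector inverts), multiplicative log-normal
#' measurement noise, an additive blank baseline, optional per-sample
#' scale factors, and censoring at a detection floor.
#'
#' @param mids list: group -> list: metabolite -> simplex vector of true
#'   isotopologue fractions (length `n_carbons + 1`).
#' @param mu_log numeric matrix (groups x metabolites) of mean natural-log
#'   abundances.
#' @param donors number of donors, crossed with groups.
#' @param replicates samples per group-donor cell.
#' @param sigma_d SD of the donor random intercept on log-abundance (drawn
#'   independently per donor and metabolite).
#' @param sigma_e SD of the per-sample biological residual on log-abundance.
#' @param cv coefficient of variation of the multiplicative log-normal
#'   measurement noise on isotopologue intensities.
#' @param baseline_mean,baseline_sd additive blank baseline signal per cell
#'   (Gaussian, truncated at zero); blanks carry baseline only.
#' @param p_nat,tracer_purity natural 13C abundance and tracer purity used
#'   in the forward convolution.
#' @param censor_floor intensities below this are reported as zero.
#' @param scale_factors optional per-sample multiplicative factors
#'   (recycled over samples in construction order); default all 1.
#' @param n_blanks number of blank samples (single batch).
#' @param seed RNG seed fixing the entire dataset.
#' @param name scenario label.
#' @return a `sim_scenario` object; fields as given plus derived
#'   `molecules`, group/donor layout and truth effect indicator tables
#'   (`abundance_effects`, `mid_effects`) for the consecutive contrasts.
#' @export
sim_scenario <- function(mids, mu_log, donors = 3, replicates = 1,
                         sigma_d = 0.25, sigma_e = 0.15, cv = 0.15,
                         baseline_mean = 50, baseline_sd = 15,
                         p_nat = 0.0107, tracer_purity = 1,
                         censor_floor = 0, scale_factors = NULL,
                         n_blanks = 3, seed = 1, name = "custom") {
  groups <- names(mids)
  if (is.null(groups) || length(groups) < 1) stopf("mids must be a named list of groups")
  mets <- names(mids[[1]])
  for (g in groups) {
    if (!identical(names(mids[[g]]), mets)) {
      stopf("metabolite sets differ between groups")
    }
    for (m in mets) {
      pi <- mids[[g]][[m]]
      if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
        stopf("MID of %s/%s is not on the simplex", g, m)
      }
      if (length(pi) != length(mids[[groups[1]]][[m]])) {
        stopf("MID length of %s differs between groups", m)
      }
    }
  }
  if (!is.matrix(mu_log) || !identical(rownames(mu_log), groups) ||
      !identical(colnames(mu_log), mets)) {
    stopf("mu_log must be a groups x metabolites matrix matching mids")
  }
  stopifnot(sigma_d >= 0, sigma_e >= 0, cv >= 0, baseline_sd >= 0)
  molecules <- data.frame(
    metabolite_id = mets,
    n_carbons = vapply(mets, function(m) length(mids[[1]][[m]]) - 1L, integer(1)),
    formula = NA_character_, stringsAsFactors = FALSE, row.names = NULL)

  # truth: which analytes carry effects under the consecutive contrasts
  ab_eff <- mid_eff <- NULL
  if (length(groups) >= 2) {
    cts <- paste0(groups[-1], "-", groups[-length(groups)])
    ab_eff <- do.call(rbind, lapply(seq_along(cts), function(i) {
      data.frame(metabolite = mets, contrast = cts[i],
                 effect = abs(mu_log[i + 1, ] - mu_log[i, ]) > 1e-12,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    mid_eff <- do.call(rbind, lapply(seq_along(cts), function(i) {
      do.call(rbind, lapply(mets, function(m) {
        d <- abs(mids[[i + 1]][[m]] - mids[[i]][[m]]) > 1e-12
        data.frame(metabolite = m, shift = seq_along(d) - 1L,
                   contrast = cts[i], effect = d,
                   stringsAsFactors = FALSE, row.names = NULL)
      }))
    }))
  }
  structure(list(
    name = name, mids = mids, mu_log = mu_log, groups = groups,
    metabolites = mets, molecules = molecules,
    donors = donors, replicates = replicates,
    sigma_d = sigma_d, sigma_e = sigma_e, cv = cv,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    p_nat = p_nat, tracer_purity = tracer_purity,
    censor_floor = censor_floor, scale_factors = scale_factors,
    n_blanks = n_blanks, seed = seed,
    abundance_effects = ab_eff, mid_effects = mid_eff
  ), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario '%s': %d groups x %d donors x %d replicates, %d metabolites\n",
              x$name, length(x$groups), x$donors, x$replicates,
              length(x$metabolites)))
  cat(sprintf("  sigma_d=%.3g sigma_e=%.3g cv=%.3g baseline=%.3g+/-%.3g seed=%d\n",
              x$sigma_d, x$sigma_e, x$cv, x$baseline_mean, x$baseline_sd,
              x$seed))
  invisible(x)
}

#' Generate a raw dataset from a scenario
#'
#' Forward model, per sample and metabolite: abundance
#' `A = exp(mu[group, met] + b[donor, met] + eps)` with
#' `b ~ N(0, sigma_d^2)` and `eps ~ N(0, sigma_e^2)`; true isotopologue
#' intensities `A * pi[group, met]`; natural-abundance convolution with
#' the same [build_correction_matrix()] kernel the corrector inverts;
#' multiplicative log-normal noise with unit mean and the configured CV;
#' per-sample scale factor; additive truncated-Gaussian baseline;
#' censoring below the floor. Blank samples carry baseline signal only.
#' Everything is reproducible from the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `raw` (measurement samples, stage `raw`), `blanks`
#'   (blank samples, stage `raw`), `meta` (sample metadata including
#'   blanks) and `truth` (realized per-sample true abundances, true MIDs,
#'   effect indicators, donor effects and scale factors).
#' @export
simulate_experiment <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  groups <- sc$groups; mets <- sc$metabolites
  donors <- paste0("D", seq_len(sc$donors))
  samples <- character(0)
  s_group <- s_donor <- character(0)
  for (g in groups) for (d in donors) for (r in seq_len(sc$replicates)) {
    samples <- c(samples, sprintf("%s_%s_R%d", g, d, r))
    s_group <- c(s_group, g); s_donor <- c(s_donor, d)
  }
  S <- length(samples)
  cfg <- correction_config(p_nat = sc$p_nat, tracer_purity = sc$tracer_purity)

  # deterministic draw order: donor effects, residuals, then per-met noise
  b <- matrix(stats::rnorm(sc$donors * length(mets), 0, sc$sigma_d),
              sc$donors, length(mets), dimnames = list(donors, mets))
  eps <- matrix(stats::rnorm(length(mets) * S, 0, sc$sigma_e),
                length(mets), S, dimnames = list(mets, samples))
  s_noise <- sqrt(log(1 + sc$cv^2))

  keys <- unlist(lapply(mets, function(m) {
    n <- sc$molecules$n_carbons[match(m, sc$molecules$metabolite_id)]
    make_rowkey(m, 0:n)
  }))
  signal <- matrix(0, length(keys), S, dimnames = list(keys, samples))
  A_true <- matrix(NA_real_, length(mets), S, dimnames = list(mets, samples))
  for (m in mets) {
    n <- sc$molecules$n_carbons[match(m, sc$molecules$metabolite_id)]
    M <- build_correction_matrix(n, cfg)
    A <- exp(sc$mu_log[cbind(s_group, m)] + b[cbind(s_donor, m)] + eps[m, ])
    A_true[m, ] <- A
    P <- vapply(s_group, function(g) sc$mids[[g]][[m]], numeric(n + 1))
    true_int <- sweep(P, 2, A, "*")
    obs <- M %*% true_int
    if (sc$cv > 0) {
      noise <- matrix(stats::rnorm(length(obs), -s_noise^2 / 2, s_noise),
                      nrow(obs), ncol(obs))
      obs <- obs * exp(noise)
    }
    signal[make_rowkey(m, 0:n), ] <- obs
  }
  scale <- if (is.null(sc$scale_factors)) rep(1, S) else
    rep_len(sc$scale_factors, S)
  names(scale) <- samples
  signal <- sweep(signal, 2, scale, "*")
  if (sc$baseline_mean > 0 || sc$baseline_sd > 0) {
    base <- matrix(stats::rnorm(length(signal), sc$baseline_mean,
                                sc$baseline_sd), nrow(signal), ncol(signal))
    signal <- signal + pmax(base, 0)
  }
  if (sc$censor_floor > 0) signal[signal < sc$censor_floor] <- 0

  blank_ids <- paste0("BLANK_", seq_len(sc$n_blanks))
  bvals <- matrix(pmax(stats::rnorm(length(keys) * sc$n_blanks,
                                    sc$baseline_mean, sc$baseline_sd), 0),
                  length(keys), sc$n_blanks,
                  dimnames = list(keys, blank_ids))

  meta <- data.frame(
    sample_id = c(samples, blank_ids),
    group = c(s_group, rep(NA_character_, sc$n_blanks)),
    donor = c(s_donor, rep(NA_character_, sc$n_blanks)),
    batch = "B1",
    is_blank = c(rep(FALSE, S), rep(TRUE, sc$n_blanks)),
    stringsAsFactors = FALSE)

  list(
    raw = iso_table(signal, sc$molecules, stage = "raw"),
    blanks = iso_table(bvals, sc$molecules, stage = "raw"),
    meta = meta,
    truth = list(abundance = A_true, mids = sc$mids,
                 abundance_effects = sc$abundance_effects,
                 mid_effects = sc$mid_effects,
                 donor_effects = b, scale_factors = scale,
                 scenario = sc$name, seed = sc$seed)
  )
}

# --- preset construction helpers -------------------------------------------

# single labeled species at m+n over an unlabeled rest
glyc_mid <- function(n, f) {
  v <- numeric(n + 1); v[1] <- 1 - f; v[n + 1] <- f
  v
}

# TCA-style MID: dominant m+2 (acetyl-CoA entry), m+3 fixed at `ratio`
# times m+2 (anaplerotic entry), small m+1 and m+4 components
tca_mid <- function(n, m2, m4 = 0.02, m1 = 0.02, ratio = 0.15) {
  v <- numeric(n + 1)
  v[2] <- m1; v[3] <- m2; v[4] <- ratio * m2
  if (n >= 4) v[5] <- m4
  v[1] <- 1 - sum(v)
  if (v[1] < 0) stopf("tca_mid fractions exceed 1")
  v
}

unlabeled <- function(n) glyc_mid(n, 0)

differentiation_scenario <- function(seed) {
  carbons <- c(hex = 6, g6p = 6, fbp = 6, dhap = 3, "3pg" = 3, pep = 3,
               pyr = 3, lac = 3, ala = 3, cit = 6, akg = 5, suc = 4,
               fum = 4, mal = 4, asp = 4, glu = 5)
  mets <- names(carbons)
  upper <- c(hex = 0.9, g6p = 0.9, fbp = 0.9, dhap = 0.85, "3pg" = 0.85)
  lower_f <- c(pep = 0.9, pyr = 0.8, lac = 0.75, ala = 0.5)
  tca_m2 <- c(cit = 0.30, akg = 0.24, suc = 0.20, fum = 0.22, mal = 0.22,
              asp = 0.19, glu = 0.18)
  tca_m4 <- c(cit = 0.06, akg = 0.03, suc = 0.02, fum = 0.02, mal = 0.03,
              asp = 0.02, glu = 0.02)
  build_group <- function(tca_scale, activated) {
    out <- list()
    for (m in mets) {
      n <- carbons[[m]]
      out[[m]] <-
        if (m %in% names(upper)) glyc_mid(n, upper[[m]])
        else if (!activated) unlabeled(n)
        else if (m %in% names(lower_f)) glyc_mid(n, lower_f[[m]])
        else tca_mid(n, tca_scale * tca_m2[[m]], tca_m4[[m]])
    }
    out
  }
  mids <- list(
    TN = build_group(1, activated = FALSE),
    TSCM = build_group(1, activated = TRUE),
    TCM = build_group(1.25, activated = TRUE),
    TEM = build_group(0.7, activated = TRUE)
  )
  base <- log(c(hex = 2e6, g6p = 4e5, fbp = 3e5, dhap = 2e5, "3pg" = 5e5,
                pep = 1e5, pyr = 8e5, lac = 3e6, ala = 6e5, cit = 1e6,
                akg = 2e5, suc = 4e5, fum = 3e5, mal = 6e5, asp = 5e5,
                glu = 2e6))
  mu <- rbind(TN = base, TSCM = base, TCM = base, TEM = base)
  # abundance effects along differentiation (natural-log fold changes)
  mu["TSCM", c("hex")] <- base["hex"] - 0.7
  mu["TSCM", c("g6p", "dhap", "ala")] <- base[c("g6p", "dhap", "ala")] + 0.7
  mu["TSCM", "lac"] <- base["lac"] + 1.0
  mu["TSCM", "suc"] <- base["suc"] - 0.5    # succinate accumulates in TN
  mu["TCM", ] <- mu["TSCM", ]
  mu["TCM", "dhap"] <- mu["TSCM", "dhap"] - 0.5
  mu["TCM", "lac"] <- mu["TSCM", "lac"] - 0.3
  mu["TEM", ] <- mu["TCM", ]
  mu["TEM", c("ala", "glu")] <- mu["TCM", c("ala", "glu")] + 0.5
  mu["TEM", "pyr"] <- mu["TCM", "pyr"] + 0.3
  colnames(mu) <- mets
  sim_scenario(mids, mu, donors = 3, replicates = 2, seed = seed,
               name = "differentiation")
}

exhaustion_scenario <- function(seed) {
  carbons <- c(hex = 6, pyr = 3, lac = 3, cit = 6, suc = 4, fum = 4,
               mal = 4, glu = 5)
  tca_m2 <- c(cit = 0.30, suc = 0.20, fum = 0.22, mal = 0.22, glu = 0.18)
  grp <- function(scale) {
    out <- list(hex = glyc_mid(6, 0.9),
                pyr = glyc_mid(3, 0.8),
                lac = glyc_mid(3, 0.75))
    for (m in names(tca_m2)) {
      out[[m]] <- tca_mid(carbons[[m]], scale * tca_m2[[m]])
    }
    out[names(carbons)]
  }
  mids <- list(TEFF = grp(1), TEX = grp(0.6))
  base <- log(c(hex = 2e6, pyr = 8e5, lac = 3e6, cit = 1e6, suc = 4e5,
                fum = 3e5, mal = 6e5, glu = 2e6))
  mu <- rbind(TEFF = base, TEX = base)
  mu["TEX", "lac"] <- base["lac"] - 0.5
  mu["TEX", "glu"] <- base["glu"] + 0.4
  colnames(mu) <- names(carbons)
  sim_scenario(mids, mu, donors = 3, replicates = 2, seed = seed,
               name = "exhaustion")
}

null_scenario <- function(seed, n_metabolites = 1000) {
  mets <- sprintf("met%04d", seq_len(n_metabolites))
  pi0 <- c(0.4, 0.3, 0.2, 0.1)
  one <- stats::setNames(rep(list(pi0), n_metabolites), mets)
  mids <- list(G1 = one, G2 = one)
  # deterministic spread of base abundances, no RNG involved
  base <- log(1e6) + 0.3 * ((seq_len(n_metabolites) %% 7) - 3)
  mu <- rbind(G1 = base, G2 = base)
  colnames(mu) <- mets
  sim_scenario(mids, mu, donors = 3, replicates = 4, sigma_d = 0.25,
               sigma_e = 0.2, cv = 0.15, seed = seed, name = "null")
}

lod_stress_scenario <- function(seed, n_metabolites = 20) {
  mets <- sprintf("lod%02d", seq_len(n_metabolites))
  pi0 <- c(0.55, 0.2, 0.15, 0.1)
  one <- stats::setNames(rep(list(pi0), n_metabolites), mets)
  mids <- list(G1 = one, G2 = one)
  # abundances straddle the blank threshold (~ baseline mean + 2 sd)
  base <- log(20) + (seq_len(n_metabolites) - 1) / (n_metabolites - 1) *
    (log(2000) - log(20))
  mu <- rbind(G1 = base, G2 = base)
  colnames(mu) <- mets
  sim_scenario(mids, mu, donors = 3, replicates = 3, sigma_d = 0.2,
               sigma_e = 0.3, cv = 0.25, baseline_mean = 50,
               baseline_sd = 15, seed = seed, name = "lod_stress")
}

#' Built-in simulation scenarios
#'
#' * `differentiation`: four T cell subsets (TN, TSCM, TCM, TEM) x 3
#'   donors x 2 replicates over a 16-metabolite glycolysis/TCA panel. TN
#'   has full labeling in upper glycolysis but none downstream of
#'   3-phosphoglycerate (an enolase block); activated subsets carry
#'   m+2-dominant TCA labeling with an m+3 component fixed at an
#'   m+3/m+2 ratio of 0.15, plus log-scale abundance effects along the
#'   differentiation axis.
#' * `exhaustion`: two subsets (TEFF, TEX), TEX with reduced TCA labeling
#'   and altered lactate/glutamate levels.
#' * `null`: two groups, 3 donors, 4 replicates, no effects anywhere —
#'   for type-I error calibration.
#' * `lod_stress`: abundances straddling the blank threshold, exercising
#'   thresholding and group cleaning.
#'
#' @param name preset name.
#' @param seed RNG seed stored in the scenario.
#' @param n_metabolites panel size for the `null` and `lod_stress`
#'   presets.
#' @return a [sim_scenario()].
#' @export
scenario_presets <- function(name = c("differentiation", "exhaustion",
                                      "null", "lod_stress"),
                             seed = 1, n_metabolites = NULL) {
  name <- match.arg(name)
  switch(name,
    differentiation = differentiation_scenario(seed),
    exhaustion = exhaustion_scenario(seed),
    null = null_scenario(seed, n_metabolites %||% 1000),
    lod_stress = lod_stress_scenario(seed, n_metabolites %||% 20)
  )
}
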