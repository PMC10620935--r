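test_that("simulation is a deterministic function of the seed", {
  sc <- scenario_presets("exhaustion", seed = 3)
  a <- simulate_experiment(sc)
  b <- simulate_experiment(sc)
  expect_identical(a$raw$values, b$raw$values)
  expect_identical(a$blanks$values, b$blanks$values)
  c <- simulate_experiment(scenario_presets("exhaustion", seed = 4))
  expect_false(identical(a$raw$values, c$raw$values))
})

test_that("noise-free simulation is inverted exactly by the pipeline", {
  sc <- scenario_presets("differentiation", seed = 2)
  sc$sigma_d <- 0; sc$sigma_e <- 0; sc$cv <- 0
  sc$baseline_mean <- 0; sc$baseline_sd <- 0
  dat <- simulate_experiment(sc)
  pr <- process_sim(dat)
  mid <- compute_mid(pr$normalized)
  meta <- dat$meta[!dat$meta$is_blank, ]
  for (s in meta$sample_id) {
    g <- meta$group[meta$sample_id == s]
    for (met in c("lac", "cit", "glu")) {
      idx <- which(mid$metabolite == met)
      idx <- idx[order(mid$shift[idx])]
      expect_equal(unname(mid$values[idx, s]), sc$mids[[g]][[met]],
                   tolerance = 1e-6)
    }
  }
})

test_that("simulator and corrector share the convolution kernel exactly", {
  sc <- scenario_presets("exhaustion", seed = 6)
  sc$sigma_d <- 0; sc$sigma_e <- 0; sc$cv <- 0
  sc$baseline_mean <- 0; sc$baseline_sd <- 0
  dat <- simulate_experiment(sc)
  tab <- dat$raw; tab$stage <- "thresholded"
  out <- correct_natural_abundance(tab)
  # corrected intensities equal true abundance times true MID
  meta <- dat$meta[!dat$meta$is_blank, ]
  s <- meta$sample_id[1]; g <- meta$group[1]
  for (met in c("lac", "cit")) {
    idx <- which(out$metabolite == met)
    idx <- idx[order(out$shift[idx])]
    truth <- dat$truth$abundance[met, s] * sc$mids[[g]][[met]]
    expect_equal(unname(out$values[idx, s]), truth, tolerance = 1e-6 * sum(truth))
  }
})

test_that("donor intraclass correlation approaches its configured value", {
  sigma_d <- 0.4; sigma_e <- 0.3
  mids <- list(G1 = list(met = c(0.5, 0.5)))
  mu <- matrix(log(1e6), 1, 1, dimnames = list("G1", "met"))
  sc <- sim_scenario(mids, mu, donors = 40, replicates = 8,
                     sigma_d = sigma_d, sigma_e = sigma_e, cv = 0,
                     baseline_mean = 0, baseline_sd = 0, seed = 7)
  dat <- simulate_experiment(sc)
  la <- log(dat$truth$abundance["met", ])
  donor <- sub("^G1_(D[0-9]+)_.*$", "\\1", colnames(dat$truth$abundance))
  ms_between <- var(tapply(la, donor, mean))
  icc_hat <- (ms_between - sigma_e^2 / 8) / (sigma_e^2 + (ms_between - sigma_e^2 / 8))
  icc_true <- sigma_d^2 / (sigma_d^2 + sigma_e^2)
  expect_equal(icc_hat, icc_true, tolerance = 0.12)
})

test_that("blank samples reproduce the configured baseline statistics", {
  sc <- scenario_presets("differentiation", seed = 9)
  sc$n_blanks <- 60
  dat <- simulate_experiment(sc)
  v <- as.vector(dat$blanks$values)
  # truncation at zero is negligible for mean 50, sd 15
  expect_equal(mean(v), sc$baseline_mean, tolerance = 0.05 * sc$baseline_mean)
  expect_equal(sd(v), sc$baseline_sd, tolerance = 0.1 * sc$baseline_sd)
})

test_that("presets encode their qualitative biology", {
  sc <- scenario_presets("differentiation", seed = 1)
  # TN: unlabeled lactate (enolase block); activated: mostly m+3 lactate
  expect_equal(sc$mids$TN$lac, c(1, 0, 0, 0))
  expect_gt(sc$mids$TSCM$lac[4], 0.5)
  # TCA MIDs keep the anaplerosis marker ratio at 0.15 in all activated groups
  for (g in c("TSCM", "TCM", "TEM")) {
    expect_equal(sc$mids[[g]]$cit[4] / sc$mids[[g]]$cit[3], 0.15,
                 tolerance = 1e-12)
  }
  # every MID is a simplex vector
  for (g in names(sc$mids)) for (m in names(sc$mids[[g]])) {
    expect_equal(sum(sc$mids[[g]][[m]]), 1, tolerance = 1e-9)
    expect_true(all(sc$mids[[g]][[m]] >= 0))
  }

  # null preset carries no effects at all
  scn <- scenario_presets("null", seed = 1, n_metabolites = 10)
  expect_false(any(scn$abundance_effects$effect))
  expect_false(any(scn$mid_effects$effect))

  # differentiation truth marks the designed lactate abundance effect
  eff <- sc$abundance_effects
  expect_true(eff$effect[eff$metabolite == "lac" & eff$contrast == "TSCM-TN"])
  expect_false(eff$effect[eff$metabolite == "hex" & eff$contrast == "TEM-TCM"])
})

test_that("lod_stress preset pushes a fifth of analyte-group cells below LOQ", {
  sc <- scenario_presets("lod_stress", seed = 2)
  dat <- simulate_experiment(sc)
  thr <- compute_blank_thresholds(bind_samples(dat$raw, dat$blanks), dat$meta)
  th <- apply_threshold_correction(dat$raw, thr, dat$meta)
  meta <- dat$meta[!dat$meta$is_blank, ]
  below_frac <- c()
  for (g in unique(meta$group)) {
    ids <- meta$sample_id[meta$group == g]
    tmat <- attr(thr, "threshold")[rownames(th$values), rep("B1", length(ids))]
    below_frac <- c(below_frac,
                    rowMeans(th$values[, ids] < tmat))
  }
  expect_gte(mean(below_frac > 1 / 3), 0.2)
  # and group cleaning is actually exercised
  cleaned <- clean_groups(th, thr, dat$meta)
  expect_gt(sum(is.na(cleaned$values)), 0)
})

test_that("scenario validation rejects malformed MIDs", {
  mids <- list(G1 = list(met = c(0.6, 0.6)))
  mu <- matrix(1, 1, 1, dimnames = list("G1", "met"))
  expect_error(sim_scenario(mids, mu), "simplex")
})
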