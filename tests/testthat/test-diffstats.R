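test_that("balanced-design LMM fixed effects equal the OLS group means", {
  set.seed(2)
  for (rep in 1:5) {
    meta <- make_meta(groups = c("A", "B"), donors = 3, replicates = 2,
                      n_blanks = 0)
    y <- setNames(exp(rnorm(nrow(meta), 10, 0.5)), meta$sample_id)
    fit <- fit_abundance_lmm(y, meta)
    ols <- tapply(log(y), meta$group, mean)
    expect_equal(unname(coef(fit)), as.vector(ols[names(coef(fit))]),
                 tolerance = 1e-6)
  }
})

test_that("zeros are replaced by half the minimum positive value before log", {
  meta <- make_meta(groups = c("A", "B"), donors = 2, replicates = 2,
                    n_blanks = 0)
  y <- setNames(c(0, 4, 8, 16, 2, 4, 8, 16), meta$sample_id)
  fit <- fit_abundance_lmm(y, meta)
  # group A mean must use log(1) = log(min positive / 2) for the zero
  expect_equal(unname(coef(fit)[["A"]]),
               mean(log(c(1, 4, 8, 16))), tolerance = 1e-6)
})

test_that("constant response yields zero difference and p = 1", {
  meta <- make_meta(groups = c("A", "B"), donors = 3, replicates = 2,
                    n_blanks = 0)
  y <- setNames(rep(5, nrow(meta)), meta$sample_id)
  fit <- fit_abundance_lmm(y, meta)
  res <- test_contrasts(list(m = fit), list("B-A" = c(A = -1, B = 1)))
  expect_equal(res$estimate, 0, tolerance = 1e-10)
  expect_equal(res$p, 1)
})

test_that("LMM group-difference estimates cover the truth", {
  set.seed(5)
  meta <- make_meta(groups = c("A", "B"), donors = 3, replicates = 2,
                    n_blanks = 0)
  delta <- 1
  hits <- 0; nsim <- 200
  bias <- numeric(nsim)
  for (i in seq_len(nsim)) {
    b <- rnorm(3, 0, 0.3)[match(meta$donor, paste0("D", 1:3))]
    mu <- ifelse(meta$group == "B", delta, 0)
    y <- setNames(exp(mu + b + rnorm(nrow(meta), 0, 0.2)), meta$sample_id)
    fit <- fit_abundance_lmm(y, meta)
    res <- test_contrasts(list(m = fit), list("B-A" = c(A = -1, B = 1)))
    bias[i] <- res$estimate - delta
    if (abs(res$estimate - delta) <= 3 * res$se) hits <- hits + 1
  }
  expect_gte(hits / nsim, 0.93)
  expect_lt(abs(mean(bias)), 0.05)
})

test_that("beta regression is symmetric and matches an independent fitter", {
  meta <- make_meta(groups = c("A", "B"), donors = 3, replicates = 3,
                    n_blanks = 0)
  # all fractions identical: group difference must vanish
  y0 <- setNames(rep(0.5, nrow(meta)), meta$sample_id)
  f0 <- fit_mid_betareg(y0, meta)
  expect_equal(unname(diff(coef(f0))), 0, tolerance = 1e-6)

  # cross-check against glmmTMB (Laplace approximation) on one dataset
  set.seed(8)
  mu <- plogis(ifelse(meta$group == "B", 0.8, -0.2))
  y <- setNames(rbeta(nrow(meta), mu * 60, (1 - mu) * 60), meta$sample_id)
  f <- fit_mid_betareg(y, meta)
  tmb <- glmmTMB::glmmTMB(
    y ~ 0 + group + (1 | donor), family = glmmTMB::beta_family(),
    data = data.frame(y = y, group = meta$group, donor = meta$donor))
  btmb <- glmmTMB::fixef(tmb)$cond
  expect_equal(unname(coef(f)), unname(btmb), tolerance = 0.02)
})

test_that("boundary fractions are admissible via the shrinkage transform", {
  meta <- make_meta(groups = c("A", "B"), donors = 3, replicates = 3,
                    n_blanks = 0)
  set.seed(10)
  y <- setNames(rbeta(nrow(meta), 2, 20), meta$sample_id)
  y[1] <- 0; y[10] <- 1
  f <- fit_mid_betareg(y, meta)
  expect_true(is.finite(f$logLik))
  N <- length(y)
  expect_equal(f$internals$y[[1]], 0.5 / N)          # 0 mapped inward
  expect_equal(sort(f$internals$y, decreasing = TRUE)[[1]],
               (1 * (N - 1) + 0.5) / N)              # 1 mapped inward
})

test_that("adaptive quadrature is stable under node refinement", {
  set.seed(12)
  meta <- make_meta(groups = c("A", "B"), donors = 3, replicates = 4,
                    n_blanks = 0)
  b <- rnorm(3, 0, 0.5)[match(meta$donor, paste0("D", 1:3))]
  mu <- plogis(ifelse(meta$group == "B", 0.5, -0.5) + b)
  y <- setNames(rbeta(nrow(meta), mu * 40, (1 - mu) * 40), meta$sample_id)
  f <- fit_mid_betareg(y, meta, nq = 9)
  expect_gt(f$sigma_d, 1e-4)  # a donor effect is actually present
  expect_lt(abs(betareg_loglik(f, 9) - betareg_loglik(f, 25)), 1e-4)
})

test_that("contrast machinery: zero contrast, single analyte, BH by hand", {
  fit <- structure(list(coefficients = c(A = 1, B = 2),
                        vcov = diag(2) * 0.25, converged = TRUE),
                   class = "lmm_fit")
  res0 <- test_contrasts(list(m = fit), list(null = c(A = 0, B = 0)))
  expect_equal(res0$estimate, 0)
  expect_equal(res0$p, 1)

  res1 <- test_contrasts(list(m = fit), list("B-A" = c(A = -1, B = 1)))
  expect_equal(res1$padj, res1$p)  # single test: BH is the identity
  expect_equal(res1$estimate, 1)
  expect_equal(res1$se, sqrt(0.5))

  # three analytes with p engineered to (0.01, 0.02, 0.9):
  z <- qnorm(1 - c(0.01, 0.02, 0.9) / 2)
  fits <- lapply(z, function(zz) {
    structure(list(coefficients = c(A = 0, B = zz * sqrt(0.5)),
                   vcov = diag(2) * 0.25, converged = TRUE),
              class = "lmm_fit")
  })
  names(fits) <- c("m1", "m2", "m3")
  res <- test_contrasts(fits, list("B-A" = c(A = -1, B = 1)))
  expect_equal(res$p, c(0.01, 0.02, 0.9), tolerance = 1e-10)
  expect_equal(res$padj, c(0.03, 0.03, 0.9), tolerance = 1e-10)
})

test_that("padj is monotone in p, bounded by 1, and at least p", {
  set.seed(14)
  fits <- lapply(1:30, function(i) {
    est <- rnorm(1, 0, 1)
    structure(list(coefficients = c(A = 0, B = est),
                   vcov = diag(2) * 0.25, converged = TRUE),
              class = "lmm_fit")
  })
  names(fits) <- paste0("m", 1:30)
  res <- test_contrasts(fits, list("B-A" = c(A = -1, B = 1)))
  o <- order(res$p)
  expect_true(all(diff(res$padj[o]) >= -1e-12))
  expect_true(all(res$padj <= 1 + 1e-12))
  expect_true(all(res$padj >= res$p - 1e-12))
})

test_that("Satterthwaite df gives heavier tails than the z default", {
  set.seed(16)
  meta <- make_meta(groups = c("A", "B"), donors = 3, replicates = 2,
                    n_blanks = 0)
  b <- rnorm(3, 0, 0.3)[match(meta$donor, paste0("D", 1:3))]
  y <- setNames(exp(0.4 * (meta$group == "B") + b +
                      rnorm(nrow(meta), 0, 0.2)), meta$sample_id)
  fit <- fit_abundance_lmm(y, meta, keep_model = TRUE)
  ct <- list("B-A" = c(A = -1, B = 1))
  z <- test_contrasts(list(m = fit), ct, df_method = "z")
  st <- test_contrasts(list(m = fit), ct, df_method = "satterthwaite")
  expect_equal(st$estimate, z$estimate)
  expect_gt(st$p, z$p)  # finite df can only widen the tails
})

test_that("contrasts referencing an absent level fail loudly", {
  fit <- structure(list(coefficients = c(A = 1, B = 2),
                        vcov = diag(2), converged = TRUE), class = "lmm_fit")
  expect_error(test_contrasts(list(m = fit), list(bad = c(A = -1, C = 1))),
               "absent level")
})

test_that("empty contrast list gives empty results", {
  fit <- structure(list(coefficients = c(A = 1, B = 2),
                        vcov = diag(2), converged = TRUE), class = "lmm_fit")
  res <- test_contrasts(list(m = fit), list())
  expect_equal(nrow(res), 0)
})

test_that("consecutive contrasts span the differentiation axis", {
  cts <- consecutive_contrasts(c("TN", "TSCM", "TCM", "TEM"))
  expect_named(cts, c("TSCM-TN", "TCM-TSCM", "TEM-TCM"))
  expect_true(all(vapply(cts, sum, numeric(1)) == 0))
  expect_equal(cts[["TCM-TSCM"]][["TCM"]], 1)
  expect_equal(cts[["TCM-TSCM"]][["TSCM"]], -1)
})
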