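test_that("index closed forms", {
  expect_equal(chi_square(0, 200), 0)
  expect_equal(chi_square(0.05, 201), 10)

  expect_equal(rmsea(39, 39, 500), 0)
  expect_equal(rmsea(78, 39, 1000), sqrt(1 / 999))
  expect_error(rmsea(10, 0, 100), "df")

  expect_equal(cfi(30, 39, 500, 66), 1)
  expect_equal(cfi(50, 39, 500, 66), 1 - 11 / 434)
  expect_equal(cfi(0, 0, 0, 0), 1)

  S <- diag(12)
  expect_equal(gfi(S, S), 1)
  expect_equal(gfi(S, 2 * S), 0)

  expect_equal(srmr(S, S), 0)
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  H2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(srmr(S2, H2), sqrt(0.04 / 3))
  # scale invariance under joint item rescaling
  d <- diag(c(2, 0.5))
  expect_equal(srmr(d %*% S2 %*% d, d %*% H2 %*% d), srmr(S2, H2))
  # GFI invariant under joint scalar rescaling
  A <- random_spd(5); B <- random_spd(5)
  expect_equal(gfi(3 * A, 3 * B), gfi(A, B))
})

test_that("communality, ratio cutoffs and rule table", {
  pop <- population_model(bifactor_pattern(0.60, 0.40))
  fit <- bifactor_ml(pop$Sigma, pop$pattern)
  # non-cross item at lambda = 0.60: R^2 = 0.36 + 0.36 = 0.72
  expect_equal(1 - fit$theta[1L] / diag(fit$Sigma_hat)[1L], 0.72,
               tolerance = 1e-5)

  expect_equal(shi_ratio(0.02, 0.5), list(ratio = 0.04, verdict = "close"))
  expect_equal(shi_ratio(0.04, 0.5), list(ratio = 0.08, verdict = "adequate"))
  expect_equal(shi_ratio(0.06, 0.5), list(ratio = 0.12, verdict = "poor"))
  expect_warning(out <- shi_ratio(0.05, 0), "communality")
  expect_equal(out$verdict, "poor")

  rules <- cutoff_rules()
  expect_setequal(rules$index,
                  c("rmsea", "cfi", "gfi", "srmr", "shi_close",
                    "shi_adequate", "rmsd"))

  # average communality increases with lambda at fixed cross value
  r2 <- sapply(c(0.15, 0.30, 0.50, 0.60), function(l) {
    p <- population_model(bifactor_pattern(l, 0.20))
    average_communality(bifactor_ml(p$Sigma, p$pattern))
  })
  expect_true(all(diff(r2) > 0))
})

test_that("population indices: saturating fit and reliability paradox", {
  gen <- bifactor_pattern(0.30, 0.20)
  ix <- population_indices(gen, gen)   # correct structure
  expect_lt(abs(ix$rmsea), 1e-6)
  expect_equal(ix$cfi, 1)
  expect_equal(ix$gfi, 1, tolerance = 1e-8)
  expect_lt(ix$srmr, 1e-6)

  # near-null misspecification (c = 0.05) passes all conventional cutoffs
  near <- population_indices(bifactor_pattern(0.60, 0.05))
  expect_lt(near$rmsea, 0.05)
  expect_gt(near$cfi, 0.95)
  expect_gt(near$gfi, 0.95)
  expect_lt(near$srmr, 0.08)

  # at c = 0.40, as lambda grows: RMSEA and SRMR increase, CFI and GFI drop
  lam <- c(0.15, 0.30, 0.50, 0.60)
  tabs <- lapply(lam, function(l) population_indices(bifactor_pattern(l, 0.40)))
  expect_true(all(diff(sapply(tabs, `[[`, "rmsea")) > 0))
  expect_true(all(diff(sapply(tabs, `[[`, "srmr")) > 0))
  expect_true(all(diff(sapply(tabs, `[[`, "cfi")) < 0))
  expect_true(all(diff(sapply(tabs, `[[`, "gfi")) < 0))

  # population indices are deterministic
  expect_identical(unclass(population_indices(gen))[1:9],
                   unclass(population_indices(gen))[1:9])
})

test_that("unbiased SRMR: population equality, ordering and debiasing", {
  gen <- bifactor_pattern(0.60, 0.30)
  pop <- population_model(gen)
  nox <- gen; nox$include_cross <- FALSE
  popfit <- bifactor_ml(pop$Sigma, nox)
  # no sampling error at the population level
  expect_equal(srmr_unbiased(pop$Sigma, popfit, n = NULL),
               srmr(pop$Sigma, popfit$Sigma_hat))

  # on every replication the corrected value cannot exceed the naive one
  nrep <- 300
  sr <- srn <- numeric(0)
  for (i in seq_len(nrep)) {
    sm <- draw_sample(pop, 100, seed = 1000 + i)
    fit <- bifactor_ml(sm$S, gen, n = 100)
    if (!fit$converged || fit$heywood) next
    s_naive <- srmr(sm$S, fit$Sigma_hat)
    s_unb <- srmr_unbiased(sm$S, fit)
    expect_lte(s_unb, s_naive + 1e-12)
    sr <- c(sr, s_unb); srn <- c(srn, s_naive)
  }
  # correct model: population SRMR is 0; the naive estimator is biased
  # upward at N = 100 while the corrected one sits near 0
  expect_gt(mean(srn), 0.02)
  expect_lt(mean(sr), 0.015)
  expect_gt(mean(srn), 3 * mean(sr))
})

test_that("full index set is coherent for a sample fit", {
  gen <- bifactor_pattern(0.50, 0.20)
  pop <- population_model(gen)
  sm <- draw_sample(pop, 500, seed = 99)
  fit <- bifactor_ml(sm$S, gen, n = 500)
  ix <- fit_indices(fit)
  expect_equal(ix$level, "sample")
  expect_equal(ix$T, 499 * fit$discrepancy)
  expect_gte(ix$rmsea, 0)
  expect_true(ix$cfi >= 0 && ix$cfi <= 1)
  expect_lte(ix$gfi, 1)
  expect_equal(ix$shi_ratio, ix$srmr_u / ix$r2_bar)
  expect_error(rmsea_ci(), "not implemented")
})
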