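test_that("ML discrepancy matches closed forms and the eigenvalue oracle", {
  expect_equal(fml(diag(4), diag(4)), 0)
  expect_equal(fml(diag(12), 2 * diag(12)), 12 * log(2) + 6 - 12)

  # oracle: F = sum over eigenvalues w of Sigma^-1 S of (w - log w - 1)
  set.seed(404)
  for (i in 1:100) {
    p <- sample(2:8, 1)
    S <- random_spd(p); Sig <- random_spd(p)
    w <- eigen(solve(Sig, S), only.values = TRUE)$values
    expect_equal(fml(S, Sig), sum(w - log(w) - 1), tolerance = 1e-8)
    expect_gte(fml(S, Sig), 0)
  }
  expect_error(fml(diag(3), diag(3) - diag(2, 3)), "positive definite")
})

test_that("correct model recovers generating parameters from population Sigma", {
  g <- generating_grid()
  for (i in seq_len(nrow(g))) {
    gen <- bifactor_pattern(g$lambda[i], g$c[i])
    pop <- population_model(gen)
    fit <- bifactor_ml(pop$Sigma, gen)
    expect_true(fit$converged)
    expect_false(fit$heywood)
    expect_lt(fit$discrepancy, 1e-10)
    expect_lt(max(abs(fit$Lambda - pop$Lambda)), 1e-5)
    expect_lt(max(abs(fit$theta - pop$theta)), 1e-5)
  }
})

test_that("misspecified model cannot reproduce a cross-loaded population", {
  gen <- bifactor_pattern(0.60, 0.40)
  pop <- population_model(gen)
  nox <- gen; nox$include_cross <- FALSE
  fit <- bifactor_ml(pop$Sigma, nox)
  expect_true(fit$converged)
  expect_gt(fit$discrepancy, 0.01)
  # factor collapse: general loadings inflate, group loadings deflate
  expect_gt(mean(fit$Lambda[, 1L]), 0.60)
  expect_lt(mean(fit$Lambda[cbind(1:12, 1L + gen$group_assignment)]), 0.60)
  # fixed-to-zero entries stay exactly zero
  expect_true(all(fit$Lambda[!loading_mask(nox)] == 0))
})

test_that("optimum is invariant to admissible starting values", {
  gen <- bifactor_pattern(0.50, 0.30)
  pop <- population_model(gen)
  sm <- draw_sample(pop, 300, seed = 8)
  f1 <- bifactor_ml(sm$S, gen, n = 300)
  idx_free <- sum(loading_mask(gen))
  start2 <- c(rep(0.3, idx_free), rep(0.7, 12))
  f2 <- bifactor_ml(sm$S, gen, n = 300, start = start2)
  expect_true(f1$converged && f2$converged)
  expect_equal(f1$discrepancy, f2$discrepancy, tolerance = 1e-8)
})

test_that("Heywood detection keys on negative unique variances", {
  gen <- bifactor_pattern(0.50, 0.20)
  pop <- population_model(gen)
  fit <- bifactor_ml(pop$Sigma, gen)
  expect_false(is_heywood(fit))
  fit$theta[3] <- -0.02
  expect_true(is_heywood(fit))
})

test_that("baseline statistics follow the independence-model closed form", {
  b <- baseline_statistics(diag(c(2, 3, 1)), n = 50)
  expect_equal(b$T_B, 0)
  expect_equal(baseline_statistics(diag(12), 100)$df_B, 66L)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  b2 <- baseline_statistics(S, n = 101)
  expect_equal(b2$F_B, -log(0.75))
  expect_equal(b2$T_B, 100 * 0.2876821, tolerance = 1e-6)
})

test_that("fit accessors and one-off covariance-file interface work", {
  gen <- bifactor_pattern(0.60, 0.20)
  pop <- population_model(gen)
  sm <- draw_sample(pop, 500, seed = 21)
  fit <- bifactor_ml(sm$S, gen, n = 500)
  expect_equal(fitted(fit), fit$Sigma_hat)
  expect_equal(length(coef(fit)), 39L)
  R <- residuals(fit, "standardized")
  expect_equal(dim(R), c(12L, 12L))
  expect_lt(max(abs(R)), 0.2)

  path <- tempfile(fileext = ".txt")
  write.table(sm$S, path, row.names = FALSE, col.names = FALSE)
  f2 <- fit_cov_file(path, n = 500, model = "correct")
  expect_equal(f2$discrepancy, fit$discrepancy, tolerance = 1e-6)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1L]]), c(500L, 12L))
})
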