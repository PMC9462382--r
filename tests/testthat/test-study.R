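test_that("grid arithmetic", {
  g <- build_grid()
  expect_equal(nrow(g), 160L)
  expect_equal(sum(g$q == "correct"), 80L)
  expect_equal(sum(g$n == 100), 40L)
  expect_equal(anyDuplicated(g$condition_id), 0L)
  # deterministic order
  expect_identical(g$condition_id, build_grid()$condition_id)
})

test_that("run_cell is reproducible and respects the replacement policy", {
  cond <- list(q = "correct", n = 200L, lambda = 0.60, c = 0.20,
               condition_id = "x")
  a <- run_cell(cond, reps = 4L, master_seed = 9L, condition_index = 3L)
  b <- run_cell(cond, reps = 4L, master_seed = 9L, condition_index = 3L)
  expect_identical(a$records, b$records)
  expect_equal(nrow(a$records), 4L)
  expect_true(all(!is.na(a$records$rmsd_cross)))  # correct model
  expect_gte(nrow(a$attempts), 4L)
  # every kept record came from a converged, non-Heywood attempt
  expect_true(all(a$attempts$converged[a$records$attempts]))
  expect_true(all(!a$attempts$heywood[a$records$attempts]))

  c2 <- run_cell(list(q = "incorrect", n = 200L, lambda = 0.60, c = 0.20,
                      condition_id = "y"),
                 reps = 3L, master_seed = 9L, condition_index = 4L)
  expect_true(all(is.na(c2$records$rmsd_cross)))
})

test_that("bad solutions concentrate in weak factors and small samples", {
  # the hard cell may legitimately hit the attempt cap (and warn)
  hard <- suppressWarnings(
    run_cell(list(q = "correct", n = 100L, lambda = 0.15, c = 0.20,
                  condition_id = "hard"),
             reps = 8L, master_seed = 2L, condition_index = 1L))
  easy <- run_cell(list(q = "correct", n = 1000L, lambda = 0.60, c = 0.20,
                        condition_id = "easy"),
                   reps = 8L, master_seed = 2L, condition_index = 2L)
  bad_rate <- function(x) mean(!x$attempts$converged | x$attempts$heywood)
  expect_gt(bad_rate(hard), bad_rate(easy))
  expect_lt(bad_rate(easy), 0.15)
})

test_that("effect-size classification bands", {
  expect_equal(classify_effect(0.04), "negligible")
  expect_equal(classify_effect(0.07), "small")
  expect_equal(classify_effect(0.12), "medium")
  expect_equal(classify_effect(0.20), "medium")
  expect_equal(classify_effect(0.68), "large")
  expect_error(classify_effect(1.2), "0, 1")
})

# balanced synthetic study records with known structure, no simulation cost
fake_records <- function(reps = 6L, seed = 1L) {
  set.seed(seed)
  g <- build_grid()
  r <- g[rep(seq_len(nrow(g)), each = reps), ]
  r$replication <- rep(seq_len(reps), times = nrow(g))
  # DV driven mainly by N, with noise
  r$rmsd_fgen <- 1 / sqrt(r$n) + rnorm(nrow(r), 0, 0.02)
  r$gfi <- 1 - 2 / sqrt(r$n) + rnorm(nrow(r), 0, 0.02)
  r$rmsd_cross <- ifelse(r$q == "correct",
                         1 / sqrt(r$n) + rnorm(nrow(r), 0, 0.05), NA)
  r
}

test_that("ANOVA meta-model: term structure, df, and eta-squared properties", {
  r <- fake_records()
  a <- anova_eta(r, "rmsd_fgen")
  expect_equal(nrow(a), 15L)   # 4 mains + 6 two-way + 4 three-way + 1 four-way
  dfs <- setNames(a$df, a$effect)
  expect_equal(unname(dfs[c("q", "N", "lambda", "c")]), c(1L, 3L, 3L, 4L))
  expect_equal(unname(dfs["q:N"]), 3L)
  expect_equal(unname(dfs["N:lambda:c"]), 36L)
  expect_equal(unname(dfs["q:N:lambda:c"]), 36L)
  expect_true(all(a$eta_sq >= 0 & a$eta_sq <= 1))
  # N dominates by construction
  expect_equal(a$effect[which.max(a$eta_sq)], "N")

  # partial eta-squared invariant under affine rescaling of the DV
  r2 <- r; r2$rmsd_fgen <- 5 * r2$rmsd_fgen - 2
  a2 <- anova_eta(r2, "rmsd_fgen")
  expect_equal(a2$eta_sq, a$eta_sq, tolerance = 1e-10)

  # q terms dropped for the cross-loading DV
  ac <- anova_eta(r, "rmsd_cross")
  expect_equal(nrow(ac), 7L)
  expect_false(any(grepl("q", ac$effect)))

  # zero between-cell variance: all effects vanish
  r3 <- r; r3$rmsd_fgen <- 1
  a3 <- anova_eta(r3, "rmsd_fgen")
  expect_true(all(a3$eta_sq < 1e-10))
})

test_that("logit analysis of bad-solution incidence", {
  set.seed(3)
  g <- build_grid()
  att <- g[rep(seq_len(nrow(g)), each = 30L), ]
  eta <- -3 + 2.5 * (att$lambda < 0.3) + 1.5 * (att$n == 100) +
    1.2 * (att$lambda < 0.3 & att$n == 100)
  att$converged <- runif(nrow(att)) > stats::plogis(eta)
  att$heywood <- FALSE
  out <- convergence_logit(att, "nonconvergence")
  expect_true(all(c("model", "coefficients", "ranking") %in% names(out)))
  # lambda and N main effects dominate the deviance ranking
  expect_setequal(out$ranking$term[1:2], c("lambda", "N"))
  expect_true("N:lambda" %in% out$ranking$term)

  # constant outcome degenerates gracefully to (smoothed) intercept-only
  att$converged <- TRUE
  expect_warning(out0 <- convergence_logit(att, "nonconvergence"), "smoothing")
  expect_lt(max(abs(out0$coefficients[-1L])), 1)
})

test_that("study runner and table export round-trip", {
  g <- build_grid()
  sub <- g[g$lambda >= 0.5 & g$n %in% c(200L, 500L) & g$c %in% c(0.10, 0.40), ]
  st <- run_study(grid = sub, reps = 3L, master_seed = 5L)
  expect_s3_class(st, "bifactor_study")
  expect_equal(nrow(st$records), 3L * nrow(sub))
  expect_true(all(table(st$records$q, st$records$n) > 0))
  # rerun reproduces byte-identical records
  st2 <- run_study(grid = sub, reps = 3L, master_seed = 5L)
  expect_identical(st$records, st2$records)

  dir <- tempfile("tables")
  paths <- export_tables(st, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "replications.csv"))
  expect_equal(nrow(back), nrow(st$records))
  expect_equal(back$srmr, st$records$srmr, tolerance = 1e-12)
  cm <- read.csv(file.path(dir, "cell_means.csv"))
  expect_equal(nrow(cm), nrow(sub))
  pop <- read.csv(file.path(dir, "population_indices.csv"))
  expect_equal(nrow(pop), 20L)
})

test_that("study configuration files round-trip into run_study arguments", {
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(c("reps: 7", "master_seed: 99", "lambda: [0.5, 0.6]",
               "n: [100, 500]", "variance_convention: literal"), cfg_file)
  cfg <- study_config(cfg_file)
  expect_equal(cfg$reps, 7L)
  expect_equal(cfg$master_seed, 99L)
  expect_equal(nrow(cfg$grid), 2L * 2L * 2L * 5L)
  expect_equal(cfg$variance_convention, "literal")

  writeLines("", cfg_file)   # empty file: the published design
  cfg0 <- study_config(cfg_file)
  expect_equal(nrow(cfg0$grid), 160L)
  expect_equal(cfg0$reps, 100L)

  writeLines("bogus: 1", cfg_file)
  expect_error(study_config(cfg_file), "unknown configuration")
})
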