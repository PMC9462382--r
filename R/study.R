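#' The full factorial study grid
#'
#' Crosses model specification (correct vs. incorrect), sample size,
#' group-loading magnitude and cross-loading magnitude into the 160-cell
#' design, in a fixed deterministic order.
#'
#' @param q Model-specification levels.
#' @param n Sample-size levels.
#' @param lambda Group-factor loading levels.
#' @param cross Cross-loading levels.
#' @return Data frame with one row per condition and a `condition_id` label.
#' @export
build_grid <- function(q = c("correct", "incorrect"),
                       n = c(100L, 200L, 500L, 1000L),
                       lambda = c(0.15, 0.30, 0.50, 0.60),
                       cross = c(0.05, 0.10, 0.20, 0.30, 0.40)) {
  g <- expand.grid(q = q, n = n, lambda = lambda, c = cross,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(g$q, g$n, g$lambda, g$c), , drop = FALSE]
  rownames(g) <- NULL
  g$condition_id <- sprintf("%s_N%d_l%.2f_c%.2f", g$q, g$n, g$lambda, g$c)
  g
}

## internal: run one replication attempt; returns fit + derived quantities
.run_attempt <- function(pop, pattern_est, n, seed) {
  sm <- draw_sample(pop, n, seed)
  if (sm$singular) return(list(converged = FALSE, heywood = FALSE, good = FALSE))
  fit <- bifactor_ml(sm$S, pattern_est, n = n)
  good <- fit$converged && !fit$heywood
  list(fit = fit, converged = fit$converged, heywood = fit$heywood, good = good)
}

#' Run one study cell with the good-solution replacement policy
#'
#' Draws fresh samples (each attempt under its own [seed_for()] seed) and
#' fits the cell's model variant until `reps` converged, non-Heywood
#' solutions are collected, logging every attempt for the
#' nonconvergence/Heywood analyses.  A cap of `10 * reps` attempts guards
#' against pathological cells; reaching it leaves the cell partial with a
#' warning.
#'
#' @param condition One row of [build_grid()] (or any list with `q`, `n`,
#'   `lambda`, `c`).
#' @param reps Number of good replications required.
#' @param master_seed Study-level master seed.
#' @param condition_index Integer index of the condition in the grid (drives
#'   the seed stream; distinct per cell).
#' @param variance_convention Passed to [population_model()].
#' @return List with `records` (data frame, one row per good replication:
#'   condition labels, recovery metrics and sample fit indices) and
#'   `attempts` (one row per attempt with `converged`/`heywood` flags).
#' @export
run_cell <- function(condition, reps, master_seed = 1L, condition_index = 1L,
                     variance_convention = "unit") {
  gen <- bifactor_pattern(condition$lambda, condition$c, include_cross = TRUE)
  pop <- population_model(gen, variance_convention)
  pattern_est <- gen
  pattern_est$include_cross <- condition$q == "correct"

  max_attempts <- 10L * reps
  rec <- vector("list", reps)
  att <- vector("list", max_attempts)
  good <- 0L; attempt <- 0L
  while (good < reps && attempt < max_attempts) {
    attempt <- attempt + 1L
    # the cell-global attempt counter is the replication stream index: it is
    # unique per attempt whether or not the solution is kept
    seed <- seed_for(condition_index, attempt, 1L, master_seed)
    res <- .run_attempt(pop, pattern_est, condition$n, seed)
    att[[attempt]] <- data.frame(
      q = condition$q, n = condition$n, lambda = condition$lambda,
      c = condition$c, attempt = attempt,
      converged = res$converged, heywood = res$heywood)
    if (!res$good) next
    good <- good + 1L
    rv <- recovery_for(res$fit, gen)
    ix <- fit_indices(res$fit)
    rec[[good]] <- data.frame(
      q = condition$q, n = condition$n, lambda = condition$lambda,
      c = condition$c, replication = good, attempts = attempt,
      rmsd_fgen = rv$rmsd_fgen, rmsd_fgroup = rv$rmsd_fgroup,
      rmsd_cross = rv$rmsd_cross, bias_fgen = rv$bias_fgen,
      bias_fgroup = rv$bias_fgroup, bias_cross = rv$bias_cross,
      chisq = ix$T, rmsea = ix$rmsea, cfi = ix$cfi, gfi = ix$gfi,
      srmr = ix$srmr, srmr_u = ix$srmr_u, r2_bar = ix$r2_bar,
      shi_ratio = ix$shi_ratio)
  }
  if (good < reps)
    warning(sprintf("cell %s: attempt cap reached with %d/%d good solutions",
                    condition$condition_id, good, reps))
  list(records = do.call(rbind, rec[seq_len(good)]),
       attempts = do.call(rbind, att[seq_len(attempt)]))
}

#' Run the full Monte Carlo study
#'
#' Executes every grid cell with [run_cell()].  Seeding is counter-based per
#' (cell, replication, attempt), so results are independent of execution
#' order and of the number of workers.
#'
#' @param grid Conditions to run; defaults to the full [build_grid()].
#' @param reps Good replications per cell (the scaled default is 100; the
#'   full-scale study uses 1000).
#' @param master_seed Study-level master seed.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @param variance_convention Passed to [population_model()].
#' @return Object of class `"bifactor_study"`: list with `records` (all good
#'   replications), `attempts` (all attempts), `reps`, `master_seed`,
#'   `variance_convention`.
#' @export
run_study <- function(grid = build_grid(), reps = 100L, master_seed = 1L,
                      workers = 1L, variance_convention = "unit") {
  runner <- function(i) run_cell(grid[i, ], reps, master_seed,
                                 condition_index = i,
                                 variance_convention = variance_convention)
  cells <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(grid)), runner, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(grid)), runner)
  }
  structure(list(
    records = do.call(rbind, lapply(cells, `[[`, "records")),
    attempts = do.call(rbind, lapply(cells, `[[`, "attempts")),
    reps = reps, master_seed = master_seed,
    variance_convention = variance_convention
  ), class = "bifactor_study")
}

#' @export
print.bifactor_study <- function(x, ...) {
  cat("Bifactor Monte Carlo study:", nrow(x$records), "good replications over",
      length(unique(interaction(x$records$q, x$records$n, x$records$lambda,
                                x$records$c))), "cells\n")
  cat("  reps/cell =", x$reps, " master seed =", x$master_seed,
      " variance convention =", x$variance_convention, "\n")
  bad <- nrow(x$attempts) - nrow(x$records)
  cat("  replaced attempts (nonconvergent or Heywood):", bad, "\n")
  invisible(x)
}

## internal: study records with the design columns as factors
.study_factors <- function(records) {
  records$q <- factor(records$q, levels = c("correct", "incorrect"))
  records$N <- factor(records$n)
  records$lambda <- factor(records$lambda)
  records$c <- factor(records$c)
  records
}

#' Factorial ANOVA meta-model with partial eta-squared
#'
#' Fits the fixed-effects factorial with all main effects and two-, three-
#' and four-way interactions of model specification, sample size, group
#' loading and cross-loading to one dependent variable of the study records,
#' and reports partial eta-squared `SS_effect / (SS_effect + SS_error)` per
#' term with a Cohen-style magnitude tag.  For `rmsd_cross` the `q` terms
#' are dropped and only correct-model records are used (cross-loadings are
#' estimated only there).  The replacement policy keeps the design balanced,
#' where sequential and partial sums of squares coincide; balance is
#' asserted before fitting.
#'
#' @param study A [run_study()] result (or its `records` data frame).
#' @param dv Dependent variable name, one of `rmsd_fgen`, `rmsd_fgroup`,
#'   `rmsd_cross`, `rmsea`, `cfi`, `gfi`, `srmr`, `srmr_u`.
#' @return Data frame with one row per model term: `effect`, `df`,
#'   `p_value`, `eta_sq` (partial) and `magnitude`.
#' @export
anova_eta <- function(study, dv) {
  records <- if (inherits(study, "bifactor_study")) study$records else study
  dv <- match.arg(dv, c("rmsd_fgen", "rmsd_fgroup", "rmsd_cross",
                        "rmsea", "cfi", "gfi", "srmr", "srmr_u"))
  cross_only <- dv == "rmsd_cross"
  if (cross_only) records <- records[records$q == "correct", , drop = FALSE]
  records <- .study_factors(records)
  cells <- if (cross_only) interaction(records$N, records$lambda, records$c)
           else interaction(records$q, records$N, records$lambda, records$c)
  counts <- table(cells)
  if (any(counts == 0L))
    stop("empty design cells: ", paste(utils::head(names(counts)[counts == 0L]),
                                       collapse = ", "))
  if (length(unique(counts)) != 1L)
    warning("design is unbalanced; sums of squares are sequential")
  fml <- if (cross_only) stats::reformulate("N * lambda * c", dv)
         else stats::reformulate("q * N * lambda * c", dv)
  aovfit <- stats::aov(fml, data = records)
  tab <- summary(aovfit)[[1L]]
  terms <- trimws(rownames(tab))
  resid_row <- terms == "Residuals"
  ss_err <- tab[resid_row, "Sum Sq"]
  eff <- tab[!resid_row, , drop = FALSE]
  eta <- eff[, "Sum Sq"] / (eff[, "Sum Sq"] + ss_err)
  # a DV with (numerically) no variation has every eta = 0 by convention
  dvv <- stats::var(records[[dv]], na.rm = TRUE)
  if (is.na(dvv) || dvv < 1e-20 * (1 + mean(records[[dv]], na.rm = TRUE)^2))
    eta[] <- 0
  data.frame(
    effect = terms[!resid_row],
    df = eff[, "Df"],
    p_value = eff[, "Pr(>F)"],
    eta_sq = eta,
    magnitude = vapply(eta, classify_effect, character(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Cohen-style magnitude tag for partial eta-squared
#'
#' Below 0.05: negligible; 0.05 to below 0.10: small; 0.10 to 0.20: medium;
#' above 0.20: large.
#'
#' @param eta_sq Partial eta-squared in `[0, 1]`.
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
classify_effect <- function(eta_sq) {
  if (is.na(eta_sq) || eta_sq < 0 || eta_sq > 1)
    stop("'eta_sq' must lie in [0, 1]")
  if (eta_sq < 0.05) "negligible"
  else if (eta_sq < 0.10) "small"
  else if (eta_sq <= 0.20) "medium"
  else "large"
}

#' Logit analysis of nonconvergence or Heywood incidence
#'
#' Fits a binomial GLM with main effects and two-way interactions of the
#' design factors to the per-attempt outcome, and ranks terms by their
#' sequential deviance reduction.  Quasi-separation (fitted probabilities at
#' the boundary) triggers a smoothed refit in which each design cell
#' receives two half-weight pseudo-attempts, one of each outcome.
#'
#' @param attempts The `attempts` table of a [run_study()] (or a study
#'   object).
#' @param outcome `"nonconvergence"` or `"heywood"`.
#' @return List with `model` (the glm fit), `coefficients` and `ranking`
#'   (data frame of terms ordered by deviance contribution).
#' @export
convergence_logit <- function(attempts, outcome = c("nonconvergence", "heywood")) {
  if (inherits(attempts, "bifactor_study")) attempts <- attempts$attempts
  outcome <- match.arg(outcome)
  d <- .study_factors(attempts)
  d$y <- as.integer(if (outcome == "nonconvergence") !d$converged else d$heywood)
  d$w <- 1
  form <- y ~ (q + N + lambda + c)^2
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = d, weights = w))
  if (any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)) {
    warning("boundary fitted probabilities; refitting with cell smoothing")
    cells <- unique(d[, c("q", "N", "lambda", "c")])
    smooth <- rbind(transform(cells, y = 0L, w = 0.5),
                    transform(cells, y = 1L, w = 0.5))
    d <- rbind(d[, c("q", "N", "lambda", "c", "y", "w")], smooth)
    fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                       data = d, weights = w))
  }
  dev <- suppressWarnings(stats::anova(fit))
  dtab <- as.data.frame(dev)
  dtab <- dtab[rownames(dtab) != "NULL", , drop = FALSE]
  ranking <- data.frame(term = rownames(dtab), deviance = dtab$Deviance,
                        row.names = NULL, stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$deviance), , drop = FALSE]
  list(model = fit, coefficients = stats::coef(fit), ranking = ranking)
}

#' Population-index table over the generating grid
#'
#' Computes the deterministic population fit indices of the misspecified
#' (no-cross) model for every (lambda, c) generating combination: the
#' "Population" column of the study's index figures.
#'
#' @param lambda,cross Generating levels (defaults: the study grid).
#' @param variance_convention Passed to [population_model()].
#' @return Data frame with one row per combination and the index columns.
#' @export
population_index_table <- function(lambda = c(0.15, 0.30, 0.50, 0.60),
                                   cross = c(0.05, 0.10, 0.20, 0.30, 0.40),
                                   variance_convention = "unit") {
  g <- expand.grid(lambda = lambda, c = cross, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    gen <- bifactor_pattern(g$lambda[i], g$c[i])
    ix <- population_indices(gen, variance_convention = variance_convention)
    data.frame(lambda = g$lambda[i], c = g$c[i], F0 = NA_real_,
               rmsea = ix$rmsea, cfi = ix$cfi, gfi = ix$gfi, srmr = ix$srmr,
               srmr_u = ix$srmr_u, r2_bar = ix$r2_bar,
               shi_ratio = ix$shi_ratio, shi_verdict = ix$shi_verdict)
  })
  out <- do.call(rbind, rows)
  out$F0 <- out$rmsea^2 * 42  # F0 = df * rmsea_pop^2 for the no-cross model
  out
}

#' Export study tables as delimited text
#'
#' Writes the replication-level records, the per-cell means (the plotting
#' data behind the study figures), the ANOVA meta-model table for every
#' dependent variable, the population-index table, a cutoff-verdict summary
#' and a small run manifest.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @param variance_convention Convention used for the population table.
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(study, dir = ".", variance_convention = study$variance_convention) {
  stopifnot(inherits(study, "bifactor_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(study$records, "replications.csv")

  num <- c("rmsd_fgen", "rmsd_fgroup", "rmsd_cross", "rmsea", "cfi", "gfi",
           "srmr", "srmr_u", "r2_bar", "shi_ratio")
  cell_means <- stats::aggregate(study$records[num],
                                 study$records[c("q", "n", "lambda", "c")],
                                 mean, na.rm = TRUE)
  wr(cell_means, "cell_means.csv")

  dvs <- c("rmsd_fgen", "rmsd_fgroup", "rmsd_cross", "rmsea", "cfi", "gfi",
           "srmr", "srmr_u")
  anova_tab <- do.call(rbind, lapply(dvs, function(dv) {
    cbind(dv = dv, anova_eta(study, dv))
  }))
  wr(anova_tab, "anova_eta.csv")

  wr(population_index_table(variance_convention = variance_convention),
     "population_indices.csv")

  rules <- cutoff_rules()
  pass <- cell_means
  pass$pass_rmsea <- pass$rmsea <= rules$threshold[rules$index == "rmsea"]
  pass$pass_cfi <- pass$cfi >= rules$threshold[rules$index == "cfi"]
  pass$pass_gfi <- pass$gfi >= rules$threshold[rules$index == "gfi"]
  pass$pass_srmr <- pass$srmr <= rules$threshold[rules$index == "srmr"]
  pass$shi_close <- pass$shi_ratio <= rules$threshold[rules$index == "shi_close"]
  pass$shi_adequate <- pass$shi_ratio <= rules$threshold[rules$index == "shi_adequate"]
  wr(pass, "cutoff_verdicts.csv")

  manifest <- data.frame(
    key = c("package_version", "master_seed", "reps",
            "variance_convention", "r_version"),
    value = c(as.character(utils::packageVersion("bifactorsim")),
              study$master_seed, study$reps, study$variance_convention,
              paste(R.version$major, R.version$minor, sep = ".")))
  wr(manifest, "manifest.csv")
  invisible(paths)
}

#' Read a study configuration file
#'
#' Loads a YAML file mirroring the study design table: factor levels
#' (`q`, `n`, `lambda`, `cross`), replication count (`reps`), `master_seed`
#' and `variance_convention`.  Omitted fields fall back to the package
#' defaults, so an empty file reproduces the published design.
#'
#' @param path Path to a YAML file.
#' @return List with `grid` (via [build_grid()]), `reps`, `master_seed` and
#'   `variance_convention`, ready to splice into [run_study()].
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines("reps: 10\nlambda: [0.5, 0.6]", cfg_file)
#' cfg <- study_config(cfg_file)
#' nrow(cfg$grid)   # 80: two lambda levels
#' @export
study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  known <- c("q", "n", "lambda", "cross", "reps", "master_seed",
             "variance_convention")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  grid_args <- cfg[intersect(names(cfg), c("q", "n", "lambda", "cross"))]
  list(
    grid = do.call(build_grid, grid_args),
    reps = if (is.null(cfg$reps)) 100L else as.integer(cfg$reps),
    master_seed = if (is.null(cfg$master_seed)) 1L else as.integer(cfg$master_seed),
    variance_convention = if (is.null(cfg$variance_convention)) "unit"
                          else match.arg(cfg$variance_convention,
                                         c("unit", "literal"))
  )
}
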