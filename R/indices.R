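#' Chi-square statistic from the ML discrepancy
#'
#' `T = (n - 1) * F`, the Wishart-likelihood convention matching the
#' `n - 1` divisor of the sample covariance.
#'
#' @param discrepancy Minimised ML discrepancy, non-negative.
#' @param n Sample size.
#' @return The test statistic.
#' @export
chi_square <- function(discrepancy, n) {
  if (discrepancy < 0) stop("'discrepancy' must be non-negative")
  (n - 1) * discrepancy
}

#' Root mean square error of approximation
#'
#' Sample form `sqrt(max(T - df, 0) / (df * (n - 1)))`; zero whenever the
#' statistic does not exceed its degrees of freedom.
#'
#' @param T Chi-square statistic.
#' @param df Model degrees of freedom (> 0).
#' @param n Sample size.
#' @return RMSEA value.
#' @export
rmsea <- function(T, df, n) {
  if (df <= 0) stop("'df' must be positive")
  sqrt(max(T - df, 0) / (df * (n - 1)))
}

#' Comparative fit index
#'
#' `1 - max(T - df, 0) / max(T_B - df_B, T - df, 0)` against the
#' independence baseline, clamped to `[0, 1]` and defined as 1 when both
#' noncentrality estimates vanish.
#'
#' @param T,df Statistic and degrees of freedom of the fitted model.
#' @param T_B,df_B Statistic and degrees of freedom of the baseline model.
#' @return CFI value in `[0, 1]`.
#' @export
cfi <- function(T, df, T_B, df_B) {
  num <- max(T - df, 0)
  den <- max(T_B - df_B, T - df, 0)
  if (den == 0) return(1)
  min(max(1 - num / den, 0), 1)
}

#' Goodness-of-fit index (ML form)
#'
#' `1 - tr[(Sigma_hat^-1 S - I)^2] / tr[(Sigma_hat^-1 S)^2]`.
#'
#' @param S Observed covariance matrix.
#' @param sigma_hat Fitted covariance matrix (positive definite).
#' @return GFI value (at most 1).
#' @export
gfi <- function(S, sigma_hat) {
  W <- tryCatch(solve(sigma_hat, S), error = function(e) NULL)
  if (is.null(W)) stop("fitted covariance is singular")
  D <- W - diag(nrow(W))
  1 - sum(D * t(D)) / sum(W * t(W))
}

#' Standardized root mean square residual (naive sample estimator)
#'
#' Root of the mean squared correlation-metric residual
#' `(s_ij - sigma_ij)/sqrt(s_ii s_jj)` over the `p(p + 1)/2` non-duplicated
#' elements.  The diagonal is included by default (its residuals vanish only
#' when the model reproduces the sample variances); set
#' `include_diagonal = FALSE` for the off-diagonal-only variant.
#'
#' @param S Observed covariance matrix with positive diagonal.
#' @param sigma_hat Fitted covariance matrix.
#' @param include_diagonal Include diagonal residuals (default `TRUE`).
#' @return SRMR value.
#' @export
srmr <- function(S, sigma_hat, include_diagonal = TRUE) {
  d <- sqrt(diag(S))
  E <- (S - sigma_hat) / tcrossprod(d)
  keep <- if (include_diagonal) lower.tri(E, diag = TRUE) else lower.tri(E)
  sqrt(mean(E[keep]^2))
}

## internal: columns of the vech-metric Jacobian d vech Sigma / d theta and
## the Fisher information 0.5 tr(SigInv dSig_a SigInv dSig_b) at (Lambda, Sigma)
.model_jacobian_at <- function(Lambda, Sigma, idx) {
  p <- idx$p
  keep <- which(lower.tri(diag(p), diag = TRUE))
  q <- idx$n_load + p
  Delta <- matrix(0, length(keep), q)
  dSig <- vector("list", q)
  ij <- which(idx$mask, arr.ind = TRUE)
  for (a in seq_len(idx$n_load)) {
    i <- ij[a, 1L]; k <- ij[a, 2L]
    dS <- matrix(0, p, p)
    dS[i, ] <- Lambda[, k]
    dS[, i] <- dS[, i] + Lambda[, k]
    dSig[[a]] <- dS
    Delta[, a] <- dS[keep]
  }
  for (i in seq_len(p)) {
    dS <- matrix(0, p, p)
    dS[i, i] <- 1
    dSig[[idx$n_load + i]] <- dS
    Delta[, idx$n_load + i] <- dS[keep]
  }
  SigInv <- tryCatch(chol2inv(chol(Sigma)), error = function(e) solve(Sigma))
  V <- vapply(dSig, function(dS) as.numeric(dS), numeric(p * p))
  Wm <- vapply(dSig, function(dS) as.numeric(SigInv %*% dS %*% SigInv),
               numeric(p * p))
  info <- 0.5 * crossprod(V, Wm)
  info <- (info + t(info)) / 2
  list(Delta = Delta, info = info, keep = keep)
}

.model_jacobian <- function(fit) {
  .model_jacobian_at(fit$Lambda, fit$Sigma_hat, .par_index(fit$pattern))
}

#' Asymptotically unbiased SRMR estimator
#'
#' Debiases the naive [srmr()] by subtracting from each squared standardized
#' residual an estimate of its sampling variance before averaging, with
#' truncation at zero: `SRMR_u = sqrt(max(0, mean(r_ij^2 - v_ij)))`.
#'
#' The variance estimates come from the normal-theory asymptotic covariance
#' of the non-duplicated sample moments, `Gamma`, projected through the
#' model: with `Delta = d vech Sigma(theta)/d theta` at the estimate and
#' `Gamma^-1` the ML weight matrix, the residual covariance is
#' `Omega = Gamma - Delta (Delta' Gamma^-1 Delta)^-1 Delta'`, whose diagonal
#' is rescaled to the correlation metric and divided by the effective sample
#' size `n - 1` (the divisor of `S`).  For a population-level fit there is
#' no sampling variance and the value equals [srmr()] exactly.
#'
#' @param S Observed covariance matrix.
#' @param fit A converged [bifactor_ml()] result for `S`.
#' @param n Sample size; `NULL` (population level) returns the naive SRMR.
#' @param include_diagonal Include diagonal residuals (default `TRUE`).
#' @return SRMR_u value.
#' @export
srmr_unbiased <- function(S, fit, n = fit$n, include_diagonal = TRUE) {
  stopifnot(inherits(fit, "bifactor_fit"))
  S <- as.matrix(S)
  if (is.null(n)) return(srmr(S, fit$Sigma_hat, include_diagonal))
  p <- nrow(S)
  jac <- .model_jacobian(fit)
  Sig <- fit$Sigma_hat
  ii <- row(Sig)[jac$keep]; jj <- col(Sig)[jac$keep]
  # diag of Gamma (normal theory): var of s_ij per unit of 1/(n-1)
  gdiag <- Sig[cbind(ii, ii)] * Sig[cbind(jj, jj)] + Sig[jac$keep]^2
  A <- tryCatch(solve(jac$info), error = function(e) {
    warning("singular information matrix; using pseudo-inverse")
    ev <- eigen(jac$info, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    ev$vectors[, pos] %*% (t(ev$vectors[, pos]) / ev$values[pos])
  })
  omega_diag <- pmax(0, gdiag - rowSums((jac$Delta %*% A) * jac$Delta))
  d <- sqrt(diag(S))
  denom <- (d[ii] * d[jj])^2
  r2 <- ((S - Sig)[jac$keep])^2 / denom
  v <- omega_diag / ((n - 1) * denom)
  use <- if (include_diagonal) rep(TRUE, length(r2)) else ii != jj
  sqrt(max(0, mean(r2[use] - v[use])))
}

#' Average communality of a fitted model
#'
#' Mean over items of `1 - theta_i / sigma_ii` with `sigma_ii` the fitted
#' item variance.  Per-item values outside `[0, 1]` (possible for Heywood
#' solutions) are clamped with a warning.
#'
#' @param fit A [bifactor_ml()] result.
#' @return Average communality.
#' @export
average_communality <- function(fit) {
  stopifnot(inherits(fit, "bifactor_fit"))
  h2 <- 1 - fit$theta / diag(fit$Sigma_hat)
  if (any(h2 < 0 | h2 > 1)) {
    if (any(fit$theta < 0))
      warning("per-item communalities outside [0, 1] clamped (Heywood solution)")
    h2 <- pmin(pmax(h2, 0), 1)
  }
  mean(h2)
}

#' Communality-corrected SRMR ratio and verdict
#'
#' The corrected index `SRMR_u / R2_bar` with cutoffs 0.05 (close fit) and
#' 0.10 (adequate fit); values above 0.10 are classed poor.
#'
#' @param srmr_u Unbiased SRMR value.
#' @param r2_bar Average communality (> 0).
#' @return List with `ratio` and `verdict` in `c("close", "adequate", "poor")`.
#' @export
shi_ratio <- function(srmr_u, r2_bar) {
  if (r2_bar < 1e-8) {
    warning("average communality is (near) zero; fit classed poor")
    return(list(ratio = Inf, verdict = "poor"))
  }
  ratio <- srmr_u / r2_bar
  verdict <- if (ratio <= 0.05) "close" else if (ratio <= 0.10) "adequate" else "poor"
  list(ratio = ratio, verdict = verdict)
}

#' Shipped cutoff conventions
#'
#' The conventional decision rules applied in the study summaries: the
#' Hu-Bentler single-index cutoffs, the two communality-corrected SRMR
#' cutoffs, and the RMSD recovery threshold.
#'
#' @return Data frame with columns `index`, `threshold`, `direction`
#'   (`"le"` means values at or below the threshold pass).
#' @export
cutoff_rules <- function() {
  data.frame(
    index = c("rmsea", "cfi", "gfi", "srmr", "shi_close", "shi_adequate", "rmsd"),
    threshold = c(0.05, 0.95, 0.95, 0.08, 0.05, 0.10, 0.20),
    direction = c("le", "ge", "ge", "le", "le", "le", "le"),
    stringsAsFactors = FALSE
  )
}

#' Goodness-of-fit index set for a fitted model
#'
#' Computes the full index battery for a fit: chi-square statistic, RMSEA,
#' CFI (against the independence baseline on the same input matrix), GFI,
#' naive SRMR, unbiased SRMR, average communality and the corrected SRMR
#' ratio.  For a population-level fit (`n` absent) the population forms are
#' used: `RMSEA = sqrt(F0/df)`, `CFI = 1 - F0/F0_B`, and `SRMR_u` equals the
#' naive SRMR (no sampling error).
#'
#' @param fit A [bifactor_ml()] result.
#' @return Object of class `"fit_index_set"`: list with `T`, `df`, `rmsea`,
#'   `cfi`, `gfi`, `srmr`, `srmr_u`, `r2_bar`, `shi_ratio`, `shi_verdict`,
#'   `level`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "bifactor_fit"))
  df <- model_df(fit$pattern)
  S <- fit$S
  base <- baseline_statistics(S, fit$n)
  F0 <- fit$discrepancy
  if (is.null(fit$n)) {
    Tval <- NA_real_
    rm <- sqrt(F0 / df)
    cf <- if (base$F_B == 0) 1 else min(max(1 - F0 / base$F_B, 0), 1)
    level <- "population"
  } else {
    Tval <- chi_square(F0, fit$n)
    rm <- rmsea(Tval, df, fit$n)
    cf <- cfi(Tval, df, base$T_B, base$df_B)
    level <- "sample"
  }
  sr <- srmr(S, fit$Sigma_hat)
  sru <- srmr_unbiased(S, fit, fit$n)
  r2 <- average_communality(fit)
  shi <- shi_ratio(sru, r2)
  structure(list(T = Tval, df = df, rmsea = rm, cfi = cf,
                 gfi = gfi(S, fit$Sigma_hat), srmr = sr, srmr_u = sru,
                 r2_bar = r2, shi_ratio = shi$ratio,
                 shi_verdict = shi$verdict, level = level),
            class = "fit_index_set")
}

#' @export
print.fit_index_set <- function(x, ...) {
  cat("Fit indices (", x$level, " level)\n", sep = "")
  if (!is.na(x$T)) cat(sprintf("  chi-square = %.3f on %d df\n", x$T, x$df))
  cat(sprintf("  RMSEA = %.4f  CFI = %.4f  GFI = %.4f\n", x$rmsea, x$cfi, x$gfi))
  cat(sprintf("  SRMR = %.4f  SRMR_u = %.4f  R2_bar = %.3f\n",
              x$srmr, x$srmr_u, x$r2_bar))
  cat(sprintf("  SRMR_u / R2_bar = %.4f (%s fit)\n", x$shi_ratio, x$shi_verdict))
  invisible(x)
}

#' Population-level fit indices for a model variant
#'
#' Fits `fitted_structure` to the population covariance implied by
#' `generating` (which always contains the true cross-loadings) and returns
#' the population index set: these are the deterministic "Population column"
#' values of the study, free of sampling error.
#'
#' @param generating A [bifactor_pattern()] with the generating values.
#' @param fitted_structure Pattern defining the estimated structure; defaults
#'   to the misspecified (no-cross) variant of `generating`.
#' @param variance_convention Passed to [population_model()].
#' @return A `"fit_index_set"` with `level = "population"`.
#'
#' @examples
#' gen <- bifactor_pattern(0.60, 0.40)
#' population_indices(gen, gen)    # correct model: perfect fit
#' population_indices(gen)         # misspecified: F0 > 0
#' @export
population_indices <- function(generating, fitted_structure = NULL,
                               variance_convention = c("unit", "literal")) {
  stopifnot(inherits(generating, "bifactor_pattern"))
  if (is.null(fitted_structure)) {
    fitted_structure <- generating
    fitted_structure$include_cross <- FALSE
  }
  pop <- population_model(generating, match.arg(variance_convention))
  fit <- bifactor_ml(pop$Sigma, fitted_structure, n = NULL)
  fit_indices(fit)
}

#' RMSEA confidence interval (not implemented)
#'
#' Declared for interface completeness; interval estimation and the test of
#' close fit are outside the scope of this package.
#'
#' @param ... Ignored.
#' @export
rmsea_ci <- function(...) {
  stop("RMSEA confidence intervals are not implemented in this package")
}
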