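#' Model-implied covariance matrix
#'
#' For an orthogonal factor model, `Sigma = Lambda Lambda' + diag(theta)`.
#'
#' @param Lambda Loading matrix (items by factors).
#' @param theta Vector of unique variances, one per item.
#' @return Symmetric covariance matrix.
#' @export
implied_covariance <- function(Lambda, theta) {
  Lambda <- as.matrix(Lambda)
  if (length(theta) != nrow(Lambda))
    stop("'theta' must have one entry per row of 'Lambda'")
  S <- tcrossprod(Lambda)
  diag(S) <- diag(S) + theta
  (S + t(S)) / 2
}

#' Construct the population bifactor model
#'
#' Assembles the population loading matrix, unique variances and implied
#' covariance matrix for a pattern's generating values.  The population model
#' always contains the cross-loadings; `include_cross` on the pattern only
#' matters at estimation time.
#'
#' Two conventions for the unique (error) variances are available:
#' \describe{
#'   \item{`"unit"`}{`theta_i = 1 - sum of squared generating loadings of
#'     item i`, so every observed variable has unit total variance and
#'     communalities read directly off the loadings.  This is the default.}
#'   \item{`"literal"`}{`theta_i = 1 - lambda_i^2` with `lambda_i` the
#'     item's primary group-factor loading only; item variances then exceed 1
#'     for items with a general loading or cross-loading.  Kept for
#'     sensitivity analysis.}
#' }
#'
#' @param pattern A [bifactor_pattern()] carrying the generating values.
#' @param variance_convention `"unit"` (default) or `"literal"`; see Details.
#' @return An object of class `"bifactor_population"`: list with `Lambda`
#'   (items x factors), `theta`, `Sigma`, the `pattern` and the convention.
#'
#' @examples
#' pop <- population_model(bifactor_pattern(0.60, 0.40))
#' range(diag(pop$Sigma))   # exactly 1 under the unit convention
#' @export
population_model <- function(pattern,
                             variance_convention = c("unit", "literal")) {
  stopifnot(inherits(pattern, "bifactor_pattern"))
  variance_convention <- match.arg(variance_convention)
  L <- generating_loadings(pattern)
  theta <- switch(variance_convention,
    unit = 1 - rowSums(L^2),
    literal = 1 - pattern$group_loading^2
  )
  if (any(theta <= 0))
    stop(sprintf(
      "non-positive unique variance under the '%s' convention (lambda = %.2f, c = %.2f)",
      variance_convention, pattern$group_loading[1L],
      pattern$cross_loadings$value[1L]))
  Sigma <- implied_covariance(L, theta)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf(
      "population covariance not positive definite (lambda = %.2f, c = %.2f)",
      pattern$group_loading[1L], pattern$cross_loadings$value[1L]))
  structure(list(Lambda = L, theta = theta, Sigma = Sigma,
                 pattern = pattern,
                 variance_convention = variance_convention),
            class = "bifactor_population")
}

#' @export
print.bifactor_population <- function(x, ...) {
  cat("Population bifactor model (", x$variance_convention,
      " variance convention)\n", sep = "")
  print(x$pattern)
  cat("  unique variances:", paste(format(unique(round(x$theta, 6))),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Write population matrices as plain text
#'
#' Dumps the loading matrix, unique variances and implied covariance of a
#' population model to three whitespace-delimited text files for inspection
#' or cross-checking with external SEM software.
#'
#' @param population A [population_model()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the paths written.
#' @export
write_population <- function(population, dir = ".", prefix = "population") {
  stopifnot(inherits(population, "bifactor_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("lambda", "theta", "sigma"), ".txt"))
  utils::write.table(population$Lambda, paths[1L],
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(matrix(population$theta, ncol = 1L), paths[2L],
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(population$Sigma, paths[3L],
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
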