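#' Draw a multivariate-normal sample and its covariance moments
#'
#' Generates `n` i.i.d. observations from N(0, Sigma) for the given
#' population model via the Cholesky factor of Sigma and returns the sample
#' covariance matrix (divisor `n - 1`).  Only the second-order moments are
#' retained: normal-theory ML estimation and all fit indices depend on the
#' data through `S` and `n` alone.
#'
#' @param population A [population_model()].
#' @param n Sample size (at least `p + 1` is recommended so `S` is almost
#'   surely positive definite; any `n >= 2` is accepted).
#' @param seed Integer seed; the draw is a deterministic function of
#'   `(population, n, seed)`.
#' @param keep_data If `TRUE` the raw data matrix is attached (for
#'   distributional checks or export); by default it is discarded.
#' @return Object of class `"sample_moments"`: list with `S`, `n`,
#'   `seed_used`, `condition_id` (label of the generating condition) and
#'   `singular` (flag set when `S` is numerically rank-deficient).
#'
#' @examples
#' pop <- population_model(bifactor_pattern(0.60, 0.20))
#' sm <- draw_sample(pop, n = 200, seed = 7)
#' dim(sm$S)
#' @export
draw_sample <- function(population, n, seed, keep_data = FALSE) {
  stopifnot(inherits(population, "bifactor_population"))
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2")
  R <- chol(population$Sigma)
  p <- ncol(R)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  X <- matrix(rnorm(n * p), n, p) %*% R
  S <- stats::cov(X)  # divisor n - 1
  singular <- inherits(try(chol(S), silent = TRUE), "try-error")
  pat <- population$pattern
  out <- structure(list(
    S = S, n = n, seed_used = as.integer(seed),
    condition_id = sprintf("lambda%.2f_c%.2f_N%d",
                           pat$group_loading[1L],
                           pat$cross_loadings$value[1L], n),
    singular = singular
  ), class = "sample_moments")
  if (keep_data) out$data <- X
  out
}

#' @export
print.sample_moments <- function(x, ...) {
  cat("Sample moments: N =", x$n, " p =", nrow(x$S),
      " seed =", x$seed_used, "\n")
  if (x$singular) cat("  [singular sample covariance]\n")
  invisible(x)
}

#' Deterministic seed for one replication attempt
#'
#' Counter-based seed derivation: each (condition, replication, attempt)
#' triple maps injectively to a seed below 2^31 derived from a single
#' study-level master seed, so a study is byte-reproducible and cells can be
#' executed in any order or in parallel.
#'
#' @param condition Integer condition index (1-based position in the grid).
#' @param replication Replication index within the cell.
#' @param attempt Attempt counter (incremented when a nonconvergent or
#'   Heywood solution is replaced).
#' @param master_seed Study-level master seed.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
seed_for <- function(condition, replication, attempt = 1L, master_seed = 1L) {
  # idx is injective for condition <= 2^12, replication <= 2^14, attempt <= 2^5
  idx <- ((as.numeric(condition) - 1) * 16384 + (as.numeric(replication) - 1)) * 32 +
    (as.numeric(attempt) - 1)
  m <- 2147483647  # 2^31 - 1, prime
  # multiplication by a unit mod m is a bijection; products stay below 2^53
  as.integer((as.numeric(master_seed) %% m + (idx %% m) * 48271) %% m)
}

#' Write a raw sample as delimited text
#'
#' Convenience writer for cross-checking against external SEM software:
#' items as columns, observations as rows, tab-separated.
#'
#' @param sample A [draw_sample()] result created with `keep_data = TRUE`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_sample <- function(sample, path) {
  stopifnot(inherits(sample, "sample_moments"))
  if (is.null(sample$data))
    stop("sample was drawn with 'keep_data = FALSE'; no raw data to write")
  utils::write.table(sample$data, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
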