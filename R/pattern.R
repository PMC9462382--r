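#' Define a bifactor loading pattern
#'
#' Constructs the measurement structure used throughout the package: an
#' orthogonal bifactor model with one general factor on which every item
#' loads, `n_group` group factors with an equal number of primary indicators
#' each, and exactly one cross-loading per group factor.  The pattern carries
#' both the generating (population) loading values and the estimation
#' structure: when `include_cross = FALSE` the cross-loadings are fixed to
#' zero at estimation time, which is the model misspecification under study.
#'
#' Cross-loading placement follows a fixed cyclic convention: the last
#' primary indicator of group factor g cross-loads on group factor g + 1
#' (wrapping around), so with 12 items the 4th item cross-loads on group 2,
#' the 8th on group 3 and the 12th on group 1.  Any fixed placement is
#' exchangeable by the symmetry of the design.
#'
#' @param lambda_group Generating loading on the primary group factor,
#'   shared by all items; must lie in (0, 1).
#' @param cross Generating value of the three cross-loadings; in \[0, 1).
#' @param include_cross Logical; if `TRUE` the cross-loadings are free
#'   parameters of the estimated model (correct specification), if `FALSE`
#'   they are fixed to zero (misspecified model).  The population model
#'   always contains them.
#' @param general Generating loading on the general factor (default 0.60).
#' @param n_items Number of observed variables (default 12).
#' @param n_group Number of group factors (default 3); must divide `n_items`.
#'
#' @return An object of class `"bifactor_pattern"`: a list with the item
#'   count, group assignment, generating loadings, cross-loading table
#'   (`item`, `factor`, `value`) and the `include_cross` flag.
#'
#' @examples
#' pat <- bifactor_pattern(0.60, 0.40)
#' n_free_parameters(pat)   # 39
#' model_df(pat)            # 39
#' @export
bifactor_pattern <- function(lambda_group, cross, include_cross = TRUE,
                             general = 0.60, n_items = 12L, n_group = 3L) {
  n_items <- as.integer(n_items)
  n_group <- as.integer(n_group)
  if (n_items %% n_group != 0L)
    stop("'n_items' must be a multiple of 'n_group'")
  if (!is.numeric(lambda_group) || length(lambda_group) != 1L ||
      lambda_group <= 0 || lambda_group >= 1)
    stop("'lambda_group' must be a single value in (0, 1)")
  if (!is.numeric(cross) || length(cross) != 1L || cross < 0 || cross >= 1)
    stop("'cross' must be a single value in [0, 1)")
  per <- n_items %/% n_group
  group <- rep(seq_len(n_group), each = per)
  # cyclic cross-loading placement: last indicator of each group -> next group
  cross_item <- per * seq_len(n_group)
  cross_factor <- c(seq_len(n_group)[-1L], 1L)
  cl <- data.frame(item = cross_item, factor = cross_factor, value = cross)

  pat <- structure(list(
    n_items = n_items,
    n_group_factors = n_group,
    general_loading = rep(general, n_items),
    group_assignment = group,
    group_loading = rep(lambda_group, n_items),
    cross_loadings = cl,
    include_cross = isTRUE(include_cross)
  ), class = "bifactor_pattern")

  # generating values must leave positive unique variance under the
  # unit-variance convention
  comm <- rowSums(generating_loadings(pat)^2)
  if (any(comm >= 1))
    stop("generating loadings imply non-positive unique variance (communality >= 1)")
  pat
}

#' Generating loading matrix of a pattern
#'
#' The population loading matrix implied by a pattern's generating values.
#' Column 1 is the general factor, columns 2..(1 + n_group) the group
#' factors.  Cross-loadings are always present here: the population model
#' contains them regardless of `include_cross`, which only governs the
#' estimation structure.
#'
#' @param pattern A [bifactor_pattern()].
#' @return Numeric matrix, `n_items` by `1 + n_group_factors`.
#' @export
generating_loadings <- function(pattern) {
  stopifnot(inherits(pattern, "bifactor_pattern"))
  p <- pattern$n_items
  m <- 1L + pattern$n_group_factors
  L <- matrix(0, p, m)
  L[, 1L] <- pattern$general_loading
  L[cbind(seq_len(p), 1L + pattern$group_assignment)] <- pattern$group_loading
  cl <- pattern$cross_loadings
  L[cbind(cl$item, 1L + cl$factor)] <- cl$value
  L
}

#' Free-loading mask of the estimated model
#'
#' Logical matrix marking which loading entries are free parameters when the
#' pattern is fitted: all general loadings, all primary group loadings, and
#' the cross-loadings only when `include_cross` is `TRUE`.
#'
#' @param pattern A [bifactor_pattern()].
#' @return Logical matrix of the same shape as [generating_loadings()].
#' @export
loading_mask <- function(pattern) {
  stopifnot(inherits(pattern, "bifactor_pattern"))
  p <- pattern$n_items
  m <- 1L + pattern$n_group_factors
  M <- matrix(FALSE, p, m)
  M[, 1L] <- TRUE
  M[cbind(seq_len(p), 1L + pattern$group_assignment)] <- TRUE
  if (pattern$include_cross) {
    cl <- pattern$cross_loadings
    M[cbind(cl$item, 1L + cl$factor)] <- TRUE
  }
  M
}

#' Number of free parameters of the estimated model
#'
#' Free loadings (per [loading_mask()]) plus one unique variance per item.
#' Factor variances are fixed at 1 and factors are orthogonal, so no factor
#' covariance parameters exist.
#'
#' @param pattern A [bifactor_pattern()].
#' @return Integer count.
#' @export
n_free_parameters <- function(pattern) {
  sum(loading_mask(pattern)) + pattern$n_items
}

#' Model degrees of freedom
#'
#' `p(p + 1)/2` non-duplicated covariance moments minus the number of free
#' parameters.
#'
#' @param pattern A [bifactor_pattern()].
#' @return Integer degrees of freedom; an error if negative.
#' @export
model_df <- function(pattern) {
  p <- pattern$n_items
  df <- (p * (p + 1L)) %/% 2L - n_free_parameters(pattern)
  if (df < 0L) stop("model has negative degrees of freedom")
  as.integer(df)
}

#' @export
print.bifactor_pattern <- function(x, ...) {
  cat("Bifactor pattern:", x$n_items, "items,", x$n_group_factors,
      "group factors (orthogonal)\n")
  cat("  general loading :", format(x$general_loading[1L]), "\n")
  cat("  group loading   :", format(x$group_loading[1L]), "\n")
  cat("  cross-loadings  :", format(x$cross_loadings$value[1L]),
      "on items", paste(x$cross_loadings$item, collapse = ", "),
      "-> groups", paste(x$cross_loadings$factor, collapse = ", "), "\n")
  cat("  estimation      :",
      if (x$include_cross) "correct (cross-loadings free)"
      else "misspecified (cross-loadings fixed to 0)", "\n")
  cat("  free parameters :", n_free_parameters(x), " df:", model_df(x), "\n")
  invisible(x)
}
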