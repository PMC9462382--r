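# Shared fixtures built in code.

# The study grid of generating conditions (lambda x cross combinations).
generating_grid <- function() {
  expand.grid(lambda = c(0.15, 0.30, 0.50, 0.60),
              c = c(0.05, 0.10, 0.20, 0.30, 0.40),
              KEEP.OUT.ATTRS = FALSE)
}

# One scaled full-grid study, computed once and shared by the acceptance
# tests (50 good replications per cell under a fixed master seed).
scaled_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(run_study(reps = 50L, master_seed = 101L))
    cache
  }
})

# Random SPD matrix of order p (for discrepancy property checks).
random_spd <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(scale, p)
}
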