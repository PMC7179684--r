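# shared fixtures: unique population configurations of the study design and
# small helpers used across test files

study_population_configs <- function() {
  cfg <- simulation_config()
  g <- unique(design_grid(cfg)[, c("vars_per_factor", "n_factors",
                                   "loading", "factor_corr")])
  rownames(g) <- NULL
  g
}

population_from_row <- function(row) {
  population_model(row$vars_per_factor, row$n_factors, row$loading,
                   row$factor_corr)
}

# a reproducible sample correlation matrix from a study-style population
random_sample_corr <- function(seed, n = 10, vars_per_factor = 4,
                               n_factors = 2, loading = 0.55,
                               factor_corr = 0.5) {
  pop <- population_model(vars_per_factor, n_factors, loading, factor_corr)
  sample_dataset(pop$implied_corr, n, seed)$sample_corr
}

# independent numerical minimizer of the quartimin criterion over oblique
# transforms (unit-length columns), used as a rotation oracle
oblique_quartimin_oracle <- function(A, n_starts = 25, seed = 42) {
  m <- ncol(A)
  obj <- function(par) {
    Tm <- matrix(par, m, m)
    nrm <- sqrt(colSums(Tm^2))
    if (any(nrm < 1e-8)) return(1e6)
    Tm <- Tm %*% diag(1 / nrm, m)
    Ti <- tryCatch(solve(Tm), error = function(e) NULL)
    if (is.null(Ti)) return(1e6)
    quartimin_criterion(A %*% t(Ti))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    par0 <- as.vector(diag(m)) + stats::rnorm(m * m, 0, 0.3)
    o <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}
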