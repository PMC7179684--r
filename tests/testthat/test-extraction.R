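test_that("SMC-based tentative unique variances match direct inversion", {
  expect_equal(smc_unique_variances(diag(5)), rep(1, 5))

  R <- matrix(c(1, 0.6, 0.6, 1), 2)
  # oracle: SMC = 1 - 1/(R^-1)_ii by explicit inversion
  smc <- 1 - 1 / diag(solve(R))
  expect_equal(smc, rep(0.36, 2), tolerance = 1e-12)
  expect_equal(smc_unique_variances(R), rep(0.64, 2), tolerance = 1e-12)

  # exchangeable population: all entries equal
  pop <- population_model(4, 2, 0.7, 0.5)
  u <- smc_unique_variances(pop$implied_corr)
  expect_lt(diff(range(u)), 1e-12)
  expect_true(all(u > 0 & u <= 1))

  # singular input is handled by the ridge and stays in bounds
  X <- matrix(rnorm(5 * 8), 5, 8)
  Rs <- sample_correlation(X)
  us <- smc_unique_variances(Rs)
  expect_true(all(us >= 1e-6 & us <= 1))
})

test_that("ULS principal factoring recovers the population solution", {
  pop <- population_model(4, 2, 0.7, 0.5)
  fit <- uls_extract(pop$implied_corr, 2, tol = 1e-10)
  expect_true(fit$converged)
  expect_true(fit$proper)
  expect_equal(fit$unique_vars, rep(0.51, 8), tolerance = 1e-4)
  # oracle: the population reduced matrix has exact rank 2; its top
  # eigenspace is the population loading space
  Rstar <- pop$implied_corr - diag(pop$unique_variances)
  e <- eigen(Rstar, symmetric = TRUE)
  oracleL <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  Tm <- orthogonal_procrustes(fit$pattern, oracleL)
  expect_lt(max(abs(fit$pattern %*% Tm - oracleL)), 1e-3)
})

test_that("ULS honours the iteration cap and flags Heywood solutions", {
  pop <- population_model(4, 2, 0.7, 0.5)
  fit0 <- uls_extract(pop$implied_corr, 2, max_iter = 0)
  expect_false(fit0$converged)
  expect_false(fit0$proper)

  expect_error(uls_extract(diag(3), 3), "smaller than")

  # small-sample Heywood frequency: weakly determined factors at N=10 are
  # improper much of the time
  pop2 <- population_model(4, 4, 0.55, 0.5)
  improper <- 0
  for (i in 1:30) {
    ds <- sample_dataset(pop2$implied_corr, 10, 400 + i)
    if (!uls_extract(ds$sample_corr, 4)$proper) improper <- improper + 1
  }
  expect_gt(improper / 30, 0.3)
})

test_that("ULS criterion decreases monotonically on sampled inputs", {
  for (i in 1:20) {
    R <- random_sample_corr(600 + i, n = 15)
    fit <- uls_extract(R, 2, tol = 1e-8)
    expect_true(all(diff(fit$criterion_trace) <= 1e-12))
  }
})

test_that("ML discrepancy matches its closed form and brute force", {
  pop <- population_model(4, 2, 0.4, 0.3)
  R <- pop$implied_corr
  p <- nrow(R)
  expect_equal(ml_discrepancy(R, R), determinant(R)$modulus[1] + p,
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(ml_discrepancy(diag(4), diag(4)), 4)

  # brute-force oracle with explicit inversion on a random PD pair
  set.seed(5)
  A <- crossprod(matrix(rnorm(36), 6)) / 6 + diag(6)
  B <- crossprod(matrix(rnorm(36), 6)) / 6 + diag(6)
  brute <- log(det(B)) + sum(diag(A %*% solve(B)))
  expect_equal(ml_discrepancy(A, B), brute, tolerance = 1e-10)

  expect_error(ml_discrepancy(diag(2), matrix(c(1, 2, 2, 1), 2)),
               "eigenvalue")
})

test_that("REFA recovers exactly representable unique variances", {
  # equal loadings + equicorrelated factors: the true model is on the
  # shrinkage path, so lambda* * Lhat must recover psi = 1 - l^2 = 0.84
  pop <- population_model(4, 2, 0.4, 0.3)
  rf <- refa_extract(pop$implied_corr, 2)
  expect_true(rf$result$proper)
  expect_equal(rf$result$unique_vars, rep(0.84, 8), tolerance = 2e-3)
  # at the exact fit the discrepancy attains its analytic minimum
  expect_equal(rf$result$criterion,
               determinant(pop$implied_corr)$modulus[1] + 8,
               ignore_attr = TRUE, tolerance = 1e-4)
  # lambda_star minimizes the evaluated path
  expect_lte(rf$result$criterion, min(rf$regfit$discrepancy_values))
})

test_that("REFA approaches truncated principal components as lambda -> 0", {
  R <- random_sample_corr(42, n = 40)
  tiny <- refa_extract(R, 2, lambda_grid = c(1e-8, 1e-7))$result
  e <- eigen(R, symmetric = TRUE)
  pca <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  Tm <- orthogonal_procrustes(tiny$pattern, pca)
  expect_lt(max(abs(tiny$pattern %*% Tm - pca)), 1e-4)
})

test_that("REFA never produces improper solutions on small-sample input", {
  configs <- study_population_configs()
  set.seed(88)
  for (i in 1:60) {
    row <- configs[sample(nrow(configs), 1), ]
    pop <- population_from_row(row)
    ds <- sample_dataset(pop$implied_corr, sample(c(10, 20), 1),
                         700000 + i)
    rf <- refa_extract(ds$sample_corr, row$n_factors)
    expect_true(rf$result$proper)
    expect_true(all(rf$result$unique_vars > 0))
    expect_true(all(rf$regfit$tentative_uniques > 0 &
                    rf$regfit$tentative_uniques <= 1))
  }
})

test_that("selected shrinkage is insensitive to doubling the grid", {
  for (i in 1:5) {
    R <- random_sample_corr(900 + i, n = 25)
    a <- refa_extract(R, 2, n_grid = 60)$regfit
    b <- refa_extract(R, 2, n_grid = 120)$regfit
    step <- diff(log(a$lambda_grid))[1]
    expect_lt(abs(log(a$lambda_star) - log(b$lambda_star)), step)
  }
})
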