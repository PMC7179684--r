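#' Tentative unique variances from squared multiple correlations
#'
#' The classic non-iterative communality starting point: each variable's
#' squared multiple correlation (SMC) with all the others is read off the
#' inverse correlation matrix, and the tentative unique variance is `1 - SMC`.
#' When `R` is singular (as it must be whenever `N <= p`) a small ridge is
#' added before inversion.
#'
#' @param R `p x p` correlation matrix (symmetric, unit diagonal).
#' @param method `"smc"` (default) or `"maxcor"`, the highest-correlation
#'   heuristic `1 - max_j |r_ij|`.
#' @param ridge Ridge constant added to the diagonal when `R` is not
#'   numerically invertible.
#' @return Length-`p` vector of tentative unique variances, clipped to
#'   `(1e-6, 1]`.
#' @export
smc_unique_variances <- function(R, method = c("smc", "maxcor"),
                                 ridge = 1e-3) {
  R <- as.matrix(R)
  method <- match.arg(method)
  p <- nrow(R)
  if (max(abs(diag(R) - 1)) > 1e-8) stop("'R' must have unit diagonal")
  if (method == "maxcor") {
    A <- abs(R); diag(A) <- 0
    u <- 1 - apply(A, 1, max)
  } else {
    ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    Rr <- if (ev_min > 1e-8) R else R + diag(ridge, p)
    d <- diag(solve(Rr))
    u <- 1 / d                    # 1 - SMC with SMC = 1 - 1/(R^-1)_ii
  }
  pmin(pmax(u, 1e-6), 1)
}

new_extraction_result <- function(pattern, unique_vars, converged, proper,
                                  n_iter, criterion, criterion_trace,
                                  method_tag) {
  structure(list(
    pattern = pattern, unique_vars = unique_vars, converged = converged,
    proper = proper, n_iter = n_iter, criterion = criterion,
    criterion_trace = criterion_trace, method_tag = method_tag
  ), class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("%s extraction: %d variables, %d factor(s)\n", x$method_tag,
              nrow(x$pattern), ncol(x$pattern)))
  cat(sprintf("  converged = %s, proper = %s, iterations = %d\n",
              x$converged, x$proper, x$n_iter))
  cat(sprintf("  final criterion = %.6g, min unique variance = %.4f\n",
              x$criterion, min(x$unique_vars)))
  invisible(x)
}

# rank-m principal-factor loadings of a reduced matrix, eigenvalues floored at 0
principal_loadings <- function(Rstar, m) {
  e <- eigen(Rstar, symmetric = TRUE)
  d <- pmax(e$values[seq_len(m)], 0)
  e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(d), m)
}

#' Unweighted least squares extraction by iterative principal factoring
#'
#' Starting from SMC-based communalities, alternates (i) rank-`m`
#' eigen-approximation of the reduced matrix `R - diag(psi)` (eigenvalues
#' floored at zero) and (ii) the communality update `psi <- 1 - rowSums(L^2)`,
#' until the decrease of the least-squares criterion
#' `0.5 * ||R - L L' - diag(psi)||_F^2` falls below `tol`. Negative unique
#' variances (Heywood cases) are allowed during iteration and judged at exit:
#' the solution is flagged improper if any `psi < 0` or the iteration cap was
#' reached.
#'
#' @param R `p x p` correlation matrix.
#' @param m Number of factors, `m < p`.
#' @param tol Absolute criterion-decrease tolerance.
#' @param max_iter Iteration cap.
#' @param init Optional initial unique variances (defaults to
#'   [smc_unique_variances()]).
#' @return An `extraction_result` with `method_tag = "ULS"`.
#' @export
uls_extract <- function(R, m, tol = 1e-3, max_iter = 200, init = NULL) {
  R <- as.matrix(R)
  p <- nrow(R)
  if (m >= p) stop("'m' must be smaller than the number of variables")
  if (max(abs(R - t(R))) > 1e-8) {
    warning("'R' is not numerically symmetric; symmetrizing")
    R <- (R + t(R)) / 2
  }
  psi <- if (is.null(init)) smc_unique_variances(R) else init
  crit_fun <- function(L, psi) {
    resid <- R - tcrossprod(L)
    diag(resid) <- diag(resid) - psi
    0.5 * sum(resid^2)
  }
  reduce <- function(psi) { Rs <- R; diag(Rs) <- 1 - psi; Rs }
  converged <- FALSE
  crit_prev <- Inf
  trace <- numeric(0)
  L <- principal_loadings(reduce(psi), m)
  crit <- crit_fun(L, psi)
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    L <- principal_loadings(reduce(psi), m)
    psi <- 1 - rowSums(L^2)
    crit <- crit_fun(L, psi)
    trace <- c(trace, crit)
    n_iter <- it
    if (crit_prev - crit < tol) { converged <- TRUE; break }
    crit_prev <- crit
  }
  proper <- converged && min(psi) >= 0
  new_extraction_result(L, psi, converged, proper, n_iter, crit, trace, "ULS")
}

#' Maximum-likelihood discrepancy between a sample and a model matrix
#'
#' `ln det(Sigma) + trace(R Sigma^-1)`; the constant terms `-ln det(R) - p`
#' of the classical ML fit function are dropped so the value is defined even
#' for singular `R`.
#'
#' @param R `p x p` sample (or population) correlation matrix.
#' @param Sigma `p x p` positive-definite model matrix.
#' @return Scalar discrepancy.
#' @export
ml_discrepancy <- function(R, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) {
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    stop("'Sigma' is not positive definite (smallest eigenvalue = ",
         format(min(ev)), ")")
  })
  logdet <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  logdet + sum(Sinv * R)
}

# golden-section search for the minimum of g on [a, b]
golden_section <- function(g, a, b, tol = 1e-9, max_iter = 80) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- g(x1); f2 <- g(x2)
  for (i in seq_len(max_iter)) {
    if (b - a < tol * (1 + b)) break
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- g(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- g(x2)
    }
  }
  if (f1 < f2) list(x = x1, f = f1) else list(x = x2, f = f2)
}

#' Regularized exploratory factor analysis (REFA) extraction
#'
#' Unique variances are modelled as a single shrinkage parameter `lambda`
#' times non-iterative tentative estimates `Lhat` (by default `1 - SMC`), so
#' `lambda` is the only parameter estimated iteratively. For each `lambda`
#' the loadings follow in closed form from the rank-`m` eigendecomposition of
#' `R - lambda * diag(Lhat)` (eigenvalues floored at zero), and `lambda` is
#' chosen to minimize the maximum-likelihood discrepancy
#' `ln det(Sigma) + trace(R Sigma^-1)` with
#' `Sigma = L L' + lambda * diag(Lhat)`. Because `lambda > 0` and
#' `Lhat > 0`, the unique-variance estimates `lambda * Lhat` are strictly
#' positive: REFA cannot produce an improper solution.
#'
#' The default search evaluates 60 logarithmically spaced values on
#' `(0.01, lambda_max]` with `lambda_max = 0.999 / max(Lhat)`, then refines
#' the bracketing interval by golden-section search.
#'
#' @param R `p x p` correlation matrix (may be singular).
#' @param m Number of factors, `m < p`.
#' @param lambda_grid Optional increasing vector of positive shrinkage values
#'   to search over; by default constructed as above.
#' @param n_grid Grid size when `lambda_grid` is `NULL`.
#' @param lambda_min Lower end of the default grid.
#' @param unique_method Tentative unique-variance estimator, see
#'   [smc_unique_variances()].
#' @return List with components `result` (an `extraction_result`,
#'   `method_tag = "REFA"`, always proper) and `regfit` (a
#'   `regularization_fit`: grid, discrepancy values, `lambda_star`,
#'   tentative uniques).
#' @export
refa_extract <- function(R, m, lambda_grid = NULL, n_grid = 60,
                         lambda_min = 0.01, unique_method = "smc") {
  R <- as.matrix(R)
  p <- nrow(R)
  if (m >= p) stop("'m' must be smaller than the number of variables")
  Lhat <- smc_unique_variances(R, method = unique_method)
  lambda_max <- 0.999 / max(Lhat)
  if (is.null(lambda_grid)) {
    lambda_grid <- exp(seq(log(lambda_min), log(lambda_max),
                           length.out = n_grid))
  } else {
    if (any(lambda_grid <= 0)) stop("'lambda_grid' must be positive")
    lambda_grid <- sort(lambda_grid)
  }
  fit_at <- function(lambda) {
    Rl <- R
    diag(Rl) <- diag(R) - lambda * Lhat
    L <- principal_loadings(Rl, m)
    Sigma <- tcrossprod(L)
    diag(Sigma) <- diag(Sigma) + lambda * Lhat
    list(L = L, g = ml_discrepancy(R, Sigma))
  }
  gvals <- vapply(lambda_grid, function(l) fit_at(l)$g, numeric(1))
  i <- which.min(gvals)
  lo <- lambda_grid[max(1L, i - 1L)]
  hi <- lambda_grid[min(length(lambda_grid), i + 1L)]
  ref <- golden_section(function(l) fit_at(l)$g, lo, hi)
  if (ref$f < gvals[i]) {
    lambda_star <- ref$x; g_star <- ref$f
  } else {
    lambda_star <- lambda_grid[i]; g_star <- gvals[i]
  }
  best <- fit_at(lambda_star)
  result <- new_extraction_result(
    pattern = best$L, unique_vars = lambda_star * Lhat, converged = TRUE,
    proper = TRUE, n_iter = length(lambda_grid), criterion = g_star,
    criterion_trace = gvals, method_tag = "REFA")
  regfit <- structure(list(
    lambda_grid = lambda_grid, discrepancy_values = gvals,
    lambda_star = lambda_star, tentative_uniques = Lhat
  ), class = "regularization_fit")
  list(result = result, regfit = regfit)
}

#' @export
print.regularization_fit <- function(x, ...) {
  cat(sprintf("REFA regularization path: %d grid points on [%.4g, %.4g]\n",
              length(x$lambda_grid), min(x$lambda_grid), max(x$lambda_grid)))
  cat(sprintf("  lambda* = %.6g, min discrepancy = %.6g\n", x$lambda_star,
              min(x$discrepancy_values)))
  invisible(x)
}
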