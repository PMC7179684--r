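#' Independent-clusters population loading matrix
#'
#' Builds the block pattern in which each of `n_factors` primary factors is
#' measured by `vars_per_factor` variables, all with the same loading, and
#' every variable loads on exactly one factor.
#'
#' @param vars_per_factor Number of variables per primary factor (>= 1).
#' @param n_factors Number of primary (group) factors (>= 1).
#' @param loading Common factor loading, in (0, 1).
#' @return A `p x f` numeric matrix, `p = vars_per_factor * n_factors`, with
#'   rows `(k-1)*vars_per_factor + 1 ... k*vars_per_factor` carrying `loading`
#'   in column `k` and zero elsewhere.
#' @examples
#' build_loading_matrix(4, 2, 0.4)
#' @export
build_loading_matrix <- function(vars_per_factor, n_factors, loading) {
  if (length(vars_per_factor) != 1L || vars_per_factor < 1 ||
      vars_per_factor != round(vars_per_factor))
    stop("'vars_per_factor' must be a positive integer")
  if (length(n_factors) != 1L || n_factors < 1 || n_factors != round(n_factors))
    stop("'n_factors' must be a positive integer")
  if (length(loading) != 1L || loading <= 0 || loading >= 1)
    stop("'loading' must lie strictly between 0 and 1")
  p <- vars_per_factor * n_factors
  L <- matrix(0, p, n_factors)
  for (k in seq_len(n_factors)) {
    rows <- ((k - 1L) * vars_per_factor + 1L):(k * vars_per_factor)
    L[rows, k] <- loading
  }
  L
}

#' Equicorrelated factor correlation matrix
#'
#' @param n_factors Number of factors (>= 1).
#' @param factor_corr Common inter-factor correlation, in (-1, 1); must keep
#'   the matrix positive definite, i.e. `factor_corr > -1/(n_factors - 1)`.
#' @return An `f x f` matrix with unit diagonal and constant off-diagonals.
#' @export
build_factor_correlation <- function(n_factors, factor_corr) {
  if (length(n_factors) != 1L || n_factors < 1 || n_factors != round(n_factors))
    stop("'n_factors' must be a positive integer")
  if (length(factor_corr) != 1L || factor_corr <= -1 || factor_corr >= 1)
    stop("'factor_corr' must lie strictly between -1 and 1")
  if (n_factors > 1 && factor_corr <= -1 / (n_factors - 1))
    stop("'factor_corr' = ", factor_corr, " makes a ", n_factors, "x",
         n_factors, " equicorrelation matrix non-positive-definite")
  Phi <- matrix(factor_corr, n_factors, n_factors)
  diag(Phi) <- 1
  Phi
}

#' Model-implied population correlation matrix
#'
#' Computes the correlation matrix implied by a correlated-factors model,
#' `Lambda Phi Lambda' + Psi`, with unique variances chosen to give unit
#' diagonal.
#'
#' @param Lambda `p x f` primary pattern matrix.
#' @param Phi `f x f` factor correlation matrix (symmetric, unit diagonal).
#' @return A `p x p` correlation matrix.
#' @export
implied_correlation <- function(Lambda, Phi) {
  Lambda <- as.matrix(Lambda)
  Phi <- as.matrix(Phi)
  if (ncol(Lambda) != nrow(Phi)) stop("non-conformable 'Lambda' and 'Phi'")
  if (max(abs(Phi - t(Phi))) > 1e-10) stop("'Phi' must be symmetric")
  if (max(abs(diag(Phi) - 1)) > 1e-10) stop("'Phi' must have unit diagonal")
  common <- Lambda %*% Phi %*% t(Lambda)
  h2 <- diag(common)
  if (any(h2 >= 1))
    stop("population communality >= 1 (Heywood population): max = ",
         format(max(h2)))
  R <- common
  diag(R) <- 1
  R
}

#' Closed-form population Schmid-Leiman bifactor target
#'
#' For an independent-clusters model with an equicorrelated factor
#' correlation matrix (common correlation `r >= 0`), the second-order factor
#' loads `sqrt(r)` on every primary factor, so the orthogonalized solution is
#' available analytically: the general column is `Lambda %*% gamma` and the
#' group block is `Lambda * sqrt(1 - r)`.
#'
#' @param Lambda `p x f` primary pattern matrix.
#' @param Phi `f x f` equicorrelated factor correlation matrix with
#'   non-negative common correlation.
#' @return A `p x (1+f)` matrix; column 1 is the general factor, columns
#'   2..(1+f) the group factors in primary-factor order.
#' @export
population_bifactor_solution <- function(Lambda, Phi) {
  Lambda <- as.matrix(Lambda)
  Phi <- as.matrix(Phi)
  f <- ncol(Lambda)
  if (nrow(Phi) != f) stop("non-conformable 'Lambda' and 'Phi'")
  off <- Phi[upper.tri(Phi)]
  if (f > 1 && max(abs(off - off[1])) > 1e-10)
    stop("'Phi' must be equicorrelated")
  r <- if (f > 1) off[1] else 0
  if (r < 0) stop("negative factor correlation is unsupported here")
  gamma <- rep(sqrt(r), f)
  general <- drop(Lambda %*% gamma)
  group <- Lambda * sqrt(1 - r)
  out <- cbind(general, group)
  colnames(out) <- c("general", paste0("group", seq_len(f)))
  out
}

#' Population model for one design cell
#'
#' Bundles the primary pattern, factor correlation, unique variances, implied
#' correlation matrix, and the analytic Schmid-Leiman bifactor target for an
#' independent-clusters population.
#'
#' @param vars_per_factor,n_factors,loading,factor_corr Scalar condition
#'   levels; see [design_grid()] for the default study levels.
#' @return An object of class `population_model`.
#' @seealso [population_bifactor_solution()], [implied_correlation()]
#' @export
population_model <- function(vars_per_factor, n_factors, loading, factor_corr) {
  Lambda <- build_loading_matrix(vars_per_factor, n_factors, loading)
  Phi <- build_factor_correlation(n_factors, factor_corr)
  R <- implied_correlation(Lambda, Phi)
  h2 <- diag(Lambda %*% Phi %*% t(Lambda))
  structure(list(
    primary_pattern = Lambda,
    factor_corr_matrix = Phi,
    unique_variances = 1 - h2,
    implied_corr = R,
    bifactor_target = population_bifactor_solution(Lambda, Phi),
    vars_per_factor = vars_per_factor,
    n_factors = n_factors,
    loading = loading,
    factor_corr = factor_corr
  ), class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Independent-clusters population model\n")
  cat(sprintf("  p = %d variables, f = %d factors (%d per factor)\n",
              nrow(x$primary_pattern), x$n_factors, x$vars_per_factor))
  cat(sprintf("  loading = %.2f, factor correlation = %.2f\n",
              x$loading, x$factor_corr))
  cat(sprintf("  communalities = %.4f, unique variances = %.4f\n",
              1 - x$unique_variances[1], x$unique_variances[1]))
  invisible(x)
}

#' Write a matrix as a header-free CSV
#'
#' Full-precision, no row or column names; the format used for population and
#' sample matrices by the command-line interface.
#'
#' @param x A numeric matrix.
#' @param path Output file path.
#' @export
export_matrix_csv <- function(x, path) {
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
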