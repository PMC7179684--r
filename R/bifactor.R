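#' Second-order factor extraction from a primary factor correlation matrix
#'
#' With two primary factors a one-factor model on the 2x2 correlation matrix
#' is under-identified; the standard equal-loading convention is used:
#' `gamma_1 = gamma_2 = sqrt(phi_12)` (proper only when `phi_12 > 0`) with
#' disturbances `1 - phi_12`. With three or more factors a single factor is
#' extracted with the requested engine; ULS disturbances are the fit's own
#' uniquenesses, REFA disturbances are `lambda* * Lhat` of the second-order
#' fit, mirroring the first-order unique-variance estimation.
#'
#' Disturbances are clipped to `[0, 1]`; a clip larger than `clip_tol` marks
#' the stage improper.
#'
#' @param Phi `f x f` primary factor correlation matrix (unit diagonal).
#' @param method `"ULS"` or `"REFA"`.
#' @param clip_tol Largest tolerated disturbance clip (default 0.05).
#' @return List with `gamma` (second-order loadings), `u2` (disturbances),
#'   and `proper`.
#' @export
second_order_extract <- function(Phi, method = c("ULS", "REFA"),
                                 clip_tol = 0.05) {
  Phi <- as.matrix(Phi)
  method <- match.arg(method)
  f <- nrow(Phi)
  if (max(abs(diag(Phi) - 1)) > 1e-8) stop("'Phi' must have unit diagonal")
  if (f == 2) {
    phi12 <- Phi[1, 2]
    if (phi12 <= 0) {
      return(list(gamma = c(0, 0), u2 = c(1, 1), proper = FALSE))
    }
    gamma <- rep(sqrt(phi12), 2)
    u2_raw <- rep(1 - phi12, 2)
    proper <- TRUE
  } else {
    if (method == "ULS") {
      fit <- uls_extract(Phi, 1)
      gamma <- fit$pattern[, 1]
      u2_raw <- fit$unique_vars
      proper <- fit$proper
    } else {
      fit <- refa_extract(Phi, 1)$result
      gamma <- fit$pattern[, 1]
      u2_raw <- fit$unique_vars
      proper <- fit$proper
    }
    if (sum(gamma) < 0) gamma <- -gamma
  }
  u2 <- pmin(pmax(u2_raw, 0), 1)
  if (max(abs(u2 - u2_raw)) > clip_tol) proper <- FALSE
  list(gamma = gamma, u2 = u2, proper = proper)
}

#' Schmid-Leiman orthogonalization
#'
#' Re-expresses a first-order oblique solution plus a second-order factor as
#' an orthogonal general + group solution: the general column is
#' `A %*% gamma` and each group column is the primary column scaled by the
#' square root of its disturbance. The identity
#' `B B' = A (gamma gamma' + diag(u2)) A'` holds exactly.
#'
#' @param A `p x f` (rotated) primary pattern matrix.
#' @param gamma Length-`f` second-order loadings.
#' @param u2 Length-`f` non-negative disturbances.
#' @param source_method Label, `"ULS"` or `"REFA"`.
#' @param proper Properness flag carried from the fitting stages.
#' @return A `bifactor_solution`: list with `general` (length `p`), `group`
#'   (`p x f`), `second_order_loadings`, `disturbances`, `source_method`,
#'   `proper`.
#' @export
schmid_leiman <- function(A, gamma, u2, source_method = "ULS",
                          proper = TRUE) {
  A <- as.matrix(A)
  f <- ncol(A)
  if (length(gamma) != f || length(u2) != f)
    stop("'gamma' and 'u2' must have one entry per primary factor")
  if (any(u2 < 0))
    stop("negative disturbance: screen improper solutions before ",
         "orthogonalizing")
  general <- drop(A %*% gamma)
  group <- A %*% diag(sqrt(u2), f)
  colnames(group) <- paste0("group", seq_len(f))
  structure(list(
    general = general, group = group, second_order_loadings = gamma,
    disturbances = u2, source_method = source_method, proper = proper
  ), class = "bifactor_solution")
}

#' Full loading matrix of a bifactor solution
#'
#' @param solution A `bifactor_solution`.
#' @return `p x (1+f)` matrix, general column first.
#' @export
bifactor_loadings <- function(solution) {
  out <- cbind(general = solution$general, solution$group)
  out
}

#' @export
print.bifactor_solution <- function(x, ...) {
  f <- ncol(x$group)
  cat(sprintf("Schmid-Leiman bifactor solution (%s): %d variables, %d group factor(s)\n",
              x$source_method, length(x$general), f))
  cat(sprintf("  proper = %s\n", x$proper))
  cat("  second-order loadings:", paste(sprintf("%.4f", x$second_order_loadings),
                                        collapse = " "), "\n")
  cat("  disturbances:         ", paste(sprintf("%.4f", x$disturbances),
                                        collapse = " "), "\n")
  invisible(x)
}

#' Fit an exploratory Schmid-Leiman bifactor model
#'
#' The four-step pipeline: (1) extract `f` primary factors from `R` with ULS
#' principal factoring or REFA; (2) rotate obliquely by direct quartimin;
#' (3) extract a second-order factor from the primary factor correlation
#' matrix with the same engine; (4) orthogonalize by the Schmid-Leiman
#' transformation. After rotation every factor column is reflected so its
#' loading sum is positive. The solution is proper only if every stage is:
#' first-order convergence and non-negative uniquenesses (ULS), rotation
#' convergence, and a proper second-order stage.
#'
#' @param R `p x p` correlation matrix.
#' @param f Number of group factors, `f < p`.
#' @param method `"ULS"` or `"REFA"`.
#' @param uls_tol,uls_max_iter ULS stopping rule (see [uls_extract()]).
#' @param lambda_grid,n_grid REFA shrinkage search (see [refa_extract()]).
#' @param rotation_tol,rotation_max_iter,normalize Quartimin settings (see
#'   [quartimin_rotate()]).
#' @param clip_tol Disturbance clip tolerance (see [second_order_extract()]).
#' @return A `bifactor_solution`, with the stage objects attached as
#'   attributes `first_order`, `rotation`, `second_order`, and (REFA) `regfit`.
#' @examples
#' pop <- population_model(4, 2, 0.7, 0.5)
#' fit <- fit_bifactor(pop$implied_corr, 2, method = "REFA")
#' round(bifactor_loadings(fit), 3)
#' @export
fit_bifactor <- function(R, f, method = c("ULS", "REFA"),
                         uls_tol = 1e-3, uls_max_iter = 200,
                         lambda_grid = NULL, n_grid = 60,
                         rotation_tol = 1e-6, rotation_max_iter = 1000,
                         normalize = FALSE, clip_tol = 0.05) {
  R <- as.matrix(R)
  method <- match.arg(method)
  if (f >= nrow(R)) stop("'f' must be smaller than the number of variables")
  regfit <- NULL
  if (method == "ULS") {
    ex <- uls_extract(R, f, tol = uls_tol, max_iter = uls_max_iter)
  } else {
    rf <- refa_extract(R, f, lambda_grid = lambda_grid, n_grid = n_grid)
    ex <- rf$result
    regfit <- rf$regfit
  }
  rot <- quartimin_rotate(ex$pattern, tol = rotation_tol,
                          max_iter = rotation_max_iter, normalize = normalize)
  A <- rot$pattern
  Phi <- rot$factor_corr
  if (f >= 2) {
    sgn <- ifelse(colSums(A) < 0, -1, 1)
    A <- sweep(A, 2, sgn, "*")
    Phi <- diag(sgn, f) %*% Phi %*% diag(sgn, f)
  }
  so <- second_order_extract(Phi, method, clip_tol = clip_tol)
  sol <- schmid_leiman(A, so$gamma, so$u2, source_method = method,
                       proper = ex$proper && rot$converged && so$proper)
  attr(sol, "first_order") <- ex
  attr(sol, "rotation") <- rot
  attr(sol, "second_order") <- so
  attr(sol, "regfit") <- regfit
  sol
}
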