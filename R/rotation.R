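#' Direct quartimin criterion
#'
#' `sum_i sum_{k<l} L[i,k]^2 * L[i,l]^2`: zero exactly when every row has at
#' most one nonzero loading (perfect simple structure), positive otherwise.
#'
#' @param pattern `p x m` loading matrix.
#' @return Non-negative scalar.
#' @export
quartimin_criterion <- function(pattern) {
  L <- as.matrix(pattern)
  m <- ncol(L)
  if (m < 2) return(0)
  L2 <- L^2
  N <- matrix(1, m, m); diag(N) <- 0
  sum(L2 * (L2 %*% N)) / 2
}

# criterion and gradient for the gradient-projection loop
quartimin_vgQ <- function(L) {
  L2 <- L^2
  m <- ncol(L)
  N <- matrix(1, m, m); diag(N) <- 0
  B <- L2 %*% N
  list(f = sum(L2 * B) / 2, Gq = 2 * L * B)
}

#' Oblique direct quartimin rotation by gradient projection
#'
#' Gradient-projection descent (Jennrich-style) on the quartimin criterion
#' over oblique transformation matrices with unit-length columns, started at
#' the identity. The rotated pattern is `A %*% t(solve(T))` and the factor
#' correlation matrix is `t(T) %*% T`, so the common part
#' `pattern %*% Phi %*% t(pattern)` equals `A %*% t(A)` at every iterate.
#'
#' The start is the identity transform. Exactly symmetric inputs (such as
#' population independent-clusters patterns) can make the identity a
#' stationary saddle of the criterion; if the descent stalls on its first
#' step with a positive criterion, one deterministic restart from a fixed
#' slightly-oblique transform is taken and the better of the two solutions
#' is returned.
#'
#' @param pattern0 `p x m` unrotated loading matrix. With `m = 1` the input
#'   is returned unchanged with `Phi = 1`.
#' @param tol Convergence tolerance on the projected-gradient norm.
#' @param max_iter Cap on outer iterations.
#' @param normalize Kaiser row normalization before rotation (default off).
#' @return A `rotated_solution`: list with `pattern`, `factor_corr`,
#'   `rotation_matrix`, `criterion_value`, `criterion_trace`, `converged`.
#' @export
quartimin_rotate <- function(pattern0, tol = 1e-6, max_iter = 1000,
                             normalize = FALSE) {
  A <- as.matrix(pattern0)
  m <- ncol(A)
  if (m < 2) {
    return(structure(list(
      pattern = A, factor_corr = matrix(1, 1, 1),
      rotation_matrix = diag(1), criterion_value = 0,
      criterion_trace = numeric(0), converged = TRUE
    ), class = "rotated_solution"))
  }
  W <- NULL
  if (normalize) {
    W <- sqrt(rowSums(A^2))
    W[W < 1e-12] <- 1
    A <- A / W
  }
  out <- gpa_oblq_quartimin(A, diag(m), tol, max_iter)
  if (length(out$criterion_trace) <= 1 && out$criterion_value > 1e-10) {
    T0 <- matrix(0.1, m, m) + diag(0.9, m)
    T0 <- T0 %*% diag(1 / sqrt(colSums(T0^2)), m)
    alt <- gpa_oblq_quartimin(A, T0, tol, max_iter)
    if (alt$criterion_value < out$criterion_value) out <- alt
  }
  L <- out$pattern
  Tm <- out$rotation_matrix
  f <- out$criterion_value
  if (normalize) L <- L * W
  structure(list(
    pattern = L, factor_corr = crossprod(Tm), rotation_matrix = Tm,
    criterion_value = if (normalize) quartimin_criterion(L) else f,
    criterion_trace = out$criterion_trace, converged = out$converged
  ), class = "rotated_solution")
}

# gradient-projection descent from a given oblique start
gpa_oblq_quartimin <- function(A, Tm, tol, max_iter) {
  m <- ncol(A)
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- quartimin_vgQ(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  al <- 1
  converged <- FALSE
  trace <- f
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), m)
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    improved <- FALSE
    for (half in 0:12) {
      X <- Tm - al * Gp
      v <- 1 / sqrt(colSums(X^2))
      Tt <- X %*% diag(v, m)
      Tti <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Tti)) {
        Lt <- A %*% t(Tti)
        vgt <- quartimin_vgQ(Lt)
        if (vgt$f < f - 0.5 * s^2 * al) {
          Tm <- Tt; Ti <- Tti; L <- Lt; vg <- vgt; f <- vgt$f
          improved <- TRUE
          break
        }
      }
      al <- al / 2
    }
    if (!improved) {
      # no step of any size improves the criterion: numerically at a minimum
      converged <- TRUE
      break
    }
    f_prev <- trace[length(trace)]
    trace <- c(trace, f)
    if (f < 1e-11 && f_prev - f < 0.1 * f_prev) {
      # criterion at its global floor (perfect simple structure) with
      # progress stalled: the projected gradient decays too slowly on
      # these quartic flats to ever meet `tol`
      converged <- TRUE
      break
    }
    G <- -t(t(L) %*% vg$Gq %*% Ti)
  }
  list(pattern = L, rotation_matrix = Tm, criterion_value = f,
       criterion_trace = trace, converged = converged)
}

#' @export
print.rotated_solution <- function(x, ...) {
  cat(sprintf("Quartimin rotation: %d x %d pattern, criterion = %.6g, %s\n",
              nrow(x$pattern), ncol(x$pattern), x$criterion_value,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Orthogonal Procrustes rotation toward a target
#'
#' Returns the orthogonal `T` minimizing `||P - F T||_F`, i.e. `T = U V'`
#' from the singular value decomposition of `F' P`.
#'
#' @param F `p x q` matrix to be rotated.
#' @param P `p x q` target matrix.
#' @return `q x q` orthogonal matrix.
#' @export
orthogonal_procrustes <- function(F, P) {
  F <- as.matrix(F); P <- as.matrix(P)
  if (!all(dim(F) == dim(P))) stop("'F' and 'P' must have the same shape")
  s <- svd(crossprod(F, P))
  s$u %*% t(s$v)
}
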