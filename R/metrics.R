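# all permutations of 1:n in lexicographic order
permutations_lex <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_lex(n - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[r])
  }
  out
}

#' Align a bifactor loading matrix with a target
#'
#' Resolves the permutation and reflection indeterminacy of the group
#' factors: the general column stays first, the `f` group columns are
#' exhaustively permuted, and every column (general included) is reflected,
#' choosing the combination that maximizes overall Tucker congruence with
#' the target. For a fixed permutation the optimal reflections are the signs
#' of the columnwise inner products, so the search maximizes the sum of
#' their absolute values over permutations; ties go to the lexicographically
#' smallest permutation.
#'
#' @param F `p x (1+f)` sample loading matrix, general column first.
#' @param P `p x (1+f)` target matrix, same layout.
#' @return List with `aligned` (the permuted/reflected `F`), `permutation`
#'   (group-column order applied), and `reflections` (signs, length `1+f`).
#' @export
align_solution <- function(F, P) {
  F <- as.matrix(F); P <- as.matrix(P)
  if (!all(dim(F) == dim(P))) stop("'F' and 'P' must have the same shape")
  f <- ncol(F) - 1L
  if (f > 6) stop("exhaustive alignment refused for more than 6 group factors")
  if (f == 0) {
    s <- sign(sum(P * F)); if (s == 0) s <- 1
    return(list(aligned = F * s, permutation = integer(0), reflections = s))
  }
  perms <- permutations_lex(f)
  best_score <- -Inf
  best <- NULL
  for (perm in perms) {
    cols <- c(1L, 1L + perm)
    dots <- colSums(P * F[, cols, drop = FALSE])
    score <- sum(abs(dots))
    if (score > best_score + 1e-12) {
      best_score <- score
      signs <- ifelse(dots < 0, -1, 1)
      best <- list(perm = perm, signs = signs, cols = cols)
    }
  }
  aligned <- sweep(F[, best$cols, drop = FALSE], 2, best$signs, "*")
  colnames(aligned) <- colnames(P)
  list(aligned = aligned, permutation = best$perm, reflections = best$signs)
}

#' Tucker congruence coefficient between two loading matrices
#'
#' The overall (matrix-level) coefficient
#' `trace(P' F) / sqrt(trace(P' P) * trace(F' F))`, optionally computed
#' after an orthogonal Procrustes rotation of `F` toward `P` to remove
#' rotational indeterminacy.
#'
#' @param P `p x q` target (population) loading matrix.
#' @param F `p x q` sample loading matrix.
#' @param procrustes Rotate `F` by [orthogonal_procrustes()] first?
#' @return Scalar in `[-1, 1]`.
#' @export
tucker_phi <- function(P, F, procrustes = FALSE) {
  P <- as.matrix(P); F <- as.matrix(F)
  if (!all(dim(F) == dim(P))) stop("'F' and 'P' must have the same shape")
  if (all(P == 0) || all(F == 0))
    stop("congruence is undefined for an all-zero matrix")
  if (procrustes) F <- F %*% orthogonal_procrustes(F, P)
  sum(P * F) / sqrt(sum(P^2) * sum(F^2))
}

#' Root mean squared error between loading blocks
#'
#' `sqrt(trace(E'E) / (p*m))` with `E = P_block - F_block`; applied
#' separately to the general column and the group block so the two sources
#' of error are reported on their own scales.
#'
#' @param P_block,F_block Conformable numeric matrices (or vectors).
#' @return Non-negative scalar.
#' @export
rmse_loadings <- function(P_block, F_block) {
  P_block <- as.matrix(P_block); F_block <- as.matrix(F_block)
  if (!all(dim(P_block) == dim(F_block))) stop("blocks must have the same shape")
  sqrt(sum((P_block - F_block)^2) / length(P_block))
}

#' Recovery metrics for one fitted replication
#'
#' Aligns the sample bifactor solution with the population target
#' (group-column permutation + columnwise reflection), then computes the
#' overall Tucker congruence after an additional orthogonal Procrustes
#' rotation, and the RMSE of the general column and of the group block on
#' the permutation/reflection-aligned matrix only — a free orthogonal
#' rotation would mix the general and group blocks and void the separate
#' RMSE report.
#'
#' @param solution A proper `bifactor_solution`.
#' @param target `p x (1+f)` population bifactor matrix.
#' @param procrustes_rmse Also Procrustes-rotate before the RMSEs
#'   (default `FALSE`).
#' @return A `recovery_metrics` object: list with `phi`, `rmse_general`,
#'   `rmse_group`, `permutation_applied`, `reflections_applied`.
#' @export
evaluate_replication <- function(solution, target, procrustes_rmse = FALSE) {
  if (!isTRUE(solution$proper))
    stop("improper solution: screen before computing recovery metrics")
  target <- as.matrix(target)
  F <- bifactor_loadings(solution)
  al <- align_solution(F, target)
  phi <- tucker_phi(target, al$aligned, procrustes = TRUE)
  base <- al$aligned
  if (procrustes_rmse) base <- base %*% orthogonal_procrustes(base, target)
  structure(list(
    phi = phi,
    rmse_general = rmse_loadings(target[, 1], base[, 1]),
    rmse_group = rmse_loadings(target[, -1, drop = FALSE],
                               base[, -1, drop = FALSE]),
    permutation_applied = al$permutation,
    reflections_applied = al$reflections
  ), class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("Recovery: phi = %.4f, RMSE(general) = %.4f, RMSE(group) = %.4f\n",
              x$phi, x$rmse_general, x$rmse_group))
  invisible(x)
}
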