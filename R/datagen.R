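#' Deterministic per-replication seed
#'
#' Maps (master seed, cell index, replication index, screening stream) to a
#' seed below 2^31 so that every replication of every design cell draws from
#' its own reproducible stream, and the unscreened improper-rate study never
#' shares a sample with the screened main study.
#'
#' The scheme is `(master * 7919 + cell * 100000 + 2 * replication +
#' screened) mod (2^31 - 1)`, which is injective over the study's range
#' (cell <= 144, replication < 50000).
#'
#' @param master_seed Integer master seed for the whole run.
#' @param cell_index Design-cell index (1-based).
#' @param replication Replication index within the cell (1-based).
#' @param screened Logical; `TRUE` for the screened main-study stream,
#'   `FALSE` for the unscreened improper-rate stream.
#' @return An integer seed in `[1, 2^31 - 1)`.
#' @export
replication_seed <- function(master_seed, cell_index, replication,
                             screened = TRUE) {
  raw <- master_seed * 7919 + cell_index * 100000 +
    2 * replication + as.integer(screened)
  as.integer(raw %% 2147483647)
}

#' Draw a multivariate-normal sample from a population correlation matrix
#'
#' Rows are i.i.d. draws `x = L z` with `L` the lower-triangular Cholesky
#' factor of `pop_corr` and `z` standard normal; generation is bit-reproducible
#' given `seed`.
#'
#' @param pop_corr `p x p` positive-definite population correlation matrix.
#' @param n Number of observations (>= 2).
#' @param seed Integer seed.
#' @param cell Optional design-cell record carried along for bookkeeping.
#' @return A `sample_dataset` object: list with `observations` (`n x p`),
#'   `sample_corr` (`p x p`), `seed`, and `cell`.
#' @export
sample_dataset <- function(pop_corr, n, seed, cell = NULL) {
  pop_corr <- as.matrix(pop_corr)
  if (n < 2) stop("'n' must be at least 2")
  U <- tryCatch(chol(pop_corr), error = function(e) {
    ev <- eigen(pop_corr, symmetric = TRUE, only.values = TRUE)$values
    stop("Cholesky decomposition failed: matrix is not positive definite ",
         "(smallest eigenvalue = ", format(min(ev)), ")")
  })
  p <- ncol(pop_corr)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- Z %*% U
  structure(list(
    observations = X,
    sample_corr = sample_correlation(X),
    seed = seed,
    cell = cell
  ), class = "sample_dataset")
}

#' Pearson correlation matrix of an observation table
#'
#' @param observations `N x p` numeric matrix, `N >= 2`, no constant column.
#' @return `p x p` symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(observations) {
  X <- as.matrix(observations)
  if (nrow(X) < 2) stop("at least 2 observations are required")
  v <- apply(X, 2, stats::var)
  if (any(v == 0))
    stop("degenerate input: zero-variance column(s) ",
         paste(which(v == 0), collapse = ", "))
  R <- stats::cor(X)
  (R + t(R)) / 2
}
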