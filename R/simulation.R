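#' Monte Carlo study configuration
#'
#' Default levels reproduce the factorial design of the study: sample sizes
#' 10/20/30/50, 4 or 8 variables per factor, 2 or 4 group factors, loadings
#' 0.40/0.55/0.70, factor correlations 0.30/0.50/0.70 — 144 cells in all —
#' with 100 retained proper replications per cell for the main study and 100
#' unscreened replications per cell for the improper-rate study.
#' `scale_factor` divides both counts for desk-scale runs.
#'
#' @param sample_sizes,vars_per_factor,n_factors,loadings,factor_corrs
#'   Condition level vectors (all non-empty).
#' @param n_keep Proper replications retained per cell.
#' @param n_unscreened Unscreened replications per cell for the
#'   improper-rate study.
#' @param master_seed Integer master seed.
#' @param scale_factor Divisor applied to `n_keep` and `n_unscreened`.
#' @param uls_tol,uls_max_iter,rotation_tol,rotation_max_iter Stopping rules
#'   passed through to [fit_bifactor()].
#' @param normalize,n_grid,clip_tol Further fitting settings passed through
#'   to [fit_bifactor()].
#' @param attempt_factor Hard cap on attempts per cell, as a multiple of the
#'   retained count.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(sample_sizes = c(10, 20, 30, 50),
                              vars_per_factor = c(4, 8),
                              n_factors = c(2, 4),
                              loadings = c(0.40, 0.55, 0.70),
                              factor_corrs = c(0.30, 0.50, 0.70),
                              n_keep = 100, n_unscreened = 100,
                              master_seed = 101, scale_factor = 1,
                              uls_tol = 1e-3, uls_max_iter = 200,
                              rotation_tol = 1e-6, rotation_max_iter = 1000,
                              normalize = FALSE, n_grid = 60,
                              clip_tol = 0.05, attempt_factor = 100) {
  levels <- list(sample_sizes = sample_sizes, vars_per_factor = vars_per_factor,
                 n_factors = n_factors, loadings = loadings,
                 factor_corrs = factor_corrs)
  empty <- vapply(levels, length, integer(1)) == 0
  if (any(empty))
    stop("empty level list(s): ", paste(names(levels)[empty], collapse = ", "))
  structure(c(levels, list(
    n_keep = n_keep, n_unscreened = n_unscreened, master_seed = master_seed,
    scale_factor = scale_factor, uls_tol = uls_tol, uls_max_iter = uls_max_iter,
    rotation_tol = rotation_tol, rotation_max_iter = rotation_max_iter,
    normalize = normalize, n_grid = n_grid, clip_tol = clip_tol,
    attempt_factor = attempt_factor
  )), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Bifactor recovery simulation configuration\n")
  cat(sprintf("  N in {%s}; p/f in {%s}; f in {%s}; l in {%s}; r in {%s}\n",
              paste(x$sample_sizes, collapse = ", "),
              paste(x$vars_per_factor, collapse = ", "),
              paste(x$n_factors, collapse = ", "),
              paste(x$loadings, collapse = ", "),
              paste(x$factor_corrs, collapse = ", ")))
  cat(sprintf("  cells = %d; n_keep = %d, n_unscreened = %d (scale 1/%g)\n",
              nrow(design_grid(x)), x$n_keep, x$n_unscreened, x$scale_factor))
  cat(sprintf("  master seed = %d\n", x$master_seed))
  invisible(x)
}

#' Enumerate the factorial design grid
#'
#' Cartesian product of the five condition level lists, in a fixed
#' documented order: factor correlation varies fastest, then loading, number
#' of factors, variables per factor, and sample size slowest. Cell indices
#' are this enumeration order.
#'
#' @param config A [simulation_config()].
#' @return A data frame with one row per cell: `cell`, `sample_size`,
#'   `vars_per_factor`, `n_factors`, `loading`, `factor_corr`, `p`.
#' @export
design_grid <- function(config = simulation_config()) {
  g <- expand.grid(factor_corr = config$factor_corrs,
                   loading = config$loadings,
                   n_factors = config$n_factors,
                   vars_per_factor = config$vars_per_factor,
                   sample_size = config$sample_sizes,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("sample_size", "vars_per_factor", "n_factors", "loading",
             "factor_corr")]
  g$p <- g$vars_per_factor * g$n_factors
  data.frame(cell = seq_len(nrow(g)), g, row.names = NULL)
}

fit_both <- function(R, f, config) {
  uls <- fit_bifactor(R, f, method = "ULS", uls_tol = config$uls_tol,
                      uls_max_iter = config$uls_max_iter,
                      rotation_tol = config$rotation_tol,
                      rotation_max_iter = config$rotation_max_iter,
                      normalize = config$normalize, clip_tol = config$clip_tol)
  refa <- fit_bifactor(R, f, method = "REFA", n_grid = config$n_grid,
                       rotation_tol = config$rotation_tol,
                       rotation_max_iter = config$rotation_max_iter,
                       normalize = config$normalize, clip_tol = config$clip_tol)
  list(ULS = uls, REFA = refa)
}

cell_record <- function(cell, method, replication, seed, metrics, proper) {
  data.frame(cell = cell$cell, sample_size = cell$sample_size,
             vars_per_factor = cell$vars_per_factor,
             n_factors = cell$n_factors, loading = cell$loading,
             factor_corr = cell$factor_corr, method = method,
             replication = replication, seed = seed,
             phi = if (is.null(metrics)) NA_real_ else metrics$phi,
             rmse_general = if (is.null(metrics)) NA_real_ else metrics$rmse_general,
             rmse_group = if (is.null(metrics)) NA_real_ else metrics$rmse_group,
             proper = proper)
}

#' Run the screened Monte Carlo replications for one design cell
#'
#' Samples are drawn sequentially from the cell's population model; a sample
#' is retained if and only if the ULS bifactor pipeline on it is proper
#' (first-order convergence without negative uniquenesses, converged
#' rotation, proper second-order stage). Both ULS and REFA are then
#' evaluated on every retained sample — the paired design behind the
#' within-subject method comparison — until `n_keep` (divided by the
#' configured scale factor) retained replications are collected or the
#' attempt cap is hit.
#'
#' @param cell One row of [design_grid()] (or a list with the same fields).
#' @param config A [simulation_config()].
#' @return A data frame of per-replication records (two rows per retained
#'   sample: methods ULS and REFA) with attributes `attempts` and `complete`.
#' @export
run_cell <- function(cell, config = simulation_config()) {
  cell <- as.list(cell)
  n_keep <- max(1L, ceiling(config$n_keep / config$scale_factor))
  pop <- population_model(cell$vars_per_factor, cell$n_factors,
                          cell$loading, cell$factor_corr)
  target <- pop$bifactor_target
  max_attempts <- config$attempt_factor * n_keep
  records <- vector("list", 2L * n_keep)
  kept <- 0L
  attempts <- 0L
  while (kept < n_keep && attempts < max_attempts) {
    attempts <- attempts + 1L
    seed <- replication_seed(config$master_seed, cell$cell, attempts,
                             screened = TRUE)
    ds <- sample_dataset(pop$implied_corr, cell$sample_size, seed, cell)
    fits <- fit_both(ds$sample_corr, cell$n_factors, config)
    if (!fits$ULS$proper) next
    kept <- kept + 1L
    m_uls <- evaluate_replication(fits$ULS, target)
    m_refa <- if (fits$REFA$proper)
      evaluate_replication(fits$REFA, target) else NULL
    records[[2L * kept - 1L]] <-
      cell_record(cell, "ULS", kept, seed, m_uls, TRUE)
    records[[2L * kept]] <-
      cell_record(cell, "REFA", kept, seed, m_refa, fits$REFA$proper)
  }
  complete <- kept == n_keep
  if (!complete)
    warning(sprintf("cell %d incomplete: %d/%d retained in %d attempts",
                    cell$cell, kept, n_keep, attempts))
  out <- do.call(rbind, records[seq_len(2L * kept)])
  if (is.null(out)) out <- cell_record(cell, "ULS", 1L, NA, NULL, FALSE)[0, ]
  attr(out, "attempts") <- attempts
  attr(out, "complete") <- complete
  out
}

#' Run the screened main study over the whole design grid
#'
#' @param config A [simulation_config()].
#' @param cells Optional subset of [design_grid()] rows to run.
#' @param verbose Print per-cell progress to stderr.
#' @return A `results_table`: long-format data frame of all replication
#'   records with attributes `config` and `attempts` (per-cell attempt
#'   counts).
#' @export
run_study <- function(config = simulation_config(), cells = NULL,
                      verbose = FALSE) {
  grid <- design_grid(config)
  if (!is.null(cells)) grid <- grid[grid$cell %in% cells, , drop = FALSE]
  out <- vector("list", nrow(grid))
  attempts <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rec <- run_cell(grid[i, ], config)
    out[[i]] <- rec
    attempts[i] <- attr(rec, "attempts")
    if (verbose)
      message(sprintf("cell %d/%d (N=%d, p=%d, f=%d, l=%.2f, r=%.2f): %d attempts",
                      grid$cell[i], max(grid$cell), grid$sample_size[i],
                      grid$p[i], grid$n_factors[i], grid$loading[i],
                      grid$factor_corr[i], attempts[i]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "config") <- config
  attr(res, "attempts") <- data.frame(cell = grid$cell, attempts = attempts)
  class(res) <- c("results_table", "data.frame")
  res
}

#' Unscreened improper-solution rate study for the ULS pipeline
#'
#' Fits the ULS bifactor pipeline to fresh, unscreened samples in every
#' design cell (independent seed stream from the main study) and reports the
#' fraction of improper solutions — non-convergence within the iteration
#' cap, any negative unique variance, or a failed second-order stage —
#' aggregated by sample size.
#'
#' @param config A [simulation_config()].
#' @param cells Optional subset of cell indices.
#' @return List with `by_cell` (per-cell improper fractions) and
#'   `by_sample_size` (aggregate fractions).
#' @export
improper_rate_study <- function(config = simulation_config(), cells = NULL) {
  grid <- design_grid(config)
  if (!is.null(cells)) grid <- grid[grid$cell %in% cells, , drop = FALSE]
  n_rep <- max(1L, ceiling(config$n_unscreened / config$scale_factor))
  improper <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, ])
    pop <- population_model(cell$vars_per_factor, cell$n_factors,
                            cell$loading, cell$factor_corr)
    bad <- 0L
    for (rep in seq_len(n_rep)) {
      seed <- replication_seed(config$master_seed, cell$cell, rep,
                               screened = FALSE)
      ds <- sample_dataset(pop$implied_corr, cell$sample_size, seed, cell)
      fit <- fit_bifactor(ds$sample_corr, cell$n_factors, method = "ULS",
                          uls_tol = config$uls_tol,
                          uls_max_iter = config$uls_max_iter,
                          rotation_tol = config$rotation_tol,
                          rotation_max_iter = config$rotation_max_iter,
                          normalize = config$normalize,
                          clip_tol = config$clip_tol)
      if (!fit$proper) bad <- bad + 1L
    }
    improper[i] <- bad
  }
  by_cell <- data.frame(grid, n = n_rep, n_improper = improper,
                        improper_rate = improper / n_rep)
  agg <- stats::aggregate(cbind(n = n, n_improper = n_improper) ~ sample_size,
                          data = by_cell, FUN = sum)
  agg$improper_rate <- agg$n_improper / agg$n
  list(by_cell = by_cell, by_sample_size = agg)
}

# complete (ULS, REFA) pairs per retained sample; rare improper REFA records
# (negative rotated factor correlation) drop their pair
results_pairs <- function(results, measure) {
  uls <- results[results$method == "ULS", ]
  refa <- results[results$method == "REFA", ]
  if (nrow(uls) == 0 || nrow(refa) == 0)
    stop("unpaired records: both methods must be present in the results")
  pairs <- merge(uls[, c("cell", "replication", measure)],
                 refa[, c("cell", "replication", measure)],
                 by = c("cell", "replication"), suffixes = c("_uls", "_refa"))
  pairs <- pairs[stats::complete.cases(pairs), ]
  if (nrow(pairs) == 0)
    stop("unpaired records: no sample has proper solutions for both methods")
  pairs
}

#' Aggregate recovery metrics over design margins
#'
#' Means and Monte Carlo standard errors of congruence and the two RMSEs per
#' method, over any subset of the design conditions; plus paired
#' ULS - REFA difference rows (method `"diff"`), computed per sample.
#'
#' @param results A `results_table` from [run_study()].
#' @param by Character vector of condition columns to aggregate by (empty =
#'   grand means).
#' @return A data frame with the margin columns, `method`, and
#'   `mean_`/`se_` columns for `phi`, `rmse_general`, `rmse_group`.
#' @export
aggregate_results <- function(results, by = character()) {
  measures <- c("phi", "rmse_general", "rmse_group")
  df <- as.data.frame(results)
  df <- df[df$proper & !is.na(df$phi), ]
  groups <- c(by, "method")
  schema <- function() {
    cols <- c(stats::setNames(rep(list(numeric(0)), length(by)), by),
              list(method = character(0)),
              stats::setNames(rep(list(numeric(0)), 2 * length(measures)),
                              c(paste0("mean_", measures), paste0("se_", measures))))
    as.data.frame(cols)
  }
  if (nrow(df) == 0) return(schema())
  key <- interaction(df[groups], drop = TRUE, lex.order = TRUE)
  agg_one <- function(sub) {
    n <- nrow(sub)
    stats::setNames(
      c(vapply(measures, function(m) mean(sub[[m]]), numeric(1)),
        vapply(measures, function(m) stats::sd(sub[[m]]) / sqrt(n), numeric(1))),
      c(paste0("mean_", measures), paste0("se_", measures)))
  }
  parts <- lapply(split(df, key), function(sub) {
    cbind(sub[1, groups, drop = FALSE], as.data.frame(as.list(agg_one(sub))))
  })
  out <- do.call(rbind, parts)
  # paired per-sample differences (ULS - REFA) on the same margins, when
  # both methods are present
  if (!all(c("ULS", "REFA") %in% df$method)) {
    rownames(out) <- NULL
    return(out)
  }
  dparts <- lapply(measures, function(m) {
    pr <- results_pairs(df, m)
    meta <- df[df$method == "ULS", c("cell", "replication", by)]
    pr <- merge(pr, meta, by = c("cell", "replication"))
    pr$d <- pr[[paste0(m, "_uls")]] - pr[[paste0(m, "_refa")]]
    pr
  })
  names(dparts) <- measures
  dkey <- if (length(by)) interaction(dparts[[1]][by], drop = TRUE,
                                      lex.order = TRUE)
          else factor(rep("all", nrow(dparts[[1]])))
  diff_rows <- lapply(levels(dkey), function(lv) {
    row <- list()
    sub1 <- dparts[[1]][dkey == lv, , drop = FALSE]
    for (b in by) row[[b]] <- sub1[[b]][1]
    row$method <- "diff"
    for (m in measures) {
      d <- dparts[[m]]$d[dkey == lv]
      row[[paste0("mean_", m)]] <- mean(d)
      row[[paste0("se_", m)]] <- stats::sd(d) / sqrt(length(d))
    }
    as.data.frame(row)
  })
  out <- rbind(out, do.call(rbind, diff_rows))
  rownames(out) <- NULL
  out
}

#' Partial eta-squared of the within-subject method factor
#'
#' For the two-level repeated-measures method factor, computed from the
#' per-sample paired differences `d = measure_ULS - measure_REFA`:
#' `SS_method = (sum d)^2 / (2 n)` and
#' `SS_error = sum_cells sum_i (d_ci - mean_c)^2 / 2`; returns
#' `SS_method / (SS_method + SS_error)`. The mean difference is attached as
#' attribute `mean_difference` (positive favors REFA when the measure is an
#' error).
#'
#' @param results A `results_table` with paired proper records.
#' @param measure One of `"phi"`, `"rmse_general"`, `"rmse_group"`.
#' @return Scalar partial eta-squared in `[0, 1]`.
#' @export
partial_eta_squared_method <- function(results, measure = "rmse_general") {
  df <- as.data.frame(results)
  df <- df[df$proper & !is.na(df[[measure]]), ]
  pairs <- results_pairs(df, measure)
  d <- pairs[[paste0(measure, "_uls")]] - pairs[[paste0(measure, "_refa")]]
  n <- length(d)
  ss_m <- sum(d)^2 / (2 * n)
  dbar <- stats::ave(d, pairs$cell)
  ss_err <- sum((d - dbar)^2) / 2
  eta2 <- if (ss_m + ss_err == 0) 0 else ss_m / (ss_m + ss_err)
  attr(eta2, "mean_difference") <- mean(d)
  eta2
}
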