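test_that("the default design grid enumerates the full factorial", {
  g <- design_grid(simulation_config())
  expect_equal(nrow(g), 144)
  expect_equal(sort(unique(g$p)), c(8, 16, 32))
  expect_equal(g$cell, seq_len(144))
  # deterministic enumeration order: factor correlation fastest
  expect_equal(g$factor_corr[1:4], c(0.3, 0.5, 0.7, 0.3))
  expect_equal(g$sample_size[1], 10)
  expect_equal(g$sample_size[144], 50)

  g1 <- design_grid(simulation_config(sample_sizes = 30, vars_per_factor = 4,
                                      n_factors = 2, loadings = 0.55,
                                      factor_corrs = 0.5))
  expect_equal(nrow(g1), 1)

  expect_error(simulation_config(loadings = numeric(0)), "empty level")
})

test_that("a single-replication cell run is paired and bit-reproducible", {
  cfg <- simulation_config(n_keep = 1, master_seed = 31)
  cell <- design_grid(cfg)[109, ]  # N = 50 cell: retention is immediate
  a <- run_cell(cell, cfg)
  b <- run_cell(cell, cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 2)
  expect_setequal(a$method, c("ULS", "REFA"))
  expect_equal(a$seed[1], a$seed[2])  # both methods see the same sample
  expect_true(all(a$proper))
  expect_equal(attr(a, "attempts"), 1L)
})

test_that("large-sample cells retain without screening losses", {
  cfg <- simulation_config(n_keep = 10, master_seed = 61)
  cell <- design_grid(cfg)[design_grid(cfg)$sample_size == 50 &
                           design_grid(cfg)$p == 8, ][1, ]
  rec <- run_cell(cell, cfg)
  expect_true(attr(rec, "complete"))
  expect_lte(attr(rec, "attempts"), 12)
  expect_equal(sum(rec$method == "ULS"), 10)
})

test_that("replaying a study with the same master seed is bit-exact", {
  cfg <- simulation_config(n_keep = 3, master_seed = 77)
  cells <- c(109, 144)  # two N = 50 cells
  r1 <- run_study(cfg, cells = cells)
  r2 <- run_study(cfg, cells = cells)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("the improper-rate study reports rates by sample size", {
  cfg <- simulation_config(n_unscreened = 8, master_seed = 19)
  g <- design_grid(cfg)
  cells <- g$cell[g$p == 8 & g$sample_size %in% c(10, 50) &
                  g$loading == 0.55 & g$factor_corr == 0.5]
  out <- improper_rate_study(cfg, cells = cells)
  expect_equal(sort(out$by_sample_size$sample_size), c(10, 50))
  expect_true(all(out$by_sample_size$improper_rate >= 0 &
                  out$by_sample_size$improper_rate <= 1))
  r <- out$by_sample_size
  expect_lte(r$improper_rate[r$sample_size == 50],
             r$improper_rate[r$sample_size == 10])
})

test_that("aggregation reproduces single records and paired differences", {
  cfg <- simulation_config(n_keep = 4, master_seed = 5)
  res <- run_study(cfg, cells = c(110, 126))
  g <- aggregate_results(res)
  uls <- g[g$method == "ULS", ]
  refa <- g[g$method == "REFA", ]
  dif <- g[g$method == "diff", ]
  # paired-difference mean equals the difference of per-method means
  # (all records proper here)
  expect_true(all(res$proper))
  expect_equal(dif$mean_rmse_general,
               uls$mean_rmse_general - refa$mean_rmse_general,
               tolerance = 1e-12)

  single <- res[res$method == "ULS" & res$replication == 1, ][1, ]
  class(single) <- class(res)
  g1 <- aggregate_results(single)
  expect_equal(g1$mean_phi, single$phi)
  expect_equal(g1$mean_rmse_group, single$rmse_group)

  empty <- res[0, ]
  class(empty) <- class(res)
  g0 <- aggregate_results(empty)
  expect_equal(nrow(g0), 0)
  expect_true(all(c("method", "mean_phi", "se_rmse_general") %in% names(g0)))

  by_n <- aggregate_results(res, by = "sample_size")
  expect_true("sample_size" %in% names(by_n))
  expect_equal(nrow(by_n), 3 * length(unique(res$sample_size)))
})

test_that("method effect size follows its sums-of-squares definition", {
  mk <- function(d_uls, d_refa, cells) {
    n <- length(d_uls)
    out <- rbind(
      data.frame(cell = cells, sample_size = 10, vars_per_factor = 4,
                 n_factors = 2, loading = 0.4, factor_corr = 0.3,
                 method = "ULS", replication = seq_len(n), seed = 1,
                 phi = 0.9, rmse_general = d_uls, rmse_group = 0.2,
                 proper = TRUE),
      data.frame(cell = cells, sample_size = 10, vars_per_factor = 4,
                 n_factors = 2, loading = 0.4, factor_corr = 0.3,
                 method = "REFA", replication = seq_len(n), seed = 1,
                 phi = 0.9, rmse_general = d_refa, rmse_group = 0.2,
                 proper = TRUE))
    class(out) <- c("results_table", "data.frame")
    out
  }
  # no method difference at all -> 0
  same <- mk(rep(0.2, 8), rep(0.2, 8), rep(1:2, each = 4))
  expect_equal(as.numeric(partial_eta_squared_method(same)), 0)
  # constant difference everywhere -> no error SS -> 1
  const <- mk(rep(0.22, 8), rep(0.20, 8), rep(1:2, each = 4))
  expect_equal(as.numeric(partial_eta_squared_method(const)), 1)
  expect_equal(attr(partial_eta_squared_method(const), "mean_difference"),
               0.02, tolerance = 1e-12)
  # hand-computed mixed case
  du <- c(0.25, 0.20, 0.30, 0.22); dr <- c(0.20, 0.18, 0.26, 0.23)
  mixed <- mk(du, dr, c(1, 1, 2, 2))
  d <- du - dr
  ss_m <- sum(d)^2 / (2 * length(d))
  dev <- d - stats::ave(d, c(1, 1, 2, 2))
  ss_e <- sum(dev^2) / 2
  expect_equal(as.numeric(partial_eta_squared_method(mixed)),
               ss_m / (ss_m + ss_e), tolerance = 1e-12)
  # a table with only one method is unpaired
  solo <- same[same$method == "ULS", ]
  class(solo) <- class(same)
  expect_error(partial_eta_squared_method(solo), "unpaired")
})
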