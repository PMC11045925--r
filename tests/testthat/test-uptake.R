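test_that("per-oocyte normalization divides by pool size", {
  expect_equal(normalize_per_oocyte(500, 10), 50)
  expect_equal(normalize_per_oocyte(0, 10), 0)
  expect_equal(normalize_per_oocyte(c(70, 100), c(7, 10)), c(10, 10))
  expect_error(normalize_per_oocyte(5, 0), ">= 1")
  expect_error(normalize_per_oocyte(-1, 10), ">= 0")
})

test_that("mixed pool sizes are compared on the per-oocyte scale", {
  # same per-oocyte signal measured in pools of 7 and 10
  m <- tibble::tibble(
    transporter = c(rep("T1", 3), rep("GFP_control", 3)),
    compound = "X",
    pool_id = paste0("pool_", c(1:3, 1:3)),
    n_oocytes = c(7, 10, 10, 10, 10, 10),
    response = c(7 * 5, 10 * 5.2, 10 * 4.8, 10 * 1, 10 * 1.1, 10 * 0.9)
  )
  out <- call_uptake(m)
  cond_mean <- mean(out$per_pool$per_oocyte[out$per_pool$transporter == "T1"])
  expect_equal(cond_mean, mean(c(5, 5.2, 4.8)), tolerance = 1e-12)
  expect_equal(out$calls$log2fc_vs_control,
               log2(mean(c(5, 5.2, 4.8)) / mean(c(1, 1.1, 0.9))),
               tolerance = 1e-12)
})

test_that("IQR outlier flags match brute-force fence enumeration", {
  expect_identical(remove_outliers_iqr(c(5, 5, 5, 5))$flagged, numeric(0))
  r <- remove_outliers_iqr(c(10, 11, 12, 13, 50))
  expect_identical(r$flagged, 50)
  expect_identical(r$keep, !oracle_iqr_flags(c(10, 11, 12, 13, 50)))
  # n < 4 guard
  expect_identical(remove_outliers_iqr(c(1, 2, 3))$keep, rep(TRUE, 3))
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    x <- sample(0:20, n, replace = TRUE)
    expect_identical(remove_outliers_iqr(x)$keep, !oracle_iqr_flags(x))
  }
})

test_that("outlier removal is idempotent on replicate-sized sets", {
  set.seed(12)
  n_new <- vapply(1:200, function(i) {
    n <- sample(3:10, 1)
    x <- rlnorm(n, 0, 0.4)
    kept <- remove_outliers_iqr(x)$kept
    length(remove_outliers_iqr(kept)$flagged)
  }, numeric(1))
  expect_gte(mean(n_new == 0), 0.99)
  # exactly nothing for n < 4
  for (i in 1:20) {
    x <- rlnorm(3)
    expect_identical(remove_outliers_iqr(x)$kept, x)
  }
})

test_that("control comparison matches the pooled t-test oracle", {
  same <- compare_to_control(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$log2fc, 0)
  expect_equal(same$p_value, 1)

  cmp <- compare_to_control(c(8, 10, 12), c(0.9, 1.0, 1.1))
  expect_equal(cmp$log2fc, log2(10), tolerance = 1e-12)
  oracle <- oracle_t_two_sided(c(8, 10, 12), c(0.9, 1.0, 1.1))
  expect_equal(cmp$p_value, oracle$p_value, tolerance = 1e-10)
  expect_lt(cmp$p_value, 0.01)

  # scaling both groups leaves the ratio (and Student t) unchanged
  s <- 7.3
  scaled <- compare_to_control(s * c(8, 10, 12), s * c(0.9, 1.0, 1.1))
  expect_equal(scaled$log2fc, cmp$log2fc, tolerance = 1e-12)
  expect_equal(scaled$p_value, cmp$p_value, tolerance = 1e-12)
})

test_that("direction calls follow the control-background logic", {
  expect_identical(call_direction(2.0, 0.01, control_background = FALSE),
                   "import")
  expect_identical(call_direction(-1.5, 0.03, control_background = TRUE),
                   "export")
  expect_identical(call_direction(-1.5, 0.03, control_background = FALSE),
                   "indeterminate")
  expect_identical(call_direction(0.9, 0.2, control_background = TRUE),
                   "none")
})

test_that("background detection requires a consistent nonzero control", {
  expect_false(detect_control_background(c(0, 0, 0)))
  expect_true(detect_control_background(c(1.9, 2.1, 2.0)))
  # zero-variance strictly positive control is significant
  expect_true(detect_control_background(c(2, 2, 2)))
  expect_warning(res <- detect_control_background(0.01), "indeterminate")
  expect_false(res)
})

test_that("significance stars map the conventional levels", {
  expect_identical(significance_stars(c(0.001, 0.01, 0.05, 0.051, NA)),
                   c("***", "**", "*", "ns", "ns"))
})

test_that("uptake calls recover simulated activities with correct signs", {
  design <- recovery_design(n_imp = 30, n_exp = 30, n_null = 40)
  sim <- simulate_oocyte_assay(design, oocyte_sim_params(
    background_ratio = 0.25, noise_cv = 0.2, seed = 13
  ))
  out <- call_uptake(sim$measurements)
  j <- dplyr::left_join(out$calls, sim$truth,
                        by = c("transporter", "compound"))
  imp <- j[j$activity == "importer", ]
  exp_ <- j[j$activity == "exporter", ]
  expect_gte(mean(imp$direction == "import"), 0.85)
  expect_gte(mean(exp_$direction == "export"), 0.85)
  # no wrong-sign significant call
  expect_false(any(imp$direction == "export"))
  expect_false(any(exp_$direction == "import"))
  # every condition is reported once
  expect_identical(nrow(out$calls), nrow(design))
})

test_that("degenerate conditions are marked indeterminate, not dropped", {
  m <- tibble::tibble(
    transporter = c("T1", "GFP_control", "GFP_control"),
    compound = "X",
    pool_id = c("pool_1", "pool_1", "pool_2"),
    n_oocytes = 10,
    response = c(100, 10, 12)
  )
  out <- call_uptake(m)
  expect_identical(out$calls$direction, "indeterminate")
  expect_true(is.na(out$calls$p_value))
})
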