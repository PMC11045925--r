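test_that("all generators are deterministic under a fixed seed", {
  p1 <- serum_sim_params(n_compounds = 30, seed = 42)
  expect_identical(simulate_serum_screen(p1), simulate_serum_screen(p1))

  design <- transporter_truth("T1", "ACA", "importer",
                              accumulation_ratio_A = 2, rate_k = 1)
  p2 <- oocyte_sim_params(seed = 42)
  expect_identical(simulate_oocyte_assay(design, p2),
                   simulate_oocyte_assay(design, p2))

  p3 <- growth_sim_params(seed = 42, t_grid = seq(0, 24, by = 1))
  expect_identical(simulate_growth_curves(p3), simulate_growth_curves(p3))
})

test_that("serum screen label counts match the requested mixture exactly", {
  sim <- simulate_serum_screen(serum_sim_params(
    n_compounds = 1000, frac_consumed = 0.2, frac_secreted = 0.15, seed = 1
  ))
  counts <- table(sim$truth$direction)
  expect_identical(unname(counts[["consumed"]]), 200L)
  expect_identical(unname(counts[["secreted"]]), 150L)
  expect_identical(unname(counts[["unchanged"]]), 650L)
  expect_identical(nrow(sim$responses), 1000L * 6L)
})

test_that("noise-free, effect-free serum screen gives identical groups", {
  sim <- simulate_serum_screen(serum_sim_params(
    n_compounds = 25, frac_consumed = 0, frac_secreted = 0,
    replicate_cv = 0, seed = 2
  ))
  wide <- tidyr::pivot_wider(sim$responses[c("compound_id", "sample_id", "response")],
                             names_from = "sample_id", values_from = "response")
  for (col in setdiff(names(wide), c("compound_id", "control_1"))) {
    expect_equal(wide[[col]], wide$control_1, tolerance = 1e-12)
  }
  expect_true(all(sim$truth$true_log2fc == 0))
})

test_that("noise-free serum effects reproduce their closed-form fold changes", {
  sim <- simulate_serum_screen(serum_sim_params(
    n_compounds = 50, replicate_cv = 0, seed = 3
  ))
  stats <- compute_log2fc_cv(sim$responses)
  j <- dplyr::left_join(stats, sim$truth, by = "compound_id")
  expect_equal(j$log2fc, j$true_log2fc, tolerance = 1e-9)
})

test_that("serum parameter validation rejects impossible mixtures", {
  expect_error(serum_sim_params(frac_consumed = 0.7, frac_secreted = 0.5),
               "<= 1")
  expect_error(serum_sim_params(effect_log2fc_range = c(-1, 1)), "positive")
  expect_error(serum_sim_params(n_replicates_per_group = 1), ">= 2")
})

test_that("oocyte generator hits its closed-form limits", {
  # saturated equilibrative importer, no background, no noise -> C_in = c_medium
  d1 <- transporter_truth("T1", "X", "importer",
                          accumulation_ratio_A = 1, rate_k = 1e6)
  s1 <- simulate_oocyte_assay(d1, oocyte_sim_params(background_ratio = 0,
                                                    noise_cv = 0, seed = 1))
  c_in <- s1$truth$c_in_true[s1$truth$transporter == "T1"]
  expect_equal(c_in, 2.0, tolerance = 1e-9)
  per_oocyte <- with(s1$measurements[s1$measurements$transporter == "T1", ],
                     response / n_oocytes)
  expect_equal(per_oocyte, rep(2.0, 3), tolerance = 1e-9)

  # exporter: beta x background
  d2 <- transporter_truth("T2", "X", "exporter", exporter_factor_beta = 0.3)
  s2 <- simulate_oocyte_assay(d2, oocyte_sim_params(background_ratio = 0.5,
                                                    noise_cv = 0, seed = 1))
  expect_equal(s2$truth$c_in_true[s2$truth$transporter == "T2"], 0.3,
               tolerance = 1e-12)
  # GFP control sits at the background
  expect_equal(s2$truth$c_in_true[s2$truth$transporter == "GFP_control"], 1.0,
               tolerance = 1e-12)
})

test_that("noisy oocyte pools agree with the closed form in expectation", {
  d <- transporter_truth("T1", "X", "importer",
                         accumulation_ratio_A = 4, rate_k = 2)
  s <- simulate_oocyte_assay(d, oocyte_sim_params(
    background_ratio = 0, noise_cv = 0.2, n_pools = 1000, seed = 4
  ))
  expected <- 4 * 2 * (1 - exp(-2 * 3))
  vals <- with(s$measurements[s$measurements$transporter == "T1", ],
               response / n_oocytes)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("expected intracellular concentration is monotone in A", {
  c_ins <- vapply(c(1, 2, 4, 8), function(A) {
    d <- transporter_truth("T", "X", "importer",
                           accumulation_ratio_A = A, rate_k = 1)
    s <- simulate_oocyte_assay(d, oocyte_sim_params(noise_cv = 0, seed = 1))
    s$truth$c_in_true[s$truth$transporter == "T"]
  }, numeric(1))
  expect_true(all(diff(c_ins) > 0))
})

test_that("oocyte design validation catches duplicates and reserved labels", {
  d <- dplyr::bind_rows(
    transporter_truth("T1", "X", "none"),
    transporter_truth("T1", "X", "none")
  )
  expect_error(simulate_oocyte_assay(d), "duplicate")
  expect_error(simulate_oocyte_assay(transporter_truth("GFP_control", "X", "none")),
               "reserved")
  expect_error(transporter_truth("T", "X", "importer", accumulation_ratio_A = 0.5),
               ">= 1")
  expect_error(transporter_truth("T", "X", "exporter", exporter_factor_beta = 1.2),
               "< 1|<= 1")
})

test_that("noiseless growth curves equal the closed-form logistic", {
  p <- growth_sim_params(od_noise_sd = 0, n_replicates = 1,
                         concentrations = c(0, 2.45), seed = 5)
  sim <- simulate_growth_curves(p)
  c0 <- sim$curves[sim$curves$conc_mM == 0, ]
  expect_equal(c0$od, oracle_logistic(c0$time_h, 0.4, 1.2, 0.01),
               tolerance = 1e-12)
  # Hill midpoint: mu and K exactly halved at c = lc50
  tr <- sim$truth[sim$truth$conc_mM == 2.45, ]
  expect_equal(tr$mu_c, 0.4 / 2, tolerance = 1e-12)
  expect_equal(tr$K_c, 1.2 / 2, tolerance = 1e-12)
  # monotone inhibition
  full <- simulate_growth_curves(growth_sim_params(od_noise_sd = 0, seed = 1))
  expect_true(all(diff(full$truth$mu_c) < 0))
})

test_that("replicate-mean noisy growth curves satisfy the Gaussian bound", {
  p <- growth_sim_params(od_noise_sd = 0.02, n_replicates = 3,
                         concentrations = 0, seed = 6)
  sim <- simulate_growth_curves(p)
  mean_curve <- sim$curves |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(od = mean(.data$od), .groups = "drop")
  clean <- oracle_logistic(mean_curve$time_h, 0.4, 1.2, 0.01)
  within <- abs(mean_curve$od - clean) <= 3 * 0.02 / sqrt(3)
  expect_gte(mean(within), 0.99)
})
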