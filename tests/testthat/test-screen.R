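make_table <- function(control, treated) {
  # control/treated: named lists compound -> replicate vector
  rows <- list()
  for (cp in names(control)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      compound_id = cp, class = "metabolite",
      sample_id = paste0("control_", seq_along(control[[cp]])),
      group = "control", replicate = seq_along(control[[cp]]),
      response = control[[cp]]
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      compound_id = cp, class = "metabolite",
      sample_id = paste0("treated_", seq_along(treated[[cp]])),
      group = "treated", replicate = seq_along(treated[[cp]]),
      response = treated[[cp]]
    )
  }
  dplyr::bind_rows(rows)
}

test_that("log2 fold change and CV match their closed forms", {
  tbl <- make_table(
    control = list(A = c(4, 4, 4), B = c(2, 2, 2), C = c(1, 3)),
    treated = list(A = c(1, 1, 1), B = c(2, 2, 2), C = c(1, 3))
  )
  st <- compute_log2fc_cv(tbl)
  a <- st[st$compound_id == "A", ]
  expect_equal(a$log2fc, -2)           # log2(1/4)
  b <- st[st$compound_id == "B", ]
  expect_equal(b$log2fc, 0)
  expect_equal(b$cv_control, b$cv_treated)
  expect_equal(b$cv_control, 0)
  cc <- st[st$compound_id == "C", ]
  expect_equal(cc$cv_control, 100 * sd(c(1, 3)) / 2, tolerance = 1e-12)
  expect_equal(cc$cv_control, 70.71068, tolerance = 1e-6)
})

test_that("zero means invoke the pseudo-count, all-zero compounds are not evaluable", {
  tbl <- make_table(
    control = list(A = c(10, 10), B = c(0, 0)),
    treated = list(A = c(0, 0), B = c(0, 0))
  )
  st <- compute_log2fc_cv(tbl)
  a <- st[st$compound_id == "A", ]
  # auto pseudo = half the smallest positive response = 5
  expect_equal(a$log2fc, log2(5 / 15))
  expect_true(a$evaluable)
  b <- st[st$compound_id == "B", ]
  expect_false(b$evaluable)
  expect_true(is.na(b$log2fc))
  res <- classify_direction(st)
  expect_identical(res$direction[res$compound_id == "B"], "unchanged")
})

test_that("direction thresholds follow the |log2fc| > 0.5 and CV < 30% rule", {
  st <- tibble::tibble(
    compound_id = c("A", "B", "C", "D"),
    mean_control = 1, mean_treated = 1,
    log2fc = c(-1.2, 0.3, 0.8, 1.2),
    cv_control = c(10, 5, 20, 10),
    cv_treated = c(12, 5, 45, 10),
    evaluable = TRUE
  )
  res <- classify_direction(st)
  expect_identical(res$direction, c("consumed", "unchanged", "unchanged",
                                    "secreted"))
  expect_identical(res$passes_filter, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(classify_direction(st, fc_threshold = 0), "> 0")
})

test_that("swapping group labels negates log2fc and swaps consumed/secreted", {
  sim <- simulate_serum_screen(serum_sim_params(n_compounds = 60, seed = 8))
  tbl <- sim$responses
  swapped <- dplyr::mutate(tbl, group = ifelse(group == "control", "treated",
                                               "control"))
  r1 <- classify_direction(compute_log2fc_cv(tbl))
  r2 <- classify_direction(compute_log2fc_cv(swapped))
  j <- dplyr::left_join(r1, r2, by = "compound_id")
  expect_equal(j$log2fc.x, -j$log2fc.y, tolerance = 1e-12)
  expect_identical(j$direction.y[j$direction.x == "consumed"] == "secreted",
                   rep(TRUE, sum(j$direction.x == "consumed")))
  expect_identical(j$direction.y[j$direction.x == "secreted"] == "consumed",
                   rep(TRUE, sum(j$direction.x == "secreted")))
})

test_that("raising the fold-change threshold never adds effect calls", {
  sim <- simulate_serum_screen(serum_sim_params(n_compounds = 150, seed = 9))
  st <- compute_log2fc_cv(sim$responses)
  n_called <- vapply(c(0.25, 0.5, 0.8, 1.2, 2), function(thr) {
    sum(classify_direction(st, fc_threshold = thr)$direction != "unchanged")
  }, numeric(1))
  expect_true(all(diff(n_called) <= 0))
})

test_that("the partition always sums to the number of compounds", {
  for (seed in 1:3) {
    sim <- simulate_serum_screen(serum_sim_params(n_compounds = 80, seed = seed))
    out <- run_exo_screen(sim$responses)
    ov <- out$summary$overall
    expect_identical(ov$consumed + ov$secreted + ov$unchanged, ov$total)
    expect_identical(ov$total, 80L)
  }
})

test_that("per-class summary buckets unknown classes with a warning", {
  sim <- simulate_serum_screen(serum_sim_params(n_compounds = 20, seed = 10))
  res <- classify_direction(compute_log2fc_cv(sim$responses))
  classes <- dplyr::distinct(sim$responses[c("compound_id", "class")])
  classes$class[1] <- "mystery"
  expect_warning(s <- summarize_screen(res, classes), "unknown")
  expect_true("unknown" %in% s$by_class$class)
  expect_identical(sum(s$by_class$consumed + s$by_class$secreted +
                         s$by_class$unchanged), 20L)
})
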