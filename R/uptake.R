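# Oocyte uptake calling: per-oocyte normalization, IQR outlier removal,
# Student's t-test against the GFP-only control, and import/export/none
# direction calls.

#' Normalize a pooled response to a per-oocyte amount
#'
#' Pools of different sizes (e.g. 7 and 10 oocytes) are put on a common
#' per-oocyte scale by dividing the pooled LC-MS response by the number of
#' oocytes extracted.
#'
#' @param response Non-negative pooled response(s).
#' @param n_oocytes Number of oocytes per pool (>= 1), recycled as needed.
#' @return Numeric vector of per-oocyte amounts.
#' @export
#' @examples
#' normalize_per_oocyte(500, 10)
normalize_per_oocyte <- function(response, n_oocytes) {
  if (any(!is.finite(response)) || any(response < 0)) {
    stop("response must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(n_oocytes)) || any(n_oocytes < 1)) {
    stop("n_oocytes must be >= 1", call. = FALSE)
  }
  response / n_oocytes
}

#' Flag outliers by the interquartile method
#'
#' Values outside `[Q1 - k * IQR, Q3 + k * IQR]` are flagged and removed, and
#' by default the fences are recomputed on the kept values until no further
#' value is flagged, so that the statistics redone after removal rest on a
#' stable replicate set (removal is then idempotent by construction).
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). With fewer than 4 values quartiles are not
#' meaningful and nothing is flagged; the same guard ends the iteration.
#'
#' @param values Non-empty numeric vector.
#' @param k Fence multiplier; default 1.5.
#' @param iterate Recompute fences on the kept values until a fixpoint
#'   (default); `FALSE` applies a single pass.
#' @return A list with `kept`, `flagged` and the logical `keep` mask.
#' @export
#' @examples
#' remove_outliers_iqr(c(10, 11, 12, 13, 50))
remove_outliers_iqr <- function(values, k = 1.5, iterate = TRUE) {
  if (length(values) == 0) stop("values must be non-empty", call. = FALSE)
  .assert_scalar_number(k, "k", lower = 0)
  keep <- rep(TRUE, length(values))
  repeat {
    idx <- which(keep)
    if (length(idx) < 4) break
    x <- values[idx]
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    bad <- x < q[1] - k * iqr | x > q[2] + k * iqr
    if (!any(bad)) break
    keep[idx[bad]] <- FALSE
    if (!iterate) break
  }
  list(kept = values[keep], flagged = values[!keep], keep = keep)
}

#' Compare a transporter condition to its control
#'
#' Log2 fold change of group means (with the screen's pseudo-count rule when
#' a mean is zero: half the smallest positive value across both groups) and a
#' two-sided Student's t-test on per-oocyte values. Equal variances are
#' assumed by default, matching the classical Student test; set
#' `var_equal = FALSE` for Welch.
#'
#' @param transporter_vals,control_vals Per-oocyte values (after outlier
#'   removal), >= 2 each for a defined p-value.
#' @param var_equal Use the pooled-variance Student test (default) or Welch.
#' @return A list with `log2fc`, `p_value`, `statistic`, `df`,
#'   `n_transporter`, `n_control`.
#' @export
#' @examples
#' compare_to_control(c(8, 10, 12), c(0.9, 1.0, 1.1))
compare_to_control <- function(transporter_vals, control_vals,
                               var_equal = TRUE) {
  mt <- mean(transporter_vals)
  mc <- mean(control_vals)
  pseudo <- .half_min_positive(c(transporter_vals, control_vals))
  lfc <- .log2_ratio(mt, mc, pseudo)
  ht <- .t_two_sample(transporter_vals, control_vals, var_equal = var_equal)
  list(log2fc = lfc, p_value = ht$p_value, statistic = ht$statistic,
       df = ht$df, n_transporter = length(transporter_vals),
       n_control = length(control_vals))
}

#' Detect endogenous background uptake in control oocytes
#'
#' Export activity is only interpretable when the compound enters GFP-only
#' control oocytes through endogenous transporters or leakage. Background is
#' declared when the control mean exceeds `blank_level` with one-sided
#' significance at `alpha` (a strictly positive zero-variance control counts
#' as significant). A single control value is indeterminate and treated as no
#' background, with a warning.
#'
#' @param control_vals Per-oocyte control values.
#' @param blank_level Blank response level; default 0.
#' @param alpha One-sided significance level.
#' @return `TRUE` when consistent background uptake is present.
#' @export
detect_control_background <- function(control_vals, blank_level = 0,
                                      alpha = 0.05) {
  .assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                        strict_lower = TRUE)
  if (length(control_vals) < 2) {
    warning("fewer than 2 control values; background indeterminate, treated as absent")
    return(FALSE)
  }
  ht <- .t_one_greater(control_vals, blank_level)
  isTRUE(ht$p_value <= alpha) && mean(control_vals) > blank_level
}

#' Call transport direction from effect size and significance
#'
#' Non-significant conditions are `none`. Significant positive log2 fold
#' changes are `import`. Significant negative shifts are `export` only when
#' the control shows endogenous background uptake; without background a
#' negative shift is uninterpretable and called `indeterminate`.
#'
#' @param log2fc Log2 fold change versus the control.
#' @param p_value Two-sided p-value versus the control.
#' @param alpha Significance level; default 0.05.
#' @param control_background Logical, from [detect_control_background()].
#' @return One of `"import"`, `"export"`, `"none"`, `"indeterminate"`.
#' @export
call_direction <- function(log2fc, p_value, alpha = 0.05,
                           control_background = FALSE) {
  .assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                        strict_lower = TRUE)
  if (is.na(p_value) || is.na(log2fc)) return("indeterminate")
  if (p_value > alpha || log2fc == 0) return("none")
  if (log2fc > 0) return("import")
  if (isTRUE(control_background)) "export" else "indeterminate"
}

#' Call uptake for every transporter x compound condition
#'
#' End-to-end caller over an oocyte measurement table: normalizes responses
#' per oocyte, removes IQR outliers within every condition (controls
#' included), tests each transporter condition against the matching GFP-only
#' control with a Student's t-test, and calls the direction of transport.
#'
#' @param measurements Tibble with `transporter`, `compound`, `pool_id`,
#'   `n_oocytes`, `response` (the schema written by
#'   [simulate_oocyte_assay()]).
#' @param alpha Significance level; default 0.05.
#' @param control_label Transporter label of the control rows.
#' @param var_equal Student (default) vs Welch t-test.
#' @param iqr_k IQR fence multiplier.
#' @param blank_level Blank level for background detection.
#' @param bh Apply Benjamini-Hochberg adjustment across conditions before
#'   direction calling (off by default, matching per-comparison testing).
#' @return A list with
#'   * `calls`: one row per non-control condition (`log2fc_vs_control`,
#'     `p_value`, `direction`, `significance_stars`, `n_used`,
#'     `n_outliers_removed`, `control_background`);
#'   * `per_pool`: long tibble of per-oocyte normalized values with outlier
#'     flags.
#' @export
#' @examples
#' design <- transporter_truth("T1", "ACA", "importer",
#'                             accumulation_ratio_A = 4, rate_k = 2)
#' sim <- simulate_oocyte_assay(design, oocyte_sim_params(seed = 1))
#' call_uptake(sim$measurements)$calls
call_uptake <- function(measurements, alpha = 0.05,
                        control_label = "GFP_control", var_equal = TRUE,
                        iqr_k = 1.5, blank_level = 0, bh = FALSE) {
  measurements <- tibble::as_tibble(measurements)
  needed <- c("transporter", "compound", "pool_id", "n_oocytes", "response")
  if (!all(needed %in% names(measurements))) {
    stop("measurements need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!any(measurements$transporter == control_label)) {
    stop("no control rows with transporter '", control_label, "'",
         call. = FALSE)
  }

  per_pool <- measurements |>
    dplyr::mutate(per_oocyte = normalize_per_oocyte(.data$response,
                                                    .data$n_oocytes)) |>
    dplyr::group_by(.data$transporter, .data$compound) |>
    dplyr::mutate(outlier = !remove_outliers_iqr(.data$per_oocyte, k = iqr_k)$keep) |>
    dplyr::ungroup()

  kept <- dplyr::filter(per_pool, !.data$outlier)
  controls <- split(
    kept$per_oocyte[kept$transporter == control_label],
    kept$compound[kept$transporter == control_label]
  )

  cond <- per_pool |>
    dplyr::filter(.data$transporter != control_label) |>
    dplyr::distinct(.data$transporter, .data$compound)

  rows <- lapply(seq_len(nrow(cond)), function(i) {
    tr <- cond$transporter[i]
    cp <- cond$compound[i]
    sel <- per_pool$transporter == tr & per_pool$compound == cp
    vals <- per_pool$per_oocyte[sel & !per_pool$outlier]
    n_out <- sum(per_pool$outlier[sel])
    ctrl <- controls[[cp]]
    if (is.null(ctrl)) ctrl <- numeric(0)
    bg <- if (length(ctrl) >= 2) {
      detect_control_background(ctrl, blank_level = blank_level, alpha = alpha)
    } else {
      FALSE
    }
    cmp <- if (length(vals) >= 2 && length(ctrl) >= 2) {
      compare_to_control(vals, ctrl, var_equal = var_equal)
    } else {
      list(log2fc = NA_real_, p_value = NA_real_)
    }
    tibble::tibble(
      transporter = tr, compound = cp,
      n_used = length(vals), n_outliers_removed = n_out,
      log2fc_vs_control = cmp$log2fc, p_value = cmp$p_value,
      control_background = bg
    )
  })
  calls <- dplyr::bind_rows(rows)
  if (bh) calls$p_value <- stats::p.adjust(calls$p_value, method = "BH")
  calls$direction <- mapply(call_direction, calls$log2fc_vs_control,
                            calls$p_value,
                            MoreArgs = list(alpha = alpha),
                            control_background = calls$control_background)
  calls$significance_stars <- significance_stars(calls$p_value)
  list(calls = calls, per_pool = per_pool)
}
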